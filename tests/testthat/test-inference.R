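# independent oracle: exact two-tailed Mann-Whitney p by enumerating all
# C(n1+n2, n1) rank assignments
enum_mw_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u_min <- min(u_obs, n1 * n2 - u_obs)
  picks <- utils::combn(n1 + n2, n1)
  all_r <- seq_len(n1 + n2)
  us <- apply(picks, 2, function(idx) sum(all_r[idx]) - n1 * (n1 + 1) / 2)
  us_min <- pmin(us, n1 * n2 - us)
  mean(us_min <= u_min)
}

test_that("Mann-Whitney U statistics, ranks and identities", {
  res <- mann_whitney_u(c(1, 2), c(1, 2))
  expect_equal(res$U1, 2)          # mid-ranks: U1 = U2 = n1*n2/2
  expect_equal(res$U2, 2)
  set.seed(11)
  for (i in 1:25) {
    n1 <- sample(2:15, 1); n2 <- sample(2:15, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    r <- mann_whitney_u(x, y)
    expect_equal(r$U1 + r$U2, n1 * n2)
    # mean ranks weighted-average to (N+1)/2
    expect_equal((r$mean_rank_1 * n1 + r$mean_rank_2 * n2) / (n1 + n2),
                 (n1 + n2 + 1) / 2)
    expect_true(r$eta_sq >= 0 && r$eta_sq <= 1)
    expect_equal(r$U, min(r$U1, r$U2))
  }
})

test_that("exact Mann-Whitney p matches full enumeration", {
  # canonical: n1 = n2 = 3, most extreme separation has U = 0 and p = 2/20
  res <- mann_whitney_u(1:3, 4:6)
  expect_equal(res$U, 0)
  expect_equal(res$p, 0.1)
  expect_equal(enum_mw_p(1:3, 4:6), 0.1)
  set.seed(21)
  for (i in 1:8) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    expect_equal(mann_whitney_u(x, y)$p, enum_mw_p(x, y))
  }
})

test_that("normal approximation agrees with enumeration for small samples", {
  # The uncorrected normal tail approximates the mid-p of the discrete exact
  # distribution (half weight on the observed point); compare on that scale,
  # over every achievable U for all group sizes 5..8.
  for (n1 in 5:8) for (n2 in 5:8) {
    picks <- utils::combn(n1 + n2, n1)
    us <- apply(picks, 2, function(idx) sum(idx) - n1 * (n1 + 1) / 2)
    sigma <- sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
    for (u in 0:floor(n1 * n2 / 2)) {
      p_norm <- 2 * pnorm(-abs(u - n1 * n2 / 2) / sigma)
      p_mid <- min(1, 2 * (mean(us < u) + 0.5 * mean(us == u)))
      expect_lt(abs(p_norm - p_mid), 0.03)
    }
  }
})

test_that("tied data fall back to the tie-corrected normal approximation", {
  x <- c(1, 2, 2, 3, 5); y <- c(2, 3, 3, 4, 6)
  r <- mann_whitney_u(x, y)
  expect_equal(r$method, "normal approximation")
  ref <- suppressWarnings(stats::wilcox.test(x, y, correct = FALSE))
  expect_equal(r$p, ref$p.value, tolerance = 1e-10)
  expect_warning(res0 <- mann_whitney_u(rep(1, 4), rep(1, 5)), "identical")
  expect_equal(res0$p, 1)
})

test_that("U reconstruction from mean ranks and report formatting", {
  expect_equal(u_from_mean_rank(7.55, 11), 17)
  expect_equal(u_from_mean_rank(3.5, 6), 0)
  r <- mann_whitney_u(c(5, 6, 7, 10), c(1, 2, 3, 4))
  # U1 = 26 - 10 = 16, U2 = 0; exact p = 2/70; Z = 8/sqrt(12), eta2 = Z^2/8
  expect_match(format_rank_test(r),
               "^U=0; p=0\\.0286; eta2=0\\.67; M rank=6\\.50$")
})

# oracle: exact signed-rank p by enumerating all 2^n sign patterns
enum_wsr_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- min(sum(r[d > 0]), sum(r[d < 0]))
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  ws <- apply(signs, 1, function(sg) {
    wp <- sum(r[sg]); min(wp, sum(r) - wp)
  })
  mean(ws <= w_obs)
}

test_that("Wilcoxon signed-rank statistics and conventions", {
  r <- wilcoxon_signed_rank(c(1, 2, 3))
  expect_equal(r$W, 0)             # one-sided extreme
  expect_equal(r$W_plus, 6)
  # zeros dropped
  expect_equal(wilcoxon_signed_rank(c(0, 0, 1, -2, 3))$n_nonzero, 3)
  expect_error(wilcoxon_signed_rank(c(0, 0, 0)), "zero")
  # W_plus matches the standard implementation
  set.seed(41)
  d <- rnorm(9)
  expect_equal(wilcoxon_signed_rank(d)$W_plus,
               unname(suppressWarnings(stats::wilcox.test(d))$statistic))
})

test_that("signed-rank normal approximation agrees with sign enumeration", {
  # n = 6 distinct |d|: enumerate all 2^6 sign patterns; the uncorrected
  # normal tail tracks the enumeration mid-p within 0.02 wherever the test
  # could reject (mid-p <= 0.3), within 0.05 elsewhere
  n <- 6
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  wp <- apply(signs, 1, function(sg) sum(seq_len(n)[sg]))
  sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24)
  for (w in 0:floor(n * (n + 1) / 4)) {
    p_norm <- 2 * pnorm((w - n * (n + 1) / 4) / sigma)
    p_mid <- min(1, 2 * (mean(wp < w) + 0.5 * mean(wp == w)))
    expect_lt(abs(p_norm - p_mid), if (p_mid <= 0.3) 0.02 else 0.05)
  }
  # and the implementation reproduces the enumeration convention end to end
  set.seed(42)
  d <- rnorm(6)
  r <- wilcoxon_signed_rank(d)
  expect_lt(abs(r$p - enum_wsr_p(d)), 0.1)
})

test_that("normal-tail reporting matches the conventional rounding", {
  expect_equal(round(2 * pnorm(-2.67), 3), 0.008)
  # an n = 11 design with W = 1 gives Z = -32/sqrt(126.5) = -2.85, p = 0.004
  r <- wilcoxon_signed_rank(c(-1, 2:11))
  expect_equal(round(r$Z, 2), -2.85)
  expect_equal(round(r$p, 3), 0.004)
  expect_equal(r$p, 2 * pnorm(r$Z))
})

test_that("Friedman statistic: closed forms and reference implementation", {
  # all conditions identical within subjects -> chi2 = 0
  m <- matrix(rep(c(1, 2, 3), each = 4), nrow = 4)
  m[] <- 5
  expect_equal(friedman_rank_test(m)$chi_sq, 0)
  # n = 2 subjects ranking k = 3 conditions identically:
  # chi2 = 0.5 * (4 + 16 + 36) - 24 = 4
  m2 <- rbind(c(1, 5, 9), c(2, 4, 8))
  expect_equal(friedman_rank_test(m2)$chi_sq, 4)
  expect_equal(friedman_rank_test(m2)$df, 2)
  # untied random matrix: match stats::friedman.test exactly
  set.seed(51)
  m3 <- matrix(rnorm(44), 11, 4)
  ref <- stats::friedman.test(m3)
  r3 <- friedman_rank_test(m3)
  expect_equal(r3$chi_sq, unname(ref$statistic))
  expect_equal(r3$p, ref$p.value)
  expect_error(friedman_rank_test(rbind(c(1, NA), c(2, 3))), "missing")
})

test_that("Friedman permutation p agrees with the asymptotic p for moderate n", {
  set.seed(52)
  m <- matrix(rnorm(40), 10, 4)
  r_asym <- friedman_rank_test(m)
  r_perm <- friedman_rank_test(m, exact = TRUE, n_perm = 4000)
  expect_lt(abs(r_asym$p - r_perm$p), 0.06)
})

test_that("mixed ANOVA matches an aov + covariance-matrix oracle", {
  set.seed(61)
  n_per <- 6; k <- 3
  d <- data.frame(
    subject = rep(1:(2 * n_per), each = k),
    group = rep(c("wt", "app"), each = n_per * k),
    time = factor(rep(1:k, 2 * n_per)),
    value = rnorm(2 * n_per * k) + rep(rnorm(2 * n_per), each = k))
  res <- mixed_anova(d, "subject", "group", "time", "value")
  # oracle for the F ratios: stats::aov with an Error stratum
  ref <- summary(stats::aov(value ~ group * time + Error(factor(subject) / time),
                            data = d))
  f_between <- ref[["Error: factor(subject)"]][[1]]["group", "F value"]
  f_within <- ref[["Error: factor(subject):time"]][[1]]["time", "F value"]
  f_inter <- ref[["Error: factor(subject):time"]][[1]]["group:time", "F value"]
  tab <- res$table
  expect_equal(tab$F[tab$effect == "between"], f_between, tolerance = 1e-8)
  expect_equal(tab$F[tab$effect == "within"], f_within, tolerance = 1e-8)
  expect_equal(tab$F[tab$effect == "interaction"], f_inter, tolerance = 1e-8)
  # oracle for epsilon: orthonormal-contrast form on the pooled covariance
  wide <- matrix(d$value, ncol = k, byrow = TRUE)
  grp <- rep(c("wt", "app"), each = n_per)
  S <- (cov(wide[grp == "wt", ]) * (n_per - 1) +
          cov(wide[grp == "app", ]) * (n_per - 1)) / (2 * n_per - 2)
  C <- t(qr.Q(qr(cbind(1, contr.poly(k))))[, -1])   # orthonormal contrasts
  M <- C %*% S %*% t(C)
  eps_ref <- sum(diag(M))^2 / ((k - 1) * sum(M^2))
  expect_equal(res$epsilon, eps_ref, tolerance = 1e-8)
  expect_true(all(tab$df1[2:3] <= c(k - 1, k - 1)))
})

test_that("mixed ANOVA limiting cases", {
  # two within levels: sphericity holds, epsilon = 1
  d2 <- data.frame(subject = rep(1:8, each = 2),
                   group = rep(c("a", "b"), each = 8),
                   time = rep(1:2, 8),
                   value = rnorm(16))
  expect_equal(mixed_anova(d2)$epsilon, 1)
  # identical groups: between-effect F = 0
  base <- data.frame(subject = rep(1:4, each = 3), time = rep(1:3, 4),
                     value = rep(c(1, 2, 3, 4), each = 3) + rep(0:2, 4))
  d0 <- rbind(transform(base, group = "a"),
              transform(base, subject = subject + 10, group = "b"))
  res0 <- mixed_anova(d0)
  expect_equal(res0$table$F[res0$table$effect == "between"], 0)
  # unbalanced design rejected
  d_bad <- d2[-1, ]
  expect_error(mixed_anova(d_bad), "unbalanced")
})

test_that("Bonferroni interpretation of comparison families", {
  fam <- bonferroni_family(c(0.021, 0.004, 0.3, 0.012), alpha = 0.05, m = 4)
  expect_equal(unique(fam$adjusted_alpha), 0.0125)
  expect_equal(fam$significant, c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(bonferroni_family(0.04, m = 1)$significant, TRUE)
  expect_error(bonferroni_family(0.04, m = 0), "m must be")
})
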