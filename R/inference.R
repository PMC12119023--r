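#' Rank-based and repeated-measures inference battery
#'
#' Implements the statistical battery used for longitudinal bouton dynamics:
#' Mann-Whitney U between genotype groups (with mean ranks, tie-corrected Z
#' and eta-squared), Wilcoxon signed-rank for pre- vs post-stimulation paired
#' comparisons, the Friedman rank test for stability across baseline
#' sessions, a one-between / one-within mixed ANOVA with Greenhouse-Geisser
#' sphericity correction for densities, and Bonferroni adjustment of
#' comparison families.
#'
#' @name inference
NULL

# tie correction term sum(t^3 - t) over tie groups of a rank vector's source values
.tie_term <- function(v) {
  t <- table(v)
  sum(t^3 - t)
}

#' Mann-Whitney U test with mean ranks and rank eta-squared
#'
#' Ranks the pooled sample with mid-ranks for ties.  `U_g = R_g - n_g(n_g+1)/2`
#' for each group; the reported `U` is `min(U1, U2)`.  `Z` uses the normal
#' approximation with tie-corrected variance and no continuity correction;
#' the effect size is `eta_sq = Z^2 / N`.  For untied samples with both sizes
#' at most `exact_max`, the two-tailed p comes from the exact U distribution;
#' otherwise from the normal approximation.
#'
#' @param x,y Numeric vectors, the two groups.
#' @param exact_max Largest group size for which the exact null distribution
#'   of U is used (untied data only).
#' @return An object of class `rank_test` with fields `U` (reported,
#'   min of the two), `U1`, `U2`, `mean_rank_1`, `mean_rank_2`, `n1`, `n2`,
#'   `Z`, `p`, `eta_sq`, `method`.
#' @export
mann_whitney_u <- function(x, y, exact_max = 12) {
  x <- as.numeric(x); y <- as.numeric(y)
  stopifnot(length(x) >= 1, length(y) >= 1, all(is.finite(c(x, y))))
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled)            # mid-ranks
  R1 <- sum(r[seq_len(n1)]); R2 <- sum(r[n1 + seq_len(n2)])
  U1 <- R1 - n1 * (n1 + 1) / 2
  U2 <- R2 - n2 * (n2 + 1) / 2
  ties <- .tie_term(pooled)
  if (ties == N^3 - N) {       # every value identical: no information
    warning("all values identical across both groups; p = 1")
    res <- list(U = U1, U1 = U1, U2 = U2,
                mean_rank_1 = R1 / n1, mean_rank_2 = R2 / n2,
                n1 = n1, n2 = n2, Z = 0, p = 1, eta_sq = 0,
                method = "degenerate")
    class(res) <- "rank_test"
    return(res)
  }
  sigma2 <- n1 * n2 / 12 * ((N + 1) - ties / (N * (N - 1)))
  Z <- (U1 - n1 * n2 / 2) / sqrt(sigma2)
  if (ties == 0 && n1 <= exact_max && n2 <= exact_max) {
    u_min <- min(U1, U2)
    p <- min(1, 2 * stats::pwilcox(u_min, n1, n2))
    method <- "exact"
  } else {
    p <- 2 * stats::pnorm(-abs(Z))
    method <- "normal approximation"
  }
  res <- list(U = min(U1, U2), U1 = U1, U2 = U2,
              mean_rank_1 = R1 / n1, mean_rank_2 = R2 / n2,
              n1 = n1, n2 = n2, Z = Z, p = p,
              eta_sq = Z^2 / N, method = method)
  class(res) <- "rank_test"
  res
}

#' Reconstruct a Mann-Whitney U statistic from a group's mean rank
#'
#' Rank arithmetic: with rank sum `R = mean_rank * n`,
#' `U = R - n(n+1)/2`.  Useful for recovering U statistics from reported
#' mean ranks.
#'
#' @param mean_rank Mean rank of the group within the pooled ranking.
#' @param n Group size.
#' @param digits Rounding applied to the result (mean ranks are usually
#'   printed to 2 decimals; the reconstructed U is an integer for untied data).
#' @return The U statistic for that group.
#' @export
u_from_mean_rank <- function(mean_rank, n, digits = 0) {
  stopifnot(n >= 1, mean_rank >= 1)
  round(mean_rank * n - n * (n + 1) / 2, digits)
}

#' Format a rank test in the conventional report style
#'
#' @param rt A `rank_test` object.
#' @return A string like `"U=17; p=0.003; eta2=0.38; M rank=14.45"` using the
#'   larger group mean rank.
#' @export
format_rank_test <- function(rt) {
  stopifnot(inherits(rt, "rank_test"))
  sprintf("U=%g; p=%s; eta2=%s; M rank=%s",
          rt$U,
          formatC(rt$p, format = "fg", digits = 3),
          formatC(rt$eta_sq, format = "fg", digits = 2),
          formatC(max(rt$mean_rank_1, rt$mean_rank_2), format = "f", digits = 2))
}

#' @export
print.rank_test <- function(x, ...) {
  cat("Mann-Whitney U (", x$method, ")\n", sep = "")
  cat(format_rank_test(x), "\n")
  cat(sprintf("  U1=%g U2=%g  n1=%d n2=%d  Z=%.3f\n", x$U1, x$U2, x$n1, x$n2, x$Z))
  invisible(x)
}

#' Wilcoxon signed-rank test for paired differences
#'
#' Zero differences are dropped; absolute differences receive mid-ranks.
#' `W` is the smaller of the positive and negative rank sums.  `Z` is the
#' normal deviate of `W` with tie-corrected variance and no continuity
#' correction (so `Z <= 0` always); the two-tailed p uses the normal
#' approximation.
#'
#' @param d Numeric vector of paired differences, or first member of each pair
#'   if `y` is given.
#' @param y Optional second member of each pair; differences are `d - y`.
#' @return An object of class `signed_rank_test` with `W`, `W_plus`,
#'   `W_minus`, `n_nonzero`, `Z`, `p`.
#' @export
wilcoxon_signed_rank <- function(d, y = NULL) {
  if (!is.null(y)) d <- as.numeric(d) - as.numeric(y)
  d <- as.numeric(d)
  stopifnot(all(is.finite(d)))
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all paired differences are zero; no test possible")
  r <- rank(abs(d))
  W_plus <- sum(r[d > 0]); W_minus <- sum(r[d < 0])
  W <- min(W_plus, W_minus)
  ties <- .tie_term(abs(d))
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - ties / 48
  Z <- (W - n * (n + 1) / 4) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(Z))
  res <- list(W = W, W_plus = W_plus, W_minus = W_minus,
              n_nonzero = n, Z = Z, p = p)
  class(res) <- "signed_rank_test"
  res
}

#' @export
print.signed_rank_test <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank: W=%g (n=%d nonzero), Z=%.2f, p=%.3g\n",
              x$W, x$n_nonzero, x$Z, x$p))
  invisible(x)
}

#' Friedman rank test for repeated measures
#'
#' Ranks conditions within each subject (mid-ranks for ties) and computes
#' `chi2 = 12 / (n k (k+1)) * sum(R_j^2) - 3 n (k+1)` with the standard tie
#' correction divisor `1 - sum(t^3 - t) / (n k (k^2 - 1))`; p is asymptotic
#' chi-squared with `k - 1` degrees of freedom.  Set `exact = TRUE` for a
#' permutation p-value (all `k!^n` within-subject orderings sampled
#' exhaustively for tiny designs, by Monte Carlo otherwise).
#'
#' @param mat Numeric matrix, subjects in rows, conditions in columns; no
#'   missing cells.
#' @param exact Use a permutation p-value instead of the asymptotic one.
#' @param n_perm Number of Monte Carlo permutations when `exact = TRUE` and
#'   full enumeration is infeasible.
#' @return An object of class `friedman_test_result` with `chi_sq`, `df`, `p`.
#' @export
friedman_rank_test <- function(mat, exact = FALSE, n_perm = 10000) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("missing cells; remove incomplete subjects before testing")
  n <- nrow(mat); k <- ncol(mat)
  stopifnot(n >= 2, k >= 2)
  stat <- .friedman_stat(mat)
  if (exact) {
    obs <- stat
    cnt <- 0L
    for (b in seq_len(n_perm)) {
      perm <- t(apply(mat, 1, sample))
      if (.friedman_stat(perm) >= obs - 1e-12) cnt <- cnt + 1L
    }
    p <- (cnt + 1) / (n_perm + 1)
  } else {
    p <- stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
  }
  res <- list(chi_sq = stat, df = k - 1, p = p, n = n, k = k)
  class(res) <- "friedman_test_result"
  res
}

.friedman_stat <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  rk <- t(apply(mat, 1, rank))
  Rj <- colSums(rk)
  chi <- 12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
  ties <- sum(apply(mat, 1, function(row) .tie_term(row)))
  corr <- 1 - ties / (n * k * (k^2 - 1))
  if (corr <= 0) return(0)   # all rows fully tied
  chi / corr
}

#' @export
print.friedman_test_result <- function(x, ...) {
  cat(sprintf("Friedman test: chi2(%d)=%.3f, p=%.3g (n=%d subjects, k=%d conditions)\n",
              x$df, x$chi_sq, x$p, x$n, x$k))
  invisible(x)
}

#' Mixed ANOVA (one between-subjects, one within-subjects factor)
#'
#' Classical univariate decomposition for a balanced one-between /
#' one-within design: the between-subjects effect is tested against
#' subjects-within-groups; the within-subjects effect and the interaction are
#' tested against the subject-by-within residual, with Greenhouse-Geisser
#' epsilon (estimated from the pooled within-group covariance of the repeated
#' measures) applied to the within and interaction degrees of freedom.
#' Effect sizes are partial eta-squared.
#'
#' @param data Data frame in long format.
#' @param subject,between,within,value Column names (strings).
#' @return Object of class `mixed_anova_result`: a data frame `table` with one
#'   row per effect (`between`, `within`, `interaction`) holding `F`, `df1`,
#'   `df2` (epsilon-corrected, fractional for within effects), `p`,
#'   `partial_eta_sq`, plus `epsilon` (GG estimate).
#' @export
mixed_anova <- function(data, subject = "subject", between = "group",
                        within = "time", value = "value") {
  stopifnot(all(c(subject, between, within, value) %in% names(data)))
  d <- data.frame(subject = factor(data[[subject]]),
                  group = factor(data[[between]]),
                  time = factor(data[[within]]),
                  y = as.numeric(data[[value]]))
  if (anyNA(d$y)) stop("missing values not supported")
  k <- nlevels(d$time)
  # wide matrix: one row per subject
  wide <- stats::xtabs(y ~ subject + time, data = d)
  counts <- stats::xtabs(~ subject + time, data = d)
  if (any(counts != 1)) stop("unbalanced within-subject design: every subject needs exactly one value per within level")
  grp_of <- d$group[match(rownames(wide), as.character(d$subject))]
  W <- matrix(as.numeric(wide), nrow = nrow(wide), ncol = k)
  n_tot <- nrow(W)
  G <- nlevels(d$group)
  if (any(table(grp_of) < 2)) stop("each group needs at least 2 subjects")

  grand <- mean(W)
  subj_means <- rowMeans(W)
  time_means <- colMeans(W)
  grp_means <- tapply(subj_means, grp_of, mean)
  cell_means <- rowsum(W, grp_of) / as.vector(table(grp_of))

  SS_total <- sum((W - grand)^2)
  SS_subj <- k * sum((subj_means - grand)^2)
  SS_between <- k * sum(table(grp_of) * (grp_means - grand)^2)
  SS_subj_within <- SS_subj - SS_between
  SS_time <- n_tot * sum((time_means - grand)^2)
  SS_cells <- sum(as.vector(table(grp_of)) * (cell_means - grand)^2)
  SS_inter <- SS_cells - SS_between - SS_time
  SS_err_within <- SS_total - SS_subj - SS_time - SS_inter

  df_between <- G - 1
  df_subj_within <- n_tot - G
  df_time <- k - 1
  df_inter <- (G - 1) * (k - 1)
  df_err_within <- (n_tot - G) * (k - 1)

  # Greenhouse-Geisser epsilon from the pooled within-group covariance
  S <- matrix(0, k, k)
  for (g in levels(grp_of)) {
    Wg <- W[grp_of == g, , drop = FALSE]
    S <- S + stats::cov(Wg) * (nrow(Wg) - 1)
  }
  S <- S / (n_tot - G)
  # double-centred covariance; epsilon = (sum lambda)^2 / ((k-1) sum lambda^2)
  Cmat <- diag(k) - 1 / k
  Sc <- Cmat %*% S %*% Cmat
  ev <- eigen(Sc, symmetric = TRUE, only.values = TRUE)$values
  ev <- ev[ev > max(ev) * 1e-12]
  eps <- if (k == 2) 1 else min(1, sum(ev)^2 / ((k - 1) * sum(ev^2)))
  eps <- max(eps, 1 / (k - 1))

  Fs <- c(between = (SS_between / df_between) / (SS_subj_within / df_subj_within),
          within = (SS_time / df_time) / (SS_err_within / df_err_within),
          interaction = (SS_inter / df_inter) / (SS_err_within / df_err_within))
  tab <- data.frame(
    effect = c("between", "within", "interaction"),
    F = as.numeric(Fs),
    df1 = c(df_between, df_time * eps, df_inter * eps),
    df2 = c(df_subj_within, df_err_within * eps, df_err_within * eps),
    partial_eta_sq = c(SS_between / (SS_between + SS_subj_within),
                       SS_time / (SS_time + SS_err_within),
                       SS_inter / (SS_inter + SS_err_within)),
    stringsAsFactors = FALSE
  )
  tab$p <- stats::pf(tab$F, tab$df1, tab$df2, lower.tail = FALSE)
  res <- list(table = tab, epsilon = eps,
              ss = c(between = SS_between, subj_within = SS_subj_within,
                     within = SS_time, interaction = SS_inter,
                     err_within = SS_err_within, total = SS_total))
  class(res) <- "mixed_anova_result"
  res
}

#' @export
print.mixed_anova_result <- function(x, ...) {
  cat(sprintf("Mixed ANOVA (GG epsilon = %.3f)\n", x$epsilon))
  tab <- x$table
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-11s F(%.2f, %.2f) = %.3f, p = %.3g, partial eta2 = %.3f\n",
                tab$effect[i], tab$df1[i], tab$df2[i], tab$F[i], tab$p[i],
                tab$partial_eta_sq[i]))
  }
  invisible(x)
}

#' Bonferroni interpretation of a family of p-values
#'
#' Keeps the raw p-values and lowers the significance threshold to
#' `alpha / m`, flagging each comparison.
#'
#' @param p Numeric vector of p-values.
#' @param alpha Familywise alpha (default 0.05).
#' @param m Number of comparisons in the family (defaults to `length(p)`).
#' @return A data frame with `p`, `adjusted_alpha`, `significant`.
#' @export
bonferroni_family <- function(p, alpha = 0.05, m = length(p)) {
  if (m < 1) stop("m must be at least 1")
  stopifnot(all(p >= 0 & p <= 1))
  data.frame(p = p, alpha = alpha, m = m,
             adjusted_alpha = alpha / m,
             significant = p < alpha / m)
}
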