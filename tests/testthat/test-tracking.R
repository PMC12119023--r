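mk_obs <- function(pos, session, type = "TB", axon = "ax1", size = 1.5) {
  n <- length(pos)
  data.frame(axon_id = rep(axon, n), session = rep(session, n),
             type = rep(type, n), arc_pos_um = pos,
             intensity_ratio = rep(if (type == "EPB") size else NA_real_, n),
             protrusion_len_um = rep(if (type == "TB") size else NA_real_, n),
             z_extent_planes = rep(3L, n), stringsAsFactors = FALSE)
}

# oracle: optimal assignment by brute force over permutations (small n)
optimal_match_cost <- function(pa, pb, tol) {
  if (!length(pa) || !length(pb)) return(0L)
  k <- min(length(pa), length(pb))
  best <- 0L
  idx_a <- seq_along(pa); idx_b <- seq_along(pb)
  combos_a <- utils::combn(idx_a, k, simplify = FALSE)
  perms <- function(v) if (length(v) <= 1) list(v) else
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  for (ca in combos_a) for (cb in utils::combn(idx_b, k, simplify = FALSE)) {
    for (pb_perm in perms(cb)) {
      d <- abs(pa[ca] - pb[pb_perm])
      best <- max(best, sum(d <= tol))
    }
  }
  best
}

test_that("greedy matching pairs by distance within tolerance", {
  a <- mk_obs(c(10, 20, 30), 1)
  b <- mk_obs(c(10, 20, 30), 2)
  m <- match_consecutive(a, b, 2)
  expect_equal(nrow(m), 3)
  expect_equal(m$dist_um, rep(0, 3))
  # 1 um displacement within 2 um tolerance -> matched
  m2 <- match_consecutive(mk_obs(10, 1), mk_obs(11, 2), 2)
  expect_equal(nrow(m2), 1)
  # 5 um displacement beyond tolerance -> unmatched (one loss + one gain)
  m3 <- match_consecutive(mk_obs(10, 1), mk_obs(15, 2), 2)
  expect_equal(nrow(m3), 0)
  expect_error(match_consecutive(mk_obs(10, 1, axon = "ax1"),
                                 mk_obs(10, 2, axon = "ax2")), "mix")
})

test_that("greedy matching attains the optimal assignment on small instances", {
  set.seed(71)
  for (i in 1:30) {
    na <- sample(0:5, 1); nb <- sample(0:5, 1)
    pa <- sort(runif(na, 0, 40)); pb <- sort(runif(nb, 0, 40))
    m <- match_consecutive(mk_obs(pa, 1), mk_obs(pb, 2), 2)
    expect_equal(nrow(m), optimal_match_cost(pa, pb, 2))
  }
})

test_that("track construction follows correspondence chains", {
  # present in all sessions -> a single track, no events after classification
  obs <- do.call(rbind, lapply(1:9, function(s) mk_obs(10, s)))
  tr <- classify_presence(build_tracks(obs, 9))
  expect_equal(length(unique(tr$track_id)), 1)
  expect_true(all(tr$present))
  expect_true(all(tr$event == ""))
  # observation only at session 4 -> gain at 4, loss at 5
  tr2 <- classify_presence(build_tracks(mk_obs(10, 4), 9))
  expect_equal(tr2$present, c(rep(FALSE, 3), TRUE, rep(FALSE, 5)))
  expect_equal(tr2$event[4], "gain")
  expect_equal(tr2$event[5], "loss")
})

test_that("tracking truth observations reproduces the simulated life histories", {
  cfg <- world_config(n_axons = 4, p_loss = 0.08, init_density_per_um = 0.12,
                      seed = 12)
  w <- generate_worlds(cfg)
  tracked <- classify_presence(build_tracks(truth_observations(w), 9, tol_um = 2))
  truth <- truth_tracks(w)
  for (axon in unique(truth$axon_id)) {
    for (s in 1:9) {
      expect_equal(sum(tracked$present[tracked$axon_id == axon & tracked$session == s]),
                   sum(truth$present[truth$axon_id == axon & truth$session == s]))
      expect_equal(sum(tracked$event[tracked$axon_id == axon & tracked$session == s] == "gain"),
                   sum(truth$event[truth$axon_id == axon & truth$session == s] == "gain"))
      expect_equal(sum(tracked$event[tracked$axon_id == axon & tracked$session == s] == "loss"),
                   sum(truth$event[truth$axon_id == axon & truth$session == s] == "loss"))
    }
  }
})

test_that("TB presence follows the establishment / loss hysteresis", {
  # lengths 1.2, 0.6, 0.3: present, present, lost at session 3
  t1 <- classify_presence(raw_track(c(1.2, 0.6, 0.3)))
  expect_equal(t1$present, c(TRUE, TRUE, FALSE))
  expect_equal(t1$event, c("", "", "loss"))
  # never reaches 1 um: never present, no events
  t2 <- classify_presence(raw_track(c(0.7, 0.8, 0.9)))
  expect_true(all(!t2$present))
  expect_true(all(t2$event == ""))
  # establishes late: absent, present (gain at 2), present
  t3 <- classify_presence(raw_track(c(0.5, 1.1, 0.5)))
  expect_equal(t3$present, c(FALSE, TRUE, TRUE))
  expect_equal(t3$event, c("", "gain", ""))
  # after a loss, presence needs re-establishment at >= 1 um
  t4 <- classify_presence(raw_track(c(1.2, 0.3, 0.6, 0.9, 1.0, 0.5)))
  expect_equal(t4$present, c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(t4$event, c("", "loss", "", "", "gain", ""))
})

test_that("no TB track resumes presence without re-establishment", {
  set.seed(81)
  for (i in 1:40) {
    sizes <- runif(9, 0.2, 1.6)
    sizes[runif(9) < 0.2] <- NA
    tr <- classify_presence(raw_track(sizes))
    p <- tr$present
    resume <- which(diff(p) == 1) + 1
    for (s in resume) {
      expect_gte(tr$size[s], 1.0)
    }
  }
})

test_that("EPB presence applies the ratio and z-plane criteria", {
  t1 <- classify_presence(raw_track(c(2.5, 1.5, 2.1), type = "EPB", z = 3L))
  expect_equal(t1$present, c(TRUE, FALSE, TRUE))
  t2 <- classify_presence(raw_track(c(2.5, 2.5), type = "EPB", z = 1L))
  expect_true(all(!t2$present))
  expect_error(classify_presence(raw_track(c(1, 1), type = "XX")), "unknown")
})

test_that("event conservation holds per axon and interval", {
  cfg <- world_config(n_axons = 3, p_loss = 0.1, seed = 14)
  tr <- classify_presence(build_tracks(truth_observations(generate_worlds(cfg)), 9))
  for (axon in unique(tr$axon_id)) {
    ta <- tr[tr$axon_id == axon, ]
    for (s in 1:8) {
      n_a <- sum(ta$present[ta$session == s])
      n_b <- sum(ta$present[ta$session == s + 1])
      gains <- sum(ta$event[ta$session == s + 1] == "gain")
      losses <- sum(ta$event[ta$session == s + 1] == "loss")
      expect_equal(n_b, n_a + gains - losses)
    }
  }
})

test_that("raising the matching tolerance never increases event counts", {
  set.seed(91)
  for (i in 1:10) {
    obs <- do.call(rbind, lapply(1:5, function(s)
      mk_obs(sort(runif(6, 0, 60)), s)))
    events <- vapply(c(0.5, 1, 2, 4, 8), function(tol) {
      tr <- classify_presence(build_tracks(obs, 5, tol_um = tol))
      sum(tr$event != "")
    }, numeric(1))
    expect_true(all(diff(events) <= 0))
  }
})
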