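test_that("world configuration is validated", {
  expect_error(world_config(axon_length_um = 80), "100")
  expect_error(world_config(p_loss = 1.2), "p_loss")
  expect_error(world_config(p_loss = NaN), "finite")
  expect_error(world_config(stim_factor = 0), "stim_factor")
  expect_error(world_config(n_sessions = 1), "n_sessions")
  expect_error(world_config(stim_profile = c(1, 1)), "stim_profile")
  expect_error(world_config(stim_window = 9), "stim_window")
  cfg <- world_config()
  # default gain rate balances losses: p_loss * density * 100
  expect_equal(cfg$gain_rate_per_100um, cfg$p_loss * cfg$init_density_per_um * 100)
})

test_that("session days and interval factors encode the design", {
  cfg <- world_config(n_sessions = 9, session_interval_h = 48, stim_session = 5)
  expect_equal(session_days(cfg), seq(-8, 8, by = 2))
  f <- interval_factors(world_config(stim_factor = 2, stim_window = c(5, 6)))
  expect_equal(f, c(1, 1, 1, 1, 2, 2, 1, 1))
  fp <- interval_factors(world_config(stim_profile = c(1, 1, 1, 1, 3, 2, 1.5, 1)))
  expect_equal(fp[5], 3)
})

test_that("generation is deterministic and respects geometry invariants", {
  cfg <- world_config(n_axons = 3, seed = 5)
  w1 <- generate_worlds(cfg)
  w2 <- generate_worlds(cfg)
  expect_identical(w1, w2)
  w3 <- generate_worlds(cfg, seed = 6)
  expect_false(identical(w1, w3))
  for (w in w1) {
    expect_equal(w$length_um, cfg$axon_length_um, tolerance = 1e-6)
    expect_true(all(diff(w$arc) > 0))
    b <- w$boutons
    expect_true(all(b$arc_pos_um >= 0 & b$arc_pos_um <= w$length_um))
    expect_true(all(b$birth_session < b$death_session))
    # size trajectories span exactly the live sessions
    expect_equal(vapply(b$sizes, length, 0L),
                 b$death_session - b$birth_session)
  }
})

test_that("no-event limit: every bouton lives all sessions, turnover zero", {
  cfg <- world_config(n_axons = 3, p_loss = 0, gain_rate_per_100um = 0, seed = 2)
  w <- generate_worlds(cfg)
  for (ww in w) {
    expect_true(all(ww$boutons$birth_session == 1))
    expect_true(all(ww$boutons$death_session == 10))
  }
  tt <- truth_tracks(w)
  lens <- setNames(vapply(w, `[[`, 0, "length_um"),
                   vapply(w, `[[`, "", "axon_id"))
  iv <- axon_dynamics(tt, lens, 9)$intervals
  expect_true(all(iv$turnover == 0))
  expect_true(all(iv$gains == 0 & iv$losses == 0))
})

test_that("minimum bouton spacing is enforced across cohabiting boutons", {
  cfg <- world_config(n_axons = 4, init_density_per_um = 0.15, p_loss = 0.1,
                      min_sep_um = 2, seed = 9)
  for (w in generate_worlds(cfg)) {
    b <- w$boutons
    for (s in seq_len(w$n_sessions)) {
      pos <- sort(b$arc_pos_um[b$birth_session <= s & b$death_session > s])
      if (length(pos) > 1) expect_true(all(diff(pos) >= cfg$min_sep_um))
    }
  }
})

test_that("balanced rates give a stationary density (slope CI covers 0)", {
  set.seed(3)
  seeds <- sample.int(2^31 - 2, 200)
  slopes <- vapply(seeds, function(sd) {
    cfg <- world_config(n_axons = 2, axon_length_um = 150, p_loss = 0.05,
                        init_density_per_um = 0.12, seed = sd)
    w <- generate_worlds(cfg)
    counts <- sapply(1:9, function(s)
      sum(vapply(w, function(ww)
        sum(ww$boutons$birth_session <= s & ww$boutons$death_session > s), 0L)))
    unname(coef(lm(counts ~ seq_len(9)))[2])
  }, numeric(1))
  # 99% CI: the slope is an unbiased zero, so a tight level only trades
  # sensitivity for replicate-seed flakiness
  ci <- mean(slopes) + c(-2.576, 2.576) * sd(slopes) / sqrt(length(slopes))
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("scaling both event rates scales expected turnover proportionally", {
  set.seed(4)
  mean_turnover <- function(factor) {
    seeds <- sample.int(2^31 - 2, 120)
    mean(vapply(seeds, function(sd) {
      cfg <- world_config(n_axons = 3, axon_length_um = 200, p_loss = 0.02,
                          init_density_per_um = 0.12, stim_factor = factor,
                          stim_window = 5, seed = sd)
      tt <- truth_tracks(generate_worlds(cfg))
      lens <- setNames(rep(200, 3), unique(tt$axon_id))
      iv <- axon_dynamics(tt, lens, 9)$intervals
      mean(iv$turnover[iv$session_b == 6], na.rm = TRUE)
    }, numeric(1)))
  }
  t1 <- mean_turnover(1)
  t2 <- mean_turnover(2)
  # small event probabilities: doubling the rates ~doubles turnover
  expect_equal(t2 / t1, 2, tolerance = 0.15)
})

test_that("truth tables carry presence vectors and conserve counts", {
  cfg <- world_config(n_axons = 2, seed = 8)
  w <- generate_worlds(cfg)
  obs <- truth_observations(w)
  tt <- truth_tracks(w)
  # a bouton born at 3 and dying at 5 is present exactly at sessions 3, 4
  w1 <- w[[1]]
  w1$boutons <- data.frame(bouton_id = "b1", type = "TB", arc_pos_um = 50,
                           birth_session = 3L, death_session = 5L,
                           stringsAsFactors = FALSE)
  w1$boutons$sizes <- list(c(1.5, 1.6))
  t1 <- truth_tracks(w1)
  expect_equal(t1$present, c(FALSE, FALSE, TRUE, TRUE, rep(FALSE, 5)))
  expect_equal(t1$event, c("", "", "gain", "", "loss", "", "", "", ""))
  # observation row count equals the summed per-session live counts
  live_sum <- sum(vapply(w, function(ww) {
    sum(sapply(1:9, function(s)
      sum(ww$boutons$birth_session <= s & ww$boutons$death_session > s)))
  }, 0))
  expect_equal(nrow(obs), live_sum)
  expect_equal(sum(tt$present), live_sum)
})

test_that("presets encode the two-genotype study arms", {
  wt <- world_preset("wt_tb"); app <- world_preset("app_tb")
  expect_equal(wt$n_axons, 11); expect_equal(app$n_axons, 11)
  expect_gt(wt$p_loss, app$p_loss)
  expect_gt(interval_factors(app)[5], interval_factors(wt)[5])
  expect_equal(interval_factors(wt)[8], 1)   # effect decays out by +8
  epb <- world_preset("wt_epb")
  expect_equal(epb$n_axons, 14)
  expect_true(all(interval_factors(epb) == 1))
})

test_that("world configs round-trip through YAML", {
  cfg <- world_config(n_axons = 5, p_loss = 0.04, genotype_label = "WT-GFP",
                      seed = 3)
  path <- tempfile(fileext = ".yaml")
  fields <- cfg[c("n_axons", "axon_length_um", "bouton_type",
                  "init_density_per_um", "p_loss", "gain_rate_per_100um",
                  "stim_factor", "n_sessions", "min_sep_um",
                  "genotype_label", "seed")]
  yaml::write_yaml(fields, path)
  cfg2 <- world_config_from_yaml(path)
  expect_identical(generate_worlds(cfg), generate_worlds(cfg2))
})
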