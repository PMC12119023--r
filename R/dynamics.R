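#' Per-axon bouton density and interval dynamics
#'
#' Summary statistics over classified tracks: per-session density
#' (boutons per um of axon, minimum analysable length 100 um), per-interval
#' turnover `(gains + losses) / (N_A + N_B)` with its gain and loss
#' fractions, baseline (pre-stimulation) averaging, and percent change from
#' baseline.
#'
#' @name dynamics
NULL

.presence_matrix <- function(tracks) {
  # tracks: classified long table for ONE axon
  stats::xtabs(present ~ track_id + session, data = tracks) > 0
}

#' Per-session bouton count and density for one axon
#'
#' @param tracks Classified track table ([classify_presence()]) for one axon.
#' @param length_um Axon arc length (um); axons shorter than `min_length_um`
#'   are rejected.
#' @param session Session index.
#' @param min_length_um Minimum analysable axon length (um).
#' @return Data frame row: `axon_id`, `session`, `n_total`, `length_um`,
#'   `density_per_um`.
#' @export
session_density <- function(tracks, length_um, session, min_length_um = 100) {
  if (length_um < min_length_um) {
    stop(sprintf("axon rejected: length %.1f um is below the %g um minimum",
                 length_um, min_length_um))
  }
  axon <- unique(tracks$axon_id)
  stopifnot(length(axon) == 1)
  n <- sum(tracks$present[tracks$session == session])
  data.frame(axon_id = axon, session = session, n_total = n,
             length_um = length_um, density_per_um = n / length_um,
             stringsAsFactors = FALSE)
}

#' Turnover, gains and losses for one consecutive-session interval
#'
#' `turnover = (losses + gains) / (N_A + N_B)` where gains and losses are
#' counted at session B; `gain_frac` and `loss_frac` use only gains or only
#' losses in the numerator, so `gain_frac + loss_frac = turnover` exactly.
#' With no boutons at either session the fractions are undefined (`NA`).
#'
#' @param tracks Classified track table for one axon.
#' @param session_a,session_b Consecutive session indices (`b = a + 1`).
#' @param day Optional interval label (the later session's imaging day).
#' @return Data frame row: `axon_id`, `day`, `session_a`, `session_b`,
#'   `n_a`, `n_b`, `gains`, `losses`, `turnover`, `gain_frac`, `loss_frac`.
#' @export
interval_dynamics <- function(tracks, session_a, session_b, day = NA_real_) {
  if (session_b != session_a + 1) {
    stop("interval_dynamics: sessions must be consecutive (got ",
         session_a, ", ", session_b, ")")
  }
  axon <- unique(tracks$axon_id)
  stopifnot(length(axon) == 1)
  pa <- tracks$present[tracks$session == session_a]
  pb <- tracks$present[tracks$session == session_b]
  ta <- tracks$track_id[tracks$session == session_a]
  tb <- tracks$track_id[tracks$session == session_b]
  pb <- pb[match(ta, tb)]                 # align by track id
  n_a <- sum(pa); n_b <- sum(pb, na.rm = TRUE)
  gains <- sum(!pa & pb, na.rm = TRUE)
  losses <- sum(pa & !pb, na.rm = TRUE)
  denom <- n_a + n_b
  data.frame(axon_id = axon, day = day,
             session_a = session_a, session_b = session_b,
             n_a = n_a, n_b = n_b, gains = gains, losses = losses,
             turnover = if (denom > 0) (gains + losses) / denom else NA_real_,
             gain_frac = if (denom > 0) gains / denom else NA_real_,
             loss_frac = if (denom > 0) losses / denom else NA_real_,
             stringsAsFactors = FALSE)
}

#' Full per-axon dynamics table over all sessions
#'
#' Convenience wrapper: per-session densities and all consecutive-interval
#' dynamics for a set of axons.
#'
#' @param tracks Classified track table, any number of axons.
#' @param lengths_um Named numeric vector of axon lengths (names = axon ids).
#' @param n_sessions Number of sessions.
#' @param days Optional vector of imaging-day labels per session; intervals
#'   are labelled with the later session's day.
#' @return List with `density` (axon x session rows) and `intervals`
#'   (axon x interval rows, schema of [interval_dynamics()]).
#' @export
axon_dynamics <- function(tracks, lengths_um, n_sessions, days = NULL) {
  if (is.null(days)) days <- seq_len(n_sessions)
  dens <- list(); ints <- list()
  for (axon in unique(tracks$axon_id)) {
    tr <- tracks[tracks$axon_id == axon, , drop = FALSE]
    for (s in seq_len(n_sessions)) {
      dens[[length(dens) + 1]] <- session_density(tr, lengths_um[[axon]], s)
    }
    for (s in seq_len(n_sessions - 1)) {
      ints[[length(ints) + 1]] <- interval_dynamics(tr, s, s + 1,
                                                    day = days[s + 1])
    }
  }
  dens <- do.call(rbind, dens)
  dens$day <- days[dens$session]
  list(density = dens, intervals = do.call(rbind, ints))
}

#' Average pre-stimulation values into a single baseline
#'
#' Arithmetic mean of the pre-stimulation values of a measure: the five
#' pre-stimulation sessions for density, or the four pre-stimulation
#' intervals for interval-defined measures (turnover, gains, losses) on the
#' standard 9-session design.
#'
#' @param x Numeric vector of pre-stimulation values (`NA`s dropped).
#' @return Scalar mean.
#' @export
baseline_average <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) stop("baseline_average: no pre-stimulation values")
  mean(x)
}

#' Recover the post-stimulation turnover increase from simulated worlds
#'
#' The parameter-recovery experiment for a transient stimulation effect:
#' simulate TB axon groups with a multiplicative factor on both event rates
#' at the first post-stimulation interval, run the ground-truth tables
#' through the dynamics stage, and express the group-mean turnover at the
#' first post-stimulation interval as a percent change from the averaged
#' pre-stimulation baseline, averaged over replicate simulations.
#'
#' @param n_axons Axons per replicate group.
#' @param p_loss Baseline per-interval loss probability (gains balanced).
#' @param stim_factor Multiplier on both event rates at the first
#'   post-stimulation interval.
#' @param n_seeds Number of replicate simulations.
#' @param seed Root seed for the replicate seed stream.
#' @param axon_length_um,init_density_per_um Axon geometry and bouton
#'   density of the simulated group.
#' @return List: `mean_pct` (mean percent increase), `se` (standard error
#'   over replicates), `pct` (per-replicate values).
#' @export
recover_turnover_increase <- function(n_axons, p_loss, stim_factor,
                                      n_seeds = 200, seed = 1,
                                      axon_length_um = 200,
                                      init_density_per_um = 0.12) {
  set.seed(seed)
  seeds <- sample.int(2^31 - 2, n_seeds)
  pct <- numeric(n_seeds)
  for (i in seq_len(n_seeds)) {
    cfg <- world_config(n_axons = n_axons, axon_length_um = axon_length_um,
                        bouton_type = "TB",
                        init_density_per_um = init_density_per_um,
                        p_loss = p_loss, stim_factor = stim_factor,
                        stim_window = 5, seed = seeds[i])
    w <- generate_worlds(cfg)
    tt <- truth_tracks(w)
    lens <- stats::setNames(vapply(w, `[[`, 0, "length_um"),
                            vapply(w, `[[`, "", "axon_id"))
    iv <- axon_dynamics(tt, lens, cfg$n_sessions, session_days(cfg))$intervals
    pre <- iv$session_b <= cfg$stim_session
    base <- mean(tapply(iv$turnover[pre], iv$axon_id[pre],
                        function(x) baseline_average(x)))
    post <- mean(iv$turnover[iv$session_b == cfg$stim_session + 1], na.rm = TRUE)
    pct[i] <- percent_change(post, base)
  }
  list(mean_pct = mean(pct), se = stats::sd(pct) / sqrt(n_seeds), pct = pct)
}

#' Calibrate a stimulation factor to a target turnover increase
#'
#' The measured percent increase is not exactly `100 * (factor - 1)`:
#' turnover is a ratio of small counts, so its expectation carries a
#' rate-dependent finite-sample term.  A preset factor is therefore defined
#' on the observable scale: this routine simulates the recovery experiment
#' at a pilot factor and rescales the effect (linear through zero at
#' `factor = 1`) so that the expected recovered increase equals
#' `target_pct`.
#'
#' @param target_pct Target percent increase of group-mean turnover at the
#'   first post-stimulation interval over baseline.
#' @param n_axons,p_loss,axon_length_um,init_density_per_um Group design
#'   passed to [recover_turnover_increase()].
#' @param n_seeds Replicates for the calibration run.
#' @param seed Seed for the calibration run (keep distinct from evaluation
#'   seeds).
#' @return Calibrated stimulation factor.
#' @export
calibrate_stim_factor <- function(target_pct, n_axons, p_loss,
                                  n_seeds = 200, seed = 99,
                                  axon_length_um = 200,
                                  init_density_per_um = 0.12) {
  f0 <- 1 + target_pct / 100
  pilot <- recover_turnover_increase(n_axons, p_loss, f0, n_seeds, seed,
                                     axon_length_um, init_density_per_um)
  1 + (f0 - 1) * target_pct / pilot$mean_pct
}

#' Percent change of a post-stimulation value from baseline
#'
#' `100 * (post - baseline) / baseline`.
#'
#' @param post Post-stimulation value.
#' @param baseline Baseline value; must be positive for the change to be
#'   defined (`NA` with a warning at zero).
#' @return Percent change.
#' @export
percent_change <- function(post, baseline) {
  if (any(baseline < 0, na.rm = TRUE)) stop("percent_change: negative baseline")
  out <- 100 * (post - baseline) / baseline
  if (any(baseline == 0, na.rm = TRUE)) {
    warning("percent_change undefined for zero baseline; returning NA")
    out[baseline == 0] <- NA_real_
  }
  out
}
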