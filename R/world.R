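#' Configuration for a synthetic axon population
#'
#' Defines the imaging design and the stochastic bouton dynamics used by
#' [generate_worlds()]: a birth-death process in which each live bouton is
#' lost between consecutive sessions with probability `p_loss` and new
#' boutons arrive as a Poisson process along the axon with rate
#' `gain_rate_per_100um` per 100 um per interval.  A transient stimulation
#' effect multiplies both event rates on selected intervals.
#'
#' @param n_axons Number of axons to simulate.
#' @param axon_length_um Axon arc length (um); at least 100.
#' @param bouton_type `"EPB"` (en passant, shaft swellings) or `"TB"`
#'   (terminaux, side protrusions); one type per axon population.
#' @param init_density_per_um Expected bouton density at the first session
#'   (boutons per um).
#' @param p_loss Per-interval probability that a live bouton is lost.
#' @param gain_rate_per_100um Expected number of new boutons per 100 um per
#'   interval.  `NULL` (default) balances gains against losses
#'   (`p_loss * init_density_per_um * 100`), giving a stationary density.
#' @param stim_factor Multiplier applied to both `p_loss` and the gain rate
#'   on the intervals in `stim_window`.
#' @param stim_window Integer indices of affected intervals (interval `i`
#'   separates sessions `i` and `i + 1`); default: the first
#'   post-stimulation interval.
#' @param stim_profile Optional numeric vector of per-interval factors
#'   (length `n_sessions - 1`) overriding `stim_factor`/`stim_window`.
#' @param n_sessions Number of imaging sessions (default 9).
#' @param session_interval_h Hours between sessions (default 48).
#' @param stim_session Session immediately after which stimulation is
#'   delivered (default 5, i.e. day 0 of a -8..+8 day design).
#' @param min_sep_um Minimum spacing between bouton positions (um); boutons
#'   are micron-scale structures and cannot overlap.
#' @param genotype_label Free-text group label carried through all tables.
#' @param seed RNG seed for [generate_worlds()].
#' @return A `world_config` list.
#' @export
world_config <- function(n_axons = 10,
                         axon_length_um = 200,
                         bouton_type = c("TB", "EPB"),
                         init_density_per_um = 0.12,
                         p_loss = 0.05,
                         gain_rate_per_100um = NULL,
                         stim_factor = 1,
                         stim_window = NULL,
                         stim_profile = NULL,
                         n_sessions = 9,
                         session_interval_h = 48,
                         stim_session = 5,
                         min_sep_um = 2,
                         genotype_label = "WT-GFP",
                         seed = 1L) {
  bouton_type <- match.arg(bouton_type)
  cfg <- list(n_axons = as.integer(n_axons),
              axon_length_um = axon_length_um,
              bouton_type = bouton_type,
              init_density_per_um = init_density_per_um,
              p_loss = p_loss,
              gain_rate_per_100um = if (is.null(gain_rate_per_100um))
                p_loss * init_density_per_um * 100 else gain_rate_per_100um,
              stim_factor = stim_factor,
              stim_window = if (is.null(stim_window)) as.integer(stim_session)
                            else as.integer(stim_window),
              stim_profile = stim_profile,
              n_sessions = as.integer(n_sessions),
              session_interval_h = session_interval_h,
              stim_session = as.integer(stim_session),
              min_sep_um = min_sep_um,
              genotype_label = genotype_label,
              seed = as.integer(seed))
  validate_world_config(cfg)
  structure(cfg, class = "world_config")
}

#' @rdname world_config
#' @param cfg A `world_config` to validate.
#' @export
validate_world_config <- function(cfg) {
  num_fields <- c("axon_length_um", "init_density_per_um", "p_loss",
                  "gain_rate_per_100um", "stim_factor", "session_interval_h",
                  "min_sep_um")
  for (f in num_fields) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || !is.finite(cfg[[f]]))
      stop(sprintf("world_config: '%s' must be a finite number", f))
  }
  if (cfg$axon_length_um < 100) stop("axon_length_um must be >= 100 um")
  if (cfg$p_loss < 0 || cfg$p_loss > 1) stop("p_loss must be in [0, 1]")
  if (cfg$gain_rate_per_100um < 0) stop("gain_rate_per_100um must be >= 0")
  if (cfg$stim_factor <= 0) stop("stim_factor must be > 0")
  if (cfg$n_sessions < 2) stop("n_sessions must be >= 2")
  if (cfg$init_density_per_um < 0) stop("init_density_per_um must be >= 0")
  if (!is.null(cfg$stim_profile) &&
      length(cfg$stim_profile) != cfg$n_sessions - 1)
    stop("stim_profile must have one factor per interval (n_sessions - 1)")
  if (any(cfg$stim_window < 1 | cfg$stim_window > cfg$n_sessions - 1))
    stop("stim_window indices must be in 1 .. n_sessions - 1")
  invisible(cfg)
}

#' Per-interval event-rate multipliers implied by a world configuration
#'
#' @param cfg A `world_config`.
#' @return Numeric vector of length `n_sessions - 1`.
#' @export
interval_factors <- function(cfg) {
  if (!is.null(cfg$stim_profile)) return(as.numeric(cfg$stim_profile))
  f <- rep(1, cfg$n_sessions - 1)
  f[cfg$stim_window] <- cfg$stim_factor
  f
}

#' Imaging-day labels of a session design
#'
#' Days relative to stimulation: session `stim_session` is day 0, so the
#' standard 9-session / 48-h design reads -8, -6, ..., 0, +2, ..., +8.
#' @param cfg A `world_config`.
#' @return Numeric vector of day offsets, one per session.
#' @export
session_days <- function(cfg) {
  (seq_len(cfg$n_sessions) - cfg$stim_session) * cfg$session_interval_h / 24
}

# draw positions uniformly on [0, L] subject to min separation from `existing`
.place_positions <- function(n, length_um, min_sep, existing = numeric(0),
                             max_tries = 1000) {
  out <- numeric(0)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      p <- stats::runif(1, 0, length_um)
      if (all(abs(p - c(existing, out)) >= min_sep)) {
        out <- c(out, p); placed <- TRUE; break
      }
    }
    if (!placed) warning("could not place a bouton respecting min_sep_um; axon is crowded")
  }
  out
}

# slightly wavy backbone rescaled to exact arc length
.make_backbone <- function(length_um, z_um = 4) {
  amp <- stats::runif(1, 1, 2.5)
  lambda <- stats::runif(1, 60, 120)
  phase <- stats::runif(1, 0, 2 * pi)
  x <- seq(0, length_um, by = 1)
  y <- amp * sin(2 * pi * x / lambda + phase)
  y <- y - min(y)
  pts <- cbind(x = x, y = y, z = rep(z_um, length(x)))
  seg <- sqrt(rowSums(diff(pts)^2))
  scale <- length_um / sum(seg)
  pts[, 1:2] <- pts[, 1:2] * scale
  pts[, 1] <- pts[, 1] - min(pts[, 1])
  arc <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  list(points = pts, arc = arc, length_um = arc[length(arc)])
}

# size trajectory while alive: stable with small session-to-session jitter
.size_trajectory <- function(type, n_obs) {
  if (type == "EPB") {
    base <- stats::runif(1, 2.3, 3.2)
    pmax(2.2, base + stats::runif(n_obs, -0.05, 0.05))
  } else {
    base <- stats::runif(1, 1.3, 2.2)
    pmax(1.25, base + stats::runif(n_obs, -0.05, 0.05))
  }
}

#' Generate ground-truth axon worlds
#'
#' Simulates each axon independently (per-axon RNG substreams derived from
#' the root seed): a wavy 3D backbone of exact arc length
#' `axon_length_um`, an initial Poisson number of boutons at density
#' `init_density_per_um` placed uniformly (with minimum spacing
#' `min_sep_um`), then for every inter-session interval independent
#' Bernoulli loss of each live bouton and Poisson arrivals of new boutons,
#' both rates multiplied by the interval's stimulation factor.
#'
#' @param cfg A [world_config()].
#' @param seed Optional override of `cfg$seed`.
#' @return A list of `axon_world` objects (class `axon_world_set`).  Each
#'   world has `axon_id`, `genotype_label`, `backbone` (n x 3 um matrix),
#'   `arc` (cumulative arc length), `length_um`, `session_days`, and
#'   `boutons`: a data frame with `bouton_id`, `type`, `arc_pos_um`,
#'   `birth_session`, `death_session` (exclusive; `n_sessions + 1` if still
#'   present at the last session) and a `sizes` list column of per-session
#'   sizes for sessions `birth .. death - 1` (intensity ratio for EPBs,
#'   protrusion length in um for TBs).
#' @export
generate_worlds <- function(cfg, seed = NULL) {
  validate_world_config(cfg)
  root_seed <- if (is.null(seed)) cfg$seed else as.integer(seed)
  set.seed(root_seed)
  axon_seeds <- sample.int(.Machine$integer.max - 1, cfg$n_axons)
  fct <- interval_factors(cfg)
  S <- cfg$n_sessions
  worlds <- vector("list", cfg$n_axons)
  for (a in seq_len(cfg$n_axons)) {
    set.seed(axon_seeds[a])
    bb <- .make_backbone(cfg$axon_length_um)
    L <- bb$length_um
    # initial cohort
    n0 <- stats::rpois(1, cfg$init_density_per_um * L)
    pos <- .place_positions(n0, L, cfg$min_sep_um)
    birth <- rep(1L, length(pos))
    death <- rep(NA_integer_, length(pos))
    alive <- rep(TRUE, length(pos))
    for (i in seq_len(S - 1)) {
      p_die <- min(1, cfg$p_loss * fct[i])
      live_idx <- which(alive)
      pos_before <- pos[alive]   # spacing also guards sites lost this interval:
                                 # a birth on a just-lost site would be scored
                                 # as the same bouton persisting
      if (length(live_idx)) {
        dies <- live_idx[stats::runif(length(live_idx)) < p_die]
        alive[dies] <- FALSE
        death[dies] <- i + 1L
      }
      lam <- cfg$gain_rate_per_100um * L / 100 * fct[i]
      n_new <- stats::rpois(1, lam)
      if (n_new > 0) {
        new_pos <- .place_positions(n_new, L, cfg$min_sep_um,
                                    existing = pos_before)
        if (length(new_pos)) {
          pos <- c(pos, new_pos)
          birth <- c(birth, rep(i + 1L, length(new_pos)))
          death <- c(death, rep(NA_integer_, length(new_pos)))
          alive <- c(alive, rep(TRUE, length(new_pos)))
        }
      }
    }
    death[is.na(death)] <- S + 1L
    n_b <- length(pos)
    sizes <- vector("list", n_b)
    for (b in seq_len(n_b)) {
      sizes[[b]] <- .size_trajectory(cfg$bouton_type, death[b] - birth[b])
    }
    boutons <- data.frame(
      bouton_id = if (n_b) sprintf("a%03d_b%03d", a, seq_len(n_b)) else character(0),
      type = rep(cfg$bouton_type, n_b),
      arc_pos_um = pos,
      birth_session = birth,
      death_session = death,
      stringsAsFactors = FALSE)
    boutons$sizes <- sizes
    worlds[[a]] <- structure(list(
      axon_id = sprintf("%s_%s_a%03d",
                        tolower(gsub("[^A-Za-z0-9]", "", cfg$genotype_label)),
                        tolower(cfg$bouton_type), a),
      genotype_label = cfg$genotype_label,
      backbone = bb$points,
      arc = bb$arc,
      length_um = L,
      session_days = session_days(cfg),
      n_sessions = S,
      bouton_type = cfg$bouton_type,
      boutons = boutons
    ), class = "axon_world")
  }
  structure(worlds, class = "axon_world_set", config = cfg)
}

#' @export
print.axon_world <- function(x, ...) {
  cat(sprintf("axon_world %s (%s): %.1f um, %d boutons (%s), %d sessions\n",
              x$axon_id, x$genotype_label, x$length_um, nrow(x$boutons),
              x$bouton_type, x$n_sessions))
  invisible(x)
}

#' @export
print.axon_world_set <- function(x, ...) {
  cat(sprintf("axon_world_set: %d axons (%s, %s)\n", length(x),
              attr(x, "config")$bouton_type, attr(x, "config")$genotype_label))
  invisible(x)
}

.is_alive <- function(boutons, session) {
  boutons$birth_session <= session & boutons$death_session > session
}

#' Ground-truth per-session bouton observation table
#'
#' Emits observations in the same schema the detection stage produces, so the
#' tracking/dynamics/statistics stages can be driven from ground truth
#' directly, bypassing image rendering.
#'
#' @param worlds An `axon_world_set` (or a single `axon_world`).
#' @return Data frame with columns `axon_id`, `session`, `type`,
#'   `arc_pos_um`, `intensity_ratio`, `protrusion_len_um`,
#'   `z_extent_planes`.
#' @export
truth_observations <- function(worlds) {
  if (inherits(worlds, "axon_world")) worlds <- list(worlds)
  rows <- list()
  for (w in worlds) {
    b <- w$boutons
    for (s in seq_len(w$n_sessions)) {
      live <- which(.is_alive(b, s))
      if (!length(live)) next
      size <- vapply(live, function(i) b$sizes[[i]][s - b$birth_session[i] + 1],
                     numeric(1))
      rows[[length(rows) + 1]] <- data.frame(
        axon_id = w$axon_id,
        session = s,
        type = b$type[live],
        arc_pos_um = b$arc_pos_um[live],
        intensity_ratio = ifelse(b$type[live] == "EPB", size, NA_real_),
        protrusion_len_um = ifelse(b$type[live] == "TB", size, NA_real_),
        z_extent_planes = ifelse(b$type[live] == "EPB", 3L, 2L),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty_observations())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$axon_id, out$session, out$arc_pos_um), ]
}

#' Ground-truth bouton track table
#'
#' One row per bouton per session in the long track schema shared with
#' [build_tracks()] output: presence, size and gain/loss events derived from
#' the simulated life histories (gain at the birth session when born after
#' session 1; loss at the death session when it falls inside the imaging
#' period).
#'
#' @inheritParams truth_observations
#' @return Data frame in the full tracks schema: `track_id`, `axon_id`,
#'   `type`, `session`, `observed`, `size`, `z_extent_planes`,
#'   `arc_pos_um`, `present`, `event` (`""`, `"gain"` or `"loss"`).
#' @export
truth_tracks <- function(worlds) {
  if (inherits(worlds, "axon_world")) worlds <- list(worlds)
  rows <- list()
  for (w in worlds) {
    b <- w$boutons
    S <- w$n_sessions
    for (i in seq_len(nrow(b))) {
      present <- seq_len(S) >= b$birth_session[i] & seq_len(S) < b$death_session[i]
      size <- rep(NA_real_, S)
      obs_sessions <- b$birth_session[i]:(b$death_session[i] - 1)
      size[obs_sessions] <- b$sizes[[i]]
      event <- rep("", S)
      if (b$birth_session[i] > 1) event[b$birth_session[i]] <- "gain"
      if (b$death_session[i] <= S) event[b$death_session[i]] <- "loss"
      rows[[length(rows) + 1]] <- data.frame(
        track_id = paste0(w$axon_id, "_", b$bouton_id[i]),
        axon_id = w$axon_id,
        type = b$type[i],
        session = seq_len(S),
        observed = present,
        size = size,
        z_extent_planes = ifelse(present,
                                 if (b$type[i] == "EPB") 3L else 2L,
                                 NA_integer_),
        arc_pos_um = ifelse(present, b$arc_pos_um[i], NA_real_),
        present = present,
        event = event,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty_tracks())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_observations <- function() {
  data.frame(axon_id = character(0), session = integer(0), type = character(0),
             arc_pos_um = numeric(0), intensity_ratio = numeric(0),
             protrusion_len_um = numeric(0), z_extent_planes = integer(0),
             stringsAsFactors = FALSE)
}

empty_tracks <- function() {
  data.frame(track_id = character(0), axon_id = character(0),
             type = character(0), session = integer(0), observed = logical(0),
             size = numeric(0), z_extent_planes = integer(0),
             arc_pos_um = numeric(0), present = logical(0),
             event = character(0), stringsAsFactors = FALSE)
}

#' Preset world configurations for the study design
#'
#' `wt_tb` / `app_tb` / `wt_epb` / `app_epb` encode the two genotype groups
#' for each bouton type: densities from the reported per-group bouton counts
#' and axon lengths, reduced baseline event rates in the amyloidosis (APP)
#' group, and a transient post-stimulation multiplicative effect on TB (not
#' EPB) event rates that decays back to 1 by the last interval.  `smoke` is a
#' minimal no-effect configuration for fast end-to-end runs.
#'
#' @param name Preset name.
#' @param seed RNG seed stored in the config.
#' @return A [world_config()].
#' @export
world_preset <- function(name = c("wt_tb", "app_tb", "wt_epb", "app_epb", "smoke"),
                         seed = 1L) {
  name <- match.arg(name)
  decay <- function(f) {        # transient: full effect at +2, gone by +8
    c(f, 1 + (f - 1) / 2, 1 + (f - 1) / 4, 1)
  }
  profile <- function(f) c(rep(1, 4), decay(f))
  switch(name,
    wt_tb = world_config(n_axons = 11, axon_length_um = 224, bouton_type = "TB",
                         init_density_per_um = 0.135, p_loss = 0.05,
                         stim_profile = profile(1.88),
                         genotype_label = "WT-GFP", seed = seed),
    app_tb = world_config(n_axons = 11, axon_length_um = 168, bouton_type = "TB",
                          init_density_per_um = 0.111, p_loss = 0.03,
                          stim_profile = profile(3.13),
                          genotype_label = "APP-GFP", seed = seed),
    wt_epb = world_config(n_axons = 14, axon_length_um = 224, bouton_type = "EPB",
                          init_density_per_um = 0.135, p_loss = 0.04,
                          stim_profile = profile(1),
                          genotype_label = "WT-GFP", seed = seed),
    app_epb = world_config(n_axons = 13, axon_length_um = 168, bouton_type = "EPB",
                           init_density_per_um = 0.111, p_loss = 0.025,
                           stim_profile = profile(1),
                           genotype_label = "APP-GFP", seed = seed),
    smoke = world_config(n_axons = 4, axon_length_um = 120, bouton_type = "TB",
                         init_density_per_um = 0.1, p_loss = 0.05,
                         stim_profile = rep(1, 8),
                         genotype_label = "WT-GFP", seed = seed)
  )
}

#' Read a world configuration from YAML
#'
#' The YAML keys mirror the [world_config()] arguments.
#' @param path YAML file path.
#' @param seed Optional seed override.
#' @return A [world_config()].
#' @export
world_config_from_yaml <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(seed)) y$seed <- seed
  do.call(world_config, y)
}
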