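#' Cross-session bouton identity tracking
#'
#' Bouton observations from consecutive sessions are paired greedily by
#' arc-length distance; chains of correspondences become tracks; presence is
#' then classified per bouton type (EPB intensity-ratio / z-plane rule, TB
#' establishment-loss hysteresis), which defines gain and loss events.
#'
#' @name tracking
NULL

#' Match bouton observations between two consecutive sessions
#'
#' Greedy nearest-neighbour pairing on arc-length distance.  Candidate pairs
#' farther apart than `tol_um` are forbidden; each observation enters at most
#' one pair; ties are broken toward the smaller distance, then the smaller
#' arc position of the earlier-session observation.
#'
#' @param obs_a,obs_b Observation data frames (rows of the observation
#'   schema) from sessions s and s+1 of the same axon and bouton type.
#' @param tol_um Maximum allowed arc-length displacement (um).
#' @return Data frame with `idx_a`, `idx_b` (row indices into the inputs) and
#'   `dist_um`; zero rows when nothing matches.
#' @export
match_consecutive <- function(obs_a, obs_b, tol_um = 2) {
  ids <- unique(c(obs_a$axon_id, obs_b$axon_id))
  if (length(ids) > 1) stop("match_consecutive: observations mix axon ids: ",
                            paste(ids, collapse = ", "))
  na <- nrow(obs_a); nb <- nrow(obs_b)
  empty <- data.frame(idx_a = integer(0), idx_b = integer(0), dist_um = numeric(0))
  if (na == 0 || nb == 0) return(empty)
  d <- abs(outer(obs_a$arc_pos_um, obs_b$arc_pos_um, `-`))
  cand <- which(d <= tol_um, arr.ind = TRUE)
  if (nrow(cand) == 0) return(empty)
  ord <- order(d[cand], obs_a$arc_pos_um[cand[, 1]])
  cand <- cand[ord, , drop = FALSE]
  used_a <- logical(na); used_b <- logical(nb)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ia <- cand[i, 1]; ib <- cand[i, 2]
    if (!used_a[ia] && !used_b[ib]) {
      used_a[ia] <- TRUE; used_b[ib] <- TRUE; keep[i] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  data.frame(idx_a = cand[, 1], idx_b = cand[, 2],
             dist_um = d[cand])
}

#' Build bouton tracks from per-session observations
#'
#' Takes the transitive closure of consecutive-session correspondences:
#' an observation with no correspondent in the previous session starts a new
#' track; a track with no correspondent in the next session simply has no
#' observation there (the presence classifier turns that into a loss).
#'
#' @param obs Observation data frame (observation schema), any number of
#'   axons; each axon must contain a single bouton type.
#' @param n_sessions Total number of imaging sessions.
#' @param tol_um Matching tolerance passed to [match_consecutive()].
#' @return Long data frame, one row per track per session: `track_id`,
#'   `axon_id`, `type`, `session`, `observed`, `size` (intensity ratio for
#'   EPBs, protrusion length for TBs), `z_extent_planes`, `arc_pos_um`.
#' @export
build_tracks <- function(obs, n_sessions, tol_um = 2) {
  stopifnot(n_sessions >= 1)
  out <- list()
  for (axon in unique(obs$axon_id)) {
    oa <- obs[obs$axon_id == axon, , drop = FALSE]
    type <- unique(oa$type)
    if (length(type) > 1) stop("build_tracks: axon ", axon, " mixes bouton types")
    per_s <- lapply(seq_len(n_sessions), function(s)
      oa[oa$session == s, , drop = FALSE])
    # track assignment per observation
    assign_s <- lapply(per_s, function(x) rep(NA_integer_, nrow(x)))
    n_tracks <- 0L
    if (nrow(per_s[[1]])) {
      assign_s[[1]] <- seq_len(nrow(per_s[[1]]))
      n_tracks <- nrow(per_s[[1]])
    }
    if (n_sessions > 1) {
      for (s in seq_len(n_sessions - 1)) {
        m <- match_consecutive(per_s[[s]], per_s[[s + 1]], tol_um)
        if (nrow(m)) assign_s[[s + 1]][m$idx_b] <- assign_s[[s]][m$idx_a]
        new_b <- which(is.na(assign_s[[s + 1]]))
        if (length(new_b)) {
          assign_s[[s + 1]][new_b] <- n_tracks + seq_along(new_b)
          n_tracks <- n_tracks + length(new_b)
        }
      }
    }
    if (n_tracks == 0) next
    size_col <- if (type == "EPB") "intensity_ratio" else "protrusion_len_um"
    tr <- data.frame(
      track_id = rep(sprintf("%s_t%03d", axon, seq_len(n_tracks)),
                     each = n_sessions),
      axon_id = axon, type = type,
      session = rep(seq_len(n_sessions), n_tracks),
      observed = FALSE, size = NA_real_, z_extent_planes = NA_integer_,
      arc_pos_um = NA_real_, stringsAsFactors = FALSE)
    for (s in seq_len(n_sessions)) {
      idx <- assign_s[[s]]
      if (!length(idx)) next
      rows <- (idx - 1L) * n_sessions + s
      tr$observed[rows] <- TRUE
      tr$size[rows] <- per_s[[s]][[size_col]]
      tr$z_extent_planes[rows] <- per_s[[s]]$z_extent_planes
      tr$arc_pos_um[rows] <- per_s[[s]]$arc_pos_um
    }
    out[[length(out) + 1]] <- tr
  }
  if (!length(out)) {
    return(data.frame(track_id = character(0), axon_id = character(0),
                      type = character(0), session = integer(0),
                      observed = logical(0), size = numeric(0),
                      z_extent_planes = integer(0), arc_pos_um = numeric(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify per-session presence and gain/loss events of bouton tracks
#'
#' Applies the scoring rules to raw tracks:
#' * EPB: present at a session when observed with intensity ratio at least
#'   `epb_ratio_min` across at least `min_z_planes` consecutive z-planes.
#' * TB: the track is *established* at the first session whose protrusion
#'   length reaches `tb_gain_len_um`; it then stays present while the length
#'   is at least `tb_loss_len_um`, and is lost at the first session where the
#'   protrusion is shorter than that (or unobserved).  Observations in the
#'   hysteresis band before establishment do not count as present; after a
#'   loss, presence can only resume by re-establishment at
#'   `tb_gain_len_um`, which is a new gain.
#'
#' Gain events are sessions where presence switches on (session >= 2), loss
#' events where it switches off.
#'
#' @param tracks Raw track data frame from [build_tracks()] (or any long
#'   table with `track_id`, `type`, `session`, `observed`, `size`,
#'   `z_extent_planes`).
#' @param params A [detection_params()] supplying the thresholds.
#' @return The input with `present` (logical) and `event` (`""`, `"gain"`,
#'   `"loss"`) columns, ordered by track and session.
#' @export
classify_presence <- function(tracks, params = detection_params()) {
  stopifnot(all(c("track_id", "type", "session", "observed", "size") %in%
                  names(tracks)))
  tracks <- tracks[order(tracks$track_id, tracks$session), , drop = FALSE]
  tracks$present <- FALSE
  tracks$event <- ""
  for (tid in unique(tracks$track_id)) {
    rows <- which(tracks$track_id == tid)
    type <- tracks$type[rows[1]]
    obs <- tracks$observed[rows]
    size <- tracks$size[rows]
    zext <- tracks$z_extent_planes[rows]
    if (type == "EPB") {
      present <- obs & !is.na(size) & size >= params$epb_ratio_min &
        !is.na(zext) & zext >= params$min_z_planes
    } else if (type == "TB") {
      present <- logical(length(rows))
      established <- FALSE
      for (i in seq_along(rows)) {
        len <- if (obs[i]) size[i] else NA_real_
        if (!established) {
          if (!is.na(len) && len >= params$tb_gain_len_um) {
            established <- TRUE
            present[i] <- TRUE
          }
        } else {
          if (!is.na(len) && len >= params$tb_loss_len_um) {
            present[i] <- TRUE
          } else {
            established <- FALSE    # lost; needs re-establishment
          }
        }
      }
    } else {
      stop("unknown bouton type: ", type)
    }
    event <- rep("", length(rows))
    if (length(rows) > 1) {
      chg <- diff(present)
      event[which(chg == 1) + 1] <- "gain"
      event[which(chg == -1) + 1] <- "loss"
    }
    tracks$present[rows] <- present
    tracks$event[rows] <- event
  }
  rownames(tracks) <- NULL
  tracks
}
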