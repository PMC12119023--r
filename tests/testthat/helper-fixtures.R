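# hand-built axon worlds with known geometry, for render/detect fixtures

# straight axon along x at y = y0, z = z0, with explicitly specified boutons
straight_world <- function(length_um = 120, type = "TB",
                           pos = numeric(0), sizes = list(),
                           n_sessions = 1, y0 = 5, z0 = 4) {
  x <- seq(0, length_um, by = 1)
  pts <- cbind(x = x, y = rep(y0, length(x)), z = rep(z0, length(x)))
  arc <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  n_b <- length(pos)
  boutons <- data.frame(
    bouton_id = if (n_b) sprintf("a001_b%03d", seq_len(n_b)) else character(0),
    type = rep(type, n_b),
    arc_pos_um = pos,
    birth_session = rep(1L, n_b),
    death_session = rep(n_sessions + 1L, n_b),
    stringsAsFactors = FALSE)
  boutons$sizes <- if (n_b) sizes else list()
  structure(list(
    axon_id = "fix_a001", genotype_label = "fixture",
    backbone = pts, arc = arc, length_um = arc[length(arc)],
    session_days = seq_len(n_sessions), n_sessions = n_sessions,
    bouton_type = type, boutons = boutons
  ), class = "axon_world")
}

# quarter-circle axon of given radius in the xy plane
quarter_circle_world <- function(radius = 50, z0 = 4) {
  th <- seq(0, pi / 2, length.out = 400)
  pts <- cbind(x = radius * cos(th), y = radius * sin(th), z = rep(z0, 400))
  pts[, 1] <- pts[, 1] - min(pts[, 1])
  pts[, 2] <- pts[, 2] - min(pts[, 2])
  arc <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  structure(list(
    axon_id = "fix_arc", genotype_label = "fixture",
    backbone = pts, arc = arc, length_um = arc[length(arc)],
    session_days = 1, n_sessions = 1L, bouton_type = "TB",
    boutons = data.frame(bouton_id = character(0), type = character(0),
                         arc_pos_um = numeric(0), birth_session = integer(0),
                         death_session = integer(0))
  ), class = "axon_world")
}

# seeds at the trace endpoints, in stack coordinates
end_seeds <- function(world, stack) {
  rbind(world$backbone[1, ], world$backbone[nrow(world$backbone), ]) -
    rep(stack$origin, each = 2)
}

# raw long track table from explicit per-session sizes (NA = unobserved)
raw_track <- function(sizes, type = "TB", z = 3L, track_id = "t1") {
  n <- length(sizes)
  data.frame(track_id = track_id, axon_id = "ax1", type = type,
             session = seq_len(n), observed = !is.na(sizes),
             size = sizes,
             z_extent_planes = ifelse(is.na(sizes), NA_integer_, z),
             arc_pos_um = ifelse(is.na(sizes), NA_real_, 10),
             stringsAsFactors = FALSE)
}
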