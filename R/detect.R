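#' Bouton detection in 3D image stacks
#'
#' Backbone tracing by ridge following between seed anchors, a rolling-median
#' backbone reference intensity, and the two bouton detectors: EPBs as
#' along-backbone intensity peaks (ratio and z-plane criteria) and TBs as
#' side protrusions measured by their length from the backbone centerline.
#'
#' @name detection
NULL

#' Detection and presence-classification parameters
#'
#' Thresholds implementing the scoring rules: an EPB requires intensity at
#' least `epb_ratio_min` times the local backbone reference across at least
#' `min_z_planes` consecutive z-planes; a TB is established at
#' `tb_gain_len_um` and lost below `tb_loss_len_um`.  The backbone reference
#' is a rolling median over `+/- reference_window_um`, excluding
#' `+/- exclusion_um` around the position being scored.
#'
#' @param epb_ratio_min EPB peak / backbone intensity ratio threshold.
#' @param min_z_planes Minimum consecutive z-planes for an EPB.
#' @param tb_gain_len_um TB establishment length (um).
#' @param tb_loss_len_um TB loss length (um); also the detection floor.
#' @param reference_window_um Half-width of the backbone reference window (um).
#' @param exclusion_um Half-width excluded around a candidate (um).
#' @param merge_dist_um Peaks closer than this along the backbone are merged
#'   to the brighter one (um).
#' @param tb_threshold_frac Voxels belong to a protrusion mask when above
#'   background + this fraction of the backbone amplitude.
#' @param tb_exclude_xy_um,tb_exclude_z_um Half-axes of the elliptical
#'   exclusion zone around the backbone centerline used to separate
#'   protrusion voxels from the backbone tube (um).
#' @param profile_step_um Arc-length sampling step of the intensity profile (um).
#' @return A `detection_params` list.
#' @export
detection_params <- function(epb_ratio_min = 2.0, min_z_planes = 2L,
                             tb_gain_len_um = 1.0, tb_loss_len_um = 0.4,
                             reference_window_um = 5, exclusion_um = 1,
                             merge_dist_um = 1,
                             tb_threshold_frac = 0.3,
                             tb_exclude_xy_um = 0.7, tb_exclude_z_um = 2.4,
                             profile_step_um = 0.25) {
  stopifnot(epb_ratio_min > 1, min_z_planes >= 1,
            tb_loss_len_um < tb_gain_len_um, tb_loss_len_um > 0,
            reference_window_um > exclusion_um, exclusion_um >= 0)
  structure(list(epb_ratio_min = epb_ratio_min,
                 min_z_planes = as.integer(min_z_planes),
                 tb_gain_len_um = tb_gain_len_um,
                 tb_loss_len_um = tb_loss_len_um,
                 reference_window_um = reference_window_um,
                 exclusion_um = exclusion_um,
                 merge_dist_um = merge_dist_um,
                 tb_threshold_frac = tb_threshold_frac,
                 tb_exclude_xy_um = tb_exclude_xy_um,
                 tb_exclude_z_um = tb_exclude_z_um,
                 profile_step_um = profile_step_um),
            class = "detection_params")
}

# robust background level and noise scale of a stack (most voxels are background)
.stack_background <- function(stack) {
  v <- as.vector(stack$data)
  bg <- stats::median(v)
  list(level = bg, sd = max(stats::mad(v), 1e-9))
}

#' Trace the axon backbone through a stack between seed anchors
#'
#' Ridge following: from each seed toward the next, the tracer advances in
#' `step_um` increments and re-centres each step on the intensity ridge by an
#' intensity-weighted centroid in the plane perpendicular to the current
#' direction.  The result is a polyline resampled at <= `step_um` spacing
#' with cumulative arc length in um (anisotropic voxel scaling is implicit
#' in the um coordinates).
#'
#' @param stack An `image_stack`.
#' @param seeds Matrix (>= 2 rows) of seed coordinates in um, in order along
#'   the axon, relative to the stack origin.
#' @param step_um Step size (um).
#' @param search_radius_um In-plane re-centring radius (um).
#' @return A `backbone_trace`: list with `points` (n x 3 um), `arc_length_um`
#'   (cumulative), `length_um`, `source = "traced"`, `axon_id`.
#' @export
trace_backbone <- function(stack, seeds, step_um = 0.5, search_radius_um = 0.8) {
  seeds <- matrix(seeds, ncol = 3)
  if (nrow(seeds) < 2) stop("need at least 2 seed points")
  bg <- .stack_background(stack)
  seed_int <- interp_stack(stack, seeds)
  if (any(seed_int < bg$level + 3 * bg$sd)) {
    stop("seed lies in background (intensity below background + 3 x noise SD)")
  }
  refine <- function(p, dir) {
    # orthonormal in-plane and axial-ish perpendiculars
    u <- c(-dir[2], dir[1], 0)
    nu <- sqrt(sum(u^2))
    if (nu < 1e-6) u <- c(1, 0, 0) else u <- u / nu
    v <- c(dir[2] * u[3] - dir[3] * u[2],
           dir[3] * u[1] - dir[1] * u[3],
           dir[1] * u[2] - dir[2] * u[1])
    a <- seq(-search_radius_um, search_radius_um, by = 0.1)
    b <- seq(-1.5, 1.5, by = 0.5)
    grid <- expand.grid(a = a, b = b)
    pts <- t(p + outer(u, grid$a) + outer(v, grid$b))
    # weight only clearly supra-noise samples so background speckle does not
    # drag the centroid
    w <- pmax(interp_stack(stack, pts) - bg$level - 2 * bg$sd, 0)^2
    if (sum(w) <= 0) return(p)
    # clamp the per-step correction: the ridge bends slowly, so a large jump
    # is a bright neighbour (bouton) or noise, not the backbone
    a_c <- max(-0.3, min(0.3, sum(w * grid$a) / sum(w)))
    b_c <- max(-0.3, min(0.3, sum(w * grid$b) / sum(w)))
    p + u * a_c + v * b_c
  }
  path <- list()
  p <- refine(seeds[1, ], seeds[2, ] - seeds[1, ])
  path[[1]] <- p
  for (k in 2:nrow(seeds)) {
    target <- seeds[k, ]
    dir <- target - p; dir <- dir / sqrt(sum(dir^2))
    max_steps <- ceiling(4 * sqrt(sum((target - p)^2)) / step_um) + 10
    best_gap <- sqrt(sum((target - p)^2))
    stalled <- 0L
    for (i in seq_len(max_steps)) {
      gap <- sqrt(sum((target - p)^2))
      if (gap <= step_um) break
      # a ridge gap shows up as persistent failure to progress
      if (gap < best_gap - 0.25 * step_um) {
        best_gap <- gap; stalled <- 0L
      } else {
        stalled <- stalled + 1L
        if (stalled > 20L) {
          stop(sprintf("disconnected ridge near (%.1f, %.1f, %.1f) um",
                       p[1], p[2], p[3]))
        }
      }
      cand <- p + dir * step_um
      newp <- refine(cand, dir)
      # guard against stalls on flat intensity
      if (sqrt(sum((newp - p)^2)) < 0.25 * step_um) newp <- cand
      dir2 <- newp - p
      dir2 <- dir2 / sqrt(sum(dir2^2))
      dir <- 0.75 * dir + 0.25 * dir2
      dir <- dir / sqrt(sum(dir^2))
      p <- newp
      path[[length(path) + 1]] <- p
    }
    p <- refine(target, dir)
    path[[length(path) + 1]] <- p
  }
  pts <- do.call(rbind, path)
  # light smoothing: suppresses centerline pull at bouton junctions, then
  # resample at the step size so arc length is not inflated by jitter
  if (nrow(pts) >= 5) {
    for (j in 1:3) {
      sm <- stats::filter(pts[, j], rep(1 / 5, 5), sides = 2)
      keep <- !is.na(sm)
      pts[keep, j] <- sm[keep]
    }
  }
  arc0 <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  s_new <- seq(0, arc0[length(arc0)], by = step_um)
  tr0 <- list(points = pts, arc_length_um = arc0, length_um = arc0[length(arc0)])
  pts <- .trace_point(tr0, s_new)
  arc <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  structure(list(points = pts, arc_length_um = arc,
                 length_um = arc[length(arc)], source = "traced",
                 axon_id = stack$axon_id),
            class = "backbone_trace")
}

#' Wrap an already-known polyline as a backbone trace
#'
#' @param points n x 2+ matrix of um coordinates (ordered along the axon).
#' @param axon_id Axon identifier carried into observations.
#' @return A `backbone_trace` with `source = "provided"`.
#' @export
backbone_trace_from_points <- function(points, axon_id = NA_character_) {
  points <- as.matrix(points)
  if (nrow(points) < 2) stop("a trace needs at least 2 points")
  arc <- c(0, cumsum(sqrt(rowSums(diff(points)^2))))
  if (any(diff(arc) < 0)) stop("arc length must be non-decreasing")
  structure(list(points = points, arc_length_um = arc,
                 length_um = arc[length(arc)], source = "provided",
                 axon_id = axon_id),
            class = "backbone_trace")
}

#' @export
print.backbone_trace <- function(x, ...) {
  cat(sprintf("backbone_trace (%s): %.1f um, %d points\n",
              x$source, x$length_um, nrow(x$points)))
  invisible(x)
}

# interpolate the trace polyline at arc positions s
.trace_point <- function(trace, s) {
  arc <- trace$arc_length_um
  s <- pmin(pmax(s, 0), trace$length_um)
  i <- findInterval(s, arc, all.inside = TRUE)
  f <- (s - arc[i]) / pmax(arc[i + 1] - arc[i], 1e-12)
  trace$points[i, , drop = FALSE] * (1 - f) +
    trace$points[i + 1, , drop = FALSE] * f
}

# along-backbone intensity profile sampled every `step` um; with ext_um > 0
# the profile continues beyond the trace ends along the end tangents (the
# shaft continues outside the analysed segment), giving end positions a
# two-sided context
.backbone_profile <- function(stack, trace, step, ext_um = 0) {
  s <- seq(0, trace$length_um, by = step)
  pts <- .trace_point(trace, s)
  if (ext_um > 0) {
    t0 <- .trace_point(trace, 0) - .trace_point(trace, 1)
    t0 <- t0 / sqrt(sum(t0^2))
    t1 <- .trace_point(trace, trace$length_um) -
      .trace_point(trace, trace$length_um - 1)
    t1 <- t1 / sqrt(sum(t1^2))
    es <- seq(step, ext_um, by = step)
    p0 <- .trace_point(trace, 0); p1 <- .trace_point(trace, trace$length_um)
    pts <- rbind(p0[rep(1, length(es)), ] + outer(rev(es), t0[1, ]),
                 pts,
                 p1[rep(1, length(es)), ] + outer(es, t1[1, ]))
    s <- c(-rev(es), s, trace$length_um + es)
  }
  list(s = s, I = interp_stack(stack, pts))
}

#' Backbone reference intensity at an arc position
#'
#' Median intensity of the along-backbone profile inside
#' `+/- reference_window_um` of `pos_um`, excluding `+/- exclusion_um`
#' around it, so a swelling at the scored position does not inflate its own
#' reference.
#'
#' @param stack An `image_stack`.
#' @param trace A `backbone_trace`.
#' @param pos_um Arc position (um).
#' @param params A [detection_params()].
#' @return Reference intensity (raw units, background included).
#' @export
backbone_reference_intensity <- function(stack, trace, pos_um,
                                         params = detection_params()) {
  if (pos_um < 0 || pos_um > trace$length_um) stop("pos_um outside the trace")
  prof <- .backbone_profile(stack, trace, params$profile_step_um)
  sel <- abs(prof$s - pos_um) <= params$reference_window_um &
    abs(prof$s - pos_um) > params$exclusion_um
  if (!any(sel)) stop("reference window empty after exclusion")
  stats::median(prof$I[sel])
}

.rolling_reference <- function(prof, params, mask = NULL, q = 0.2) {
  # Shaft reference for the detector: a low quantile of the windowed profile
  # (optionally with candidate swellings masked out), so that in dense
  # bouton clusters - where swellings can cover most of the window - the
  # reference still tracks the backbone plateau rather than the boutons.
  global_fallback <- if (!is.null(mask) && any(!mask)) {
    stats::quantile(prof$I[!mask], q, names = FALSE)
  } else {
    stats::quantile(prof$I, q, names = FALSE)
  }
  vapply(seq_along(prof$s), function(i) {
    sel <- abs(prof$s - prof$s[i]) <= params$reference_window_um &
      abs(prof$s - prof$s[i]) > params$exclusion_um
    if (!is.null(mask)) sel <- sel & !mask
    if (!any(sel)) return(global_fallback)
    stats::quantile(prof$I[sel], q, names = FALSE)
  }, numeric(1))
}

# consecutive z-planes around the brightest plane with intensity above
# background + half the peak-above-background, at fixed (x, y)
.z_extent <- function(stack, xy, bg) {
  nz <- dim(stack$data)[3]
  zc <- (seq_len(nz) - 0.5) * stack$voxel[3]
  col <- interp_stack(stack, cbind(xy[1], xy[2], zc))
  pk <- which.max(col)
  thr <- bg + 0.5 * (col[pk] - bg)
  above <- col >= thr
  lo <- pk; while (lo > 1 && above[lo - 1]) lo <- lo - 1
  hi <- pk; while (hi < nz && above[hi + 1]) hi <- hi + 1
  hi - lo + 1L
}

#' Detect en passant boutons (EPBs) along a traced backbone
#'
#' Scores local maxima of the along-backbone intensity profile: a candidate
#' is reported when its background-subtracted peak is at least
#' `epb_ratio_min` times the background-subtracted rolling-median backbone
#' reference and the above-half-peak region spans at least `min_z_planes`
#' consecutive z-planes.  Maxima closer than `merge_dist_um` merge into the
#' brighter one.
#'
#' @param stack An `image_stack`.
#' @param trace A `backbone_trace`.
#' @param params A [detection_params()].
#' @return Observation data frame (observation schema), possibly empty.
#' @export
detect_epb <- function(stack, trace, params = detection_params()) {
  bg <- .stack_background(stack)$level
  prof <- .backbone_profile(stack, trace, params$profile_step_um, ext_um = 2.5)
  # two-pass reference: a first pass flags candidate swellings, which are
  # then excluded from every reference window (a bouton cluster must not
  # inflate its own denominator)
  ref1 <- .rolling_reference(prof, params)
  ratio1 <- (prof$I - bg) / pmax(ref1 - bg, 1e-9)
  ref <- .rolling_reference(prof, params, mask = ratio1 >= 1.3)
  ratio <- (prof$I - bg) / pmax(ref - bg, 1e-9)
  above <- ratio >= params$epb_ratio_min
  if (!any(above)) return(empty_observations())
  # peaks: local maxima of the ratio profile inside the above-threshold
  # region (two nearby swellings can keep the ratio above threshold between
  # them, so a run may hold several boutons), then merge close peaks
  np <- length(ratio)
  left <- c(ratio[1], ratio[-np]); right <- c(ratio[-1], ratio[np])
  is_max <- ratio >= left & ratio >= right
  # plateau de-duplication: keep the first sample of each flat maximum
  is_max[is_max & c(FALSE, ratio[-1] == ratio[-np]) & c(FALSE, is_max[-np])] <- FALSE
  peaks <- which(above & is_max)
  merged <- logical(length(peaks))
  for (j in seq_along(peaks)) {
    if (merged[j]) next
    close_j <- which(abs(prof$s[peaks] - prof$s[peaks[j]]) <= params$merge_dist_um)
    keep <- close_j[which.max(ratio[peaks[close_j]])]
    merged[setdiff(close_j, keep)] <- TRUE
  }
  peaks <- peaks[!merged]
  # swellings of the continuing shaft beyond the segment ends are not scored
  peaks <- peaks[prof$s[peaks] >= -0.4 &
                   prof$s[peaks] <= trace$length_um + 0.4]
  if (!length(peaks)) return(empty_observations())
  rows <- lapply(peaks, function(i) {
    p <- .trace_point(trace, prof$s[i])
    zext <- .z_extent(stack, p[1, 1:2], bg)
    data.frame(axon_id = trace$axon_id %||% stack$axon_id %||% NA_character_,
               session = stack$session %||% NA_integer_,
               type = "EPB",
               arc_pos_um = min(max(prof$s[i], 0), trace$length_um),
               intensity_ratio = ratio[i],
               protrusion_len_um = NA_real_,
               z_extent_planes = zext, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$z_extent_planes >= params$min_z_planes, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# 6-connected components of voxel index matrix (n x 3); returns labels
.connected_components <- function(idx, dims) {
  n <- nrow(idx)
  lin <- idx[, 1] + (idx[, 2] - 1) * dims[1] + (idx[, 3] - 1) * dims[1] * dims[2]
  lookup <- new.env(hash = TRUE, size = n)
  for (i in seq_len(n)) assign(as.character(lin[i]), i, envir = lookup)
  labels <- integer(n)
  comp <- 0L
  offsets <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                   c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  off_lin <- offsets[, 1] + offsets[, 2] * dims[1] + offsets[, 3] * dims[1] * dims[2]
  for (i in seq_len(n)) {
    if (labels[i] > 0) next
    comp <- comp + 1L
    queue <- i
    labels[i] <- comp
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (nb in lin[cur] + off_lin) {
        j <- mget(as.character(nb), envir = lookup, ifnotfound = list(NULL))[[1]]
        if (!is.null(j) && labels[j] == 0) {
          labels[j] <- comp
          queue <- c(queue, j)
        }
      }
    }
  }
  labels
}

#' Detect terminaux bouton (TB) candidates as side protrusions
#'
#' Thresholds the volume at background + `tb_threshold_frac` of the backbone
#' amplitude, removes voxels inside an elliptical exclusion zone around the
#' backbone centerline (half-axes `tb_exclude_xy_um` laterally and
#' `tb_exclude_z_um` axially, matching the anisotropic blur of the shaft),
#' and groups the remaining voxels into 6-connected components.  Each
#' component is a protrusion candidate; its length is the largest distance
#' from the centerline among voxels at or above half the backbone amplitude
#' (FWHM edge localisation), its arc position is that of the nearest
#' centerline point.  All candidates with length >= `tb_loss_len_um` are
#' reported; present/absent classification is deferred to tracking, which
#' owns the hysteresis rule.
#'
#' @inheritParams detect_epb
#' @return Observation data frame (observation schema), possibly empty.
#' @export
detect_tb <- function(stack, trace, params = detection_params()) {
  bg <- .stack_background(stack)$level
  prof <- .backbone_profile(stack, trace, params$profile_step_um)
  amp <- stats::median(prof$I) - bg             # backbone plateau amplitude
  if (amp <= 0) return(empty_observations())
  thr <- bg + params$tb_threshold_frac * amp
  d <- dim(stack$data)
  keep <- which(stack$data >= thr)
  if (!length(keep)) return(empty_observations())
  ai <- arrayInd(keep, d)
  vx <- (ai[, 1] - 0.5) * stack$voxel[1]
  vy <- (ai[, 2] - 0.5) * stack$voxel[2]
  vz <- (ai[, 3] - 0.5) * stack$voxel[3]
  # distances to the centerline polyline (dense samples), extended beyond the
  # trace ends so the continuing axon shaft outside the analysed segment is
  # excluded rather than mistaken for a protrusion
  cl_arc <- seq(0, trace$length_um, by = 0.25)
  cl <- .trace_point(trace, cl_arc)
  ext_um <- 6
  t0 <- .trace_point(trace, 1) - .trace_point(trace, 0)
  t0 <- t0 / sqrt(sum(t0^2))
  t1 <- .trace_point(trace, trace$length_um) -
    .trace_point(trace, trace$length_um - 1)
  t1 <- t1 / sqrt(sum(t1^2))
  ext_s <- seq(0.25, ext_um, by = 0.25)
  p0 <- .trace_point(trace, 0); p1 <- .trace_point(trace, trace$length_um)
  cl <- rbind(p0[rep(1, length(ext_s)), ] - outer(ext_s, t0[1, ]),
              cl,
              p1[rep(1, length(ext_s)), ] + outer(ext_s, t1[1, ]))
  cl_arc <- c(-rev(ext_s), cl_arc, trace$length_um + ext_s)
  n <- length(vx)
  d_xy <- numeric(n); d_z <- numeric(n); d_3 <- numeric(n); near <- integer(n)
  chunk <- 2000L
  for (st in seq(1, n, by = chunk)) {
    en <- min(st + chunk - 1L, n)
    dx <- outer(vx[st:en], cl[, 1], `-`)
    dy <- outer(vy[st:en], cl[, 2], `-`)
    dz <- outer(vz[st:en], cl[, 3], `-`)
    d2 <- dx^2 + dy^2 + dz^2
    j <- max.col(-d2, ties.method = "first")
    sel <- cbind(seq_len(en - st + 1), j)
    d_xy[st:en] <- sqrt(dx[sel]^2 + dy[sel]^2)
    d_z[st:en] <- abs(dz[sel])
    d_3[st:en] <- sqrt(d2[sel])
    near[st:en] <- j
  }
  outside <- (d_xy / params$tb_exclude_xy_um)^2 +
    (d_z / params$tb_exclude_z_um)^2 >= 1
  if (!any(outside)) return(empty_observations())
  ai <- ai[outside, , drop = FALSE]
  vals <- stack$data[keep][outside]
  d_3 <- d_3[outside]; d_xy <- d_xy[outside]; near <- near[outside]
  labels <- .connected_components(ai, d)
  half <- bg + 0.5 * amp
  rows <- list()
  for (cc in unique(labels)) {
    sel <- labels == cc
    if (sum(sel) < 2) next
    solid <- sel & vals >= half
    if (!any(solid)) next
    # protrusion length measured laterally from the centerline: the axial
    # PSF (sigma >> voxel) smears thin side branches in z, so the in-plane
    # distance of the farthest half-maximum voxel localises the tip
    len <- max(d_xy[solid]) + 0.5 * stack$voxel[1]   # voxel centre -> edge
    if (len < params$tb_loss_len_um) next
    jn <- near[sel][which.min(d_3[sel])]
    # junction must sit on the analysed segment (with headroom for the
    # traced endpoint stopping slightly short of the anatomical end);
    # protrusions rooted clearly beyond the ends are not scored
    if (cl_arc[jn] < -1.5 || cl_arc[jn] > trace$length_um + 1.5) next
    z_planes <- sort(unique(ai[solid, 3]))
    if (length(z_planes) == 1) {
      zext <- 1L
    } else {
      r <- rle(diff(z_planes) == 1)
      zext <- if (any(r$values)) max(r$lengths[r$values]) + 1L else 1L
    }
    rows[[length(rows) + 1]] <- data.frame(
      axon_id = trace$axon_id %||% stack$axon_id %||% NA_character_,
      session = stack$session %||% NA_integer_,
      type = "TB", arc_pos_um = min(max(cl_arc[jn], 0), trace$length_um),
      intensity_ratio = NA_real_,
      protrusion_len_um = len,
      z_extent_planes = zext, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty_observations())
  out <- do.call(rbind, rows)
  out <- out[order(out$arc_pos_um), , drop = FALSE]
  # one protrusion can split across the exclusion zone into two components;
  # merge candidates closer than the merge distance, keeping the longer
  keep <- rep(TRUE, nrow(out))
  if (nrow(out) > 1) {
    for (i in 2:nrow(out)) {
      prev <- max(which(keep[1:(i - 1)]))
      if (out$arc_pos_um[i] - out$arc_pos_um[prev] < params$merge_dist_um) {
        if (out$protrusion_len_um[i] > out$protrusion_len_um[prev]) {
          keep[prev] <- FALSE
        } else {
          keep[i] <- FALSE
        }
      }
    }
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect boutons of the appropriate type for an axon
#'
#' @param stack An `image_stack`.
#' @param trace A `backbone_trace`.
#' @param type `"EPB"` or `"TB"`.
#' @param params A [detection_params()].
#' @return Observation data frame.
#' @export
detect_boutons <- function(stack, trace, type, params = detection_params()) {
  switch(match.arg(type, c("EPB", "TB")),
         EPB = detect_epb(stack, trace, params),
         TB = detect_tb(stack, trace, params))
}
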