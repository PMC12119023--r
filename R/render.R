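#' Rendering configuration for synthetic two-photon stacks
#'
#' Voxel geometry, anisotropic Gaussian PSF widths and intensity/noise model
#' used by [render_stack()].  Defaults are typical two-photon scales:
#' 0.25 um lateral / 1.0 um axial voxels, PSF sigma 0.3 um (xy) / 1.2 um (z).
#'
#' @param voxel_xy_um,voxel_z_um Voxel spacing (um); must be positive.
#' @param psf_sigma_xy_um,psf_sigma_z_um Gaussian PSF sigma (um).
#' @param backbone_intensity Mean on-backbone signal (photon counts) after
#'   blurring; bouton swellings scale relative to this.
#' @param background Background level (photon counts).
#' @param read_noise_sd Gaussian read-noise SD (intensity units).
#' @param photon_noise Apply Poisson noise to the photon counts.
#' @return A `render_config` list.
#' @export
render_config <- function(voxel_xy_um = 0.25, voxel_z_um = 1.0,
                          psf_sigma_xy_um = 0.3, psf_sigma_z_um = 1.2,
                          backbone_intensity = 100, background = 10,
                          read_noise_sd = 2, photon_noise = TRUE) {
  stopifnot(voxel_xy_um > 0, voxel_z_um > 0,
            psf_sigma_xy_um > 0, psf_sigma_z_um > 0,
            backbone_intensity >= 0, background >= 0, read_noise_sd >= 0)
  if (backbone_intensity == 0) stop("backbone_intensity must be positive to image anything")
  if (voxel_xy_um > psf_sigma_xy_um * 2 || voxel_z_um > psf_sigma_z_um * 2) {
    warning("voxel spacing exceeds 2x the PSF sigma: the stack is undersampled")
  }
  structure(list(voxel_xy_um = voxel_xy_um, voxel_z_um = voxel_z_um,
                 psf_sigma_xy_um = psf_sigma_xy_um,
                 psf_sigma_z_um = psf_sigma_z_um,
                 backbone_intensity = backbone_intensity,
                 background = background,
                 read_noise_sd = read_noise_sd,
                 photon_noise = isTRUE(photon_noise)),
            class = "render_config")
}

#' Noise-free rendering preset
#' @inheritParams render_config
#' @param ... Passed to [render_config()].
#' @export
render_config_noiseless <- function(...) {
  render_config(read_noise_sd = 0, photon_noise = FALSE, ...)
}

# --- low-level array helpers ------------------------------------------------

# 1D Gaussian convolution along dimension `dm` of a 3D array (zero padding)
.gauss_blur_dim <- function(arr, sigma_vox, dm) {
  if (sigma_vox <= 0) return(arr)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- stats::dnorm(-r:r, sd = sigma_vox)
  k <- k / sum(k)
  d <- dim(arr)
  perm <- c(dm, setdiff(1:3, dm))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = d[dm])
  pad <- matrix(0, nrow = r, ncol = ncol(m))
  f <- stats::filter(rbind(pad, m, pad), k, sides = 2)
  m2 <- matrix(f[(r + 1):(r + d[dm]), ], nrow = d[dm])
  a2 <- array(m2, dim = d[perm])
  aperm(a2, order(perm))
}

.gauss_blur <- function(arr, sigma_vox_xyz) {
  arr <- .gauss_blur_dim(arr, sigma_vox_xyz[1], 1)
  arr <- .gauss_blur_dim(arr, sigma_vox_xyz[2], 2)
  .gauss_blur_dim(arr, sigma_vox_xyz[3], 3)
}

# trilinear deposit of weighted samples (um coordinates) into a voxel array;
# voxel centres sit at (i - 0.5) * spacing
.deposit <- function(arr, pts, w, voxel) {
  pts <- matrix(pts, ncol = 3)
  g <- sweep(pts, 2, voxel, "/") - 0.5      # continuous voxel index - 1
  i0 <- floor(g)
  f <- g - i0
  d <- dim(arr)
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    ix <- i0[, 1] + cx + 1L; iy <- i0[, 2] + cy + 1L; iz <- i0[, 3] + cz + 1L
    wt <- w *
      (cx * f[, 1] + (1 - cx) * (1 - f[, 1])) *
      (cy * f[, 2] + (1 - cy) * (1 - f[, 2])) *
      (cz * f[, 3] + (1 - cz) * (1 - f[, 3]))
    ok <- ix >= 1 & ix <= d[1] & iy >= 1 & iy <= d[2] & iz >= 1 & iz <= d[3]
    if (any(ok)) {
      lin <- ix[ok] + (iy[ok] - 1) * d[1] + (iz[ok] - 1) * d[1] * d[2]
      add <- rowsum(wt[ok], lin)
      at <- as.integer(rownames(add))
      arr[at] <- arr[at] + add[, 1]
    }
  }
  arr
}

#' Trilinear interpolation of an image stack at continuous um positions
#'
#' @param stack An `image_stack`.
#' @param pts n x 3 matrix of (x, y, z) positions in um.
#' @return Numeric vector of interpolated intensities (outside voxels clamp
#'   to the border).
#' @export
interp_stack <- function(stack, pts) {
  v <- stack$data
  d <- dim(v)
  pts <- matrix(pts, ncol = 3)
  g <- sweep(pts, 2, stack$voxel, "/") - 0.5
  g[, 1] <- pmin(pmax(g[, 1], 0), d[1] - 1)
  g[, 2] <- pmin(pmax(g[, 2], 0), d[2] - 1)
  g[, 3] <- pmin(pmax(g[, 3], 0), d[3] - 1)
  i0 <- pmin(floor(g), rep(1, nrow(g)) %o% (d - 2))
  i0[i0 < 0] <- 0
  f <- g - i0
  out <- numeric(nrow(pts))
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    wt <- (cx * f[, 1] + (1 - cx) * (1 - f[, 1])) *
      (cy * f[, 2] + (1 - cy) * (1 - f[, 2])) *
      (cz * f[, 3] + (1 - cz) * (1 - f[, 3]))
    out <- out + wt * v[cbind(i0[, 1] + cx + 1L, i0[, 2] + cy + 1L, i0[, 3] + cz + 1L)]
  }
  out
}

# linear interpolation of the backbone polyline at arc positions s (um)
.backbone_point <- function(world, s) {
  arc <- world$arc
  pts <- world$backbone
  s <- pmin(pmax(s, 0), arc[length(arc)])
  i <- findInterval(s, arc, all.inside = TRUE)
  f <- (s - arc[i]) / (arc[i + 1] - arc[i])
  pts[i, , drop = FALSE] * (1 - f) + pts[i + 1, , drop = FALSE] * f
}

# unit tangent at arc position s
.backbone_tangent <- function(world, s) {
  eps <- 0.5
  p1 <- .backbone_point(world, s - eps)
  p2 <- .backbone_point(world, s + eps)
  t <- p2 - p1
  t / sqrt(sum(t^2))
}

#' Render one imaging session of an axon world as a 3D image stack
#'
#' The axon backbone is drawn as a uniform-intensity line (extended a few um
#' beyond both ends, as real axons continue outside the analysed segment) and
#' blurred with the anisotropic Gaussian PSF, so it appears as a tube whose
#' on-axis plateau equals `backbone_intensity`.  Live EPBs multiply the local
#' line density by their intensity ratio over a ~0.75 um Gaussian
#' neighbourhood; live TBs are rendered as side tubes of the session's
#' protrusion length, perpendicular to the backbone in the imaging plane.
#' Optional Poisson photon noise and Gaussian read noise are applied on top
#' of the background.
#'
#' @param world An `axon_world`.
#' @param session Session index.
#' @param rc A [render_config()].
#' @param seed RNG seed for the noise draw (ignored when noise is off).
#' @param margin_um Empty margin around the axon bounding box (um).
#' @return An `image_stack`: list with `data` (array x,y,z), `voxel`
#'   (um spacings), `origin` (um), `axon_id`, `session`.
#' @export
render_stack <- function(world, session, rc = render_config(), seed = 1L,
                         margin_um = 4) {
  stopifnot(inherits(world, "axon_world"))
  if (session < 1 || session > world$n_sessions) stop("session out of range")
  ext <- 3                    # backbone extension beyond segment ends (um)
  bb <- world$backbone
  tb_max <- 3                 # allow room for protrusions
  lo <- apply(bb, 2, min) - margin_um - c(ext, tb_max, 0)
  hi <- apply(bb, 2, max) + margin_um + c(ext, tb_max, 0)
  lo[3] <- min(bb[, 3]) - 4; hi[3] <- max(bb[, 3]) + 4
  voxel <- c(rc$voxel_xy_um, rc$voxel_xy_um, rc$voxel_z_um)
  dims <- pmax(2L, ceiling((hi - lo) / voxel))
  arr <- array(0, dim = dims)

  step <- 0.05
  L <- world$length_um
  # backbone including extensions along the end tangents
  s_grid <- seq(0, L, by = step)
  pts <- .backbone_point(world, s_grid) - rep(lo, each = length(s_grid))
  t0 <- .backbone_tangent(world, 0); t1 <- .backbone_tangent(world, L)
  ext_t <- seq(step, ext, by = step)
  p_start <- .backbone_point(world, 0); p_end <- .backbone_point(world, L)
  ext_pts <- rbind(
    p_start[rep(1, length(ext_t)), ] - outer(ext_t, t0[1, ]),
    p_end[rep(1, length(ext_t)), ] + outer(ext_t, t1[1, ])
  ) - rep(lo, each = 2 * length(ext_t))

  live <- which(.is_alive(world$boutons, session))
  w_bb <- rep(step, length(s_grid))
  if (world$bouton_type == "EPB" && length(live)) {
    # EPB: local multiplicative swelling of the line density (Gaussian,
    # sigma 0.6 um).  The along-axon PSF blur attenuates a Gaussian bump by
    # w / sqrt(w^2 + sigma_psf^2); pre-compensating makes the *observable*
    # peak / backbone ratio equal the ground-truth ratio, which is how the
    # presence criterion defines bouton intensity.
    w_sig <- 0.6
    comp <- sqrt(w_sig^2 + rc$psf_sigma_xy_um^2) / w_sig
    for (i in live) {
      b <- world$boutons[i, ]
      ratio <- b$sizes[[1]][session - b$birth_session + 1]
      w_bb <- w_bb + step * (ratio - 1) * comp *
        exp(-(s_grid - b$arc_pos_um)^2 / (2 * w_sig^2))
    }
  }
  arr <- .deposit(arr, pts, w_bb, voxel)
  arr <- .deposit(arr, ext_pts, rep(step, nrow(ext_pts)), voxel)

  if (world$bouton_type == "TB" && length(live)) {
    for (i in live) {
      b <- world$boutons[i, ]
      len <- b$sizes[[1]][session - b$birth_session + 1]
      base <- .backbone_point(world, b$arc_pos_um)
      tang <- .backbone_tangent(world, b$arc_pos_um)
      n_xy <- c(-tang[1, 2], tang[1, 1], 0)
      n_xy <- n_xy / sqrt(sum(n_xy^2))
      side <- if (i %% 2 == 0) 1 else -1
      tt <- seq(0, len, by = step)
      tube <- base[rep(1, length(tt)), ] + outer(tt, side * n_xy) -
        rep(lo, each = length(tt))
      arr <- .deposit(arr, tube, rep(step, length(tt)), voxel)
    }
  }

  sig_vox <- c(rc$psf_sigma_xy_um, rc$psf_sigma_xy_um, rc$psf_sigma_z_um) / voxel
  arr <- .gauss_blur(arr, sig_vox)

  # calibrate: on-backbone plateau (away from boutons and ends) -> backbone_intensity
  stack0 <- list(data = arr, voxel = voxel, origin = lo)
  s_ref <- seq(2, L - 2, by = 0.5)
  if (length(live)) {
    near <- vapply(s_ref, function(s)
      any(abs(s - world$boutons$arc_pos_um[live]) < 2.5), logical(1))
    s_ref <- s_ref[!near]
  }
  if (length(s_ref) < 5) s_ref <- seq(2, L - 2, by = 0.5)
  ref_pts <- .backbone_point(world, s_ref) - rep(lo, each = length(s_ref))
  plateau <- stats::median(interp_stack(stack0, ref_pts))
  arr <- arr * (rc$backbone_intensity / plateau) + rc$background

  if (rc$photon_noise || rc$read_noise_sd > 0) {
    set.seed(seed)
    if (rc$photon_noise) arr[] <- stats::rpois(length(arr), pmax(arr, 0))
    if (rc$read_noise_sd > 0)
      arr <- arr + stats::rnorm(length(arr), sd = rc$read_noise_sd)
    arr[arr < 0] <- 0
  }

  structure(list(data = arr, voxel = voxel, origin = unname(lo),
                 axon_id = world$axon_id, session = session),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("image_stack %s session %s: %d x %d x %d voxels @ (%.3g, %.3g, %.3g) um\n",
              x$axon_id %||% "?", x$session %||% "?",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              x$voxel[1], x$voxel[2], x$voxel[3]))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an image stack as a multi-page TIFF (one page per z-plane)
#'
#' Intensities are stored as 16-bit counts; the voxel size and origin are
#' recorded in a JSON sidecar next to the TIFF (`<file>.json`) so the stack
#' round-trips exactly.
#'
#' @param stack An `image_stack`.
#' @param path Output file (`.tif`).
#' @export
write_stack_tiff <- function(stack, path) {
  d <- dim(stack$data)
  pages <- lapply(seq_len(d[3]), function(z) {
    # TIFF page: rows = y, cols = x, values in [0, 1] as counts / 65535
    t(pmin(round(stack$data[, , z]), 65535L)) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  meta <- list(voxel_um = as.numeric(stack$voxel),
               origin_um = as.numeric(stack$origin),
               axon_id = stack$axon_id, session = stack$session)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF written by [write_stack_tiff()]
#'
#' @param path TIFF file path.
#' @return An `image_stack`.
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path)) stop("missing stack metadata sidecar: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  nz <- length(pages)
  d1 <- dim(pages[[1]])
  arr <- array(0, dim = c(d1[2], d1[1], nz))
  for (z in seq_len(nz)) arr[, , z] <- t(pages[[z]]) * 65535
  structure(list(data = arr, voxel = as.numeric(meta$voxel_um),
                 origin = as.numeric(meta$origin_um),
                 axon_id = meta$axon_id, session = meta$session),
            class = "image_stack")
}
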