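## Sample n points uniformly inside a sphere (d = diameter) or ellipsoid
## (axes = full axis lengths c(ax, ay, az)), centered at `center` (nm).
sample_in_shape <- function(n, shape = c("sphere", "ellipsoid"),
                            diameter = 450, axes = c(350, 350, 200),
                            center = c(0, 0, 0)) {
  shape <- match.arg(shape)
  semi <- if (shape == "sphere") rep(diameter / 2, 3) else axes / 2
  ## uniform in the unit ball, then scale per axis
  p <- matrix(stats::rnorm(3 * n), ncol = 3)
  p <- p / sqrt(rowSums(p^2)) * stats::runif(n)^(1 / 3)
  sweep(p %*% diag(semi), 2, center, "+")
}

#' Generate a synthetic MFM-PALM blinking movie (localization tables)
#'
#' Fluorophores sit at fixed positions inside their cluster shapes; each
#' frame they activate sparsely, stay on for a geometrically distributed
#' number of consecutive frames (mean `mean_event_frames`), and every
#' active frame yields one localization: true position + anisotropic
#' Gaussian localization noise + stage drift.  Immobilized gold-nanorod
#' fiducials are localized in every frame with small jitter plus the same
#' drift.  The ground truth records every fluorophore's identity and
#' cluster, so grouping and drift correction can be checked against an
#' oracle.
#'
#' With `activation = "sequential"` fluorophores turn on one at a time with
#' dark gaps in between, guaranteeing non-overlapping events (exact event
#' counting); with `"random"` each inactive fluorophore activates with
#' probability `activation_rate` per frame.
#'
#' @param clusters list, one per cluster: `list(center = c(x, y, z) nm,
#'   n_fluorophores, shape = "sphere"|"ellipsoid", diameter, axes)`.
#' @param activation `"sequential"` or `"random"`.
#' @param activation_rate per-frame activation probability
#'   (random mode; default 0.02 keeps <= ~1 new event per cluster per
#'   frame).
#' @param mean_event_frames mean on-time, frames (geometric; default 2).
#' @param loc_noise localization precision SDs `c(x, y, z)`, nm
#'   (default 20, 20, 50).
#' @param fiducials matrix of fiducial positions (n x 3, nm) or `NULL`.
#' @param fiducial_jitter per-frame fiducial localization SD, nm.
#' @param drift either `NULL`, a total-drift vector `c(dx, dy, dz)` applied
#'   as a linear ramp over the movie, or an `n_frames` x 3 matrix.
#' @param n_frames movie length (extended automatically in sequential mode
#'   if too short).
#' @param seed RNG seed.
#' @return list: `locs` (localization data.frame with `frame`, `x_nm`,
#'   `y_nm`, `z_nm`, `sigma_xy_nm`, `sigma_z_nm`, `is_fiducial`), `truth`
#'   (per-localization `fluorophore` and `cluster` ids; per-fluorophore
#'   table; the drift trace; cluster definitions).
#' @export
generate_palm_movie <- function(clusters = list(
                                  list(center = c(0, 0, 0),
                                       n_fluorophores = 21,
                                       shape = "sphere", diameter = 450)),
                                activation = c("sequential", "random"),
                                activation_rate = 0.02,
                                mean_event_frames = 2,
                                loc_noise = c(20, 20, 50),
                                fiducials = rbind(c(-2000, -2000, 0),
                                                  c(2000, 2000, 0)),
                                fiducial_jitter = 2,
                                drift = NULL, n_frames = 400, seed = 1) {
  activation <- match.arg(activation)
  set.seed(seed)
  loc_noise <- rep_len(loc_noise, 3L)
  ## fluorophore ground-truth positions
  fl <- list()
  for (ci in seq_along(clusters)) {
    cl <- clusters[[ci]]
    ctr <- cl$center %||% c(0, 0, 0)
    pos <- sample_in_shape(cl$n_fluorophores, cl$shape %||% "sphere",
                           diameter = cl$diameter %||% 450,
                           axes = cl$axes %||% c(350, 350, 200),
                           center = c(0, 0, 0))
    if (!is.null(cl$rotation)) pos <- pos %*% cl$rotation
    pos <- sweep(pos, 2, ctr, "+")
    fl[[ci]] <- data.frame(fluorophore = NA_integer_, cluster = ci,
                           x = pos[, 1], y = pos[, 2], z = pos[, 3])
  }
  fl <- do.call(rbind, fl)
  fl$fluorophore <- seq_len(nrow(fl))
  n_fl <- nrow(fl)
  ## on-times (geometric, support >= 1, mean mean_event_frames)
  on_len <- 1L + stats::rgeom(n_fl, prob = 1 / mean_event_frames)
  if (activation == "sequential") {
    gap <- 2L
    start <- cumsum(c(1L, utils::head(on_len, -1) + gap))
    n_frames <- max(n_frames, start[n_fl] + on_len[n_fl] + 1L)
  } else {
    start <- rep(NA_integer_, n_fl)
    pending <- seq_len(n_fl)
    for (f in seq_len(n_frames)) {
      if (!length(pending)) break
      act <- stats::runif(length(pending)) < activation_rate
      start[pending[act]] <- f
      pending <- pending[!act]
    }
  }
  ## drift trace
  dr <- matrix(0, n_frames, 3)
  if (!is.null(drift)) {
    if (is.matrix(drift)) {
      if (nrow(drift) < n_frames)
        stopf("drift matrix shorter than the movie")
      dr <- drift[seq_len(n_frames), , drop = FALSE]
    } else {
      ramp <- (seq_len(n_frames) - 1) / max(n_frames - 1, 1)
      dr <- outer(ramp, drift)
    }
  }
  rows <- list()
  for (i in seq_len(n_fl)) {
    if (is.na(start[i]) || start[i] > n_frames) next
    frames <- start[i]:min(start[i] + on_len[i] - 1L, n_frames)
    k <- length(frames)
    rows[[length(rows) + 1L]] <- data.frame(
      frame = frames - 1L,
      x_nm = fl$x[i] + stats::rnorm(k, 0, loc_noise[1]) + dr[frames, 1],
      y_nm = fl$y[i] + stats::rnorm(k, 0, loc_noise[2]) + dr[frames, 2],
      z_nm = fl$z[i] + stats::rnorm(k, 0, loc_noise[3]) + dr[frames, 3],
      sigma_xy_nm = loc_noise[1], sigma_z_nm = loc_noise[3],
      is_fiducial = FALSE, fluorophore = fl$fluorophore[i],
      cluster = fl$cluster[i])
  }
  if (!is.null(fiducials)) {
    fiducials <- as.matrix(fiducials)
    for (j in seq_len(nrow(fiducials))) {
      rows[[length(rows) + 1L]] <- data.frame(
        frame = 0:(n_frames - 1L),
        x_nm = fiducials[j, 1] + stats::rnorm(n_frames, 0, fiducial_jitter) +
          dr[, 1],
        y_nm = fiducials[j, 2] + stats::rnorm(n_frames, 0, fiducial_jitter) +
          dr[, 2],
        z_nm = fiducials[j, 3] + stats::rnorm(n_frames, 0, fiducial_jitter) +
          dr[, 3],
        sigma_xy_nm = fiducial_jitter, sigma_z_nm = fiducial_jitter,
        is_fiducial = TRUE, fluorophore = NA_integer_,
        cluster = NA_integer_)
    }
  }
  locs <- do.call(rbind, rows)
  locs <- locs[order(locs$frame), , drop = FALSE]
  rownames(locs) <- NULL
  truth_cols <- c("fluorophore", "cluster")
  truth <- locs[, c("frame", truth_cols)]
  list(locs = locs[, setdiff(names(locs), truth_cols)],
       truth = list(per_localization = truth, fluorophores = fl,
                    drift = data.frame(frame = 0:(n_frames - 1L),
                                       dx = dr[, 1], dy = dr[, 2],
                                       dz = dr[, 3]),
                    clusters = clusters),
       n_frames = n_frames)
}

#' Project a Z-stack into a raw multifocal camera frame
#'
#' The forward counterpart of [assemble_mfm]: each plane of the stack is
#' resampled through its tile's registration transform, multiplied by the
#' tile transmission, and placed at the tile's grid position.  Used to
#' build synthetic MFM frames with known ground truth for round-trip tests.
#'
#' @param stack 3D array `[y, x, plane]` matching `geom$tile_shape`.
#' @param geom an [mfm_geometry].
#' @return camera-frame matrix.
#' @export
mfm_project <- function(stack, geom) {
  th <- geom$tile_shape[1]; tw <- geom$tile_shape[2]
  lay <- geom$tile_layout
  frame <- matrix(0, nrow(lay) * th, ncol(lay) * tw)
  gx <- rep(0:(tw - 1), each = th); gy <- rep(0:(th - 1), times = tw)
  for (r in seq_len(nrow(lay))) for (cc in seq_len(ncol(lay))) {
    p <- lay[r, cc]
    if (is.na(p) || p < 1 || p > dim(stack)[3]) next
    tr <- geom$transforms[[p]]
    tile <- if (tr$dx == 0 && tr$dy == 0 && tr$scale == 1) {
      stack[, , p]
    } else {
      ## tile coordinate q maps from common coordinate p = q*scale + shift
      matrix(bilinear_sample(stack[, , p], gx * tr$scale + tr$dx,
                             gy * tr$scale + tr$dy), th, tw)
    }
    frame[((r - 1) * th + 1):(r * th), ((cc - 1) * tw + 1):(cc * tw)] <-
      tile * geom$transmission[p]
  }
  frame
}
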