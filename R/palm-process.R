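#' Multifocal-plane microscope geometry
#'
#' A diffractive grating images several focal planes side-by-side on one
#' camera frame; the default layout is nine planes 380 nm apart on a 3x3
#' tile grid, with a final image voxel of 120 x 120 x 380 nm.  Each tile
#' carries a registration transform (translation plus optional isotropic
#' scale) and a transmission factor.
#'
#' @param n_planes number of focal planes.
#' @param plane_spacing axial spacing between consecutive planes, nm.
#' @param tile_shape `c(height, width)` of one tile, pixels.
#' @param tile_layout integer matrix mapping grid positions to plane indices
#'   (1-based; row-major default `matrix(1:9, 3, 3, byrow = TRUE)`).
#' @param lateral_pixel lateral pixel size, nm.
#' @param transforms list (one per plane) of `list(dx, dy, scale)`:
#'   a feature at tile coordinate `p` appears at common-grid coordinate
#'   `p * scale + shift`.  Default identity.
#' @param transmission per-plane relative transmission factors (> 0).
#' @return An object of class `mfm_geometry`.
#' @export
mfm_geometry <- function(n_planes = 9, plane_spacing = 380,
                         tile_shape = c(32, 32),
                         tile_layout = matrix(seq_len(n_planes),
                                              ceiling(sqrt(n_planes)),
                                              ceiling(n_planes /
                                                ceiling(sqrt(n_planes))),
                                              byrow = TRUE),
                         lateral_pixel = 120,
                         transforms = NULL, transmission = NULL) {
  if (n_planes < 1) stopf("n_planes must be >= 1")
  if (plane_spacing <= 0) stopf("plane_spacing must be > 0")
  transmission <- transmission %||% rep(1, n_planes)
  if (any(transmission <= 0)) stopf("transmission factors must be > 0")
  transforms <- transforms %||% replicate(n_planes,
    list(dx = 0, dy = 0, scale = 1), simplify = FALSE)
  structure(list(n_planes = n_planes, plane_spacing = plane_spacing,
                 tile_shape = tile_shape, tile_layout = tile_layout,
                 lateral_pixel = lateral_pixel, transforms = transforms,
                 transmission = transmission),
            class = "mfm_geometry")
}

## Bilinear sample of img (matrix) at 0-based coordinates (xs, ys);
## outside the support -> 0.
bilinear_sample <- function(img, xs, ys) {
  nr <- nrow(img); nc <- ncol(img)
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  val <- function(yy, xx) {
    ok <- xx >= 0 & xx <= nc - 1 & yy >= 0 & yy <= nr - 1
    out <- numeric(length(xx))
    out[ok] <- img[cbind(yy[ok] + 1, xx[ok] + 1)]
    out
  }
  (1 - fx) * (1 - fy) * val(y0, x0) + fx * (1 - fy) * val(y0, x0 + 1) +
    (1 - fx) * fy * val(y0 + 1, x0) + fx * fy * val(y0 + 1, x0 + 1)
}

#' Assemble a raw multifocal camera frame into a Z-stack
#'
#' Crops each tile from the camera frame, divides it by its transmission
#' factor, resamples it through its registration transform onto the common
#' lateral grid, and stacks the planes in order with `z = plane_index *
#' plane_spacing` (plane 0 nearest the coverslip).
#'
#' @param frame raw camera frame (matrix) whose shape equals
#'   `tile_shape * dim(tile_layout)`.
#' @param geom an [mfm_geometry].
#' @return 3D array `[y, x, plane]`.
#' @export
assemble_mfm <- function(frame, geom) {
  th <- geom$tile_shape[1]; tw <- geom$tile_shape[2]
  lay <- geom$tile_layout
  if (nrow(frame) < nrow(lay) * th || ncol(frame) < ncol(lay) * tw)
    stopf("tile layout (%dx%d tiles of %dx%d) exceeds frame (%dx%d)",
          nrow(lay), ncol(lay), th, tw, nrow(frame), ncol(frame))
  stack <- array(0, c(th, tw, geom$n_planes))
  gx <- rep(0:(tw - 1), each = th); gy <- rep(0:(th - 1), times = tw)
  for (r in seq_len(nrow(lay))) for (cc in seq_len(ncol(lay))) {
    p <- lay[r, cc]
    if (is.na(p) || p < 1) next
    tile <- frame[((r - 1) * th + 1):(r * th),
                  ((cc - 1) * tw + 1):(cc * tw)] / geom$transmission[p]
    tr <- geom$transforms[[p]]
    if (tr$dx == 0 && tr$dy == 0 && tr$scale == 1) {
      stack[, , p] <- tile
    } else {
      v <- bilinear_sample(tile, (gx - tr$dx) / tr$scale,
                           (gy - tr$dy) / tr$scale)
      stack[, , p] <- matrix(v, th, tw)
    }
  }
  stack
}

## 3D Gaussian model over a window; fixed widths, free position/amp/bg.
gauss3d_model <- function(par, xw, yw, zw, sx, sz) {
  amp <- par[1]; x0 <- par[2]; y0 <- par[3]; z0 <- par[4]; bg <- par[5]
  amp * exp(-((xw - x0)^2 + (yw - y0)^2) / (2 * sx^2) -
              (zw - z0)^2 / (2 * sz^2)) + bg
}

#' Detect single-molecule localizations in a multifocal movie
#'
#' Candidate voxels above `background + k * sigma` (robust estimates over
#' the stack) that are 3x3x3 local maxima are fit by least squares with a
#' 3D Gaussian of fixed width in a 7x7 pixel by 3 plane window.  Fits whose
#' windows overlap another candidate's window are rejected (sparse-emitter
#' PALM regime), as are saturated windows.  Precision estimates follow the
#' standard background-corrected centroid formula.
#'
#' @param stacks list of 3D arrays `[y, x, plane]`, one per movie frame (or
#'   a single array).
#' @param geom an [mfm_geometry] giving the voxel size.
#' @param k detection threshold in robust-noise units (default 5).
#' @param psf_sigma_px lateral PSF sigma, pixels (default FWHM 225 nm at the
#'   MFM pixel size).
#' @param psf_sigma_planes axial PSF sigma, planes (default 1).
#' @param saturation ADU level treated as saturation (default Inf).
#' @return data.frame: `frame` (0-based), `x_nm`, `y_nm`, `z_nm`,
#'   `photons`, `sigma_xy_nm`, `sigma_z_nm`.
#' @export
detect_localizations <- function(stacks, geom = mfm_geometry(), k = 5,
                                 psf_sigma_px =
                                   fwhm_to_sigma(225) / geom$lateral_pixel,
                                 psf_sigma_planes = 1,
                                 saturation = Inf) {
  if (is.array(stacks) && length(dim(stacks)) == 3L) stacks <- list(stacks)
  out <- list()
  for (f in seq_along(stacks)) {
    st <- stacks[[f]]
    bg <- stats::median(st); sg <- stats::mad(st)
    thr <- bg + k * sg
    cand <- which(st > thr, arr.ind = TRUE)
    if (nrow(cand) == 0L) next
    ## keep only 3x3x3 local maxima
    is_max <- vapply(seq_len(nrow(cand)), function(i) {
      y <- cand[i, 1]; x <- cand[i, 2]; z <- cand[i, 3]
      nb <- st[max(1, y - 1):min(dim(st)[1], y + 1),
               max(1, x - 1):min(dim(st)[2], x + 1),
               max(1, z - 1):min(dim(st)[3], z + 1)]
      st[y, x, z] >= max(nb)
    }, TRUE)
    cand <- cand[is_max, , drop = FALSE]
    if (nrow(cand) == 0L) next
    ## reject candidates whose 7x7x3 windows overlap
    ok <- rep(TRUE, nrow(cand))
    if (nrow(cand) > 1L) for (i in seq_len(nrow(cand) - 1L))
      for (j in (i + 1L):nrow(cand)) {
        if (abs(cand[i, 1] - cand[j, 1]) < 7 &&
            abs(cand[i, 2] - cand[j, 2]) < 7 &&
            abs(cand[i, 3] - cand[j, 3]) < 3) ok[c(i, j)] <- FALSE
      }
    cand <- cand[ok, , drop = FALSE]
    for (i in seq_len(nrow(cand))) {
      y <- cand[i, 1]; x <- cand[i, 2]; z <- cand[i, 3]
      ys <- max(1, y - 3):min(dim(st)[1], y + 3)
      xs <- max(1, x - 3):min(dim(st)[2], x + 3)
      zs <- max(1, z - 1):min(dim(st)[3], z + 1)
      win <- st[ys, xs, zs, drop = FALSE]
      if (max(win) >= saturation) next
      xw <- array(rep(xs - 1, each = length(ys)), dim(win))
      yw <- array(rep(ys - 1, times = length(xs)), dim(win))
      zw <- array(rep(zs - 1, each = length(ys) * length(xs)), dim(win))
      p0 <- c(st[y, x, z] - bg, x - 1, y - 1, z - 1, bg)
      obj <- function(p) sum((gauss3d_model(p, xw, yw, zw, psf_sigma_px,
                                            psf_sigma_planes) - win)^2)
      fit <- stats::optim(p0, obj, method = "Nelder-Mead",
                          control = list(maxit = 500, reltol = 1e-10))
      p <- fit$par
      photons <- max(sum(win - p[5]), 1)
      s_nm <- psf_sigma_px * geom$lateral_pixel
      a <- geom$lateral_pixel
      b2 <- sg^2
      prec_xy <- sqrt((s_nm^2 + a^2 / 12) / photons +
                        8 * pi * s_nm^4 * b2 / (a^2 * photons^2))
      prec_z <- prec_xy * (psf_sigma_planes * geom$plane_spacing) / s_nm
      out[[length(out) + 1L]] <- data.frame(
        frame = f - 1L,
        x_nm = p[2] * geom$lateral_pixel,
        y_nm = p[3] * geom$lateral_pixel,
        z_nm = p[4] * geom$plane_spacing,
        photons = photons, sigma_xy_nm = prec_xy, sigma_z_nm = prec_z)
    }
  }
  if (!length(out))
    return(data.frame(frame = integer(0), x_nm = numeric(0),
                      y_nm = numeric(0), z_nm = numeric(0),
                      photons = numeric(0), sigma_xy_nm = numeric(0),
                      sigma_z_nm = numeric(0)))
  do.call(rbind, out)
}

#' Group per-frame localizations into fluorophore events
#'
#' Detections in consecutive frames closer (laterally) than `link_radius`
#' are considered the same fluorophore; linking is greedy nearest-neighbor
#' frame to frame (ties broken by smallest distance, then lowest index).
#' With the default `max_gap = 0`, a re-activation after any dark gap counts
#' as a new event.
#'
#' @param locs data.frame with columns `frame`, `x_nm`, `y_nm` (optionally
#'   `z_nm`, `sigma_xy_nm`, `sigma_z_nm`).
#' @param link_radius linking radius, nm (default 60 = 3x the ~20 nm
#'   lateral precision).
#' @param max_gap allowed dark frames inside one event (default 0).
#' @return data.frame of events: `event`, `x_nm`, `y_nm`, `z_nm`
#'   (precision-weighted mean position), `n_frames`, `start_frame`; the
#'   per-localization event assignment is attached as attribute
#'   `"assignment"`.
#' @export
group_events <- function(locs, link_radius = 60, max_gap = 0) {
  if (link_radius <= 0) stopf("link_radius must be > 0")
  n <- nrow(locs)
  ev <- integer(n)
  if (n > 0) {
    ord <- order(locs$frame)
    open_id <- integer(0); open_frame <- integer(0)
    open_x <- numeric(0); open_y <- numeric(0)
    next_id <- 1L
    for (f in sort(unique(locs$frame))) {
      idx <- ord[locs$frame[ord] == f]
      alive <- open_frame >= f - 1L - max_gap & open_frame < f
      cand_chain <- which(alive)
      ## greedy matching: all (loc, chain) pairs within radius, best first
      if (length(cand_chain) && length(idx)) {
        dx <- outer(locs$x_nm[idx], open_x[cand_chain], "-")
        dy <- outer(locs$y_nm[idx], open_y[cand_chain], "-")
        dist <- sqrt(dx^2 + dy^2)
        pairs <- which(dist <= link_radius, arr.ind = TRUE)
        if (nrow(pairs)) {
          o <- order(dist[pairs], pairs[, 1], pairs[, 2])
          pairs <- pairs[o, , drop = FALSE]
          used_loc <- logical(length(idx))
          used_chain <- logical(length(cand_chain))
          for (r in seq_len(nrow(pairs))) {
            li <- pairs[r, 1]; ci <- pairs[r, 2]
            if (used_loc[li] || used_chain[ci]) next
            used_loc[li] <- TRUE; used_chain[ci] <- TRUE
            ch <- cand_chain[ci]
            ev[idx[li]] <- open_id[ch]
            open_frame[ch] <- f
            open_x[ch] <- locs$x_nm[idx[li]]
            open_y[ch] <- locs$y_nm[idx[li]]
          }
          idx_new <- idx[!used_loc]
        } else idx_new <- idx
      } else idx_new <- idx
      for (i in idx_new) {
        ev[i] <- next_id
        open_id <- c(open_id, next_id)
        open_frame <- c(open_frame, f)
        open_x <- c(open_x, locs$x_nm[i]); open_y <- c(open_y, locs$y_nm[i])
        next_id <- next_id + 1L
      }
    }
  }
  ids <- sort(unique(ev))
  wmean <- function(v, w) if (all(!is.finite(w)) || sum(w) == 0)
    mean(v) else sum(v * w) / sum(w)
  rows <- lapply(ids, function(id) {
    s <- locs[ev == id, , drop = FALSE]
    wxy <- if ("sigma_xy_nm" %in% names(s)) 1 / s$sigma_xy_nm^2
           else rep(1, nrow(s))
    wz <- if ("sigma_z_nm" %in% names(s)) 1 / s$sigma_z_nm^2
          else rep(1, nrow(s))
    data.frame(event = id,
               x_nm = wmean(s$x_nm, wxy), y_nm = wmean(s$y_nm, wxy),
               z_nm = if ("z_nm" %in% names(s)) wmean(s$z_nm, wz)
                      else NA_real_,
               n_frames = nrow(s), start_frame = min(s$frame))
  })
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(event = integer(0), x_nm = numeric(0), y_nm = numeric(0),
               z_nm = numeric(0), n_frames = integer(0),
               start_frame = integer(0))
  attr(res, "assignment") <- ev
  res
}

#' Correct localizations for stage drift using fiducial markers
#'
#' Per-frame drift is the mean, over fiducials fit in that frame, of each
#' fiducial's displacement from its own first-frame position; frames without
#' any fiducial fit get linearly interpolated drift.  The drift is
#' subtracted from every localization in x, y and z.
#'
#' @param locs data.frame of sample localizations (`frame`, `x_nm`, `y_nm`,
#'   `z_nm`).
#' @param fiducial_locs data.frame of fiducial localizations (same columns;
#'   an optional `fiducial_id` column identifies tracks, otherwise tracks
#'   are built by nearest-position assignment from first appearance).
#' @return `locs` with drift subtracted; the per-frame drift trace is
#'   attached as attribute `"drift"` (data.frame `frame`, `dx`, `dy`, `dz`).
#' @export
drift_correct <- function(locs, fiducial_locs) {
  if (is.null(fiducial_locs) || nrow(fiducial_locs) == 0L)
    stopf("drift correction requires at least one fiducial")
  fl <- fiducial_locs[order(fiducial_locs$frame), , drop = FALSE]
  if (!"fiducial_id" %in% names(fl)) {
    ## nearest-position track assignment from first appearances
    id <- integer(nrow(fl))
    tx <- numeric(0); ty <- numeric(0)
    for (i in seq_len(nrow(fl))) {
      if (length(tx)) {
        d2 <- (tx - fl$x_nm[i])^2 + (ty - fl$y_nm[i])^2
        j <- which.min(d2)
      } else j <- integer(0)
      if (length(j) && d2[j] < 1e6) {  # within 1 um of a known fiducial
        id[i] <- j; tx[j] <- fl$x_nm[i]; ty[j] <- fl$y_nm[i]
      } else {
        tx <- c(tx, fl$x_nm[i]); ty <- c(ty, fl$y_nm[i])
        id[i] <- length(tx)
      }
    }
    fl$fiducial_id <- id
  }
  frames <- sort(unique(c(locs$frame, fl$frame)))
  ## reference = each fiducial's first-frame position
  ref <- do.call(rbind, lapply(split(fl, fl$fiducial_id), function(s) {
    s[which.min(s$frame), c("fiducial_id", "x_nm", "y_nm", "z_nm")]
  }))
  fl$rx <- ref$x_nm[match(fl$fiducial_id, ref$fiducial_id)]
  fl$ry <- ref$y_nm[match(fl$fiducial_id, ref$fiducial_id)]
  fl$rz <- ref$z_nm[match(fl$fiducial_id, ref$fiducial_id)]
  per_frame <- function(col, refcol) {
    v <- tapply(fl[[col]] - fl[[refcol]], fl$frame, mean)
    obs_frames <- as.numeric(names(v))
    if (length(obs_frames) == 1L) return(rep(unname(v), length(frames)))
    stats::approx(obs_frames, as.numeric(v), xout = frames, rule = 2)$y
  }
  drift <- data.frame(frame = frames,
                      dx = per_frame("x_nm", "rx"),
                      dy = per_frame("y_nm", "ry"),
                      dz = per_frame("z_nm", "rz"))
  m <- match(locs$frame, drift$frame)
  locs$x_nm <- locs$x_nm - drift$dx[m]
  locs$y_nm <- locs$y_nm - drift$dy[m]
  if ("z_nm" %in% names(locs)) locs$z_nm <- locs$z_nm - drift$dz[m]
  attr(locs, "drift") <- drift
  locs
}
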