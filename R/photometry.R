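#' Aperture photometry policy
#'
#' Measurement geometry for cluster photometry: a circular aperture whose
#' radius equals the typical FWHM of a centromere cluster (4 pixels = 428 nm
#' at 107 nm pixels) and an adjacent background annulus 5 pixels wide, whose
#' continuous area is (9^2 - 4^2)/4^2 = 4.0625 times the aperture area.
#' Pixels belong to a region when their centers do (no partial pixels).
#'
#' @param aperture_radius aperture radius, pixels.
#' @param annulus_width width of the background annulus, pixels; the annulus
#'   inner radius equals `aperture_radius`.
#' @param background_estimator `"median"` (robust default) or `"mean"`.
#' @return An object of class `aperture_policy`.
#' @export
aperture_policy <- function(aperture_radius = 4, annulus_width = 5,
                            background_estimator = c("median", "mean")) {
  if (!is_scalar_num(aperture_radius) || aperture_radius <= 0)
    stopf("aperture_radius must be positive")
  if (!is_scalar_num(annulus_width) || annulus_width <= 0)
    stopf("annulus_width must be positive")
  background_estimator <- match.arg(background_estimator)
  r <- aperture_radius; w <- annulus_width
  structure(list(aperture_radius = r, annulus_width = w,
                 background_estimator = background_estimator,
                 area_ratio = ((r + w)^2 - r^2) / r^2),
            class = "aperture_policy")
}

## Pixel-center masks for aperture and annulus around (cx, cy), 0-based.
aperture_masks <- function(dim_yx, cx, cy, policy) {
  x <- matrix(rep(0:(dim_yx[2] - 1), each = dim_yx[1]), dim_yx[1])
  y <- matrix(rep(0:(dim_yx[1] - 1), times = dim_yx[2]), dim_yx[1])
  d <- sqrt((x - cx)^2 + (y - cy)^2)
  list(aperture = d <= policy$aperture_radius,
       annulus = d > policy$aperture_radius &
         d <= policy$aperture_radius + policy$annulus_width)
}

#' Detect candidate cluster centers in a wavelet-filtered frame
#'
#' Finds 8-connected local maxima whose amplitude exceeds
#' `min_snr * 1.4826 * MAD` of the spot image, and enforces a minimum mutual
#' distance of one aperture radius (the brighter candidate wins).  Centers
#' are returned brightest-first in 0-based pixel coordinates.
#'
#' @param spot_image matrix from [extract_spot_image].
#' @param min_snr detection threshold in robust-noise units (> 0).
#' @param min_separation minimum distance between detections, pixels
#'   (default the standard aperture radius, 4).
#' @return data.frame with columns `x`, `y`, `amplitude` (possibly 0 rows).
#' @export
detect_clusters <- function(spot_image, min_snr = 5, min_separation = 4) {
  spot_image <- as.matrix(spot_image)
  if (min_snr <= 0) stopf("min_snr must be positive")
  noise <- stats::mad(spot_image)  # 1.4826 * MAD
  thr <- min_snr * noise
  nr <- nrow(spot_image); nc <- ncol(spot_image)
  empty <- data.frame(x = numeric(0), y = numeric(0), amplitude = numeric(0))
  if (all(spot_image <= thr)) return(empty)
  ## local maxima over the 8-neighborhood (interior pixels only)
  is_max <- matrix(TRUE, nr, nc)
  is_max[c(1, nr), ] <- FALSE; is_max[, c(1, nc)] <- FALSE
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    shifted <- matrix(-Inf, nr, nc)
    shifted[max(1, 1 + dy):min(nr, nr + dy), max(1, 1 + dx):min(nc, nc + dx)] <-
      spot_image[max(1, 1 - dy):min(nr, nr - dy),
                 max(1, 1 - dx):min(nc, nc - dx)]
    is_max <- is_max & (spot_image >= shifted)
  }
  cand <- which(is_max & spot_image > thr, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(empty)
  amp <- spot_image[cand]
  ord <- order(amp, decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]; amp <- amp[ord]
  keep <- logical(length(amp))
  for (i in seq_along(amp)) {
    if (i == 1L) { keep[1] <- TRUE; next }
    prev <- which(keep)
    d2 <- (cand[prev, 1] - cand[i, 1])^2 + (cand[prev, 2] - cand[i, 2])^2
    keep[i] <- all(d2 >= min_separation^2)
  }
  data.frame(x = cand[keep, 2] - 1, y = cand[keep, 1] - 1,
             amplitude = amp[keep])
}

#' Aperture photometry of one cluster
#'
#' Sums calibrated pixel values inside the aperture, estimates the local
#' background per pixel in the surrounding annulus, and converts the
#' background-corrected signal into photoelectrons.  For a Z-stack, the
#' measurement is taken on the single Z-slice with maximal aperture sum
#' (the in-focus slice).
#'
#' @param frame calibrated [image_stack] (or bare matrix treated as a
#'   calibrated single frame) in ADU.
#' @param center numeric `c(x, y)` (0-based pixels); for stacks an optional
#'   third element fixes the Z-slice instead of the max-sum rule.
#' @param policy an [aperture_policy].
#' @param cam a [camera_model] for the photoelectron conversion.
#' @param exposure exposure time, s; defaults to the stack's metadata.
#' @param cell_id,stage,n_centromeres_in_spot optional annotation carried
#'   into the measurement (stage one of G1, S, G2, M, A, T; 16 or 32
#'   centromeres per spot).
#' @return An object of class `cluster_measurement`: center, `net_adu`,
#'   `net_photons`, `background_per_pixel`, `exposure`, `photon_rate`, and
#'   the annotations.
#' @export
aperture_photometry <- function(frame, center, policy = aperture_policy(),
                                cam = camera_model(), exposure = NULL,
                                cell_id = NA, stage = NA,
                                n_centromeres_in_spot = NA) {
  if (inherits(frame, "image_stack")) {
    if (!frame$calibrated)
      stopf("aperture_photometry refuses uncalibrated input")
    exposure <- exposure %||% frame$exposure
    px <- frame$pixels
  } else {
    px <- as.matrix(frame)
    exposure <- exposure %||% 1
  }
  if (!is.na(stage)) stage <- match.arg(stage, c("G1", "S", "G2", "M", "A", "T"))
  if (is.matrix(px)) px <- array(px, c(dim(px), 1L))
  d <- dim(px)[1:2]
  cx <- center[1]; cy <- center[2]
  rmax <- policy$aperture_radius + policy$annulus_width
  if (cx - rmax < 0 || cy - rmax < 0 || cx + rmax > d[2] - 1 ||
      cy + rmax > d[1] - 1)
    stopf("aperture+annulus at (%.1f, %.1f) clipped by the frame edge",
          cx, cy)
  m <- aperture_masks(d, cx, cy, policy)
  nz <- dim(px)[3]
  z_sel <- if (length(center) >= 3L && !is.na(center[3])) {
    as.integer(center[3]) + 1L
  } else {
    which.max(vapply(seq_len(nz),
                     function(z) sum(px[, , z][m$aperture]), 0))
  }
  slice <- px[, , z_sel]
  ap_sum <- sum(slice[m$aperture])
  bg <- switch(policy$background_estimator,
               median = stats::median(slice[m$annulus]),
               mean = mean(slice[m$annulus]))
  net_adu <- ap_sum - bg * sum(m$aperture)
  net_photons <- adu_to_photons(net_adu, cam)
  structure(list(center = c(x = cx, y = cy, z = z_sel - 1L),
                 net_adu = net_adu, net_photons = net_photons,
                 background_per_pixel = bg, exposure = exposure,
                 photon_rate = net_photons / exposure,
                 cell_id = cell_id, stage = stage,
                 n_centromeres_in_spot = n_centromeres_in_spot),
            class = "cluster_measurement")
}

#' @export
print.cluster_measurement <- function(x, ...) {
  cat(sprintf(
    "cluster at (%.1f, %.1f, z=%d): %.0f photons (%.0f photons/s), bg %.2f ADU/px\n",
    x$center[1], x$center[2], x$center[3], x$net_photons, x$photon_rate,
    x$background_per_pixel))
  invisible(x)
}

#' Normalize a cluster measurement to 16 centromeres
#'
#' In S and G2 the replicated (32) centromeres occupy a single dot; values
#' are corrected per 16 centromeres so stages are comparable.
#'
#' @param m a `cluster_measurement` with `n_centromeres_in_spot` set (16 or
#'   32), or a numeric photon value with `n_centromeres` supplied.
#' @param n_centromeres overrides/supplies the centromere count.
#' @return photoelectrons per 16 centromeres.
#' @export
per16_normalize <- function(m, n_centromeres = NULL) {
  if (inherits(m, "cluster_measurement")) {
    n <- n_centromeres %||% m$n_centromeres_in_spot
    v <- m$net_photons
  } else {
    n <- n_centromeres
    v <- m
  }
  if (is.null(n) || is.na(n)) stopf("centromere count per spot is not set")
  if (!n %in% c(16, 32)) stopf("n_centromeres_in_spot must be 16 or 32")
  v * 16 / n
}

#' Centromeric fraction and free/bound ratio of nuclear signal
#'
#' Compares the photon content of a centromeric cluster with the total
#' nuclear signal; the chaperone pool experiment expects roughly a fourfold
#' excess of free over centromere-bound protein.
#'
#' @param nuclear_total total nuclear photoelectrons (>= cluster).
#' @param cluster_photons centromeric cluster photoelectrons (>= 0).
#' @return list with `fraction` (cluster/nuclear), `ratio_free_to_bound`,
#'   and `defined` (FALSE when the cluster signal is zero).
#' @export
centromeric_fraction <- function(nuclear_total, cluster_photons) {
  if (cluster_photons < 0 || nuclear_total < cluster_photons)
    stopf("need nuclear_total >= cluster_photons >= 0")
  if (cluster_photons == 0)
    return(list(fraction = 0, ratio_free_to_bound = NA_real_,
                defined = FALSE))
  list(fraction = cluster_photons / nuclear_total,
       ratio_free_to_bound = (nuclear_total - cluster_photons) /
         cluster_photons,
       defined = TRUE)
}

#' Five-number summary of a measurement group
#'
#' Minimum, first quartile, median, third quartile and maximum, with
#' quartiles by linear interpolation between order statistics (the
#' inclusive scheme, `quantile(type = 7)`).
#'
#' @param values numeric vector (n >= 1), e.g. photon rates of a group of
#'   measurements.
#' @return named list `min`, `q1`, `median`, `q3`, `max`, `n`.
#' @export
summarize_quartiles <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 1L || any(is.na(values)))
    stopf("need at least one non-missing value")
  q <- stats::quantile(values, c(0, .25, .5, .75, 1), names = FALSE, type = 7)
  list(min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5],
       n = length(values))
}

#' Convert a list of cluster measurements to a data.frame
#'
#' @param measurements list of `cluster_measurement` objects.
#' @return data.frame with one row per measurement (cell_id, stage, x, y, z,
#'   net_adu, net_photons, photon_rate, n_centromeres_in_spot).
#' @export
measurements_table <- function(measurements) {
  do.call(rbind, lapply(measurements, function(m) {
    data.frame(cell_id = m$cell_id, stage = m$stage,
               x = m$center[1], y = m$center[2], z = m$center[3],
               net_adu = m$net_adu, net_photons = m$net_photons,
               photon_rate = m$photon_rate,
               n_centromeres_in_spot = m$n_centromeres_in_spot,
               row.names = NULL)
  }))
}
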