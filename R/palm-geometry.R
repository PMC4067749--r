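#' 3D geometry of a localization cluster
#'
#' Summarizes the shape of a drift-corrected set of fluorophore positions.
#' The enclosing diameter is twice the `majority_fraction` quantile of
#' radial distances from the centroid -- the sphere "sufficient to contain
#' the majority" of detections.  Ellipsoid axes come from PCA with a
#' uniform-ellipsoid moment estimator (semi-axis = sqrt(5) * SD along the
#' axis), optionally deconvolving the known localization precision in
#' quadrature; the equatorial diameter averages the two major axes and the
#' polar distance is the minor axis, so equatorial >= polar by construction.
#' Volume is the ellipsoid volume `(4/3) * pi * a^2 * c` with equatorial
#' semi-axis `a` and polar semi-axis `c`.
#'
#' @param points n x 3 matrix (or data.frame with `x_nm`, `y_nm`, `z_nm`) of
#'   event positions, nm; n >= 4.
#' @param majority_fraction quantile used for the enclosing sphere
#'   (default 0.9).
#' @param precision localization precision SD to deconvolve, nm: scalar or
#'   `c(x, y, z)` (default 0 = none).
#' @return An object of class `cluster_geometry`: `centroid`,
#'   `enclosing_diameter`, `pca_axes`, `pca_sd`, `equatorial_diameter`,
#'   `polar_distance`, `volume`, `n_events`, `degenerate`.
#' @export
cluster_geometry <- function(points, majority_fraction = 0.9,
                             precision = 0) {
  points <- as_points3(points)
  n <- nrow(points)
  if (n < 4L) stopf("cluster geometry needs >= 4 points (got %d)", n)
  if (majority_fraction <= 0 || majority_fraction > 1)
    stopf("majority_fraction must be in (0, 1]")
  noise_cov <- as_noise_cov(precision)
  centroid <- colMeans(points)
  centered <- sweep(points, 2, centroid)
  r <- sqrt(rowSums(centered^2))
  enclosing <- 2 * stats::quantile(r, majority_fraction, names = FALSE)
  S <- stats::cov(centered)
  raw_eig <- eigen(S, symmetric = TRUE)
  degenerate <- raw_eig$values[3] < 1e-18 * raw_eig$values[1]
  if (degenerate) {
    axes <- raw_eig$vectors; eq <- NA_real_; pol <- NA_real_
    vol <- NA_real_
  } else {
    ## deconvolve the localization-noise covariance before the
    ## eigendecomposition: with anisotropic precision the raw minor axis
    ## tracks the minimum of signal + noise, not the true polar axis
    eg <- eigen(S - noise_cov, symmetric = TRUE)
    axes <- eg$vectors
    ## floor at 1% of the raw eigenvalues so axes stay positive when
    ## noise dominates an axis
    vals <- pmax(eg$values, 0.01 * raw_eig$values)
    semi <- sqrt(5) * sqrt(vals)         # uniform-ellipsoid moments
    a <- mean(semi[1:2]); cpol <- semi[3]
    eq <- 2 * a; pol <- 2 * cpol
    vol <- 4 / 3 * pi * a^2 * cpol
  }
  structure(list(centroid = centroid, enclosing_diameter = enclosing,
                 majority_fraction = majority_fraction,
                 pca_axes = axes, pca_sd = sqrt(pmax(raw_eig$values, 0)),
                 equatorial_diameter = eq, polar_distance = pol,
                 volume = vol, n_events = n, degenerate = degenerate),
            class = "cluster_geometry")
}

## precision spec -> 3x3 localization-noise covariance (nm^2)
as_noise_cov <- function(precision) {
  if (is.matrix(precision)) {
    if (!identical(dim(precision), c(3L, 3L)))
      stopf("precision matrix must be 3 x 3 (a noise covariance)")
    precision
  } else diag(rep_len(precision, 3L)^2)
}

#' @export
print.cluster_geometry <- function(x, ...) {
  cat(sprintf("cluster of %d events: enclosing sphere %.0f nm (q = %.2f)\n",
              x$n_events, x$enclosing_diameter, x$majority_fraction))
  if (!x$degenerate)
    cat(sprintf("  ellipsoid %.0f nm equatorial x %.0f nm polar, volume %.3g nm^3\n",
                x$equatorial_diameter, x$polar_distance, x$volume))
  invisible(x)
}

as_points3 <- function(points) {
  if (is.data.frame(points)) {
    cols <- intersect(c("x_nm", "y_nm", "z_nm"), names(points))
    if (length(cols) == 3L) points <- points[, cols] else
      points <- points[, 1:3]
  }
  m <- as.matrix(points)
  if (ncol(m) != 3L || any(!is.finite(m)))
    stopf("points must be an n x 3 matrix of finite coordinates")
  unname(m)
}

#' Split a cell's localizations into its one or two clusters
#'
#' 2-means on positions, accepted only when the inter-centroid distance
#' exceeds both apparent cluster diameters; otherwise the cell is treated
#' as carrying a single cluster.
#'
#' @param points n x 3 matrix of positions, nm.
#' @return list of 1 or 2 point matrices.
#' @export
separate_clusters <- function(points) {
  points <- as_points3(points)
  if (nrow(points) < 8L) return(list(points))
  km <- stats::kmeans(points, centers = 2, nstart = 5)
  d_cent <- sqrt(sum((km$centers[1, ] - km$centers[2, ])^2))
  diam <- vapply(1:2, function(k) {
    p <- points[km$cluster == k, , drop = FALSE]
    if (nrow(p) < 2L) return(0)
    2 * max(sqrt(rowSums(sweep(p, 2, colMeans(p))^2)))
  }, 0)
  if (d_cent > max(diam)) {
    lapply(1:2, function(k) points[km$cluster == k, , drop = FALSE])
  } else list(points)
}

#' Center-align (and orient) clusters and pool their events
#'
#' Each cluster is centered on its centroid.  In `anaphase` mode each
#' cluster is additionally rotated into its PCA frame so that the long axis
#' lies along x and the minor (polar) axis along z -- the "long axis rotated
#' horizontally" convention -- before pooling, so that a joint ellipsoid can
#' be estimated.  In `G1` mode clusters are only centered.
#'
#' @param clusters list (>= 2) of point matrices (n x 3, nm).
#' @param mode `"G1"` or `"anaphase"`.
#' @param precision localization precision (scalar, `c(x, y, z)` SDs in nm,
#'   or a 3x3 noise covariance): in anaphase mode the alignment rotation is
#'   taken from the noise-corrected covariance of each cluster, and the
#'   noise covariance rotated into the aligned frame (averaged over
#'   clusters) is attached to the result as attribute `"noise_cov"` for use
#'   by [cluster_geometry].
#' @return pooled matrix of aligned points, with attribute `"noise_cov"`.
#' @export
compile_clusters <- function(clusters, mode = c("G1", "anaphase"),
                             precision = 0) {
  mode <- match.arg(mode)
  if (length(clusters) < 2L) stopf("need >= 2 clusters to compile")
  noise_cov <- as_noise_cov(precision)
  rotated_noise <- list()
  aligned <- lapply(clusters, function(p) {
    p <- as_points3(p)
    cen <- sweep(p, 2, colMeans(p))
    if (mode == "anaphase") {
      rot <- eigen(stats::cov(cen) - noise_cov, symmetric = TRUE)$vectors
      if (det(rot) < 0) rot[, 3] <- -rot[, 3]
      rotated_noise[[length(rotated_noise) + 1L]] <<-
        t(rot) %*% noise_cov %*% rot
      cen <- cen %*% rot
    } else {
      rotated_noise[[length(rotated_noise) + 1L]] <<- noise_cov
    }
    cen
  })
  pooled <- do.call(rbind, aligned)
  attr(pooled, "noise_cov") <- Reduce(`+`, rotated_noise) /
    length(rotated_noise)
  pooled
}

#' Ratio of two cluster volumes
#'
#' @param g_large,g_small `cluster_geometry` objects (positive volumes).
#' @return `g_large$volume / g_small$volume`.
#' @export
volume_ratio <- function(g_large, g_small) {
  v1 <- g_large$volume; v2 <- g_small$volume
  if (!is.finite(v1) || !is.finite(v2) || v1 <= 0 || v2 <= 0)
    stopf("volume_ratio requires positive finite volumes")
  v1 / v2
}

#' Airy-disk FWHM of a diffraction-limited spot
#'
#' `0.51 * lambda / NA`, the standard FWHM of the in-focus Airy pattern.
#'
#' @param emission_wavelength nm.
#' @param numerical_aperture objective NA.
#' @return FWHM, nm.
#' @examples
#' airy_fwhm(593, 1.35)  # ~224 nm
#' @export
airy_fwhm <- function(emission_wavelength, numerical_aperture) {
  if (emission_wavelength <= 0 || numerical_aperture <= 0)
    stopf("wavelength and NA must be positive")
  0.51 * emission_wavelength / numerical_aperture
}
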