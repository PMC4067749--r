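#' Synthetic microscopy scene specification
#'
#' A stated forward model of the wide-field microscope: point emitters with
#' Gaussian PSF (FWHM 225 nm lateral -- the measured Airy-disk scale), a
#' diffuse nuclear disk and a cytoplasmic ellipse of background photon
#' rates, and the EMCCD noise chain of the camera model.  Every generated
#' image carries its ground truth.
#'
#' @param shape frame shape `c(ny, nx)`, pixels.
#' @param clusters list of clusters, each a list with `center = c(x, y)`
#'   (0-based px), and either `positions` (matrix of emitter x,y px) or
#'   `n_emitters` plus `radius_nm` (emitters sampled uniformly in a disk of
#'   that radius); `rate` = photons/s per emitter.
#' @param nucleus `list(center = c(x, y), radius, rate)`: diffuse nuclear
#'   background, photons/px/s (or `NULL`).
#' @param cytoplasm `list(center, radii = c(rx, ry), rate)` ellipse
#'   (or `NULL`).
#' @param psf_fwhm lateral PSF FWHM, nm.
#' @param pixel_size nm per pixel.
#' @param exposure s.
#' @param cam a [camera_model].
#' @param seed seed fixing all randomness of rendering.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(shape = c(64, 64), clusters = list(),
                       nucleus = NULL, cytoplasm = NULL,
                       psf_fwhm = 225, pixel_size = 107, exposure = 1,
                       cam = camera_model(), seed = 1) {
  if (psf_fwhm <= 0 || pixel_size <= 0) stopf("psf and pixel size must be > 0")
  if (fwhm_to_sigma(psf_fwhm) / pixel_size > min(shape))
    stopf("PSF wider than the frame")
  for (cl in clusters) {
    if (!is.null(cl$rate) && cl$rate < 0) stopf("emitter rates must be >= 0")
  }
  structure(list(shape = shape, clusters = clusters, nucleus = nucleus,
                 cytoplasm = cytoplasm, psf_fwhm = psf_fwhm,
                 pixel_size = pixel_size, exposure = exposure, cam = cam,
                 seed = seed),
            class = "scene_spec")
}

## Pixel-integrated Gaussian PSF image of one emitter (0-based center).
psf_image <- function(shape, x0, y0, sigma_px, photons) {
  px <- diff(stats::pnorm(seq(-0.5, shape[2] - 0.5), mean = x0,
                          sd = sigma_px))
  py <- diff(stats::pnorm(seq(-0.5, shape[1] - 0.5), mean = y0,
                          sd = sigma_px))
  photons * outer(py, px)
}

## Resolve emitter positions/rates of a scene's clusters (uses the RNG).
resolve_emitters <- function(spec) {
  out <- list()
  for (i in seq_along(spec$clusters)) {
    cl <- spec$clusters[[i]]
    if (!is.null(cl$positions)) {
      pos <- as.matrix(cl$positions)
    } else {
      n <- cl$n_emitters %||% 1L
      rad_px <- (cl$radius_nm %||% 0) / spec$pixel_size
      if (rad_px > 0) {
        th <- stats::runif(n, 0, 2 * pi)
        rr <- rad_px * sqrt(stats::runif(n))
        pos <- cbind(cl$center[1] + rr * cos(th),
                     cl$center[2] + rr * sin(th))
      } else {
        pos <- cbind(rep(cl$center[1], n), rep(cl$center[2], n))
      }
    }
    out[[i]] <- data.frame(cluster = i, x = pos[, 1], y = pos[, 2],
                           rate = cl$rate %||% 0)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(cluster = integer(0), x = numeric(0), y = numeric(0),
               rate = numeric(0))
}

## Expected photoelectron image (no noise, no dark) of a scene.
expected_photon_image <- function(spec, emitters) {
  img <- matrix(0, spec$shape[1], spec$shape[2])
  sig <- fwhm_to_sigma(spec$psf_fwhm) / spec$pixel_size
  for (i in seq_len(nrow(emitters)))
    img <- img + psf_image(spec$shape, emitters$x[i], emitters$y[i], sig,
                           emitters$rate[i] * spec$exposure)
  xs <- matrix(rep(0:(spec$shape[2] - 1), each = spec$shape[1]),
               spec$shape[1])
  ys <- matrix(rep(0:(spec$shape[1] - 1), times = spec$shape[2]),
               spec$shape[1])
  if (!is.null(spec$cytoplasm)) {
    cy <- spec$cytoplasm
    inside <- ((xs - cy$center[1]) / cy$radii[1])^2 +
      ((ys - cy$center[2]) / cy$radii[2])^2 <= 1
    img <- img + inside * cy$rate * spec$exposure
  }
  if (!is.null(spec$nucleus)) {
    nu <- spec$nucleus
    inside <- (xs - nu$center[1])^2 + (ys - nu$center[2])^2 <= nu$radius^2
    img <- img + inside * nu$rate * spec$exposure
  }
  img
}

## EMCCD noise chain: expected electrons -> integer ADU frame.
emccd_noise <- function(mu_e, cam) {
  n <- matrix(stats::rpois(length(mu_e), mu_e), nrow(mu_e))
  g <- matrix(0, nrow(mu_e), ncol(mu_e))
  nz <- n > 0
  g[nz] <- stats::rgamma(sum(nz), shape = n[nz], scale = cam$em_gain)
  adu <- g / (cam$em_gain * cam$conversion_gain) +
    stats::rnorm(length(mu_e), 0, cam$readout_noise / cam$conversion_gain)
  bias <- if (is.matrix(cam$bias_level)) cam$bias_level else
    matrix(cam$bias_level, nrow(mu_e), ncol(mu_e))
  flat <- if (is.matrix(cam$flat_field)) cam$flat_field else 1
  pmax(round(adu * flat + bias), 0)
}

#' Render one raw camera frame of a scene
#'
#' Forward model: expected photoelectron image (emitters through the
#' pixel-integrated Gaussian PSF, plus diffuse backgrounds and thermal
#' signal), then the EMCCD noise chain -- Poisson shot noise, EM-register
#' gamma multiplication (excess noise factor ~2), Gaussian readout noise,
#' conversion to ADU, bias offset and integer quantization.
#'
#' @param spec a [scene_spec].
#' @param t acquisition time, s (reserved for state-dependent visibility).
#' @param seed overrides the scene seed.
#' @return raw [image_stack]; ground truth (emitter table with expected
#'   photons, and the noise-free expected photon image) attached as
#'   attribute `"truth"`.
#' @export
render_frame <- function(spec, t = 0, seed = spec$seed) {
  set.seed(seed)
  emitters <- resolve_emitters(spec)
  expected <- expected_photon_image(spec, emitters)
  cam <- spec$cam
  mu <- expected + cam$dark_current * spec$exposure
  adu <- emccd_noise(mu, cam)
  st <- image_stack(adu, pixel_size = spec$pixel_size,
                    exposure = spec$exposure, value_format = "raw_adu")
  emitters$photons <- emitters$rate * spec$exposure
  attr(st, "truth") <- list(emitters = emitters, expected = expected)
  st
}

#' Generate a tetO/TetR calibration titration with ground truth
#'
#' One image per replicate per array size: a single spot carrying
#' `n_operators x 2` fluorophores (TetR homodimer; optionally binomially
#' thinned by `occupancy`) over a diffuse nuclear background of unbound
#' repressor.  The per-fluorophore photon rate is the generator's ground
#' truth for calibration recovery.
#'
#' @param operator_counts tetO array sizes (default `c(7, 14, 21)`; the
#'   112x array is available but excluded from default calibration).
#' @param per_fluorophore_rate photons/s per fluorophore (default 45,
#'   consistent with a ~36-GFP cluster yielding ~1500 photons/s).
#' @param n_images replicates per array size.
#' @param occupancy operator occupancy probability (default 1 = full).
#' @param spot_radius_nm emitter spread radius within a spot, nm.
#' @param exposure s (default 2, the calibration-measurement exposure).
#' @param shape,cam,seed as in [scene_spec].
#' @return list: `images` (list of raw stacks), `truth` (data.frame with
#'   label, expected_max, n_emitters per image), `per_fluorophore_rate`.
#' @export
generate_titration <- function(operator_counts = c(7, 14, 21),
                               per_fluorophore_rate = 45, n_images = 50,
                               occupancy = 1, spot_radius_nm = 100,
                               exposure = 2, shape = c(48, 48),
                               cam = camera_model(), seed = 1) {
  set.seed(seed)
  images <- list(); truth <- list()
  for (nop in operator_counts) {
    emax <- nop * 2L
    for (i in seq_len(n_images)) {
      n_em <- if (occupancy >= 1) emax else
        stats::rbinom(1, emax, occupancy)
      spec <- scene_spec(
        shape = shape,
        clusters = list(list(center = shape[2:1] / 2, n_emitters = n_em,
                             radius_nm = spot_radius_nm,
                             rate = per_fluorophore_rate)),
        nucleus = list(center = shape[2:1] / 2, radius = min(shape) / 3,
                       rate = per_fluorophore_rate / 4),
        exposure = exposure, cam = cam,
        seed = child_seed(seed, sprintf("titration_%d_%d", nop, i)))
      images[[length(images) + 1L]] <- render_frame(spec)
      truth[[length(truth) + 1L]] <- data.frame(
        label = sprintf("tetO_%dx", nop), n_operator_sites = nop,
        expected_max = emax, n_emitters = n_em, image = length(images))
    }
  }
  list(images = images, truth = do.call(rbind, truth),
       per_fluorophore_rate = per_fluorophore_rate)
}

#' Generate telophase centromere-cluster scenes
#'
#' Each scene carries one cluster of `n_emitters` fluorophores (default
#' 2 x 16: two molecules on each of the 16 clustered centromeres) spread in
#' a disk of the cluster's physical radius, over nuclear background.
#'
#' @param n_images number of cells.
#' @param n_emitters fluorophores per cluster (default 32).
#' @param per_fluorophore_rate photons/s per fluorophore.
#' @param cluster_radius_nm cluster radius (default 225 = 450 nm across).
#' @param exposure,shape,cam,seed as in [generate_titration].
#' @return list `images`, `truth`.
#' @export
generate_cluster_scenes <- function(n_images = 50, n_emitters = 32,
                                    per_fluorophore_rate = 45,
                                    cluster_radius_nm = 225, exposure = 2,
                                    shape = c(48, 48), cam = camera_model(),
                                    seed = 1) {
  set.seed(seed)
  images <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    spec <- scene_spec(
      shape = shape,
      clusters = list(list(center = shape[2:1] / 2, n_emitters = n_emitters,
                           radius_nm = cluster_radius_nm,
                           rate = per_fluorophore_rate)),
      nucleus = list(center = shape[2:1] / 2, radius = min(shape) / 3,
                     rate = per_fluorophore_rate / 10),
      exposure = exposure, cam = cam,
      seed = child_seed(seed, sprintf("cluster_%d", i)))
    images[[i]] <- render_frame(spec)
  }
  list(images = images,
       truth = data.frame(image = seq_len(n_images), n_emitters = n_emitters,
                          expected_photons = n_emitters *
                            per_fluorophore_rate * exposure))
}
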