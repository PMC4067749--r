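#' EMCCD camera model
#'
#' Bundles the calibration constants of an electron-multiplying CCD operated
#' at a fixed EM gain, together with optional reference frames (bias, dark,
#' flat field).  The defaults are the working constants of a back-illuminated
#' EMCCD at EM gain 50: conversion factor 0.044 photoelectrons per ADU,
#' readout noise 0.470 e- RMS, thermal (dark) current 0.014 e-/s.
#'
#' `conversion_gain` is input-referred: multiplying background-corrected ADU
#' by it yields detected photoelectrons, with the EM multiplication already
#' folded in.
#'
#' @param conversion_gain photoelectrons per ADU at the working EM gain.
#' @param readout_noise readout noise, photoelectrons RMS (input-referred).
#' @param dark_current thermal current, photoelectrons per pixel per second.
#' @param em_gain electron-multiplication factor (dimensionless, >= 1).
#' @param bias_level ADU offset: a scalar or a reference frame (matrix).
#' @param flat_field per-pixel sensitivity map; renormalized to mean 1 on
#'   construction so that flat-fielding is photometrically neutral.  A scalar
#'   (or `NULL`) means a perfectly flat sensor.
#' @param dark_frame optional measured dark frame in ADU per second; when
#'   supplied it overrides the scalar `dark_current` model during
#'   calibration.
#' @return An object of class `camera_model`.
#' @examples
#' cam <- camera_model()
#' adu_to_photons(170455, cam)  # ~7500 photoelectrons
#' @export
camera_model <- function(conversion_gain = 0.044, readout_noise = 0.470,
                         dark_current = 0.014, em_gain = 50,
                         bias_level = 100, flat_field = NULL,
                         dark_frame = NULL) {
  if (!is_scalar_num(conversion_gain) || conversion_gain <= 0)
    stopf("conversion_gain must be a positive number")
  if (!is_scalar_num(readout_noise) || readout_noise < 0)
    stopf("readout_noise must be >= 0")
  if (!is_scalar_num(dark_current) || dark_current < 0)
    stopf("dark_current must be >= 0")
  if (!is_scalar_num(em_gain) || em_gain < 1)
    stopf("em_gain must be >= 1")
  if (!is.null(flat_field) && !is_scalar_num(flat_field)) {
    flat_field <- as.matrix(flat_field)
    if (any(!is.finite(flat_field)) || any(flat_field <= 0))
      stopf("flat_field must be strictly positive and finite")
    flat_field <- flat_field / mean(flat_field)
  } else if (!is.null(flat_field)) {
    if (flat_field <= 0) stopf("flat_field must be strictly positive")
    flat_field <- 1
  }
  structure(list(conversion_gain = conversion_gain,
                 readout_noise = readout_noise,
                 dark_current = dark_current,
                 em_gain = em_gain,
                 bias_level = bias_level,
                 flat_field = flat_field,
                 dark_frame = dark_frame),
            class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat("EMCCD camera model\n")
  cat(sprintf("  conversion gain : %.4g e-/ADU\n", x$conversion_gain))
  cat(sprintf("  readout noise   : %.4g e- RMS\n", x$readout_noise))
  cat(sprintf("  dark current    : %.4g e-/px/s\n", x$dark_current))
  cat(sprintf("  EM gain         : %g\n", x$em_gain))
  cat(sprintf("  bias            : %s\n",
              if (is.matrix(x$bias_level)) "reference frame"
              else sprintf("%.4g ADU", x$bias_level)))
  cat(sprintf("  flat field      : %s\n",
              if (is.matrix(x$flat_field)) "reference frame" else "uniform"))
  invisible(x)
}

#' Image stack container
#'
#' Holds 2D/3D/4D pixel data with physical scales and exposure metadata.
#' Arrays are indexed `[y, x]`, `[y, x, z]` or `[y, x, z, t]`; user-facing
#' pixel coordinates are 0-based with pixel centers at integer positions
#' (x = column - 1, y = row - 1).
#'
#' @param pixels numeric array (2--4 dimensions).  Raw stacks must contain
#'   nonnegative integer-valued ADU.
#' @param pixel_size lateral pixel size, nm (107 for the wide-field camera,
#'   120 for the multifocal-plane system).
#' @param z_step axial step, nm (333 wide-field, 380 multifocal).
#' @param exposure exposure time per frame, s.
#' @param timestamps acquisition time of each frame, s (nondecreasing).
#' @param calibrated has the stack been bias/dark/flat corrected?
#' @param value_format `"raw_adu"` or `"calibrated_adu"`.
#' @param provenance free-form record of which reference frames were applied.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(pixels, pixel_size = 107, z_step = 333,
                        exposure = 1, timestamps = NULL,
                        calibrated = FALSE, value_format = if (calibrated)
                          "calibrated_adu" else "raw_adu",
                        provenance = NULL) {
  if (is.matrix(pixels)) pixels <- array(pixels, c(dim(pixels), 1L))
  if (!is.array(pixels) || length(dim(pixels)) < 2L ||
      length(dim(pixels)) > 4L)
    stopf("pixels must be a 2D, 3D or 4D array")
  if (any(dim(pixels) < 1L)) stopf("all stack dimensions must be >= 1")
  if (!is_scalar_num(pixel_size) || pixel_size <= 0)
    stopf("pixel_size must be positive")
  if (!is_scalar_num(z_step) || z_step <= 0) stopf("z_step must be positive")
  if (exposure < 0) stopf("exposure must be nonnegative")
  value_format <- match.arg(value_format, c("raw_adu", "calibrated_adu"))
  if (value_format == "raw_adu") {
    if (any(pixels < 0)) stopf("raw ADU values must be nonnegative")
    if (any(abs(pixels - round(pixels)) > 1e-9))
      stopf("raw ADU values must be integers")
  }
  if (!is.null(timestamps)) {
    if (is.unsorted(timestamps)) stopf("timestamps must be nondecreasing")
  }
  structure(list(pixels = pixels, pixel_size = pixel_size, z_step = z_step,
                 exposure = exposure, timestamps = timestamps,
                 calibrated = isTRUE(calibrated),
                 value_format = value_format,
                 provenance = provenance),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("image_stack: %s [%s], %s, %g nm/px, %g s exposure\n",
              paste(dim(x$pixels), collapse = " x "),
              x$value_format,
              if (x$calibrated) "calibrated" else "raw",
              x$pixel_size, x$exposure))
  invisible(x)
}

## Apply a per-frame reference (scalar or matrix) to every slice of a stack.
sweep_frames <- function(pixels, ref, op) {
  if (!is.matrix(ref)) return(get(op)(pixels, ref))
  d <- dim(pixels)
  if (!identical(dim(ref), d[1:2]))
    stopf("reference frame shape (%s) does not match frame shape (%s)",
          paste(dim(ref), collapse = "x"), paste(d[1:2], collapse = "x"))
  array(get(op)(as.vector(pixels), as.vector(ref)), d)
}

#' Calibrate a raw stack to floating-point ADU
#'
#' Converts a raw EMCCD stack into calibrated 32-bit-style floating point
#' values by subtracting the bias level and the expected thermal signal and
#' dividing by the (mean-1 normalized) flat field:
#' `out = (raw - bias - dark_current * exposure / conversion_gain) / flat`.
#' When the camera carries a measured dark frame (ADU/s) it overrides the
#' scalar dark-current model.
#'
#' @param raw an [image_stack] with `value_format = "raw_adu"`.
#' @param cam a [camera_model].
#' @return A calibrated [image_stack]; provenance records which references
#'   were applied so downstream photometry can refuse uncalibrated input.
#' @export
calibrate_stack <- function(raw, cam) {
  if (!inherits(raw, "image_stack")) stopf("raw must be an image_stack")
  if (!inherits(cam, "camera_model")) stopf("cam must be a camera_model")
  if (raw$value_format != "raw_adu")
    stopf("calibrate_stack expects raw ADU input (got %s)", raw$value_format)
  if (raw$exposure < 0) stopf("negative exposure")
  px <- sweep_frames(raw$pixels, cam$bias_level, "-")
  if (!is.null(cam$dark_frame)) {
    px <- sweep_frames(px, cam$dark_frame * raw$exposure, "-")
    dark_src <- "dark_frame"
  } else {
    px <- px - cam$dark_current * raw$exposure / cam$conversion_gain
    dark_src <- "dark_scalar"
  }
  if (!is.null(cam$flat_field)) px <- sweep_frames(px, cam$flat_field, "/")
  image_stack(px, pixel_size = raw$pixel_size, z_step = raw$z_step,
              exposure = raw$exposure, timestamps = raw$timestamps,
              calibrated = TRUE, value_format = "calibrated_adu",
              provenance = list(bias = if (is.matrix(cam$bias_level))
                "frame" else "scalar", dark = dark_src,
                flat = if (is.matrix(cam$flat_field)) "frame" else "none"))
}

#' Invert the calibration of a stack (for round-trip checks)
#'
#' @param cal calibrated [image_stack].
#' @param cam the [camera_model] used to calibrate it.
#' @param quantize round back to integer ADU?
#' @return A raw [image_stack].
#' @export
uncalibrate_stack <- function(cal, cam, quantize = TRUE) {
  if (cal$value_format != "calibrated_adu")
    stopf("uncalibrate_stack expects a calibrated stack")
  px <- cal$pixels
  if (!is.null(cam$flat_field)) px <- sweep_frames(px, cam$flat_field, "*")
  if (!is.null(cam$dark_frame)) {
    px <- sweep_frames(px, cam$dark_frame * cal$exposure, "+")
  } else {
    px <- px + cam$dark_current * cal$exposure / cam$conversion_gain
  }
  px <- sweep_frames(px, cam$bias_level, "+")
  if (quantize) px <- pmax(round(px), 0)
  image_stack(px, pixel_size = cal$pixel_size, z_step = cal$z_step,
              exposure = cal$exposure, timestamps = cal$timestamps,
              calibrated = FALSE, value_format = "raw_adu")
}

#' Convert background-corrected ADU to photoelectrons
#'
#' Background-corrected signal in calibrated ADU is converted into detected
#' photoelectrons (the equivalent of detected photons) by multiplying with
#' the camera conversion gain.  Strictly linear and sign-preserving; negative
#' net ADU passes through for the caller to interpret.
#'
#' @param net_adu background-corrected signal, ADU (any numeric shape).
#' @param cam a [camera_model].
#' @return photoelectrons, same shape as `net_adu`.
#' @export
adu_to_photons <- function(net_adu, cam) {
  if (!inherits(cam, "camera_model")) stopf("cam must be a camera_model")
  net_adu * cam$conversion_gain
}
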