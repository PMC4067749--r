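#' tetO/TetR calibration standard
#'
#' An array of tet operator sites bound by fluorescent-protein-tagged
#' tetracycline repressor.  TetR is a homodimer, so each operator can carry
#' at most two fluorophores: a 14x array holds up to 28 GFPs and a 21x array
#' up to 42.  Full occupancy is assumed for calibration (the known bias
#' direction: partial occupancy in the standards would inflate cluster
#' counts).
#'
#' @param n_operator_sites number of tetO sites (7, 14, 21 or 112).
#' @param fluorophores_per_site fluorophores per occupied operator
#'   (default 2, homodimer).
#' @param label optional label; defaults to e.g. `"tetO_14x"`.
#' @param measured optional list of `cluster_measurement`s or a data.frame
#'   with a `photon_rate` column.
#' @return An object of class `calibration_standard`.
#' @export
calibration_standard <- function(n_operator_sites, fluorophores_per_site = 2,
                                 label = sprintf("tetO_%dx", n_operator_sites),
                                 measured = NULL) {
  if (!is_scalar_num(n_operator_sites) || n_operator_sites < 0)
    stopf("n_operator_sites must be a nonnegative count")
  if (!is_scalar_num(fluorophores_per_site) || fluorophores_per_site < 1)
    stopf("fluorophores_per_site must be >= 1")
  if (is.list(measured) && !is.data.frame(measured))
    measured <- measurements_table(measured)
  structure(list(n_operator_sites = n_operator_sites,
                 fluorophores_per_site = fluorophores_per_site,
                 label = label, measured = measured),
            class = "calibration_standard")
}

#' Maximum fluorophore load of a calibration standard
#'
#' @param std a [calibration_standard].
#' @return `n_operator_sites * fluorophores_per_site`.
#' @export
max_fluorophores <- function(std) {
  std$n_operator_sites * std$fluorophores_per_site
}

#' Fit the photons-per-fluorophore calibration
#'
#' Least-squares regression through the origin of each standard's *median*
#' photon rate against its maximum fluorophore number.  Medians (not means)
#' resist occupancy outliers and match how grouped intensities are
#' summarized.  The slope is the photon rate of a single fluorophore.
#'
#' @param standards list of [calibration_standard]s (>= 2 distinct
#'   `expected_max` values), each with >= `min_measurements` measurements at
#'   a common exposure or rate-normalized.
#' @param min_measurements minimum measurements per standard (default 5).
#' @return An object of class `counting_calibration`: `slope`
#'   (photons/fluorophore/s), `fit_standards`, `medians`, `expected_max`,
#'   `residuals`.
#' @export
fit_calibration <- function(standards, min_measurements = 5) {
  if (inherits(standards, "calibration_standard")) standards <- list(standards)
  emax <- vapply(standards, max_fluorophores, 0)
  if (length(unique(emax)) < 2L)
    stopf("calibration needs >= 2 distinct standards")
  med <- vapply(standards, function(s) {
    if (is.null(s$measured) || nrow(s$measured) < min_measurements)
      stopf("standard %s has fewer than %d measurements", s$label,
            min_measurements)
    stats::median(s$measured$photon_rate)
  }, 0)
  slope <- sum(emax * med) / sum(emax^2)
  if (slope <= 0) stopf("degenerate calibration data: nonpositive slope")
  resid <- med - slope * emax
  if (stats::sd(med) < 1e-12 * max(abs(med)))
    warnf("calibration standards have equal medians; fit is degenerate")
  structure(list(slope = slope,
                 fit_standards = vapply(standards, `[[`, "", "label"),
                 expected_max = emax, medians = med, residuals = resid),
            class = "counting_calibration")
}

#' @export
print.counting_calibration <- function(x, ...) {
  cat(sprintf("counting calibration: %.4g photons/fluorophore/s (%s)\n",
              x$slope, paste(x$fit_standards, collapse = ", ")))
  invisible(x)
}

#' Estimate the molecule count of a cluster
#'
#' Divides a cluster's photon rate by the calibrated per-fluorophore photon
#' rate.  For a telophase cluster (16 clustered centromeres, mature
#' fluorophores -- the canonical counting stage) the per-centromere count is
#' `molecules / 16`.
#'
#' @param m a `cluster_measurement`, or a numeric photon rate
#'   (photons/s, e.g. a group median).
#' @param cal a [counting_calibration].
#' @param n_centromeres centromeres in the cluster (default 16, telophase).
#' @return An object of class `count_estimate`: `molecules`,
#'   `molecules_per_centromere`.
#' @export
estimate_count <- function(m, cal, n_centromeres = 16) {
  if (!inherits(cal, "counting_calibration") || cal$slope <= 0)
    stopf("cal must be a counting_calibration with positive slope")
  rate <- if (inherits(m, "cluster_measurement")) m$photon_rate else m
  molecules <- rate / cal$slope
  structure(list(molecules = molecules,
                 molecules_per_centromere = molecules / n_centromeres,
                 n_centromeres = n_centromeres),
            class = "count_estimate")
}

#' @export
print.count_estimate <- function(x, ...) {
  cat(sprintf("%.1f molecules (%.2f per centromere, n = %d centromeres)\n",
              x$molecules, x$molecules_per_centromere, x$n_centromeres))
  invisible(x)
}
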