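#' @name pipeline
#' @title End-to-end analysis pipelines
#' @description
#' Orchestrated runs composing the synthetic generator, calibration,
#' wavelet filtering, photometry, counting, kinetics and PALM geometry into
#' figure-level reports.  Every report embeds the seed and a hash of the
#' effective configuration, so identical inputs give identical reports.
NULL

## stable short hash of a config list
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, force = TRUE)
  v <- utf8ToInt(as.character(s))
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967291)
}

merge_config <- function(defaults, config) {
  for (nm in names(config)) defaults[[nm]] <- config[[nm]]
  defaults
}

## Wavelet-assisted photometry of the brightest spot in one raw image.
measure_brightest_spot <- function(raw, cam, policy, scale_ids = 1:3,
                                   min_snr = 5) {
  cal <- calibrate_stack(raw, cam)
  frame <- cal$pixels[, , 1]
  spot <- wavelet_filter(frame, scale_ids = scale_ids)
  det <- detect_clusters(spot, min_snr = min_snr,
                         min_separation = policy$aperture_radius)
  if (nrow(det) == 0L) return(NULL)
  aperture_photometry(spot, center = c(det$x[1], det$y[1]), policy = policy,
                      cam = cam, exposure = cal$exposure)
}

#' Run the molecule-counting pipeline on synthetic data
#'
#' Generates tetO/TetR titration standards (7x/14x/21x, full occupancy) and
#' telophase centromere-cluster scenes with exactly 2 x 16 fluorophores,
#' pushes both through calibration, wavelet filtering and aperture
#' photometry, fits the photons-per-fluorophore calibration on the standard
#' medians, and converts the cluster photon rates to molecule counts.
#'
#' @param config optional overrides: `seed`, `n_images`,
#'   `per_fluorophore_rate`, `operator_counts`, `n_cluster_emitters`,
#'   `min_snr`.
#' @return report list: `calibration` (slope etc.), `counts` (per-cluster
#'   molecules), `count_summary` (five-number summary),
#'   `median_molecules`, `molecules_per_centromere`, `seed`, `config_hash`.
#' @export
run_counting <- function(config = list()) {
  cfg <- merge_config(list(seed = 1, n_images = 50,
                           per_fluorophore_rate = 45,
                           operator_counts = c(7, 14, 21),
                           n_cluster_emitters = 32, min_snr = 5), config)
  cam <- camera_model()
  policy <- aperture_policy()
  tit <- generate_titration(operator_counts = cfg$operator_counts,
                            per_fluorophore_rate = cfg$per_fluorophore_rate,
                            n_images = cfg$n_images, cam = cam,
                            seed = child_seed(cfg$seed, "titration"))
  standards <- lapply(cfg$operator_counts, function(nop) {
    idx <- tit$truth$image[tit$truth$n_operator_sites == nop]
    ms <- Filter(Negate(is.null), lapply(tit$images[idx], function(im)
      measure_brightest_spot(im, cam, policy, min_snr = cfg$min_snr)))
    if (!length(ms)) stopf("counting stage failed: no detections for %dx", nop)
    calibration_standard(nop, measured = ms)
  })
  cal <- fit_calibration(standards)
  cl <- generate_cluster_scenes(n_images = cfg$n_images,
                                n_emitters = cfg$n_cluster_emitters,
                                per_fluorophore_rate =
                                  cfg$per_fluorophore_rate,
                                cam = cam,
                                seed = child_seed(cfg$seed, "clusters"))
  ms <- Filter(Negate(is.null), lapply(cl$images, function(im)
    measure_brightest_spot(im, cam, policy, min_snr = cfg$min_snr)))
  if (!length(ms)) stopf("counting stage failed: no cluster detections")
  rates <- vapply(ms, `[[`, 0, "photon_rate")
  counts <- rates / cal$slope
  med_est <- estimate_count(stats::median(rates), cal)
  list(calibration = cal, counts = counts,
       count_summary = summarize_quartiles(counts),
       median_molecules = med_est$molecules,
       molecules_per_centromere = med_est$molecules_per_centromere,
       n_clusters_measured = length(ms),
       seed = cfg$seed, config_hash = config_hash(cfg))
}

## Haar-measure random 3D rotation.
random_rotation3 <- function() {
  qr_d <- qr(matrix(stats::rnorm(9), 3))
  q <- qr.Q(qr_d)
  d <- sign(diag(qr.R(qr_d)))
  q <- q %*% diag(d)
  if (det(q) < 0) q[, 3] <- -q[, 3]
  q
}

#' Run the anaphase-compaction pipeline on synthetic PALM data
#'
#' Generates drifting MFM-PALM localization movies for G1 cells (spherical
#' clusters, 450 nm across, ~21 events each) and anaphase cells (randomly
#' oriented 350 x 350 x 200 nm ellipsoids), drift-corrects them against
#' fiducials, groups localizations into fluorophore events, pools
#' center-aligned clusters per condition, and compares the ellipsoid
#' volumes.
#'
#' @param config optional overrides: `seed`, `n_clusters_per_condition`,
#'   `g1_events`, `ana_events`, `g1_diameter`, `ana_axes`, `drift`.
#' @return report list with per-condition `cluster_geometry` objects,
#'   `volume_ratio`, `seed`, `config_hash`.
#' @export
run_compaction <- function(config = list()) {
  cfg <- merge_config(list(seed = 1, n_clusters_per_condition = 10,
                           g1_events = 21, ana_events = 24,
                           g1_diameter = 450, ana_axes = c(350, 350, 200),
                           drift = c(100, -50, 200)), config)
  loc_noise <- c(20, 20, 50)
  one_condition <- function(mode) {
    set.seed(child_seed(cfg$seed, paste0("rot_", mode)))
    pts <- lapply(seq_len(cfg$n_clusters_per_condition), function(i) {
      cl <- if (mode == "G1")
        list(center = c(0, 0, 0), n_fluorophores = cfg$g1_events,
             shape = "sphere", diameter = cfg$g1_diameter)
      else
        list(center = c(0, 0, 0), n_fluorophores = cfg$ana_events,
             shape = "ellipsoid", axes = cfg$ana_axes,
             rotation = random_rotation3())
      mv <- generate_palm_movie(
        clusters = list(cl), activation = "sequential",
        loc_noise = loc_noise, drift = cfg$drift,
        seed = child_seed(cfg$seed, sprintf("%s_%d", mode, i)))
      corr <- drift_correct(mv$locs[!mv$locs$is_fiducial, ],
                            mv$locs[mv$locs$is_fiducial, ])
      ## sequential activation guarantees temporal separation, so the link
      ## radius only needs to stay below the cluster separation scale
      ev <- group_events(corr, link_radius = 150)
      ## events average n_frames localizations, improving their precision
      attr(ev, "noise_shrink") <- mean(1 / ev$n_frames)
      ev
    })
    shrink <- mean(vapply(pts, attr, 0, "noise_shrink"))
    pts <- lapply(pts, function(ev) as.matrix(ev[, c("x_nm", "y_nm",
                                                     "z_nm")]))
    eff_noise <- diag(loc_noise^2) * shrink
    pooled <- compile_clusters(pts, mode = if (mode == "G1") "G1"
                               else "anaphase", precision = eff_noise)
    cluster_geometry(pooled, precision = attr(pooled, "noise_cov"))
  }
  g1 <- one_condition("G1")
  ana <- one_condition("anaphase")
  list(g1 = g1, anaphase = ana,
       volume_ratio = volume_ratio(g1, ana),
       seed = cfg$seed, config_hash = config_hash(cfg))
}

#' Run the kinetics pipelines on synthetic data
#'
#' Maturation-halftime fit on a cycloheximide-block course, pulse-chase
#' classification against ground truth, and targeted-photobleaching
#' recovery times pooled across cell-cycle stages.
#'
#' @param config optional overrides: `seed`, `n_cells_maturation`,
#'   `n_cells_pulse_chase`, `n_cells_frap`.
#' @return report list: `t_half`, `plateau`, `pulse_chase` (confusion
#'   table), `frap` (stage means, pooled mean), `seed`, `config_hash`.
#' @export
run_kinetics <- function(config = list()) {
  cfg <- merge_config(list(seed = 1, n_cells_maturation = 20,
                           n_cells_pulse_chase = 40, n_cells_frap = 42),
                      config)
  mat <- generate_maturation_course(n_cells = cfg$n_cells_maturation,
                                    seed = child_seed(cfg$seed, "mat"))
  fit <- fit_maturation_halftime(mat$course$t_min, mat$course$net_photons,
                                 t_block = mat$truth$t_block)
  pc <- generate_pulse_chase_panel(n_cells = cfg$n_cells_pulse_chase,
                                   seed = child_seed(cfg$seed, "pc"))
  cls <- classify_pulse_chase(pc$panel$pulse, pc$panel$chase,
                              second_pc = pc$panel$second_pc,
                              bleach_factor = pc$bleach_factor)
  confusion <- table(truth = pc$truth$label, classified = cls)
  fr <- generate_frap_course(n_cells = cfg$n_cells_frap,
                             seed = child_seed(cfg$seed, "frap"))
  recs <- lapply(fr$series, function(s)
    frap_recovery_time(s$net_photons, fr$truth$baseline_sigma,
                       fr$truth$sampling_interval, times = s$t_min,
                       cell_id = s$cell_id[1], stage = s$stage[1]))
  rec_t <- vapply(recs, `[[`, 0, "recovery_time")
  stage <- vapply(recs, `[[`, "", "stage")
  ok <- !is.na(rec_t)
  stage_means <- tapply(rec_t[ok], stage[ok], mean)
  stage_n <- tapply(rec_t[ok], stage[ok], length)
  list(t_half = fit$t_half, plateau = fit$plateau,
       plateau_empirical = fit$plateau_empirical,
       pulse_chase = confusion,
       frap = list(stage_means = stage_means, stage_n = stage_n,
                   pooled_mean = pooled_mean_recovery(as.numeric(stage_means),
                                                      as.numeric(stage_n)),
                   n_censored = sum(!ok)),
       seed = cfg$seed, config_hash = config_hash(cfg))
}
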