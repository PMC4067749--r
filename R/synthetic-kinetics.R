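#' Generate a cycloheximide-block maturation time course
#'
#' Emulates the translation-block experiment: protein deposited on new
#' centromere clusters by `t_block` minutes after S-phase entry, then no
#' further synthesis, so cluster brightness rises purely by fluorophore
#' maturation: `I(t) = A * (1 - exp(-k_mat * (t - t_block)))` for
#' `t >= t_block`, with per-observation multiplicative Gaussian noise.
#'
#' @param model a [fluorophore_state_model] (its `k_mat` sets the truth).
#' @param t_block translation-block time, min (default 10, i.e. drug added
#'   10 min after entry into S phase).
#' @param timepoints sampling times, min (default 0--180 every 10 min;
#'   points before `t_block` are reported as zero-intensity baseline).
#' @param n_cells number of cells measured per timepoint.
#' @param plateau_photons asymptotic cluster brightness A, photons per 1 s
#'   exposure (default 1750, the plateau scale of the block experiment).
#' @param noise_cv multiplicative noise coefficient of variation
#'   (default 0.05).
#' @param seed RNG seed.
#' @return list: `course` (data.frame cell_id, t_min, net_photons), `truth`
#'   (t_half, plateau, t_block).
#' @export
generate_maturation_course <- function(model = fluorophore_state_model(),
                                       t_block = 10,
                                       timepoints = seq(0, 180, by = 10),
                                       n_cells = 20,
                                       plateau_photons = 1750,
                                       noise_cv = 0.05, seed = 1) {
  set.seed(seed)
  rows <- expand.grid(cell_id = seq_len(n_cells), t_min = timepoints)
  mean_i <- ifelse(rows$t_min < t_block, 0,
                   plateau_photons *
                     (1 - exp(-model$k_mat * (rows$t_min - t_block))))
  rows$net_photons <- mean_i * (1 + stats::rnorm(nrow(rows), 0, noise_cv))
  list(course = rows,
       truth = list(t_half = log(2) / model$k_mat,
                    plateau = plateau_photons, t_block = t_block))
}

#' Generate targeted-photobleaching (FRAP) recovery series
#'
#' Single-rate binding-site exchange with an unbleached nuclear pool in
#' `free_pool_ratio`-fold excess over the bound molecules: after a complete
#' bleach of one cluster, its signal recovers as
#' `plateau * (1 - exp(-(t - t_bleach)/exchange_time))`, where the plateau
#' is the pre-bleach level scaled by the pool-depletion factor
#' `free / (free + bound)`.  Additive Gaussian measurement noise is applied.
#' The defaults place the mean detection time (threshold = 3 x
#' `baseline_sigma`) near 5 minutes.
#'
#' @param prebleach_photons pre-bleach cluster signal (default 10000
#'   photons in a 5 s exposure).
#' @param free_pool_ratio free:bound excess (default 4).
#' @param exchange_time binding-site exchange timescale, min (default 15).
#' @param bleach_time min (default 0).
#' @param sampling_interval min between post-bleach images (default 1).
#' @param n_timepoints post-bleach images per cell.
#' @param n_cells number of cells (default 42).
#' @param baseline_sigma measurement noise SD, photons (default 700).
#' @param stages cell-cycle labels recycled over cells.
#' @param seed RNG seed.
#' @return list: `series` (list of per-cell data.frames t_min,
#'   net_photons, stage), `truth` (exchange_time, plateau, threshold and the
#'   implied noise-free detection time).
#' @export
generate_frap_course <- function(prebleach_photons = 10000,
                                 free_pool_ratio = 4, exchange_time = 15,
                                 bleach_time = 0, sampling_interval = 1,
                                 n_timepoints = 30, n_cells = 42,
                                 baseline_sigma = 700,
                                 stages = c("G1", "S", "M", "A", "T"),
                                 seed = 7) {
  set.seed(seed)
  plateau <- prebleach_photons * free_pool_ratio / (free_pool_ratio + 1)
  t <- bleach_time + sampling_interval * seq_len(n_timepoints)
  thr <- 3 * baseline_sigma
  series <- lapply(seq_len(n_cells), function(i) {
    mean_s <- plateau * (1 - exp(-(t - bleach_time) / exchange_time))
    data.frame(cell_id = i, stage = stages[(i - 1) %% length(stages) + 1],
               t_min = t,
               net_photons = mean_s + stats::rnorm(length(t), 0,
                                                   baseline_sigma))
  })
  t_detect <- bleach_time - exchange_time * log(1 - thr / plateau)
  list(series = series,
       truth = list(exchange_time = exchange_time, plateau = plateau,
                    threshold = thr, baseline_sigma = baseline_sigma,
                    sampling_interval = sampling_interval,
                    noise_free_detection_time = t_detect))
}

#' Generate a photoconversion pulse-chase panel
#'
#' Red-channel cluster photometry at the pulse and chase timepoints (and a
#' confirmatory second photoconversion) for a mixed population: cells that
#' cross the G1/S boundary between the timepoints lose their marked
#' centromeric protein entirely (replacement), all others retain it up to
#' imaging bleaching.  Ground-truth labels accompany every cell.
#'
#' @param n_cells panel size (default 40).
#' @param frac_crossing_s fraction of cells crossing G1/S during the chase.
#' @param replacement_at_S if `FALSE`, even S-crossing cells retain signal
#'   (control panel).
#' @param bleach_factor surviving signal fraction from imaging bleaching.
#' @param pulse_photons mean marked-cluster signal at pulse.
#' @param noise_cv multiplicative measurement noise.
#' @param seed RNG seed.
#' @return list: `panel` (data.frame cell_id, pulse, chase, second_pc),
#'   `truth` (data.frame cell_id, label), `bleach_factor`.
#' @export
generate_pulse_chase_panel <- function(n_cells = 40, frac_crossing_s = 0.3,
                                       replacement_at_S = TRUE,
                                       bleach_factor = 0.8,
                                       pulse_photons = 7500,
                                       noise_cv = 0.1, seed = 1) {
  set.seed(seed)
  crossing <- stats::runif(n_cells) < frac_crossing_s
  replaced <- crossing & replacement_at_S
  pulse <- pulse_photons * (1 + stats::rnorm(n_cells, 0, noise_cv))
  chase <- ifelse(replaced,
                  abs(stats::rnorm(n_cells, 0, 0.02 * pulse_photons)),
                  pulse * bleach_factor *
                    (1 + stats::rnorm(n_cells, 0, noise_cv)))
  second_pc <- pulse_photons * (1 + stats::rnorm(n_cells, 0, noise_cv))
  list(panel = data.frame(cell_id = seq_len(n_cells), pulse = pulse,
                          chase = chase, second_pc = second_pc),
       truth = data.frame(cell_id = seq_len(n_cells),
                          label = ifelse(replaced, "lost_replaced",
                                         "retained")),
       bleach_factor = bleach_factor)
}
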