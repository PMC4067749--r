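#' Photoconvertible fluorophore state model
#'
#' Kinetic scheme for a tandem-dimer Eos-type (or GFP-type) fluorophore:
#' newly synthesized protein folds and then matures slowly into a green
#' emitting state (half-time ~40 min at 25 C, so the default maturation rate
#' is ln2/40 per minute); violet (405 nm) light converts mature green
#' fluorophores irreversibly to a red-emitting state; both emitting states
#' can enter reversible dark states and bleach irreversibly under their
#' respective excitation light; fixation can convert a fraction of
#' fluorophores to red.
#'
#' All rates are per minute.  The dark-state rates have no measured values
#' in this system; the defaults are order-of-magnitude placeholders for
#' simulation only.
#'
#' @param k_mat maturation rate, immature -> green (default `log(2)/40`).
#' @param p_pc photoconversion probability per 405 nm pulse, green -> red.
#' @param k_bleach_green,k_bleach_red bleaching rates while the matching
#'   excitation light is on.
#' @param k_dark_on,k_dark_off reversible dark-state entry (illumination-on)
#'   and spontaneous exit rates.
#' @param p_rescue_405 probability per 405 nm pulse of returning a dark
#'   fluorophore to its emitting state.
#' @param fixation_conversion_prob green -> red probability upon fixation.
#' @return An object of class `fluorophore_state_model`.
#' @export
fluorophore_state_model <- function(k_mat = log(2) / 40, p_pc = 0.9,
                                    k_bleach_green = 0.02,
                                    k_bleach_red = 0.02,
                                    k_dark_on = 0.05, k_dark_off = 0.5,
                                    p_rescue_405 = 0.3,
                                    fixation_conversion_prob = 0.2) {
  rates <- c(k_mat = k_mat, k_bleach_green = k_bleach_green,
             k_bleach_red = k_bleach_red, k_dark_on = k_dark_on,
             k_dark_off = k_dark_off)
  if (any(!is.finite(rates)) || any(rates < 0))
    stopf("all rates must be finite and >= 0")
  probs <- c(p_pc = p_pc, p_rescue_405 = p_rescue_405,
             fixation_conversion_prob = fixation_conversion_prob)
  if (any(probs < 0 | probs > 1)) stopf("probabilities must be in [0, 1]")
  structure(c(as.list(rates), as.list(probs)),
            class = "fluorophore_state_model")
}

#' Fluorophore state names
#' @return The six model states; `bleached` is absorbing.
#' @export
fluorophore_states <- function() {
  c("immature", "green", "green_dark", "red", "red_dark", "bleached")
}

#' Illumination schedule
#'
#' A timeline of contiguous illumination segments plus instantaneous 405 nm
#' pulses.  Channels: `"none"`, `"green_ex"` (470/488 nm), `"red_ex"`
#' (561/555 nm).  Times are minutes.
#'
#' @param durations segment durations, min (> 0).
#' @param channels channel per segment.
#' @param pulses_405 absolute times (min) of instantaneous 405 nm pulses.
#' @return An object of class `illumination_schedule` with segment start and
#'   end times.
#' @export
illumination_schedule <- function(durations, channels = "none",
                                  pulses_405 = numeric(0)) {
  if (any(durations <= 0)) stopf("segment durations must be > 0")
  channels <- rep_len(channels, length(durations))
  bad <- setdiff(channels, c("none", "green_ex", "red_ex"))
  if (length(bad)) stopf("unknown channel: %s", bad[1])
  ends <- cumsum(durations)
  structure(list(start = c(0, ends[-length(ends)]), end = ends,
                 channel = channels, pulses_405 = sort(pulses_405),
                 total = ends[length(ends)]),
            class = "illumination_schedule")
}

## Active transitions for a state under a channel: list(to=..., rate=...)
state_transitions <- function(model, state, channel) {
  switch(state,
    immature = list(to = "green", rate = model$k_mat),
    green = if (channel == "green_ex")
      list(to = c("bleached", "green_dark"),
           rate = c(model$k_bleach_green, model$k_dark_on))
      else list(to = character(0), rate = numeric(0)),
    green_dark = list(to = "green", rate = model$k_dark_off),
    red = if (channel == "red_ex")
      list(to = c("bleached", "red_dark"),
           rate = c(model$k_bleach_red, model$k_dark_on))
      else list(to = character(0), rate = numeric(0)),
    red_dark = list(to = "red", rate = model$k_dark_off),
    bleached = list(to = character(0), rate = numeric(0)))
}

apply_pulse <- function(model, state) {
  u <- stats::runif(1)
  switch(state,
    green = if (u < model$p_pc) "red" else state,
    green_dark = if (u < model$p_rescue_405) "green" else state,
    red_dark = if (u < model$p_rescue_405) "red" else state,
    state)
}

#' Simulate an ensemble of fluorophores through an illumination schedule
#'
#' Continuous-time Markov simulation with per-molecule exponential waiting
#' times; 405 nm pulses are applied as Bernoulli state flips at their
#' scheduled instants.  Molecules are born immature at their synthesis time.
#'
#' @param model a [fluorophore_state_model].
#' @param schedule an [illumination_schedule].
#' @param n_fluorophores ensemble size (>= 1).
#' @param synthesis_times per-molecule birth times, min (recycled;
#'   default 0).
#' @param seed RNG seed for reproducibility.
#' @param times time grid (min) on which occupancies are reported; default
#'   128 points spanning the schedule plus all segment boundaries.
#' @param initial_state state at birth (default `"immature"`).
#' @return list with `times`, `occupancy` (matrix, time x state, fractions
#'   of the ensemble), and `trajectories` (per-molecule data.frames of jump
#'   times and states).
#' @export
simulate_ensemble <- function(model, schedule, n_fluorophores,
                              synthesis_times = 0, seed = 1,
                              times = NULL, initial_state = "immature") {
  if (n_fluorophores < 1) stopf("n_fluorophores must be >= 1")
  initial_state <- match.arg(initial_state, fluorophore_states())
  set.seed(seed)
  birth <- rep_len(synthesis_times, n_fluorophores)
  if (is.null(times))
    times <- sort(unique(c(schedule$start, schedule$end,
                           seq(0, schedule$total, length.out = 128))))
  states <- fluorophore_states()
  pulses <- schedule$pulses_405
  traj <- vector("list", n_fluorophores)
  occ <- matrix(0, length(times), length(states),
                dimnames = list(NULL, states))
  for (i in seq_len(n_fluorophores)) {
    t <- birth[i]; st <- initial_state
    jt <- t; js <- st
    for (s in seq_along(schedule$start)) {
      t1 <- schedule$end[s]
      if (t >= t1) next
      ch <- schedule$channel[s]
      seg_pulses <- pulses[pulses > max(t, schedule$start[s]) & pulses <= t1]
      for (pt in c(seg_pulses, t1)) {
        ## evolve continuously up to pt
        repeat {
          tr <- state_transitions(model, st, ch)
          tot <- sum(tr$rate)
          if (tot <= 0) { t <- pt; break }
          dt <- stats::rexp(1, tot)
          if (t + dt >= pt) { t <- pt; break }
          t <- t + dt
          st <- sample(tr$to, 1, prob = tr$rate)
          jt <- c(jt, t); js <- c(js, st)
        }
        if (pt %in% seg_pulses) {
          new <- apply_pulse(model, st)
          if (new != st) { st <- new; jt <- c(jt, t); js <- c(js, st) }
        }
      }
    }
    traj[[i]] <- data.frame(t = jt, state = js)
    idx <- findInterval(times, jt)
    vis <- idx >= 1L
    if (any(vis))
      occ[cbind(which(vis), match(js[idx[vis]], states))] <-
        occ[cbind(which(vis), match(js[idx[vis]], states))] + 1
    ## before birth the molecule does not exist; count it as immature
    if (any(!vis)) occ[which(!vis), "immature"] <-
        occ[which(!vis), "immature"] + 1
  }
  list(times = times, occupancy = occ / n_fluorophores, trajectories = traj)
}

#' Fit the fluorophore maturation half-time
#'
#' Least-squares fit of the single-exponential maturation model
#' `I(t) = A * (1 - exp(-ln2 * (t - t0) / t_half))` for `t >= t0`, with the
#' deposition/translation-block time `t0` fixed.  The plateau is also
#' reported as the empirical mean of points beyond 100 min (the
#' normalization rule used for cycloheximide-block courses); both estimates
#' are returned.
#'
#' @param timepoints times, min (>= 5 points spanning rise and plateau).
#' @param intensities cluster photon values at `timepoints`.
#' @param t_block deposition/block time `t0`, min (default 0).
#' @return list: `t_half` (min), `plateau` (fitted A), `plateau_empirical`
#'   (mean of points with t > 100 min, or NA), `fit` (the `nls` object),
#'   `residual_sd`.
#' @export
fit_maturation_halftime <- function(timepoints, intensities, t_block = 0) {
  keep <- timepoints >= t_block & is.finite(intensities)
  t <- timepoints[keep]; y <- intensities[keep]
  if (length(t) < 5L) stopf("need >= 5 timepoints at or after t_block")
  plateau_emp <- if (any(t > 100)) mean(y[t > 100]) else {
    warnf("no points beyond 100 min; empirical plateau rule inapplicable")
    NA_real_
  }
  a0 <- max(plateau_emp, max(y), na.rm = TRUE)
  ## crude half-time start: first time the signal passes A/2
  th0 <- t[which(y >= a0 / 2)[1]] - t_block
  if (is.na(th0) || th0 <= 0) th0 <- diff(range(t)) / 4
  fit <- tryCatch(
    stats::nls(y ~ A * (1 - exp(-log(2) * (t - t_block) / th)),
               start = list(A = a0, th = th0),
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE),
               algorithm = "port", lower = c(A = 0, th = 1e-6)),
    error = function(e) stopf("maturation fit failed to converge: %s",
                              conditionMessage(e)))
  co <- stats::coef(fit)
  list(t_half = unname(co["th"]), plateau = unname(co["A"]),
       plateau_empirical = plateau_emp, fit = fit,
       residual_sd = stats::sigma(fit))
}

#' Classify pulse-chase clusters as retained or lost/replaced
#'
#' After photoconversion marks the mature pool red (pulse), a cluster that
#' still carries at least `retention_fraction` of its pulse signal at chase
#' (after correcting for imaging-induced bleaching) retains its marked
#' protein; one at or below `loss_fraction` has lost/replaced it (the
#' hallmark of cells crossing G1/S); anything between is ambiguous.  A
#' second photoconversion at the end of the experiment controls for
#' Z-range: clusters whose second-pulse signal is below detection are
#' flagged out-of-range and excluded.
#'
#' @param pulse red-channel cluster photons at the pulse timepoint.
#' @param chase red-channel cluster photons at the chase timepoint.
#' @param second_pc optional red signal after the confirmatory second
#'   photoconversion.
#' @param bleach_factor expected surviving fraction of signal due to imaging
#'   bleaching alone (default 1 = no correction); estimate it from non-S
#'   cells.
#' @param retention_fraction,loss_fraction classification thresholds
#'   (defaults 0.5 / 0.25; these separate the bimodal synthetic
#'   distributions with margin and are configurable).
#' @param detection_limit photon level below which a signal counts as
#'   undetected.
#' @return character vector: `"retained"`, `"lost_replaced"`, `"ambiguous"`
#'   or `"out_of_range"`.
#' @export
classify_pulse_chase <- function(pulse, chase, second_pc = NULL,
                                 bleach_factor = 1,
                                 retention_fraction = 0.5,
                                 loss_fraction = 0.25,
                                 detection_limit = 0) {
  if (any(is.na(pulse))) stopf("missing pulse measurement")
  n <- length(pulse)
  if (length(chase) != n) stopf("pulse and chase lengths differ")
  ratio <- (chase / bleach_factor) / pulse
  cls <- ifelse(ratio >= retention_fraction, "retained",
                ifelse(ratio <= loss_fraction, "lost_replaced", "ambiguous"))
  if (!is.null(second_pc))
    cls[second_pc <= detection_limit] <- "out_of_range"
  cls
}

#' Recovery time after targeted photobleaching
#'
#' Fluorescence is "detected again" at the first timepoint where the cluster
#' signal exceeds `background + 3 * baseline_sigma`; a series that never
#' crosses the threshold is censored.
#'
#' @param signal per-timepoint cluster photons after the bleach.
#' @param baseline_sigma noise SD of the post-bleach baseline, photons.
#' @param sampling_interval minutes between timepoints.
#' @param times optional explicit times, min (default
#'   `sampling_interval * seq_along(signal)`).
#' @param background residual background level, photons (default 0).
#' @param cell_id,stage optional annotation.
#' @return An object of class `recovery_record`: `recovery_time` (min, NA if
#'   censored), `censored`, `threshold`, `sampling_interval`.
#' @export
frap_recovery_time <- function(signal, baseline_sigma, sampling_interval,
                               times = NULL, background = 0,
                               cell_id = NA, stage = NA) {
  if (length(signal) < 1L) stopf("empty recovery series")
  if (sampling_interval <= 0) stopf("sampling_interval must be > 0")
  times <- times %||% (sampling_interval * seq_along(signal))
  thr <- background + 3 * baseline_sigma
  hit <- which(signal > thr)
  structure(list(
    recovery_time = if (length(hit)) times[hit[1]] else NA_real_,
    censored = length(hit) == 0L, threshold = thr,
    sampling_interval = sampling_interval, cell_id = cell_id, stage = stage),
    class = "recovery_record")
}

#' Pooled mean recovery time across cell-cycle stages
#'
#' Sample-size-weighted mean of stage-wise mean recovery times.
#'
#' @param means stage-wise mean recovery times, min.
#' @param n stage-wise sample sizes (>= 1).
#' @return pooled mean, min.
#' @export
pooled_mean_recovery <- function(means, n) {
  if (length(means) != length(n) || any(n < 1))
    stopf("means and n must match, all n >= 1")
  sum(means * n) / sum(n)
}
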