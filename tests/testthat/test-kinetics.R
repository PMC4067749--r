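test_that("state model validates rates and probabilities", {
  m <- fluorophore_state_model()
  expect_equal(m$k_mat, log(2) / 40, tolerance = 1e-12)  # 40 min half-time
  expect_equal(m$p_pc, 0.9)
  expect_error(fluorophore_state_model(k_mat = -1), "rates")
  expect_error(fluorophore_state_model(p_pc = 1.5), "probabilities")
  expect_error(illumination_schedule(c(10, 0)), "durations")
  expect_error(illumination_schedule(10, "blue"), "unknown channel")
})

test_that("ensemble simulation matches closed-form two-state solutions", {
  n <- 10000
  ## stasis: all rates zero, start green
  m0 <- fluorophore_state_model(k_mat = 0, k_bleach_green = 0, k_dark_on = 0)
  sim0 <- simulate_ensemble(m0, illumination_schedule(20, "green_ex"),
                            500, seed = 1, initial_state = "green")
  expect_true(all(sim0$occupancy[, "green"] == 1))

  sch <- illumination_schedule(80, "green_ex")
  se <- function(p) 3 * sqrt(p * (1 - p) / n)
  ## maturation only: green fraction 1 - exp(-k t); half at 40 min
  mm <- fluorophore_state_model(k_bleach_green = 0, k_dark_on = 0)
  simm <- simulate_ensemble(mm, sch, n, seed = 2)
  i40 <- which.min(abs(simm$times - 40))
  expect_lt(abs(simm$occupancy[i40, "green"] - 0.5), se(0.5))
  ## bleach only
  mb <- fluorophore_state_model(k_mat = 0, k_bleach_green = 0.1,
                                k_dark_on = 0)
  simb <- simulate_ensemble(mb, sch, n, seed = 3, initial_state = "green")
  i10 <- which.min(abs(simb$times - 10))
  expect_lt(abs(simb$occupancy[i10, "green"] - exp(-1)), se(exp(-1)))
  ## dark exchange only: equilibrium k_off/(k_on + k_off)
  md <- fluorophore_state_model(k_mat = 0, k_bleach_green = 0,
                                k_dark_on = 0.3, k_dark_off = 0.6)
  simd <- simulate_ensemble(md, sch, n, seed = 4, initial_state = "green")
  i_end <- length(simd$times)
  expect_lt(abs(simd$occupancy[i_end, "green"] - 2 / 3), se(2 / 3))
})

test_that("405 pulses photoconvert green to red as Bernoulli flips", {
  m <- fluorophore_state_model(k_mat = 0, k_bleach_green = 0, k_dark_on = 0,
                               p_pc = 1)
  sch <- illumination_schedule(10, "none", pulses_405 = 5)
  sim <- simulate_ensemble(m, sch, 400, seed = 5, initial_state = "green")
  before <- max(which(sim$times < 5))
  expect_equal(unname(sim$occupancy[before, "green"]), 1)
  expect_equal(unname(sim$occupancy[length(sim$times), "red"]), 1)
  ## partial conversion probability
  m2 <- fluorophore_state_model(k_mat = 0, k_bleach_green = 0,
                                k_dark_on = 0, p_pc = 0.5)
  sim2 <- simulate_ensemble(m2, sch, 10000, seed = 6,
                            initial_state = "green")
  expect_lt(abs(sim2$occupancy[length(sim2$times), "red"] - 0.5),
            3 * sqrt(0.25 / 10000))
})

test_that("maturation fit recovers (t_half, A) on the closed form", {
  t <- seq(10, 180, 5)
  y <- 1750 * (1 - exp(-log(2) * (t - 10) / 40))
  f <- fit_maturation_halftime(t, y, t_block = 10)
  expect_equal(f$t_half, 40, tolerance = 1e-4)
  expect_equal(f$plateau, 1750, tolerance = 1e-4)
  ## at t - t0 = t_half the curve is at A/2 by definition
  expect_equal(1750 * (1 - exp(-log(2))), 1750 / 2)
  ## empirical plateau rule: mean of points beyond 100 min
  expect_equal(f$plateau_empirical, mean(y[t > 100]))
  expect_warning(fit_maturation_halftime(t[t < 100], y[t < 100],
                                         t_block = 10),
                 "100 min")
  expect_error(fit_maturation_halftime(c(1, 2, 3), c(1, 2, 3)), ">= 5")
})

test_that("maturation fit is unbiased over stochastic replicates", {
  ## 200 replicates at 5% multiplicative noise; median within 3% of truth
  est <- vapply(1:200, function(i) {
    g <- generate_maturation_course(n_cells = 4, seed = 5000 + i)
    fit_maturation_halftime(g$course$t_min, g$course$net_photons,
                            t_block = g$truth$t_block)$t_half
  }, 0)
  expect_lt(abs(median(est) - 40) / 40, 0.03)
})

test_that("pulse-chase classification follows thresholds and controls", {
  expect_equal(classify_pulse_chase(1000, 1000), "retained")
  expect_equal(classify_pulse_chase(1000, 0, second_pc = 900),
               "lost_replaced")
  expect_equal(classify_pulse_chase(1000, 400), "ambiguous")
  expect_equal(classify_pulse_chase(1000, 0, second_pc = 0), "out_of_range")
  expect_error(classify_pulse_chase(NA, 1), "missing pulse")
  ## invariance to global intensity rescaling
  set.seed(7)
  p <- rlnorm(30, log(5000), .4); ch <- p * runif(30, 0, 1.2)
  for (c_mult in c(0.01, 1, 50))
    expect_equal(classify_pulse_chase(p * c_mult, ch * c_mult),
                 classify_pulse_chase(p, ch))
  ## generator panel is classified perfectly at default thresholds
  pan <- generate_pulse_chase_panel(n_cells = 40, seed = 2)
  cls <- classify_pulse_chase(pan$panel$pulse, pan$panel$chase,
                              second_pc = pan$panel$second_pc,
                              bleach_factor = pan$bleach_factor)
  expect_equal(cls, pan$truth$label)
  ## replacement_at_S = FALSE -> everything retained
  pan0 <- generate_pulse_chase_panel(n_cells = 20,
                                     replacement_at_S = FALSE, seed = 3)
  expect_true(all(classify_pulse_chase(pan0$panel$pulse, pan0$panel$chase,
                                       bleach_factor = pan0$bleach_factor)
                  == "retained"))
})

test_that("FRAP recovery detection and pooling behave as specified", {
  ## permanently dark series is censored
  r0 <- frap_recovery_time(rep(0, 10), baseline_sigma = 10,
                           sampling_interval = 1)
  expect_true(r0$censored)
  ## step from 0 to 10x threshold at 5 min with 1-min sampling
  sig <- c(0, 0, 0, 0, 300, 300, 300, 300, 300, 300)
  r1 <- frap_recovery_time(sig, baseline_sigma = 10, sampling_interval = 1)
  expect_equal(r1$recovery_time, 5)
  expect_equal(r1$threshold, 30)
  ## nondecreasing in the detection threshold (censored counts as Inf)
  set.seed(8)
  s <- cumsum(abs(rnorm(30, 25, 10)))
  rts <- vapply(c(5, 20, 50, 120, 1e4), function(bs) {
    r <- frap_recovery_time(s, bs, 1)
    if (r$censored) Inf else r$recovery_time
  }, 0)
  expect_true(all(diff(rts) >= 0))
  expect_equal(rts[5], Inf)
  ## Table-style pooling: weighted mean of stage means
  expect_equal(pooled_mean_recovery(c(5.2, 4.5, 4.9, 4.7, 5.1),
                                    c(9, 4, 7, 13, 9)),
               4.907143, tolerance = 1e-6)
  expect_equal(pooled_mean_recovery(4.2, 9), 4.2)
  expect_equal(pooled_mean_recovery(c(5, 5, 5), c(1, 10, 3)), 5)
})

test_that("synthetic FRAP series yield ~5 min mean detection across 42 cells", {
  g <- generate_frap_course(seed = 7)
  recs <- lapply(g$series, function(s)
    frap_recovery_time(s$net_photons, g$truth$baseline_sigma,
                       g$truth$sampling_interval, times = s$t_min))
  rt <- vapply(recs, `[[`, 0, "recovery_time")
  expect_false(anyNA(rt))
  expect_lt(abs(mean(rt) - 5) / 5, 0.20)
})
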