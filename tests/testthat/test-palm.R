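test_that("assemble_mfm places tiles at their planes and round-trips", {
  geom <- mfm_geometry(tile_shape = c(8, 8))
  ## single bright pixel in tile 5 (grid row 2, col 2) -> plane 5
  frame <- matrix(0, 24, 24)
  frame[8 + 3, 8 + 5] <- 9
  st <- assemble_mfm(frame, geom)
  expect_equal(dim(st), c(8, 8, 9))
  expect_equal(st[3, 5, 5], 9)
  expect_equal(sum(st), 9)
  ## Z extent of a 9-plane stack at 380 nm spacing
  expect_equal((geom$n_planes - 1) * geom$plane_spacing, 3040)
  ## round trip with known shifts (<= 3 px) and transmissions
  truth <- array(0, c(16, 16, 9))
  for (z in 1:9)
    truth[, , z] <- gaussian_spot_frame(c(16, 16), 7.3, 8.1, 5, 1000) *
      exp(-(z - 5)^2 / 6)
  interior <- 5:12
  rms_vs_truth <- function(g2) {
    back <- assemble_mfm(mfm_project(truth, g2), g2)
    sqrt(mean((back[interior, interior, ] -
                 truth[interior, interior, ])^2))
  }
  ## integer shifts: resampling is exact -> RMS < 1% of peak
  set.seed(10)
  g_int <- mfm_geometry(tile_shape = c(16, 16),
                        transforms = lapply(1:9, function(i)
                          list(dx = sample(-3:3, 1), dy = sample(-3:3, 1),
                               scale = 1)),
                        transmission = runif(9, 0.7, 1.3))
  expect_lt(rms_vs_truth(g_int), 0.01 * max(truth))
  ## sub-pixel shifts: two bilinear passes -> interpolation-limited
  g_frac <- mfm_geometry(tile_shape = c(16, 16),
                         transforms = lapply(1:9, function(i)
                           list(dx = runif(1, -3, 3), dy = runif(1, -3, 3),
                                scale = 1)),
                         transmission = runif(9, 0.7, 1.3))
  expect_lt(rms_vs_truth(g_frac), 0.05 * max(truth))
  ## layout exceeding the frame errors
  expect_error(assemble_mfm(matrix(0, 10, 10), geom), "exceeds")
})

test_that("detect_localizations finds sparse emitters with stated precision", {
  geom <- mfm_geometry(tile_shape = c(24, 24))
  expect_equal(nrow(detect_localizations(array(0, c(24, 24, 9)), geom)), 0)
  sig <- 95.5 / 120
  mk_stack <- function(x0, y0, z0, amp, seed) {
    set.seed(seed)
    st <- array(rnorm(24 * 24 * 9, 10, 1), c(24, 24, 9))
    for (z in 1:9) {
      w <- exp(-((z - 1) - z0)^2 / 2)
      st[, , z] <- st[, , z] +
        amp * w * gaussian_spot_frame(c(24, 24), x0, y0,
                                      2.355 * sig, 2 * pi * sig^2)
    }
    st
  }
  ## Monte Carlo: lateral error < 3x reported precision in >= 95% of runs
  hits <- vapply(1:100, function(i) {
    x0 <- 10 + runif(1); y0 <- 12 + runif(1)
    loc <- detect_localizations(mk_stack(x0, y0, 4.2, 40, i), geom)
    if (nrow(loc) != 1) return(FALSE)
    err <- sqrt((loc$x_nm - x0 * 120)^2 + (loc$y_nm - y0 * 120)^2)
    err < 3 * loc$sigma_xy_nm
  }, TRUE)
  expect_gte(mean(hits), 0.95)
  ## two resolvable emitters with overlapping 7x7 windows: both rejected
  ## (pairs below ~1 px separation merge into a single candidate instead)
  st2 <- mk_stack(9, 12, 4, 40, 1) + mk_stack(13, 12, 4, 40, 2) - 10
  expect_equal(nrow(detect_localizations(st2, geom)), 0)
})

test_that("group_events implements consecutive-frame linking", {
  ## n well-separated single-frame localizations -> n events
  single <- data.frame(frame = rep(3L, 4), x_nm = c(0, 500, 1000, 1500),
                       y_nm = 0)
  expect_equal(nrow(group_events(single)), 4)
  ## same position frames 3,4,5 -> one event of 3 frames
  run3 <- data.frame(frame = c(3L, 4L, 5L), x_nm = c(0, 5, -4), y_nm = 0)
  ev <- group_events(run3)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$n_frames, 3)
  expect_equal(ev$start_frame, 3)
  ## frames 1 and 5 with max_gap 0 -> two events
  gap <- data.frame(frame = c(1L, 5L), x_nm = c(0, 0), y_nm = 0)
  expect_equal(nrow(group_events(gap)), 2)
  expect_equal(nrow(group_events(gap, max_gap = 3)), 1)
  ## precision-weighted mean position
  wtd <- data.frame(frame = 1:2, x_nm = c(0, 30), y_nm = 0,
                    sigma_xy_nm = c(10, 20))
  expect_equal(group_events(wtd)$x_nm, 30 * (1 / 400) / (1 / 100 + 1 / 400))
})

test_that("grouping matches the connected-components oracle on movies", {
  for (seed in 1:4) {
    mv <- generate_palm_movie(
      clusters = list(list(center = c(0, 0, 0), n_fluorophores = 15,
                           shape = "sphere", diameter = 400)),
      activation = "sequential", fiducials = NULL, seed = seed)
    locs <- mv$locs
    expect_lte(nrow(locs), 200)
    got <- nrow(group_events(locs, link_radius = 150))
    expect_equal(got, oracle_group_count(locs, link_radius = 150))
    expect_equal(got, 15)   # sequential activation guarantees exactness
  }
})

test_that("drift correction recovers fiducial and cluster positions", {
  ## static fiducials: output equals input
  mv0 <- generate_palm_movie(drift = NULL, seed = 2)
  c0 <- drift_correct(mv0$locs[!mv0$locs$is_fiducial, ],
                      mv0$locs[mv0$locs$is_fiducial, ])
  expect_lt(max(abs(c0$x_nm - mv0$locs$x_nm[!mv0$locs$is_fiducial])), 15)
  ## linear drift (100, -50, 200) nm: post-correction fiducial RMS < 5 nm
  mv <- generate_palm_movie(drift = c(100, -50, 200), seed = 3)
  fid <- mv$locs[mv$locs$is_fiducial, ]
  fid_corr <- drift_correct(fid, fid)
  for (f_id in unique(round(fid_corr$x_nm / 1000))) {
    sel <- round(fid_corr$x_nm / 1000) == f_id
    rms <- sqrt(mean((fid_corr$x_nm[sel] - mean(fid_corr$x_nm[sel]))^2 +
                       (fid_corr$y_nm[sel] - mean(fid_corr$y_nm[sel]))^2 +
                       (fid_corr$z_nm[sel] - mean(fid_corr$z_nm[sel]))^2))
    expect_lt(rms, 5)
  }
  ## cluster localizations match undrifted truth within precision
  samp <- drift_correct(mv$locs[!mv$locs$is_fiducial, ], fid)
  truth_pos <- mv$truth$fluorophores
  ids <- mv$truth$per_localization$fluorophore[!mv$locs$is_fiducial]
  resid <- samp$x_nm - truth_pos$x[match(ids, truth_pos$fluorophore)]
  expect_lt(abs(mean(resid)), 10)
  expect_lt(sd(resid), 30)        # ~20 nm noise + drift residue
  ## two fiducials with equal and opposite jitter -> zero drift trace
  ja <- data.frame(frame = rep(0:9, 2),
                   x_nm = c(rep(0, 10) + sin(1:10), rep(5000, 10) - sin(1:10)),
                   y_nm = 0, z_nm = 0,
                   is_fiducial = TRUE)
  pt <- data.frame(frame = 0:9, x_nm = 100, y_nm = 100, z_nm = 100)
  corr <- drift_correct(pt, ja)
  expect_lt(max(abs(attr(corr, "drift")$dx)), 1e-9)
  expect_equal(corr$x_nm, rep(100, 10))
  expect_error(drift_correct(pt, ja[0, ]), "fiducial")
})

test_that("cluster geometry matches order-statistics and moment truths", {
  expect_error(cluster_geometry(matrix(0, 3, 3)), ">= 4 points")
  set.seed(31)
  ## uniform 450 nm sphere: enclosing diameter ~ 450 * 0.9^(1/3) = 434.3
  pts <- cenquant:::sample_in_shape(4000, "sphere", diameter = 450)
  g <- cluster_geometry(pts)
  expect_equal(g$enclosing_diameter, 450 * 0.9^(1 / 3), tolerance = 0.02)
  ## moment estimator recovers the full diameter on both axis kinds
  expect_equal(g$equatorial_diameter, 450, tolerance = 0.03)
  expect_equal(g$polar_distance, 450, tolerance = 0.03)
  ## with q = 0.965 the enclosing sphere is within 5% of the true diameter
  g965 <- cluster_geometry(pts, majority_fraction = 0.965)
  expect_lt(abs(g965$enclosing_diameter - 450) / 450, 0.05)
  ## consistency: at n = 10^4 the diameter estimate is within 1% of truth
  set.seed(32)
  big <- cenquant:::sample_in_shape(10000, "sphere", diameter = 450)
  gb <- cluster_geometry(big)
  expect_lt(abs(gb$enclosing_diameter - 450 * 0.9^(1 / 3)) /
              (450 * 0.9^(1 / 3)), 0.01)
  ## anaphase-scale ellipsoid with anisotropic noise at n = 24: averaged
  ## over replicate draws the equatorial axis is recovered within 15%; the
  ## single-cluster polar axis is small-sample-bias-limited (~20% low), so
  ## only the pooled multi-cluster route (see pipeline/acceptance tests)
  ## reaches 15% on the polar axis
  set.seed(3)
  r24 <- t(vapply(1:40, function(i) {
    p <- cenquant:::sample_in_shape(24, "ellipsoid",
                                    axes = c(350, 350, 200)) +
      cbind(rnorm(24, 0, 20), rnorm(24, 0, 20), rnorm(24, 0, 50))
    g <- cluster_geometry(p, precision = c(20, 20, 50))
    c(g$equatorial_diameter, g$polar_distance)
  }, c(0, 0)))
  expect_lt(abs(mean(r24[, 1]) - 350) / 350, 0.15)
  expect_lt(abs(mean(r24[, 2]) - 200) / 200, 0.30)
  ## degenerate (coplanar) input flagged, sphere metrics still returned
  flat_pts <- cbind(rnorm(20), rnorm(20), 0)
  gf <- cluster_geometry(flat_pts)
  expect_true(gf$degenerate)
  expect_true(is.finite(gf$enclosing_diameter))
})

test_that("compile_clusters aligns and pools; separate_clusters splits", {
  set.seed(41)
  base <- cenquant:::sample_in_shape(30, "sphere", diameter = 400)
  shifted <- sweep(base, 2, c(5000, -2000, 300), "+")
  pooled <- compile_clusters(list(base, shifted), "G1")
  expect_equal(nrow(pooled), 60)
  ## identical clusters at different positions overlay exactly
  cen <- sweep(base, 2, colMeans(base))
  expect_equal(pooled[1:30, ], cen, ignore_attr = TRUE)
  expect_equal(pooled[31:60, ], cen, ignore_attr = TRUE)
  expect_error(compile_clusters(list(base)), ">= 2")
  ## anaphase mode aligns randomly oriented ellipsoids
  set.seed(42)
  ell <- lapply(1:10, function(i)
    cenquant:::sample_in_shape(150, "ellipsoid",
                               axes = c(350, 350, 200)) %*%
      cenquant:::random_rotation3())
  pooled_e <- compile_clusters(ell, "anaphase")
  ge <- cluster_geometry(pooled_e)
  expect_lt(abs(ge$polar_distance - 200) / 200, 0.10)
  expect_lt(abs(ge$equatorial_diameter - 350) / 350, 0.10)
  ## two-cluster cells split when separation is clear
  two <- rbind(base, shifted)
  parts <- separate_clusters(two)
  expect_equal(length(parts), 2)
  expect_equal(sort(vapply(parts, nrow, 0L)), c(30, 30))
  expect_equal(length(separate_clusters(base)), 1)
})

test_that("volume ratio and Airy FWHM follow their closed forms", {
  sph <- list(volume = 4 / 3 * pi * 225^3)
  ell <- list(volume = 4 / 3 * pi * 175^2 * 100)
  expect_equal(volume_ratio(sph, ell), 450^3 / (350 * 350 * 200))
  expect_equal(volume_ratio(sph, ell), 3.719, tolerance = 1e-3)
  expect_equal(volume_ratio(sph, sph), 1)
  dbl <- list(volume = 8 * sph$volume)
  expect_equal(volume_ratio(dbl, ell), 8 * volume_ratio(sph, ell))
  expect_error(volume_ratio(sph, list(volume = 0)), "positive")
  expect_equal(airy_fwhm(593, 1.35), 224.04, tolerance = 1e-4)
  expect_equal(airy_fwhm(2 * 593, 1.35), 2 * airy_fwhm(593, 1.35))
  expect_equal(airy_fwhm(225 / 0.51, 1), 225)
})
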