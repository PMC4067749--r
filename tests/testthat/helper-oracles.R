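## Independent oracles used across the suite.  These deliberately use
## brute-force implementations, not the package's code paths.

## Dense 2D convolution with the dilated separable B3 kernel and mirror
## boundary, via explicit loops.
oracle_b3_smooth <- function(img, step) {
  w <- c(1, 4, 6, 4, 1) / 16
  off <- c(-2, -1, 0, 1, 2) * step
  refl <- function(i, n) {
    p <- 2 * n - 2
    j <- (i - 1) %% p
    if (j < 0) j <- j + p
    if (j >= n) j <- p - j
    j + 1
  }
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    acc <- 0
    for (a in 1:5) for (b in 1:5) {
      acc <- acc + w[a] * w[b] *
        img[refl(r + off[a], nr), refl(cc + off[b], nc)]
    }
    out[r, cc] <- acc
  }
  out
}

## Connected-components event grouping: nodes are localizations, edges
## connect pairs in consecutive frames (gap <= max_gap) within link_radius
## laterally.
oracle_group_count <- function(locs, link_radius = 60, max_gap = 0) {
  n <- nrow(locs)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    df <- abs(locs$frame[i] - locs$frame[j])
    if (df < 1 || df > 1 + max_gap) next
    d <- sqrt((locs$x_nm[i] - locs$x_nm[j])^2 +
                (locs$y_nm[i] - locs$y_nm[j])^2)
    if (d <= link_radius) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  length(unique(vapply(seq_len(n), find, 0L)))
}

## Sorted-array five-number summary with type-7 interpolation.
oracle_five_number <- function(x) {
  s <- sort(x); n <- length(s)
  at <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
  }
  c(min = s[1], q1 = at(.25), median = at(.5), q3 = at(.75), max = s[n])
}

## Deterministic pixel-integrated Gaussian test frame (photon units).
gaussian_spot_frame <- function(shape, x0, y0, fwhm_px, total) {
  sig <- fwhm_px / (2 * sqrt(2 * log(2)))
  px <- diff(pnorm(seq(-0.5, shape[2] - 0.5), x0, sig))
  py <- diff(pnorm(seq(-0.5, shape[1] - 0.5), y0, sig))
  total * outer(py, px)
}

## identity-conversion camera so matrices in photon units can be fed to
## aperture_photometry directly
cam_identity <- function() camera_model(conversion_gain = 1)
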