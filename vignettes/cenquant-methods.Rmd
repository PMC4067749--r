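---
title: "Models and methods behind cenquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cenquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cenquant)
```

This vignette explains the models the package implements, the parameters
that matter, what the synthetic generator does and does not emulate, and
the numerical choices made where the design was genuinely open. It states
no empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. Camera model and photon calibration

An EMCCD at fixed EM gain is summarized by four constants: the
input-referred conversion gain $g$ (photoelectrons per ADU; default
0.044), readout noise (0.470 e$^-$ RMS), thermal current (0.014 e$^-$/px/s)
and the EM multiplication factor (50). Calibration maps raw counts to
floating-point ADU:

$$\mathrm{cal} = \frac{\mathrm{raw} - \mathrm{bias} - D\,t/g}{\mathrm{flat}},$$

after which background-corrected sums convert to photoelectrons as
$N = g \cdot \mathrm{net\ ADU}$. Two choices here:

* **Flat fields are renormalized to mean 1 on load**, so flat-fielding is
  photometrically neutral — it redistributes sensitivity without changing
  the mean photon scale.
* **Thermal correction defaults to the scalar expectation** $D\,t/g$ in
  ADU; a measured dark frame (ADU/s), when supplied, overrides the scalar
  model. The published description of the instrument does not say which
  was used; both are supported.

Because the EM register multiplies each photoelectron through a cascade
well modeled as a gamma distribution with shape $n$ and scale equal to the
EM gain, the variance of a calibrated flat region is
$\approx 2\mu + \sigma_r^2$ photoelectrons$^2$ — the excess noise factor
of 2 that makes EMCCD error bars twice the naive shot-noise value. The
synthetic generator reproduces exactly this chain (Poisson → gamma →
Gaussian read noise → quantization), and a property test checks the
variance relation on $10^5$ pixels.

## 2. Wavelet separation and what a "spot image" measures

The *à trous* transform convolves repeatedly with the separable B3-spline
kernel $(1,4,6,4,1)/16$, doubling the tap spacing at each level; detail
scale $k$ is the difference of successive smooths and the residual is the
last smooth. Reconstruction is exact by construction and tested at
$10^{-5}$ relative error. Boundaries are mirror-padded; coefficients are
never thresholded (detection thresholds live in the photometry layer);
decomposition is 2D per Z-slice.

Two quantitative facts, computed from the decomposition itself and frozen
into tests, matter for interpretation:

* The max-energy scale for Gaussian spots of FWHM 1, 2, 4, 8 px is
  1, 1, 2, 4 — nondecreasing, and within scales 1–3 for anything up to
  4 px FWHM. Summing scales 1+2+3 therefore keeps diffraction-scale
  objects and rejects structures much larger.
* Because detail scales are zero-mean, the scales-1–3 spot image retains a
  *fixed fraction* (~84%, stable across spot FWHM 1.5–4 px) of a spot's
  flux inside the standard aperture. Absolute photon quotes must therefore
  come from raw-frame annulus photometry; wavelet-filtered photometry is
  used where a bright diffuse background would otherwise bias the annulus,
  and its capture fraction cancels in any ratio of identically measured
  quantities — which is exactly how the counting calibration uses it. A
  test demonstrates the regime: a nuclear-scale blob (FWHM 20 px, 40×
  the spot flux) biases raw photometry by >10% while capture-normalized
  wavelet photometry stays within 5%.

## 3. Aperture photometry conventions

Pixels belong to the aperture or annulus when their *centers* do: the
measurement is deterministic and matches integer-aperture photometry
practice; the 4× area ratio of the published geometry is stated in
continuous terms (65/16 = 4.0625). The background estimator defaults to
the median (robust against neighboring spots); the original software's
estimator is unspecified. For Z-stacks the measurement is taken on the
slice maximizing the aperture sum — the in-focus plane — rather than on a
projection. Quartile summaries use linear interpolation between order
statistics (inclusive scheme). Cell-cycle stage is user-supplied metadata,
never inferred from images.

## 4. Molecule counting

Calibration regresses each standard's **median** photon rate through the
origin against its maximum fluorophore load (operators × 2 for a
homodimeric repressor); medians resist occupancy outliers and match how
grouped intensities are reported. Full operator occupancy is assumed — the
known bias direction: partial occupancy in the standards would inflate
cluster counts. The 112× array is supported as an optional standard but
excluded from the default calibration, mirroring its absence from the
published comparison. Telophase is the canonical counting stage: 16
clustered centromeres and fully matured fluorophores. Counting is
scale-free: multiplying all rates by any constant leaves counts unchanged
(tested).

## 5. Fluorophore photophysics and kinetics

The state model has six states — immature, green, green-dark, red,
red-dark, bleached — with maturation `k_mat = ln2/40` per minute (the
measured ~40 min half-time at 25°C), photoconversion as a Bernoulli flip
per 405 nm pulse (p = 0.9), and illumination-gated bleaching/dark-state
entry. **All kinetics times are minutes**; the experiments (maturation,
pulse-chase, recovery) live on that scale, so one unit is used
throughout. Dark-state and bleaching rates have no measured values in
this system; the defaults are order-of-magnitude placeholders for
simulation only and are flagged as such.

* **Maturation fitting** uses a single exponential from a fixed
  deposition/block time. The apparent tension between a ~40 min half-time
  and a plateau reached by ~70 min (a pure exponential is only at 70% after
  70 min) is resolved by *reporting both* the fitted asymptote and the
  empirical plateau (mean of points beyond 100 min — the published
  normalization rule), not by adding states.
* **Pulse-chase classification** uses retention/loss thresholds of
  0.5/0.25 on the bleach-corrected chase:pulse ratio. These are not
  published values; they were chosen once to bisect the strongly bimodal
  distribution (retained clusters keep ~80% of signal, replaced ones
  ~zero) and are exposed as parameters. Whether the original analysis
  corrected for imaging bleaching is unstated, so the correction factor is
  an explicit argument. A second-photoconversion control below detection
  flags a cluster out-of-range and excludes it.
* **Recovery detection** uses threshold = background + 3σ, the standard
  reading of "fluorescence is detected again"; recovery time is the first
  sampled time above threshold, censored if never reached, and is
  provably nondecreasing in the threshold (tested).

## 6. The synthetic world

The generator is the package's stated world; its defaults are the
conditions the measurements describe, chosen once:

| Parameter | Default | Basis |
| --- | --- | --- |
| PSF | Gaussian, FWHM 225 nm | measured Airy FWHM; Gaussian is the standard approximation |
| pixel / Z-step (wide-field) | 107 / 333 nm | instrument geometry |
| MFM voxel | 120 × 120 × 380 nm, 9 planes | instrument geometry |
| cluster photon scales | 1 750, 7 500, 11 000 photons | printed measurement scales |
| per-fluorophore rate | 45 photons/s | ~36-GFP cluster ≈ 1 500 photons/s |
| localization precision | 20/20/50 nm (x/y/z) | quoted accuracies |
| free:bound chaperone pool | 4 | printed nuclear excess |
| FRAP: exchange 15 min, baseline σ 700, prebleach 10 000 | — | calibrated once so threshold crossing lands at ~4.5 min, per the stated ~5 min detection scale |
| event on-time | geometric, mean 2 frames | no published value; flagged |
| per-event photon budget | 1 000 | no published value; flagged |

What it does **not** emulate: real cell-shape variability (nuclei are
disks, cytoplasm ellipses), chromatic/spatial PSF aberrations, clock-induced
charge, out-of-focus structure in Z, stage-dependent expression noise, or
fixation artifacts. A green test therefore establishes that the *analysis
chain* is unbiased under the stated noise model at the stated scales — not
that it is robust to every pathology of real data. Pulse-chase panels are
generated at the measurement level (per-cell photometry values), since the
classifier consumes measurements; rendering is exercised by the
photometry/counting scenes.

Every generator is a pure function of (parameters, seed): reruns are
byte-identical, and every output carries its ground truth.

## 7. PALM processing choices

* **Grouping** links localizations in consecutive frames within
  `link_radius` (default 60 nm = 3× lateral precision) by greedy nearest
  neighbor; `max_gap = 0`, so a re-activation after a dark gap counts as a
  new event — matching the published caveat that dark-state returns may
  cause multiple detections of one fluorophore. Note that the displacement
  between two localizations of the *same* fluorophore has SD
  $\sqrt2 \times 20$ nm per axis, so at 60 nm ~10% of true links break;
  exact event-count recovery on sequentially activated movies therefore
  uses a 150 nm radius, which is safe whenever events are temporally
  exclusive and clusters are micrometres apart.
* **Drift correction** subtracts the per-frame mean displacement of each
  fiducial from its own first-frame position, interpolating frames without
  fiducial fits. Residual fiducial RMS < 5 nm under smooth ≤ 500 nm drift
  is a tested property.
* **Geometry.** The enclosing diameter is twice the `majority_fraction`
  (default 0.9) quantile of radial distances — the sphere "containing the
  majority" of events; for a uniform sphere this estimates
  $0.9^{1/3} \approx 0.97$ of the true diameter. Ellipsoid axes use a
  uniform-ellipsoid moment estimator (semi-axis $= \sqrt5 \times$ SD)
  after subtracting the known localization-noise covariance from the
  sample covariance *before* eigendecomposition. Two facts force this
  design: (i) a per-axis quantile of |projection| underestimates a uniform
  ellipsoid axis by ~27% at q = 0.9; (ii) with 50 nm axial noise against a
  100 nm polar semi-axis, an uncorrected estimator overestimates the polar
  axis by ~50%, and because the noise is anisotropic the *raw* PCA minor
  axis tracks the minimum of signal-plus-noise — deconvolution must
  precede the eigendecomposition, and pooled estimation must use the
  noise covariance rotated into each cluster's aligned frame
  (`compile_clusters` propagates it). Grouped events average
  `n_frames` localizations, so pipelines shrink the noise covariance by
  the mean of `1/n_frames`.
* **Small-sample limits.** The smallest eigenvalue of a 3-D sample
  covariance at n ≈ 24 is biased low by ~20–25%; a single cluster's polar
  axis is therefore bias-limited, while pooling ten aligned clusters
  (the published compilation approach) recovers both axes within 15% —
  the regime the acceptance suite tests. Degenerate (coplanar) point sets
  are flagged and reported with sphere metrics only. Two-cluster cells are
  split by 2-means, accepted only when the centroid separation exceeds
  both apparent diameters.
* **MFM assembly** restricts tile registration to translation + isotropic
  scale by default (full affine is out of scope); with integer shifts
  resampling is exact, with sub-pixel shifts the generator→assembly round
  trip carries two bilinear interpolations and is interpolation-limited.

## 8. Known limitations

* Absolute wavelet-photometry values require the capture-fraction
  normalization described in §2; only ratios are calibration-free.
* The counting calibration inherits the full-occupancy assumption and the
  equal-maturation assumption between standards and clusters; immature
  fractions are modeled in the kinetics module, not corrected here.
* Sub-pixel emitter pairs (≲1 px apart) merge into a single localization
  candidate; the overlap-rejection rule operates on resolvable candidates.
* Text-based stack I/O replaces TIFF (no TIFF reader in the supported
  dependency set); the format is lossless but not interoperable with
  imaging software without conversion.
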