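# cenquant

Quantitative fluorescence-microscopy analysis of budding-yeast centromere
clusters, for cell biologists counting molecules and measuring dynamics at
the diffraction limit. The 16 yeast centromeres cluster into a single
diffraction-scale focus; `cenquant` implements the full measurement chain
with which the copy number, turnover and 3D geometry of centromeric
proteins (a CENP-A histone variant and its chaperone) can be established
from calibrated images — together with a synthetic-microscopy generator
that produces every input with known ground truth, so the whole chain is
testable end to end.

## What it computes

- **Photon-calibrated photometry.** Raw EMCCD frames are calibrated as
  `(ADU − bias − dark·t/g)/flat` and background-corrected aperture sums are
  converted to photoelectrons with the conversion gain *g* (defaults:
  0.044 e⁻/ADU at EM gain 50, readout 0.470 e⁻ RMS, dark 0.014 e⁻/s).
  Apertures follow astronomy practice: radius 4 px (428 nm at 107 nm/px)
  with a 5 px annulus whose area is (9²−4²)/4² ≈ 4× the aperture.
- **À trous wavelet separation.** The stationary B3-spline wavelet
  transform splits each frame into detail scales (scale *k* holds
  structures of FWHM ≈ 2^(k−1) px) plus a smooth residual, with exact
  reconstruction; summing scales 1–3 isolates spots up to ~4 px FWHM from
  diffuse nuclear fluorescence before photometry.
- **Molecule counting.** Cluster photon rates are converted to molecule
  numbers by regression through the origin against tetO/TetR-GFP
  calibration standards (a 14× array binds ≤ 2×14 = 28 GFPs, a 21× array
  ≤ 42, since TetR is a homodimer): `molecules = rate / slope`.
- **Fluorophore kinetics.** A six-state photophysics model of a
  photoconvertible tandem-dimer fluorophore (immature → green → red, with
  reversible dark states and bleaching) is simulated as a continuous-time
  Markov ensemble; maturation half-time is fit as
  `I(t) = A(1 − e^{−ln2·(t−t₀)/t½})`; pulse-chase panels are classified
  retained / lost-replaced; targeted-photobleaching recovery times are
  detected at background + 3σ and pooled across cell-cycle stages.
- **MFM-PALM 3D geometry.** Multifocal-plane frames (9 planes, 380 nm
  apart, 120 nm pixels) are assembled into stacks; single-molecule events
  are detected, grouped across consecutive frames, drift-corrected against
  gold-nanorod fiducials, and summarized as enclosing-sphere/ellipsoid
  cluster geometry with localization-noise deconvolution
  (volume = 4/3·π·a²·c).

## Worked example

```r
library(cenquant)

cam <- camera_model()                 # 0.044 e-/ADU, EM gain 50
spec <- scene_spec(shape = c(48, 48),
                   clusters = list(list(center = c(24, 24),
                                        n_emitters = 1, rate = 1500)),
                   exposure = 5, seed = 2)
cal <- calibrate_stack(render_frame(spec), cam)
aperture_photometry(cal, c(24, 24), aperture_policy(), cam)
#> cluster at (24.0, 24.0, z=0): 7527 photons (1505 photons/s), bg -0.09 ADU/px
```

A 1500 photons/s emitter imaged for 5 s is recovered at 7527 photons —
within shot noise of the expected 7500. The end-to-end counting pipeline
(tetO titration standards + telophase clusters carrying 2×16 fluorophores):

```r
run_counting(list(seed = 1))
#> slope: 37.97 photons/fluorophore/s
#> median molecules: 31.3   (1.96 per centromere)
#> five-number summary: 29.3 / 30.5 / 31.3 / 32.2 / 33.9  (n = 50)
```

The median count lands within 3% of the true 32 molecules — two per
centromere. Kinetics and compaction reports, same interface:

```r
run_kinetics(list(seed = 1))    # t_half 39.4 min, FRAP pooled mean 4.5 min
run_compaction(list(seed = 1))  # G1 sphere 453 nm; anaphase 346 x 184 nm
                                # volume ratio 3.45 (>= 3-fold compaction)
```

A command-line wrapper for calibration, wavelet filtering, photometry and
the pipelines is installed at `inst/cli/cenquant`
(`Rscript <lib>/cenquant/cli/cenquant photometry --in cal.txt --out m.csv`).

## Layout

| Path | Contents |
| --- | --- |
| `R/camera.R` | camera model, calibration, ADU→photoelectrons |
| `R/wavelet.R` | à trous decomposition, spot-image extraction |
| `R/photometry.R` | detection, aperture photometry, summaries |
| `R/counting.R` | tetO standards, calibration fit, count estimates |
| `R/kinetics.R` | state model, ensemble simulation, maturation/FRAP/pulse-chase |
| `R/palm-process.R`, `R/palm-geometry.R` | MFM assembly, localization, grouping, drift, 3D geometry |
| `R/synthetic*.R` | ground-truth generators for every input |
| `R/pipeline.R`, `R/cli.R`, `R/io.R` | end-to-end runs, CLI, plain-text I/O |
| `vignettes/cenquant-methods.Rmd` | models, assumptions, design choices |
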