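---
title: "Methods: label-free IR tissue classification in mirtissue"
author: "mirtissue authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: label-free IR tissue classification in mirtissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mirtissue` classifies colorectal tissue in quantum-cascade-laser (QCL)
mid-infrared hyperspectral images without staining. This vignette is the
package's account of the science behind each stage: the models and their
assumptions, the parameters that matter, the numerical choices, and what
validation on synthetic phantoms does and does not demonstrate.

## Data model

A measurement is an H × W × B absorbance cube (`HyperCube`): every pixel
carries a spectrum on a shared uniform wavenumber grid (`SpectralAxis`),
stored descending from 1800 to 948 cm⁻¹ at 2 cm⁻¹ spacing in the
acquisition configuration the package targets. Cubes are exchanged as ENVI
header/raster pairs (written canonically as band-sequential float32,
little-endian; other interleaves are accepted on read). Label maps
(`LabelMap`) are integer rasters with fixed index-color palettes; code 0 is
background and always renders black.

## Quality control

Tissue sections contain folds, cracks, detached regions and debris whose
spectra would poison both training and classification. `qualityFilter`
retains a pixel iff

* the trapezoidal integral of absorbance over the amide I window
  (default 1700–1600 cm⁻¹) lies within `[amideIntegralMin,
  amideIntegralMax]` (defaults 1 and 120 absorbance·cm⁻¹) — below is
  `low-signal` (empty slide, lumen mucus washed away), above is
  `saturated` (folds, thick debris, blood); and
* the signal-to-noise ratio — the amide I peak divided by the standard
  deviation of the linearly detrended signal in a signal-free window at the
  high-energy edge (default 1800–1760 cm⁻¹, where the laser modules carry
  little tissue information) — is at least `snrMin` (default 5).

The integral bounds and SNR floor are not universal constants: they were
calibrated once on the phantom band library so that clean tissue (including
the weak lumen signal) passes while zero and high-baseline debris spectra
fail, and they are all exposed in `qcParams()` for real data.

## Resonant-Mie EMSC correction

Cell-sized structures scatter mid-IR light resonantly and superimpose
broad oscillatory distortions on absorbance spectra, strongest at sample
edges. The package removes them by extended multiplicative signal
correction (EMSC): each spectrum is decomposed by ordinary least squares as

$$A(\tilde\nu) = c\,m(\tilde\nu) + a + b\tilde\nu +
  \sum_{k=1}^{K} g_k p_k(\tilde\nu) + \varepsilon,$$

and corrected to $(A - a - b\tilde\nu - \sum_k g_k p_k)/c$. The interferent
subspace $p_1 \dots p_K$ consists of the first K principal components of a
family of van de Hulst extinction curves
$Q(\rho) = 2 - (4/\rho)\sin\rho + (4/\rho^2)(1-\cos\rho)$,
$\rho = 2\pi d (n-1)\tilde\nu$, evaluated over a grid of sphere diameters
d (10 steps in 2–20 µm) and refractive indices n (9 steps in 1.1–1.5).
Because ρ depends on d and n only through the product d(n−1), the family is
effectively a one-parameter curve set and K = 6 components capture
essentially all of its variance; the basis-building test verifies ≥ 95%
against a full-rank SVD oracle.

Design choices worth spelling out:

* **Baseline order.** Constant plus linear only. Higher polynomial orders
  start absorbing genuine band structure; the Mie components already model
  the smooth curvature that matters.
* **Reference spectrum.** The mean of the QC-retained spectra of the cube
  being corrected. A per-cube reference avoids shipping a measured
  substrate spectrum and adapts to the tissue at hand. Its known weakness
  is that an in-cube mean is itself scatter-contaminated — and EMSC
  preserves whatever is in the reference. The package therefore
  orthogonalizes the reference against the span of `[1, ν̃, p₁…p₆]` before
  fitting ("reference purge"). Without the purge the mean distortion of
  the cube survives correction essentially unattenuated; with it, the
  residual distortion on phantom/twin pairs drops by many orders of
  magnitude (the acceptance run reports the measured median).
* **One iteration.** `mieCorrectCube(iterations = 1)` is the default;
  with `iterations > 1` the reference is recomputed from corrected
  spectra and the fit repeated. For the distortion family modeled here one
  pass suffices, and the tests assert only that both settings reduce
  distortion rather than ranking them.
* **Degenerate pixels.** A fit with |c| < `cMin` (default 0.1) would blow
  up under division; such pixels are not corrected but routed to
  background by updating the QC mask (`mieCorrectCube` returns the cube
  *and* the updated mask for exactly this reason).
* **Correction window.** The full loaded axis (1800–948 cm⁻¹): scatter
  correction precedes fingerprint cropping, so the amide I region
  anchors the fit even though classification later discards nothing below
  998 cm⁻¹.

How correction quality is measured deserves a note. The package's efficacy
metric compares a corrected distorted cube against its *identically
corrected* clean twin, not against the raw twin. EMSC correction always
normalizes amplitude and removes baseline; comparing against the raw twin
would conflate that (shared, harmless) transform with the distortion
removal one actually wants to measure. On phantom twins the only difference
between the two inputs is the injected distortion, so the twin-corrected
residual isolates exactly the distortion that survives.

### Numerical details

* `vdhExtinction` switches to the Taylor series
  $\rho^2/2 - \rho^4/36 + \rho^6/1440$ for ρ < 10⁻², because the closed
  form loses ~4·10⁻⁸ absolute accuracy near ρ = 10⁻⁴ through cancellation
  in $(4/\rho^2)(1-\cos\rho)$.
* The EMSC design is solved by QR decomposition; a rank-deficient design
  names its collinear columns in the error. The self-fit identities
  (c = 1, a = b = gₖ = 0 for the reference itself) hold to 10⁻⁸ and
  correct-then-fit is the identity to 10⁻⁶; the fitter is checked against
  a brute-force normal-equations oracle on 100 random designs.

## Second derivatives, cropping, downsampling

Database curation clusters 9-point Savitzky-Golay second-derivative
spectra (polynomial order 3 — the conventional pairing with a 9-point
window — derivative order 2, scaled by 1/spacing²). Interior points are
exact for any cubic; edges use the one-sided polynomial fits. The operator
is linear and is applied as a single matrix product per cube. One accuracy
caveat: for a Gaussian band the 9-point smoothed second derivative at the
band center carries a bias that scales like the squared ratio of window to
band width — about 2% at a FWHM of 40 grid steps, but ~20% at 10 steps.
Clustering is unaffected (all spectra share the bias); absolute curvature
readings from narrow bands are not to be trusted.

Classification uses the unsmoothed Mie-corrected spectra on the
1760–998 cm⁻¹ fingerprint grid (382 channels at 2 cm⁻¹) — both forest
levels see the identical vector. Clustering defaults to the slightly
narrower 1750–1000 cm⁻¹ window (`clusterRange`), reflecting the lower
laser energy at the edges; both windows are parameters. `downsampleCube`
decimates from the highest wavenumber (2 → 4/8/16 cm⁻¹ keeps every
2nd/4th/8th channel), and `overviewImage` extracts the single amide I
plane (1656 cm⁻¹, ties toward the higher wavenumber) used for rapid
morphological preselection.

## Database curation and the cascade

`buildDatabase` samples QC-retained pixels per class (without replacement,
capped at `perClassCap`, stratified across source cubes), then purges each
class sample by k-means clustering of its second-derivative spectra:
if the smallest of `clusterK = 3` clusters holds under `outlierFraction =
5%` of the sample it is dropped as probable mislabels or residual
artifacts. Clustering here curates; it never defines classes.

Muscle is represented by **two** roster subclasses (anatomically the
muscularis mucosae and muscularis propria differ spectrally enough that a
single class is a poor fit); they merge into one white "muscle" class only
at render time. Debris/blood is a trained level-1 class mapped to
background at render — diagnosis must not depend on it, but rejecting it
only via QC would leave the classifier blind to the debris that passes.

The level-2 database covers tumor and necrosis (drawn from
pathological-region ground truth) and inflammation (drawn from
inflammatory-cell pixels — the only possible source for that class).

Both forests are 500 trees with 16 candidate features per split (clamped
to the feature count on coarser grids), Gini impurity importance, trained
single-threaded with a fixed seed. Prediction aggregates the per-tree
votes in the package, breaking ties toward the lowest display class code,
so that classification is bit-reproducible — forest libraries typically
break ties randomly. The cascade routing: QC-rejected pixels are
background in both maps; level-1 `pathological` pixels are re-classified
by the second forest; level-1 `inflammatory` pixels pass through unchanged
into the level-2 map (they are shown there purely for morphological
context); everything else is background at level 2.

## Diagnosis

A sample is called tumor-positive iff its tumor-pixel fraction strictly
exceeds the 2% threshold. Two conventions are deliberate:

* **Denominator = tissue pixels** (level-1 nonzero), not the full frame:
  including empty slide area would make the call depend on how much bare
  substrate was imaged. The choice is a config option.
* **Strict inequality** at the threshold: exactly 2% is negative.

The threshold exists because isolated tumor-labeled pixels arise from
spectral noise; 2% trades those false alarms against sensitivity to
low-burden sections. Metrics (sensitivity, specificity, PPV, NPV) are
reported as exact fractions plus half-up-rounded integer percents, the
clinical reporting convention.

## The phantom generator

`synthesizeCube` produces cubes whose statistical structure matches what
the classifier assumes: a layered colon wall (lumen, crypt-bearing mucosa,
thin muscularis mucosae, submucosa, muscularis propria) with tumor blobs
(necrotic cores) invading the submucosa, scattered inflammatory-cell
clusters, and debris in the lumen; per-class spectra as sums of
pseudo-Voigt bands at the canonical protein/nucleic-acid/carbohydrate
positions (amide I ~1656, amide II ~1546, CH ~1452, amide III/phosphate
1310–1240, carbohydrate 1160–1030 cm⁻¹) with class-distinct amplitudes;
per-pixel lognormal amplitude jitter (σ = 0.05); linear baselines (debris
anomalously high, 0.6–1.6 absorbance); van de Hulst distortion of
amplitude 0.1 on all tissue-boundary pixels plus 30% of interior tissue
pixels (emulating edge coherence); and i.i.d. Gaussian detector noise
(σ = 0.01 absorbance, a realistic figure for current QCL microbolometer
systems). One master seed expands into fixed per-stage child seeds, so
disabling one nuisance (e.g. `mieScale = 0`) leaves every other stage's
draws bit-identical — this is what makes clean-twin comparisons exact.

What the phantom does **not** emulate: measured class spectra (no
numerical mean spectra are published for this instrument class; the band
library is a stand-in and no spectral fidelity is claimed), instrument
fringing, focal-plane inhomogeneity, mosaic stitching offsets, spatial
correlation of noise, or the absolute absorbance levels of FFPE tissue.
Phantom classes are linearly separable at zero noise by construction.
Consequently, passing the end-to-end tests demonstrates that the pipeline
is *correct* (it recovers known truth under its stated noise model), not
that the reported clinical accuracy transfers to real tissue: patient-level
performance on real sections cannot be reproduced from synthetic data.

## Problem sizes and determinism

The test suite and acceptance script run at desk scale by choice: training
on two 96 × 96 phantoms with ≤ 250 spectra per class (the cap defaults to
2000 for real use), pixel accuracy on a fresh 128 × 128 phantom, Mie
efficacy on a 64 × 64 twin pair, and a 40-sample study (30 tumor-bearing
at 10% target tumor fraction, 10 tumor-free) of 64 × 64 phantoms under the
2% rule. Every stage is deterministic under a fixed seed — synthesis,
sampling, clustering restarts, forest training and vote tie-breaking — and
the full pipeline is asserted bit-reproducible, maps and study CSV alike.

## Known limitations

* The achieved tumor fraction of the geometry generator tracks its target
  within ±8% relative (±20% is the hard error bound); exact fractions are
  read from the ground-truth map, never assumed.
* Databases built on different substrates (or instruments with different
  response) are not interchangeable; the package deliberately refuses to
  classify across mismatched wavenumber grids but cannot detect substrate
  mismatch.
* Discrete-frequency (few-wavenumber) classification is out of scope: the
  Mie correction as formulated needs the full spectral window.
* `pixel_size` is carried as metadata only; the package does not reconcile
  field-of-view and array-size conventions of particular instruments.
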