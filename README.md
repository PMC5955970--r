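# mirtissue

Label-free classification of colorectal tissue in quantum-cascade-laser
(QCL) infrared hyperspectral images.

Mid-infrared microscopes record, for every pixel of a tissue thin section,
a full absorbance spectrum over the fingerprint-rich 1800–948 cm⁻¹ range.
Because the spectrum encodes the biochemical composition of the pixel,
tissue types — and in particular tumor — can be recognized without any
staining. `mirtissue` implements the complete analysis workflow for such
data, aimed at spectroscopists and computational pathologists who want a
tested, reproducible reference implementation:

1. **Quality control** — pixels are retained only if the trapezoidal
   integral of the amide I band (1700–1600 cm⁻¹) lies within bounds and
   the signal-to-noise ratio (amide I peak over the detrended standard
   deviation in the signal-free 1800–1760 cm⁻¹ edge) is sufficient.
2. **Resonant-Mie scatter correction** — each retained spectrum is
   decomposed by extended multiplicative signal correction (EMSC),

   A(ν̃) = c·m(ν̃) + a + b·ν̃ + Σₖ gₖ·pₖ(ν̃) + ε,

   where m is the (scatter-purged) mean spectrum of the cube and p₁…p₆ are
   principal components of a family of van de Hulst extinction curves
   Q(ρ) = 2 − (4/ρ)·sin ρ + (4/ρ²)·(1 − cos ρ) with ρ = 2π·d·(n−1)·ν̃ over
   d ∈ [2, 20] µm, n ∈ [1.1, 1.5]. The corrected spectrum is
   (A − a − b·ν̃ − Σ gₖpₖ)/c.
3. **Cascaded random-forest classification** — on the 382-channel
   1760–998 cm⁻¹ fingerprint grid, a first 500-tree forest (16 candidate
   features per split) assigns tissue types (pathological, inflammatory,
   muscle, connective, crypts, lumen, debris); pixels called pathological
   go to a second forest that resolves tumor, necrosis and inflammation.
   Training databases are curated from annotated cubes with k-means /
   Ward clustering of 9-point Savitzky-Golay second-derivative spectra.
4. **Diagnosis** — a sample is called tumor-positive when its
   tumor-pixel fraction (over tissue pixels) strictly exceeds 2%;
   study-level sensitivity, specificity, PPV and NPV are derived from
   the per-sample calls.

Cubes are read and written as ENVI header/raster pairs; label maps render
to index-color PNGs (red tumor/pathological, yellow inflammatory cells,
white muscle, green connective, cyan crypts, blue lumen, magenta necrosis,
black background). A synthetic colon-wall **phantom generator** with known
ground truth (layered mucosa/submucosa/muscularis geometry, pseudo-Voigt
class spectra, Mie distortion on tissue boundaries, detector noise)
supports end-to-end validation of every stage.

## Worked example

```r
library(mirtissue)

# train the two-level cascade on two 96 x 96 phantoms
casc <- trainPhantomCascade(nCubes = 2, spec = phantomSpec(height = 96, width = 96),
                            perClassCap = 250, nTrees = 500, seed = 42)
casc
#> TrainedCascade: 500 trees, 16 features/split, 382 channels
#>   level 1: lumen, crypts, connective, muscleA, muscleB, inflammatory, pathological, debris (OOB acc 1.000)
#>   level 2: tumor, necrosis, inflammation (OOB acc 1.000)

# classify and diagnose a fresh phantom with ~10% tumor burden
syn <- synthesizeCube(phantomSpec(height = 128, width = 128, seed = 7))
res <- classifySample(syn$cube, casc)
res$level1
#> LabelMap (level 1): 128 x 128 pixels
#>   background                 50
#>   pathological               1714
#>   inflammatory               291
#>   muscle                     5828
#>   connective                 5516
#>   crypts                     747
#>   lumen                      2238
res$diagnosis
#> DiagnosisResult: positive (tumor fraction 0.0852, threshold 0.020; 1391 / 16334 pixels)

# which wavenumbers drive the level-1 forest?
head(sort(variableImportance(casc)$level1, decreasing = TRUE))
#>       1240       1454       1238       1230       1236       1242
#> 0.02182834 0.02098340 0.02061713 0.01894100 0.01732183 0.01724032
```

The level-1 map recovers the phantom's layered colon-wall morphology; the
diagnosis is positive because 8.5% of tissue pixels carry the tumor code,
well above the 2% rule. The most important wavenumbers fall in the
amide III / phosphate region around 1240 cm⁻¹ and the CH-deformation band
near 1450 cm⁻¹, where the phantom classes differ most.

Index-color renderings are written with
`renderLabelMap(res$level1, "level1.png")`, and cubes go to disk via
`writeCube()` / `readCube()`.

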