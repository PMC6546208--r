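# cellmorph

Quantitative morphometrics for single adherent cells imaged by
fluorescence microscopy.  The shape of a spread cell and the texture of
its stained f-actin network are sensitive readouts of cytoskeletal
state — drugs that depolymerize actin or microtubules, stabilize
filaments or inhibit myosin II each leave a characteristic signature.
`cellmorph` turns a segmented single-cell image (a grayscale actin frame
plus binary cell and nucleus masks, with the cell centered in a fixed
square frame) into ~268 interpretable features in nine categories, and
provides the analysis layer used to compare experimental conditions in
that feature space.

## Feature categories

**Textural** (from the grayscale actin image, restricted to the cell
mask):

- *Band-based* — mean intensity in 10 equal-width concentric annuli
  about the cell center of mass, plus the indices/values of the extreme
  bands and the above-average adjusted intensity
  `AAAI = Σ_b max(0, Ī_b − Ī) / (10 Ī)`.  Sensitive to radially
  symmetric actin reorganization (e.g. the concentric rings induced by
  Cytochalasin D).
- *Grayscale fractal dimension* — box-counting dimension
  `FD = −d log N(ε) / d log ε` of four edge binarizations (Sobel,
  Prewitt, Roberts, Canny) of the actin image.
- *GLCM* — 23 Haralick-style statistics of the gray-level co-occurrence
  matrix at 1-pixel displacement, computed for 0°, 45°, 90°, 135° and
  averaged over directions.

**Irregularity** (from the traced cell boundary): the radial signal
ρ(t), the distance from the mask center of mass to the t-th boundary
pixel, is expanded in a Fourier series
`ρ(t) = C₀ + Σₙ Aₙ cos(wnt) + Bₙ sin(wnt)`, `w = 2π/nPixel`.

- *Waviness* — the rotation-invariant amplitudes `Cₙ = √(Aₙ² + Bₙ²)`
  for n = 0…35 (C₀ is the mean cell radius).
- *Roughness* — surface-roughness statistics (Ra, Rq, Rp, Rv, Rt, sd,
  skewness, kurtosis) of the residual between ρ(t) and its 35-term
  reconstruction: boundary variation too fine for the retained
  harmonics.

**Spreading** (from the binary masks):

- *Geometric* — area, chain-code perimeter, moment-equivalent ellipse
  axes, circularity `4πA/P²`, extent, equivalent diameter,
  centroid-to-boundary radii, solidity; the same set for the nucleus
  plus the nucleus/cell area ratio.
- *Convex hull* — hull area/perimeter, solidity, convexity, hull
  circularity and eccentricity, vertex count.
- *Zernike moments* — magnitudes `|Z_nm|` of the projection of the mask
  onto the Zernike polynomial basis, order n ≤ 30, repetition
  m ≤ min(n, 10), n − m even (146 values).  The frame's inscribed
  circle maps to the unit disk with one fixed scale for the whole
  cohort, so `|Z₀₀|` is exactly proportional to cell area.

**Analysis**: per-cell feature tables; Pearson correlation heat maps
computed within each condition group and averaged (so group mean shifts
do not masquerade as redundancy); per-category PCA (z-scored, first 4
components); and primary-principal-component (PPC) selection — for each
component, `MAX-P` is the worst-case Welch t-test p-value over all
requested group comparisons, and the PPC is the component minimizing
`MAX-P`, i.e. the single axis that best separates every comparison at
once.

**Synthetic data**: a generator for star-shaped cells
`ρ(θ) = R + Σₙ aₙ cos(nθ + φₙ)` with tunable low-frequency waviness,
high-frequency roughness, and interior textures (uniform, concentric
bands, oriented fibers, speckle), so every stage of the pipeline is
testable without microscope data.

## Worked example

```r
library(cellmorph)

spec <- synth_spec(n_cells = 6, seed = 1, mean_radius_px = 60,
                   radius_sd_px = 10,
                   waviness = data.frame(freq = c(3, 5),
                                         mean = c(6, 4), sd = c(2, 1)),
                   roughness_amp = 0.8, frame_side = 256,
                   texture = "banded")
cells <- generate_cells(spec, condition = "banded")
cells[[1]]
#> <cell_image> banded_001 [banded]  frame 256x256  area 8766 px  nucleus 1060 px

f <- extract_features(cells[[1]])
round(f[c("band_max_index", "band_aaai", "fd_canny", "glcm_contrast",
          "wav_C0", "wav_C3", "wav_C5", "rough_rq",
          "geo_area", "geo_circularity", "hull_solidity", "z_0_0")], 3)
#>  band_max_index       band_aaai        fd_canny   glcm_contrast          wav_C0
#>           8.000           0.249           1.239           3.035          52.293
#>          wav_C3          wav_C5        rough_rq        geo_area geo_circularity
#>           6.516           2.731           0.911        8766.000           0.445
#>   hull_solidity           z_0_0
#>           0.947           0.170
```

Reading: this cell's actin is brightest in the 8th of 10 concentric
bands (a banded/ring phenotype), its mean radius is 52.3 px with strong
3-lobed waviness (C₃ = 6.5 matches the generator's mean amplitude of
6), sub-harmonic boundary roughness of about 0.9 px RMS, and the deep
lobes drag circularity down to 0.45 while the convex hull stays nearly
full (solidity 0.95).

```r
ft <- assemble_feature_table(cells, categories = c("waviness", "geometry"))
ft
#> <feature_table> 6 cells x 50 features (waviness, geometry)
pca_category(ft, "waviness")
#> <pca_result> 6 cells, 4 components; explained: 29.1% 23.4% 21.2% 18.2%
```

With condition labels and a comparisons table
(`data.frame(group_a, group_b)`), `select_ppc()` then picks the
component with the smallest worst-case Welch p-value.

## Command line

A thin wrapper over the same functions lives at
`inst/cli/cellmorph.R`:

```sh
Rscript inst/cli/cellmorph.R synth      --out data/ --n 40 --seed 1 --frame 512
Rscript inst/cli/cellmorph.R preprocess --manifest raw.csv --out cells/ --threshold auto
Rscript inst/cli/cellmorph.R features   --manifest cells/manifest.csv --out features.csv
Rscript inst/cli/cellmorph.R analyze    --features features.csv \
                                        --comparisons comparisons.csv --out report/
```

## Further reading

The methods vignette (`vignettes/cellmorph-methods.Rmd`) documents the
models, parameter defaults, numerical conventions (connectivity,
perimeter weights, quantization, Zernike scaling), the design of the
synthetic generator, and known limitations.
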