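---
title: "cellmorph: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cellmorph: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellmorph)
```

This vignette explains the measures `cellmorph` computes, the numerical
conventions behind them, what the synthetic-data generator does and does
not emulate, and the design choices made where several defensible
options existed.  It states no empirical numbers beyond what the test
suite and `scripts/acceptance.R` themselves compute.

## The cell model

A cell enters the pipeline as a `cell_image`: a square grayscale frame
(stained f-actin, intensities in [0, 255]), a binary cell mask with
exactly one 8-connected component whose center of mass lies within half
a pixel of the frame center, and optionally a nucleus mask.  The fixed
frame matters: several measures (Zernike moments in particular) are
defined relative to the frame, not the cell, so that cells of different
sizes remain comparable.

Preprocessing raw frames (`preprocess_cell`) follows the standard
segmentation chain: Otsu's threshold (maximizing between-class variance
over all 256 candidate 8-bit levels, computed by cumulative histogram
moments; a numeric override is available where an operator would
adjust the automatic value), largest-object extraction, hole filling,
and centering by an integer translation (never resampling, so mask
pixel sets are preserved exactly; the residual centroid offset is at
most half a pixel, and centering is idempotent).

Digital-topology conventions, used consistently everywhere: objects are
8-connected, background is 4-connected; coordinates are (row, col),
0.5-px pixel centers on an integer grid, row increasing downward; the
boundary is traced by Moore-neighbor tracing with Jacob's stopping
criterion, starting at the uppermost-then-leftmost boundary pixel and
oriented counterclockwise.  Holes are ignored by the tracer; 1-px-thin
protrusions are traversed out and back (a closed walk), which is the
behavior the downstream Fourier analysis expects of a closed curve.
Masks are filled before feature extraction by default (holes in actin
staining are almost always segmentation artifacts); the flag is exposed
for cohorts where that assumption fails.

## Textural measures

**Band-based.** The mask is partitioned into 10 annuli of equal radial
width `Δr = R_max / 10` about the center of mass (`R_max` = largest
centroid-to-pixel distance; the outermost band is closed so the extreme
pixel is never dropped).  Reported: the 10 band means, the indices
(1-based, ties to the innermost band) and values of the minimum and
maximum bands, and the above-average adjusted intensity
`AAAI = Σ_b max(0, Ī_b − Ī) / (10 Ī)` (defined as 0 for an all-black
cell).  An empty band reports mean 0.

**GLCM.** Intensities inside the mask are quantized into `g = 8` levels
by equal-width bins over the within-mask min–max range; background
pixels are excluded from pairs entirely.  Both choices need a word.
`g = 8` is standard co-occurrence practice and keeps the matrix well
populated for small cells (the paper-scale alternative, 256 levels,
produces nearly empty matrices at typical cell areas); including
background zeros would let the mask silhouette swamp the actin texture.
Min–max quantization makes the statistics invariant to affine intensity
shifts, but it also means rare extreme pixels stretch the binning: a
punctate (speckle) texture compresses its background into few levels
and can show *lower* GLCM entropy than a flat noisy fill, even though
it looks "busier".  The generator tests therefore characterize
punctate texture by its higher contrast and maximum probability, not by
entropy.

The co-occurrence matrix at displacement 1 px is computed for 0°, 45°,
90°, 135° (angles counterclockwise from the +col axis), symmetrized
(`counts + t(counts)`) before normalization, and 23 statistics are
evaluated per direction and averaged over the four directions, making
the reported values invariant to image rotation on the pixel grid.
The 23 statistics are the Haralick/Soh/Clausi set: autocorrelation,
contrast, two correlation forms, cluster prominence and shade,
dissimilarity, energy, entropy, two homogeneity forms, maximum
probability, sum of squares, sum average/variance/entropy, difference
variance/entropy, the two information measures of correlation, inverse
difference, and the two normalized inverse-difference forms.  Entropies
use natural logarithms with `0·log 0 := 0`; Haralick's original
convention is kept for the sum variance (deviation about the sum
entropy); correlation-type statistics are defined as 0 when a marginal
variance vanishes.  Every statistic is verified against an independent
brute-force double loop at 1e-10.

**Fractal dimension.** The actin image is binarized by four edge
detectors — Sobel, Prewitt, Roberts (threshold: 4x the mean in-mask
gradient magnitude, the classic automatic rule for gradient edge maps)
and Canny (Gaussian σ = √2; high hysteresis threshold at the 70th
percentile of in-mask gradient magnitudes, low = 0.4·high) — and each
edge map's box-counting dimension is reported.  Grids use box sides
2^k anchored at the array origin (no offset averaging; the simplest
faithful reading of the counting definition), k from 0 to
⌊log₂ min(side)⌋, and FD is the negated least-squares slope of
log N(ε) vs log ε.  A constant cell yields empty edge maps and FD = 0.
Convolutions use replicate padding so the frame border contributes no
spurious gradients.

## Irregularity measures

The boundary is represented by the radial signal ρ(t): the distance
from the mask center of mass to the t-th boundary pixel *in traversal
order*.  Indexing by traversal order rather than polar angle is
deliberate: for strongly non-convex cells ρ(θ) is multi-valued, while
ρ(t) is always well defined; and it makes C₀ exactly the mean
centroid-to-boundary distance, i.e. the geometric mean cell radius, so
the two are correlated at exactly 1 across any population.

The signal is expanded as
`ρ(t) = C₀ + Σₙ Aₙ cos(wnt) + Bₙ sin(wnt)`, `w = 2π/nPixel`, with the
2/nPixel amplitude normalization chosen so a pure cosine of amplitude
*a* yields `Cₙ = √(Aₙ²+Bₙ²) = a`.  The first 35 harmonics are kept
(reconstruction of even quite irregular cells is visually excellent at
35 terms); `Cₙ` discards the phase, making the waviness vector
invariant to rotation of the cell and to the choice of starting pixel.
For boundaries shorter than 2·35+1 pixels the expansion truncates to
the available harmonics and missing amplitudes report 0.

One bias is worth knowing about.  Because t advances by boundary
pixels, not by angle, a shape with strong lobes traverses θ at varying
speed; a pure cos(5θ) star is therefore *not* a pure harmonic in t —
its fundamental is attenuated by a few percent and genuine overtone
content appears at n = 10, 15, … (for a 10-px lobe amplitude on a 50-px
radius, the n = 10 overtone is about 0.55 px, and the recovered C₅ is
about 9.5, both confirmed against a continuous arc-length oracle that
removes rasterization entirely).  This is a property of the
parametrization, not an implementation error; amplitude comparisons
*between* cells are unaffected because all cells share the same
parametrization.

**Roughness** is the residual between ρ(t) and its 35-term
reconstruction — boundary variation at spatial frequencies above the
waviness cutoff — summarized by the surface-metrology statistics Ra
(mean |e|), Rq (RMS), Rp (max), Rv (min), Rt (Rp−Rv), standard
deviation, skewness and non-excess kurtosis.  Skewness and kurtosis use
population (biased) definitions.  Rasterization alone contributes
roughly 0.2 px of Rq, which is the noise floor for these measures.

## Spreading measures

**Geometric.** Area is the pixel count; the perimeter is the 8-chain
length of the traced boundary (axial steps 1, diagonal steps √2).  With
this convention a digital disk's perimeter undershoots the smooth
circle slightly, so circularity `4πA/P²` sits a few percent *below* 1
for disks and may exceed 1 marginally for other digitized shapes; it is
reported unclamped.  Ellipse axes, eccentricity and orientation come
from the second central moments of the pixel coordinates (axes = 4√λ).
Radii (mean/max/min) are centroid-to-boundary-pixel distances — the
mean is by construction identical to the waviness C₀.

**Convex hull.** The hull is computed over boundary pixel centers
(`grDevices::chull`) with exactly-collinear vertices pruned; a
degenerate 1-px-thin mask falls back to the half-pixel-buffered pixel
corners.  Because pixel centers sit half a pixel inside the true object
boundary, the hull slightly underestimates the enclosed area and
solidity (mask area / hull area) can marginally exceed 1 for convex
digital shapes — again reported unclamped, with ~2% digitization slack.
Rasterized lobe tips are blunt, so a 5-lobed star's hull retains up to
~4 vertices per tip after pruning.  Hull eccentricity uses exact
polygon moment integrals (Green's theorem), not vertex moments.

**Zernike moments.**
`Z_nm = (n+1)/π Σ f(x,y) R_nm(ρ) e^{−imθ} ΔA` over the unit disk, with
f the binary mask and the frame's inscribed circle mapped to the unit
disk at one fixed scale for the whole cohort.  Per-cell bounding-circle
normalization (the other common convention) would divide out cell size
and destroy the exact `|Z₀₀| ∝ area` identity this fixed mapping
guarantees; size-invariant analyses can always standardize the feature
columns instead.  Radial polynomials are evaluated from the factorial
form via log-factorials (exact in double precision to n = 30) with
cached ρ-powers and angular harmonics; magnitudes for n ≤ 10 are
verified against direct per-pixel summation at 1e-6 relative.  Pixels
outside the inscribed circle are ignored with a warning — cells should
fit inside it, which the centering contract and generator guarantee.
The default enumeration (n ≤ 30, m ≤ min(n, 10), n − m even) yields 146
magnitudes.

## Analysis layer

Feature tables hold cells × features with per-column category tags and
per-row condition labels; cells with absent nucleus channels carry NA
markers (absent, never zero) which correlation handles pairwise and
PCA by excluding the nucleus category when more than 10% is missing.

Pearson correlation between features is computed *within* each
condition group and averaged over groups: pooled correlation would
count between-condition mean shifts as feature redundancy.  Zero
variance is an error in the scalar API (`pearson`) and a skipped,
logged pair in the matrix API.

Per-category PCA z-scores the features first — the categories mix px²,
px and dimensionless quantities, so raw-covariance PCA would be
dominated by area-like columns.  Four components are retained by
default (in practice they account for nearly all variance within a
category); loading signs follow a deterministic convention (largest
|loading| positive) so runs are exactly reproducible.  The PCA is fit
on the pooled data, not per condition pair, so scores of all groups
live in one space.

Group comparisons use Welch's unequal-variance t-test (the safe default
when drug treatments change spread as well as location).  The
primary-principal-component (PPC) of a category is the component among
the first four minimizing the worst-case (maximum) p-value over all
requested comparisons, ties to the lowest index.  These p-values rank
separability; they are not significance claims, so no multiplicity
correction is applied in the selection.  The per-feature significance
report (`feature_significance`) does apply Benjamini–Hochberg by
default, with a flag to disable.

## The synthetic generator

`synth_spec` defines a population of star-shaped cells
`ρ(θ) = R + Σ aₙ cos(nθ + φₙ)`: R ~ N(mean_radius, sd), amplitudes
drawn per cell from the spec's per-frequency normal distributions with
uniform phases, plus fixed-amplitude high-frequency components
(default n ∈ {45, 60, 75}) below the 35-harmonic cutoff's resolution —
the roughness channel.  Masks are rasterized exactly (a pixel is inside
iff its distance to the center is ≤ ρ(θ) at the pixel's angle — no
polygon approximation, no anti-aliasing in masks), holes filled,
re-centered.  Draws that would turn the radius negative are rejected
and redrawn (at most 100 times).

Default study conditions: frame 1024 px with mean radius 150 ± 20 px
(cells occupy a realistic ~1/10 of the frame area, as in typical
40x single-cell crops); waviness spread over harmonics 2–8 with
amplitudes 12/n ± 4/n (low-frequency lobes dominating, consistent with
spread epithelial-like outlines); roughness amplitude 1 px; uniform
texture at 120 ± 15 gray levels; nucleus at 0.35 of the cell radius.
Tests and the acceptance script scale the frame down (96–512 px) with
radii scaled proportionally; those sizes are stated in each test and
are the package's choice of problem size.

Textures: *uniform* (flat + Gaussian noise), *banded* (intensity from
the band index through a supplied 10-vector — the concentric-ring
phenotype of actin-depolymerized cells), *fibrous* (Gaussian-profile
line segments with von Mises orientations, Best–Fisher sampler —
stress-fiber anisotropy), *speckle* (Bernoulli bright foci).  Fibrous
anisotropy is visible in the per-direction GLCM contrast before angle
averaging.

Reproducibility: every cell is generated from its own seed derived
deterministically from (base seed, cell index), so populations are
bit-reproducible and cell i does not depend on how many cells are
generated.  Written populations (PNG pairs + manifest) are
byte-identical across runs.

What the generator does **not** emulate: real segmentation errors
(debris, touching cells, out-of-focus halos), intensity statistics of
any particular stain or detector, spatially correlated noise, or any
biophysics of actin organization.  Passing tests on synthetic cells
validates the measurement and analysis machinery — the geometry of the
measures, their invariances and their discriminative logic — not the
biological claims one might make from real cohorts.

## Numerical choices and degenerate inputs

- Otsu on a constant image is an error ("degenerate histogram"); ties
  among optimal thresholds resolve to the lowest level.
- Equal-area components resolve to the one whose first pixel comes
  first in row-major scan order.
- Constant intensity inside the mask quantizes to level 1 everywhere;
  the resulting single-entry GLCM reports contrast 0, energy 1,
  entropy 0, and correlation-type statistics 0.
- A single-pixel "fractal" has N(ε) = 1 at every scale and FD 0; a
  single grid scale also reports 0.
- Boundaries shorter than 8 px are rejected for Fourier analysis;
  masks of area < 4 are rejected for tracing.
- Missing nucleus: NA markers, excluded pairwise.
- Zero-variance Welch comparisons: p = 1 for equal means, 0 otherwise.

## Known limitations

- The traversal-order parametrization attenuates strong lobes' Fourier
  amplitudes by up to ~5% and creates overtones (see above); this is
  shared by any pixel-indexed boundary Fourier method.
- Chain-code perimeters carry a few percent of direction-dependent
  bias; circularity/convexity comparisons are only meaningful within a
  fixed convention.
- Box counting with a single origin-anchored grid (no offset
  averaging) is the simplest faithful estimator but has higher
  variance on small edge maps than multi-offset variants.
- GLCM statistics depend on the quantization rule; values are not
  comparable across different `g` or different quantization ranges.
- The Canny hysteresis thresholds adapt to each cell's gradient
  distribution, so its edge maps are not comparable across cells in
  absolute density — only the derived fractal dimension is used.

## Problem sizes used in the shipped checks

Unit and property tests run on 96–256 px frames with radii 15–60 px,
populations of 4–8 cells, and 80 cells (2 × 40) for the end-to-end
discrimination check; the acceptance script uses 40 cells at 512 px.
These sizes keep the full suite in the low minutes on one CPU while
leaving every measure far from its degenerate regime.
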