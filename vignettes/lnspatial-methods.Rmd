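---
title: "Methods: spatial neutrophil/B-cell neighborhood analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial neutrophil/B-cell neighborhood analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lnspatial)
```

# The analysis

`lnspatial` quantifies how B-cell activation and proliferation depend on
the distance to B-helper neutrophils in lymph-node tissue, and how
neutrophil infiltration of B follicles stratifies survival. The pipeline is

1. per-channel **rolling-ball background subtraction** (64 µm ball),
2. **nuclear segmentation** on DAPI with a fixed 1 µm region growth,
3. **positivity calls** for CD19 (B cells) and CD66b (neutrophils) from the
   ratio of cell signal to local background,
4. the **proximity statistic**: marker intensity and density of CD19⁺ cells
   binned by distance to the nearest CD66b⁺ cell, normalized to image-wide
   values, pooled across images and compared bin-wise,
5. **follicle infiltration** density (neutrophils per 0.01 mm²) with
   high/low stratification, and
6. **Kaplan–Meier / log-rank** survival comparison with follow-up capped at
   1862 days (five years).

Every stage is exercised on synthetic tissue phantoms with known ground
truth; no clinical data ship with the package.

# The proximity statistic

For image $j$, let $d_i$ be the Euclidean centroid distance of CD19⁺ cell
$i$ to its nearest CD66b⁺ cell. Distances are assigned to half-open bins
$(l_{k-1}, l_k]$ with default edges $0, 10, 30, 50, 100, \infty$ µm;
distance 0 falls in the first bin, so ties at edges are deterministic. Per
bin the mean marker intensity and the cell density are divided by the
image-wide mean over all CD19⁺ cells and the image-wide CD19⁺ density. The
density denominator for bin $k$ is the area of the image region whose
distance-to-nearest-neutrophil lies in that bin, computed from a pixel
distance map of the analyzable field — this handles image borders exactly,
where naive annulus areas overcount. With a single bin $(0, \infty]$ both
normalized quantities are exactly 1, a property the tests assert.

Design choices that were genuinely open:

* **Distance base.** Each B cell contributes once, at its
  nearest-neutrophil distance. An alternative reading ("annuli around each
  neutrophil, B cells counted once per neutrophil") produces overlapping
  counting units and no conservation property; we kept nearest-distance as
  the default because the binned axis is then a partition of the B-cell
  population (bin counts sum to the CD19⁺ total, asserted in tests).
* **Normalization population.** Image-wide values are computed over CD19⁺
  cells (the quantity profiled is a property of B cells), not all cells.
* **Empty bins propagate as missing**, never as zero — zeros would bias
  pooled means toward flatness or deficit.
* **Pooling unit is the image** (3–5 images per lymph node is typical);
  per-bin values are compared across images with Kruskal–Wallis, and all
  pairwise bin contrasts use Wilcoxon signed-rank tests on images
  contributing both bins, Bonferroni-corrected with $m$ = number of pairs
  actually performed. With $n$ images the smallest attainable two-sided
  signed-rank p-value is $2^{1-n}$, so at least 12 images are needed for a
  Bonferroni-adjusted significance at $m = 10$ — cohort sizes below that
  cannot reach significance by construction.
* Images with **no CD66b⁺ cell** (distance undefined) or a zero
  normalization denominator are excluded and logged, not imputed.

# Rolling-ball background subtraction

The background is the upper envelope traced by a ball of physical radius
$r$ (default 64 µm, converted to pixels via the image pixel size) rolled
under the intensity surface — a grayscale opening with a spherical
structuring element, implemented in C++ with the apex-normalized height
profile $b(k) = \sqrt{r^2 - \lVert k\rVert^2} - r$ so constant images pass
through exactly. Two classic practicalities:

* **Pre-smoothing.** The envelope is a pointwise-minimum construction, so
  isolated low-noise pixels would drag it down; a 3×3 mean filter is
  applied to the copy used for background estimation (`presmooth = TRUE`).
* **Shrinking.** For radii above 16 px the image is reduced by a block
  minimum, the ball rolled at the reduced scale, and the result bilinearly
  re-enlarged.

The estimated background is finally capped at the original image, which
makes the decomposition exact: `subtracted + background == original` at
every pixel and `subtracted >= 0`.

Monotonicity in the ball radius deserves a caveat: it is *not* a pointwise
property for arbitrary images. A larger ball stays lower at narrow peaks
but rides higher over narrow pits, so noisy images violate both
directions. On the method's intended inputs — bright features on a smooth
background — the background is monotone non-increasing in the radius, up
to ball-discretization error; the tests assert exactly that, with a
tolerance of 0.1% of the intensity range.

DAPI is not background-subtracted by default (only the marker channels
are); `include_dapi = TRUE` changes that.

# Segmentation and features

The DAPI channel is normalized, Gaussian-smoothed (σ = 0.5 µm), thresholded
with Otsu's method, and touching nuclei are split by a watershed on the
distance transform (minimum basin depth 1 px). Regions outside a
7–120 µm² area window are removed. These policies are explicit parameters
(`segmentation_params()`) because nuclear segmentation is part of the
analysis contract: equivalence to any proprietary segmenter cannot be
claimed, only recovery of synthetic ground truth (recall and precision
≥ 0.90 at 3 µm centroid tolerance on default phantoms, asserted in tests).

Nuclear masks are grown outward by 1 µm to approximate the whole cell;
contested pixels go to the nearest seed (Voronoi division), so labels never
merge and the label count is conserved. Per-cell features are the centroid
(pixel-center convention: top-left origin, x = column, y = row, micron
position = (index − 1) × pixel size), the nucleus area, and the mean of
every channel's subtracted and background layer over the grown mask. The
per-cell mean of the *background layer* is the "local background" that
positivity ratios are computed against; an annulus-based alternative was
considered and rejected as it reintroduces neighbor contamination in dense
follicles.

# Positivity calibration

A cell is positive for CD19 or CD66b when its signal-to-local-background
ratio reaches a cutoff calibrated on a subselection of images. The default
calibration fits a two-class Gaussian mixture (equal variances) to the
log-ratios and cuts where the class posteriors cross. The textbook
alternative — an Otsu-style between-class variance scan — is provided but
is *not* the default: neutrophils are typically 0.1–10% of cells, and at
that imbalance the variance criterion places the cut inside the majority
mode (on rendered phantoms this cost ~8 percentage points of truth
agreement). Zero backgrounds are floored at a configurable ε (10⁻³) before
ratioing.

Double-positive cells are excluded from both phenotype sets by default
(they are most often segmentation doublets); `cd66b-wins` / `cd19-wins`
policies are available, and the double-positive count is recorded.

# Follicles and survival

Neutrophil counts inside annotated follicle polygons use an even-odd
point-in-polygon rule with boundary points counted inside (deterministic
and documented); density is count per 0.01 mm². Two stratification rules
circulate for "high vs low infiltration" and they are not equivalent, so
the rule is a required recorded parameter: `median` (ties at the median go
to "low") or `zero-vs-any` (no detected neutrophils = "low"). The package
never silently chooses between them.

Survival uses the product-limit estimator and the standard log-rank test
(hypergeometric variance), with events preceding censorings at tied times.
Follow-up beyond 1862 days is capped with the event flag cleared —
administrative censoring at five years — *before* estimation. The tests
check the estimator against a hand-rolled product-limit oracle, its
agreement with the exponential closed form at n = 1000, the null size of
the log-rank test, and its power (≥ 80% at hazard ratio 3 with 40 per
arm).

# What the phantom emulates — and what it does not

`phantom_config()` defaults define the study conditions: an 800×800 µm
field at 1 µm/px; four follicle discs of radius 70 µm with 100 B cells
each; 8 neutrophils, half inside follicles; 150 unclassified cells; nuclei
of radius 3 µm under a hard-core minimum spacing of 8 µm; lognormal
cell-to-cell intensity variation (σ = 0.2, mean 1); a smooth additive
background field (logistic-squashed Gaussian grid, scale 120 µm, amplitude
15) over a constant autofluorescence floor of 5; Gaussian pixel noise
(σ = 3). The floor matters: real tissue background never reaches zero, and
without it signal-to-background ratios of negative cells are dominated by
the denominator. The proximity effect multiplies the marker intensity of B
cells within `effect_radius_um` (10 µm) of any neutrophil by
`effect_amplitude`; amplitude 1 is the null regime. Note that the
hard-core spacing leaves only the 8–10 µm shell of the first distance bin
populated, so first-bin counts per image are small (~10) — pooling across
20 images is what makes the first-bin estimate stable.

One root seed drives derived child streams (`derive_seed()`) for layout,
rendering, cohorts and per-image analyses, so any stage can be regenerated
in isolation and full runs are byte-reproducible.

The phantom deliberately omits: optics (PSF, ApoTome sectioning
artifacts), autofluorescence spectra and channel crosstalk, 3-D tissue
context, irregular follicle shapes, and cell-shape variation beyond discs.
Passing tests therefore demonstrate that the *computational pipeline*
recovers known spatial structure under realistic densities and noise — not
that any particular biological imaging system is calibrated.

Synthetic survival cohorts draw exponential event times with arm-specific
hazards (defaults 1/1500 and 1/500 per day, hazard ratio 3, mirroring a
clearly separated high/low prognosis split), administratively censored at
2200 days and capped at 1862.

# Problem sizes and numerical choices

The shipped tests and the acceptance script use: 20 phantom images for the
null-flatness and effect-recovery checks (truth tables, no rendering); two
fully rendered default phantoms (~560 cells each) for segmentation,
phenotyping and background-subtraction fidelity; 200 replicate cohorts of
40+40 for log-rank power; 20 random 200-cell tables for the brute-force
oracle equivalence of the spatial binning. These sizes make the Monte
Carlo error small relative to every asserted tolerance while keeping a
full run in minutes on one core.

Other numerical policies: images are processed as floating point
throughout (integer round-trip is a writer concern); TIFF output stores
32-bit floats in [0, 1] with the intensity scale and pixel size in a JSON
sidecar; all tabular outputs are plain CSV; follicle annotations are
GeoJSON in micron coordinates.

# Known limitations

* Nearest-distance profiles ignore neutrophil clustering (two adjacent
  neutrophils are not "more" neighborhood than one); pair-correlation
  machinery is out of scope.
* The mixture calibration assumes log-ratios form two roughly Gaussian
  classes; heavily skewed positive populations may need a fixed cutoff.
* The watershed policy under-splits nuclei that overlap with no intensity
  valley; at the phantom's hard-core spacing this is rare, but real
  crowded tissue will need the area window retuned.
* With fewer than ~12 images, Bonferroni-adjusted signed-rank contrasts
  cannot reach 0.05 (see above); the Kruskal–Wallis overall test remains
  informative.
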