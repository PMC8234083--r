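# lnspatial

Spatial analysis of neutrophil/B-cell neighborhoods in multiplexed
immunofluorescence images of lymph nodes.

## The problem

Neutrophils with a B-helper phenotype (N<sub>BH</sub>) sit inside the B-cell
follicles of regional lymph nodes, where they can drive B-cell activation
(AID expression) and proliferation (Ki67). Two questions follow from tissue
sections stained for DAPI / CD19 / CD66b / AID-or-Ki67:

1. **Is B-cell activation spatially coupled to neutrophils?** For every
   CD19⁺ B cell, take the Euclidean distance *d* to the nearest CD66b⁺
   neutrophil and bin it into (0, 10], (10, 30], (30, 50], (50, 100],
   (100, ∞) µm. Per bin *k* report the mean marker intensity and the cell
   density of the assigned B cells, normalized to whole-image values:

   I_k = mean{ AID_i : d_i ∈ bin k } / mean{ AID_i : all CD19⁺ },
   ρ_k = (n_k / A_k) / (N / A),

   where A_k is the area of the image region whose
   distance-to-nearest-neutrophil falls in bin k (from a pixel distance
   map, so image borders are handled exactly). A flat profile (I_k ≡ 1)
   means no spatial coupling; enrichment in the first bin means B cells
   touching neutrophils are more activated. Bins are compared across images
   with a Kruskal–Wallis test and Bonferroni-corrected signed-rank
   contrasts.

2. **Does follicle infiltration by neutrophils stratify survival?**
   Neutrophils are counted inside annotated follicle polygons
   (density per 0.01 mm²), samples are split into high/low infiltration
   (median split or zero-vs-any), and the groups are compared with
   Kaplan–Meier curves and a log-rank test, with follow-up capped at five
   years (1862 days).

Every stage runs on synthetic tissue phantoms with known ground truth
(cell positions, classes, true marker intensities, a controllable proximity
effect), so the whole pipeline is testable without restricted clinical data.

The supporting stages mirror standard tissue cytometry practice:
rolling-ball background subtraction with a physical ball radius (64 µm
default), DAPI nuclear segmentation with watershed splitting and a fixed
1 µm region growth, and CD19/CD66b positivity calls from the ratio of cell
signal to local background with automatically calibrated cutoffs. A qPCR
module computes 2^−ΔCt and 2^−ΔΔCt relative expression.

## Worked example

Generate eight phantom images in which B cells within 10 µm of a neutrophil
have 1.5× marker intensity, and recover that effect from the binned
profile:

```r
library(lnspatial)

geom <- list(width_um = 800, height_um = 800, pixel_size_um = 1)
tabs <- lapply(1:8, function(i) truth_cell_table(generate_layout(
  phantom_config(effect_amplitude = 1.5, seed = 100 + i))))
names(tabs) <- paste0("img", 1:8)

profs <- profile_images(tabs, radial_bins(), geom)$profiles
cmp <- pool_and_compare(profs)
cmp$pooled
#>  bin n_images      mean         sd
#>    1        8 1.6084269 0.29702667
#>    2        8 1.0099175 0.03014332
#>    3        8 0.9893169 0.02233355
#>    4        8 0.9957175 0.01942452
#>    5        8 0.9887404 0.01540984
cmp
#> bin comparison on normalized_intensity: Kruskal-Wallis chi-sq = 21.598 (df 4), p = 0.000241
```

The first bin (B cells within 10 µm of a neutrophil) is enriched ~1.6-fold
while all further bins sit at 1; the Kruskal–Wallis test across bins is
highly significant. With `effect_amplitude = 1` the profile is flat.

The full image pipeline (render → subtract background → segment →
phenotype → profile → follicle scoring → survival) runs as one call:

```r
run_pipeline(validate_config(list(seed = 42)), out_dir = "demo_out")
```

writing `cells.csv`, `profiles.csv`, `infiltration.csv`, `survival.csv`,
`km.csv` and a JSON manifest keyed by the configuration hash. A thin shell
front end is in `inst/scripts/lnspatial-pipeline.R`.

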