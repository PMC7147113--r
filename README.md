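# flsquant

Quantification of filopodia-like structures (FLS) from confocal z-stacks.

FLS are parallel actin bundles reconstituted on supported lipid bilayers in
*Xenopus* egg extract: each structure grows from a disk-like base at the
membrane plane (the bottom z-slice) tens of micrometres into the extract.
Perturbation screens — e.g. adding antibody fragments (scFvs) to the assay —
change how many structures form, how long, how thick-based and how straight
they are. `flsquant` turns calibrated z-stacks into those numbers and turns
a whole screen into a phenotype map:

- **Segmentation** — each z-slice is band-pass filtered with a 2D
  difference of Gaussians, thresholded at `mean + k·sd` of the response,
  and reduced to 8-connected components.
- **Greedy tracing** — components are linked from the base slice upward:
  seeds are slice-0 components in descending base-area order, each trace
  repeatedly claims the nearest unclaimed component within `max_link_um`
  in the next available slice (gap tolerance 1 slice), ties broken by
  (y, x). Fully deterministic, frozen by a literal reference
  implementation (`trace_oracle()`).
- **Morphometrics** — per structure: path length
  `Σ √((Δx·s)² + (Δy·s)² + (Δz·h)²)` through node centroids (pixel size
  `s`, z-step `h`), straightness = end-to-end / path length ∈ (0, 1], and
  base area = slice-0 component area × `s²`; per region: count and means.
- **Phenotype embedding** — per condition, six features (median FLS count,
  median per-region mean length, median per-region mean base area, each
  with and without supplemental actin), standardised and embedded by exact
  t-SNE with perplexity 2.49 and early exaggeration 12.
- **Linescan scoring** — a filopodium is marker-positive when its linescan
  maximum strictly exceeds `mean + 1·sd` of the maxima of the image's
  background linescans; two-sample Kolmogorov–Smirnov comparisons are
  labelled with Bonferroni-corrected four-way tiers
  (\* p < 0.0125, \*\* p < 0.0025, \*\*\* p < 0.00025).
- **Synthetic data** — generators for image stacks (with exact polyline
  ground truth), linescan sets and screen tables with planted clusters, so
  the entire pipeline is validated without microscopy downloads.

## Worked example

```r
library(flsquant)

# a synthetic region: 5 filaments, 18 slices, 0.1 um/px, 1 um z-step
cfg <- fls_stack_config(n_filaments = 5, seed = 11)
sim <- generate_fls_stack(cfg)
q   <- quantify_stack(sim$stack)   # segment -> trace -> measure
print(q$measures, digits = 3)
#>   trace_id path_length_um straightness base_area_um2 n_nodes
#> 1        1           5.03        0.995          0.70       6
#> 2        2          12.11        0.992          0.68      13
#> 3        3           7.04        0.995          0.68       8
#> 4        4           9.08        0.991          0.67      10
#> 5        5          10.03        0.998          0.65      11
```

All five planted filaments are found; compare the ground truth (arc
lengths 12.10, 10.03, 9.08, 7.04 and 5.03 µm, straightness 0.991–0.998,
base area π·0.5² ≈ 0.785 µm²): lengths and straightness are recovered to
within ~0.01 µm and ~0.005, base areas read ≈ 14% low — a stable
discretisation bias of thresholding a blurred disk, shared by all
conditions (see the vignette). Per-region summary and a screen-level
embedding:

```r
q$summary
#>   region_id condition actin_state fls_count mean_length_um mean_base_area_um2 mean_straightness
#> 1    region         C  none_added         5           8.66              0.676             0.994

tab <- generate_phenotype_conditions(23, n_regions_per_condition = 12, seed = 1)
emb <- embed_2d(scale_features(build_feature_matrix(tab)), seed = 0)
emb
#> <fls_embedding> 23 conditions, perplexity 2.49, early exaggeration 12, seed 0
head(emb$coordinates, 3)
#>                 x         y
#> C      -61.359023 -69.55364
#> scFv1   -7.792365  30.15247
#> scFv10  -3.601362  38.13703
```

File-to-file orchestration (TIFF stacks + metadata CSV in, CSVs and a JSON
run manifest out) is provided by `run_quantify()`, `run_embed()` and
`run_score()`, and a thin CLI lives in `inst/scripts/flsquant-cli.R`
(subcommands `simulate`, `quantify`, `embed`, `score`, `all`).

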