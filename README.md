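# coamap

Quantification, zoning and staging of **corpora amylacea (CoA)** —
spherical polyglucosan inclusion bodies of the ageing human brain — in
calibrated single-channel fluorescence micrographs of the hippocampal
formation.

The package is aimed at neuropathology image-analysis work in which CoA
are visualised as bright, roughly circular objects against dim tissue
autofluorescence, sampled as fields of view (FOV) of 1600 × 1200 px
covering 0.2 mm², at seven pial-surface sites (alveus APS, fimbria FPS,
prosubiculum PPS, subiculum SPS, medial/lateral entorhinal cortex
MPS/LPS, collateral sulcus CPS) and seven neuropil regions. It provides:

* **Detection** — thresholding (Otsu or fixed), 8-connected labelling,
  exact pixel-count areas and equivalent diameters
  *d* = 2·√(*A*/π), a 3 µm minimum size, and the unbiased counting
  frame (objects intersecting the left or bottom border are excluded;
  right/top are inclusion borders).
* **Per-field parameters** — CoA count, area fraction (%), mean /
  minimum / maximum equivalent diameter, with the zero-handling rules
  (zeros enter density analyses; empty fields contribute no diameters).
* **HD/LD zoning** — a subpial high-density band of fixed depth (100 µm
  at the fimbria, 70 µm at the prosubiculum, 40 µm elsewhere), centroid
  zone assignment, packing density (count/mm²), and the
  area-over-centre-line thickness estimator for traced HD polygons.
* **Staging** — a decision ladder assigning stages 0–4 from regional
  densities (half-open bands 0–10 / 10–50 / 50–500 CoA per field) and
  deep-white-matter spread, plus a continuous burden score
  Σ log(1 + mean count) (+2/+4 for deep-white-matter flags) that orders
  sections into a ranked CoA sequence.
* **Statistics** — Spearman correlation grids (region × parameter) with
  Benjamini–Hochberg FDR per grid, unpaired pooled t-tests, one-way
  ANOVA, and a Levene gate selecting Fisher's LSD (equal variances) or
  Games–Howell (Welch t with Welch–Satterthwaite df referred to the
  studentized range) post hoc comparisons.
* **A synthetic-micrograph generator** with exact ground truth — Poisson
  counts in the HD band, hard-core separation, truncated-lognormal
  diameters (median 9 µm, 3–30 µm), a staged regional gradient peaking at
  the fimbria, and cohort covariates in which age enlarges CoA but does
  not change their density.

## Worked example

Simulate a stage-3 section, summarise it and classify its stage:

```r
library(coamap)
cal <- calibration()                     # 1600 x 1200 px, 0.2 mm^2
sec <- simulate_section(sim_config(stage = 3), cal,
                        section_id = "S01", seed = 42)
prof <- build_section_profiles(ground_truth_summaries(sec), sec$section)
round(unlist(prof[pial_regions()]), 1)
#>  APS  FPS  PPS  SPS  MPS  LPS  CPS
#> 29.7 71.0 49.7 39.7 27.3 15.3  8.7
classify_stage(prof)$stage
#> [1] 3
```

The mean per-field counts peak at the fimbria pial surface (71 CoA per
field, inside the 50–500 stage-3 band) and decay towards the collateral
sulcus; with lateral-ventricle deep white matter involved, the ladder
returns stage 3.

Render one fimbria field, detect and zone it:

```r
sim <- simulate_fov(sim_config(hd_intensity = 250,
                               diameter_bounds_um = c(4, 20),
                               min_separation_um = 25),
                    cal, "FPS", seed = 7)
det <- detect(sim$micrograph)            # otsu -> label -> filter
nrow(det); sum(sim$objects$in_frame)
#> [1] 22
#> [1] 22
round(unlist(summarize_fov(det, cal, "FPS")[-(1:3)]), 2)
#>             count area_fraction_pct  mean_diameter_um   min_diameter_um
#>             22.00              0.79              9.45              6.83
#>   max_diameter_um
#>             13.09

part <- zone_partition("FPS", cal)       # 100 um HD band
z <- assign_zones(det, part)
summarize_zone(z, part, "HD")$packing_density_per_mm2
#> [1] 387.3
```

All 22 ground-truth objects retained by the counting frame are detected;
the field holds 22 CoA (0.79% area fraction, mean diameter 9.45 µm), and
the HD band's packing density (387/mm²) is ~29-fold the LD zone's —
the subpial concentration the zoning is designed to measure.

`run_pipeline(run_config(...))` chains simulate → detect → quantify →
stage → stats into one seeded run that writes every table
(`objects.csv`, `fov_summaries.csv`, `zone_summaries.csv`, `stages.csv`,
`stats_grid.csv`, `hd_ld_tests.csv`) plus a manifest with MD5 hashes. A
thin command-line wrapper lives at `inst/scripts/coamap.R`.

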