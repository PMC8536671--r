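---
title: "Quantifying, zoning and staging corpora amylacea: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying, zoning and staging corpora amylacea: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

Corpora amylacea (CoA) are spherical polyglucosan inclusion bodies that
accumulate in the ageing human brain. In the hippocampal formation they are
not randomly scattered: they concentrate in a narrow band just beneath the
pial border, their density peaks at the fimbria and decays along the pial
surface in both directions, and their numbers and sizes change with age.
`coamap` implements the quantitative chain needed to study this pattern in
calibrated single-channel fluorescence micrographs: per-field measurement,
subpial zoning, whole-section staging, and the inference battery that
relates the measurements to covariates. Because no public image set
accompanies this kind of material, the package also contains a synthetic
micrograph generator with exact ground truth, so that every stage of the
chain is testable end to end.

## Fields of view and calibration

The unit of measurement is a field of view (FOV): a single-plane grayscale
image of 1600 x 1200 pixels covering 0.2 mm^2, giving a pixel side of
`sqrt(200000 / 1920000)` = 0.32275 um. `calibration()` carries this
geometry and derives the physical FOV area from it; every area and
diameter in the package is computed in physical units through it. Other
rasters are supported (the test-suite pipeline uses reduced 480 x 360 px
fields for speed), with the constraint that a subpial field must be at
least as deep as its high-density zone.

Fourteen sampling regions are distinguished: seven pial surfaces -- alveus
(APS), fimbria (FPS), prosubiculum (PPS), subiculum (SPS), medial (MPS)
and lateral (LPS) entorhinal cortex, collateral sulcus (CPS) -- and seven
neuropil regions (wall of lateral ventricle, fimbria, CA4-CA1,
subiculum).

## Detection

`detect()` composes three steps.

1. **Binarisation.** Otsu's threshold on a 256-level histogram (or a fixed
   level) separates the bright CoA discs from the dim autofluorescent
   background; the 256-level granularity is ample because the disc/background
   contrast is an order of magnitude larger than the noise. The original
   workflow rendered images black/white by hand; an automated threshold
   makes runs reproducible and is recorded in the run configuration.
2. **Labelling and measurement.** Foreground components are labelled with
   8-connectivity (diagonally touching pixels join, matching the topology
   of rasterised discs). Area is the exact pixel count times the pixel
   area; the centroid is the mean of pixel centres; the equivalent
   diameter is `2 * sqrt(area / pi)`. Feret diameters are not used; all
   size statistics in this package are equivalent diameters.
3. **Filtering.** Two rules: a minimum equivalent diameter of 3 um
   (inclusive -- the analysis detection floor), and the unbiased counting
   frame: objects intersecting the left or bottom image border are
   excluded, objects touching only the right or top border are kept. When
   adjacent fields tile a region this counts each object exactly once,
   which is what makes summed counts per unit area an unbiased density
   estimate.

Two conventions here were genuinely open and are declared rather than
derived: the 3 um bound is applied to the equivalent *diameter* (all size
results are reported as diameters), and touching CoA are *not* split by a
watershed -- no splitting rule is defined for this material, the
generator's hard-core separation keeps contact rare, and merged cases
remain measurable against ground truth.

## Per-field parameters and zoning

`summarize_fov()` computes the five per-field parameters: count, area
fraction (%), and the mean, minimum and maximum equivalent diameter. An
empty field records count 0 and area fraction 0, and those zeros enter
density analyses; its diameters are missing and never enter diameter
analyses. The "minimum diameter" of a field is the diameter of its single
smallest object (regional values then average across fields).

Subpial fields are split by `zone_partition()` into a high-density (HD)
band -- from the pial border down to a fixed depth of 100 um at the
fimbria, 70 um at the prosubiculum and 40 um elsewhere -- and the
low-density (LD) remainder. Zone membership is decided by the object
centroid, with the boundary itself belonging to the HD zone; a centroid
rule is deterministic and exactly checkable against ground truth, whereas
an overlap-fraction rule would not be. Neuropil fields have no pial border
and all their objects are LD by convention. `estimate_hd_thickness()`
implements the area-over-centre-line estimator for a traced HD polygon;
on a constant-depth band it is exact by construction. Packing density is
count per mm^2 of the zone's own area; HD/LD fold changes are ratios of
per-region means and are reported missing when the LD mean is zero.

In synthetic fields the pial border is the straight top edge; for real
curved borders the partition accepts a polyline and depth becomes
point-to-polyline distance. No geometry package for this exists among the
package's dependencies, so the shoelace area, polyline length and
point-to-segment distance are implemented directly (~30 lines, each
oracle-tested).

## Staging and the ranked sequence

A section profile is the vector of mean per-field counts in the seven
pial regions plus two spatial-extent flags (deep white matter of the wall
of the lateral ventricle; deep white matter of the parahippocampal and
fusiform gyri). `classify_stage()` walks a decision ladder from stage 4
down to stage 0; the printed density bands (0-10, 10-50, 50-500 CoA per
field) overlap at their endpoints and are resolved as half-open intervals
with boundary values going to the higher stage. "Continuous spread across
the pial surface" is operationalised as nonzero counts in both the
prosubiculum and subiculum pial surfaces -- no quantitative continuity
rule exists, so the weakest faithful reading was chosen. The flags are
*inputs* (derived from neuropil field counts), not inferred from pixels,
which keeps staging testable independently of detection.

The manual lowest-to-highest burden ranking of sections is replaced by a
computed burden score: the sum of `log1p(mean count)` over pial regions,
plus 2 for lateral-ventricle and 4 for parahippocampal/fusiform deep
white matter involvement. The log compresses the right-skewed counts so
no single region dominates; the flag bonuses order sections with equal
pial burden by spatial extent. Only the induced *rank order* is
interpreted downstream, and any strictly monotone alternative would
preserve the package's guarantees; the weights are a declared convention,
not an estimate. Ties in `rank_sequence()` are broken by section id, so
the sequence is invariant to input order.

## The inference battery

The battery mirrors a conventional SPSS-style analysis:

* **Spearman's rho** on average ranks, two-sided p from the t
  approximation `t = r * sqrt((n - 2) / (1 - r^2))`; an exact permutation
  p (full enumeration) is available for n <= 8. Pairwise deletion of
  missing diameters reproduces the per-cell n variation of the
  correlation grids.
* **Benjamini-Hochberg FDR** across all cells of one covariate's grid as
  a single family (the adjustment method and family are conventions;
  missing cells shrink the family).
* **Pooled t-tests** for HD vs LD comparisons; degenerate zero-variance
  input is guarded (equal means give p = 1, unequal means p = 0 with a
  warning).
* **One-way ANOVA** by direct sums-of-squares decomposition, with the
  pooled within-group mean square exposed for the LSD test; at k = 2 the
  F statistic equals the squared pooled t.
* **Levene's gate**: an ANOVA on absolute deviations from the group mean
  (the SPSS default; median centring -- Brown-Forsythe -- is available).
  When Levene's p exceeds the gate level, post hoc comparisons use
  Fisher's LSD; otherwise Games-Howell, i.e. pairwise Welch t statistics
  with Welch-Satterthwaite df referred to the studentized range via
  `q = |t| * sqrt(2)` (base R's `ptukey`). At k = 2 Games-Howell reduces
  exactly to the Welch t-test, which the tests verify.

A known limitation: mean-centred Levene is mildly anticonservative in
small samples; the package reports it as computed and leaves the choice
of centring to the caller.

## What the generator emulates -- and what it does not

`simulate_fov()` draws a Poisson number of CoA in the HD band (intensity
`hd_intensity` per mm^2) and in the LD remainder (`ld_ratio` times that,
default 0.1), places them uniformly with a hard-core minimum separation
of 10 um by rejection sampling, draws diameters from a lognormal with
median 9 um (sd 0.25 on the log scale) truncated to 3-30 um -- matching a
reported mean diameter near 9.1 um, observed means of 6-15 um, and mature
CoA of up to 30 um -- and stamps each disc onto the raster (a pixel
belongs to a disc iff its centre lies within the radius) at a constant
bright level over a constant background with Gaussian noise. The default
levels (background 500, noise sd 50, disc 5000 on the 16-bit scale) give
a contrast-to-noise ratio of 90; the configuration refuses settings where
the disc level is within 5 noise SDs of the background.

`simulate_section()` realises the staged spatial model through expected
per-field counts per region (`stage_targets()`): stage 1 confines CoA to
the fimbria pial surface (expected 5 per field); stage 2 extends them to
the prosubiculum and subiculum (30/22/15); stages 3 and 4 spread them
continuously along the pial border with a monotone decay away from the
fimbria (peaking at 80 and 150 per field respectively) and involve the
deep white matter (lateral ventricle at stage 3, plus
parahippocampal/fusiform at stage 4). The values sit strictly inside the
printed stage bands, at least one expected count away from every
boundary, so stage recovery is unambiguous; at the densest setting the
HD band occupancy stays near one third of the jamming density of
sequential hard-core placement, so rejection sampling terminates. Counts
are specified per standard 0.2 mm^2 field and converted to spatial
intensities, so smaller rasters scale their expected counts with area.
The parahippocampal/fusiform flag lies outside the fourteen sampled
regions and is therefore emitted directly in the section ground truth.

`simulate_cohort()` draws ages uniformly on 42-89 years and BMI on
20-42 kg/m^2, assigns stages independently of age (the deposition
sequence is modelled as age-independent), and shifts each subject's
median diameter by `age_diameter_slope` (default 0.05 um/year) around the
age midpoint -- diameters grow with age, densities do not. Three fields
per region are simulated per section; the number of fields per region is
configurable because no canonical value exists.

Deliberately **not** emulated: blood vessels and perivascular CoA,
lipofuscin or other distractor inclusions, Z-stacks (each field is one
focal plane), curved pial borders (the border is the top image edge;
the polyline interface covers real borders), and spatial clustering
beyond the hard-core constraint. Passing tests therefore demonstrate
that the chain is correct *given* bright, roughly circular, well-separated
objects on a stationary background -- they do not certify segmentation
quality on real tissue, where touching CoA, uneven illumination and
autofluorescent structures occur.

## Numerical choices and degenerate inputs

* Discs are rasterised by centre-distance thresholding; ground truth
  records both the true circle and the exact stamped pixel set (area,
  centroid, equivalent diameter, border clipping), because an object cut
  by an inclusion border is legitimately measured from its visible part.
* Object order after labelling is deterministic: first pixel in a
  row-major scan.
* Empty masks, constant images, zero-area zones, zero-length centre
  lines, all-equal groups and sub-minimum sample sizes all have defined
  behaviour (empty outputs, errors naming the cause, or guarded p
  values), exercised in the tests.
* Identical seed and configuration give byte-identical images and
  tables; every simulation entry point takes a seed.

## Problem sizes used by the test suite

The packaged checks run at sizes chosen to give stable statistics on a
single CPU: 100 rendered default-geometry fields for detection fidelity,
50 random masks against a pixel-level brute-force oracle, 200 tiled
fields on a torus for counting-frame unbiasedness, 100 fields for HD/LD
ratio recovery, 50 sections for stage recovery, 1000 random families for
the BH oracle, 2000 null replicates per test for empirical size, and one
30-subject cohort for effect-structure recovery. `scripts/acceptance.R`
recomputes all of these from scratch for any seed.
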