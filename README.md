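# sacmorph

Quantification toolkit for starburst amacrine cell (SAC) biology and the
retinal direction-selective circuit. SACs are planar, radially symmetric
retinal interneurons that tile the retina in quasi-regular mosaics,
stratify in two inner-plexiform-layer (IPL) bands, confine their synaptic
outputs to the outer third of the dendritic arbor, and drive direction
selectivity in downstream ganglion cells (DSGCs). `sacmorph` implements the
complete measurement chain used to phenotype these cells, together with
seeded synthetic-data generators so every stage can be exercised and
validated without imaging or recording data.

The package is aimed at retinal neurobiologists quantifying single-cell
morphology (SWC reconstructions), population spacing (soma coordinates),
lamination (intensity-versus-depth profiles), synaptic puncta tables, and
sorted multielectrode-array (MEA) spike counts.

## What it computes

**Single-cell morphometry** (`morphometry()`, or piecewise):

- total dendritic length, branch-point count, convex-hull field area,
  soma area, radial extent;
- Sholl profiles at fixed radius steps (default 1 µm), plus the
  radial-distance normalization that averages intersection counts over
  successive 10% spans of the cell's radial extent (10 bins);
- self-crossings of dendrites within single z-planes (`z_tol` = 0.5 µm);
- hypertrophic-dendrite classification: a cell is hypertrophic when any
  dendrite caliber (diameter) beyond the proximal 5 µm exceeds 1 µm
  (strict).

**Mosaic spacing** (`nn_regularity_index()`, `regularity_index_ratio()`,
`density_recovery_profile()`):

- nearest-neighbor regularity index `RI = mean(d_NN) / sd(d_NN)` (a Poisson
  pattern scores ≈ 1.91);
- RI ratio against the median of matched completely-random (CSR) patterns;
- Rodieck's density recovery profile with the dead-space effective radius
  `r_eff = sqrt(deficit / (π · mean density))`.

**Lamination and intensity** (`bin_lamination()`, `normalized_intensity()`):
20 equal depth sections of the IPL as intensity fractions; per-cell ROI
means normalized to background.

**Synaptic puncta** (`filter_puncta()`, `puncta_stats()`,
`compartmentalization_fraction()`): volume-equivalent-diameter filtering at
0.5 µm, distances from the soma, and the fraction of puncta in the outer
third of the arbor.

**DSGC classification** (`classify_units()`): units with ≥ 400 total
spikes get a direction selectivity index
`DSI = (P − N) / (P + N)` from preferred/null mean counts, a least-squares
von Mises tuning fit `r(θ) = b + a·exp(κ(cos(θ − µ) − 1))` with R² fit
quality, and the closed-form tuning width
`FWHM = 2·acos(1 − ln2/κ)`. A putative DSGC needs DSI > 0.37, fit
quality > 0.5, and ≥ 10 mean spikes in the preferred direction.

**Statistics** (`fisher_exact_two_sided()`, `sholl_auc_compare()`,
`group_compare()`): an exact two-sided Fisher test written from first
principles (sum-of-small-probabilities convention), Sholl area-under-curve
group comparison, and t-test / ANOVA + Tukey / Kruskal-Wallis wrappers with
mean ± SEM reporting.

**Synthetic data** (`gen_arbor()`, `gen_mosaic()`, `gen_mea_responses()`,
`gen_lamination()`, `gen_puncta()`, `gen_mea_layout()`): seeded generators
for all of the above inputs, plus `run_cohort_study()`, an end-to-end
control-versus-knockout cohort simulation.

## Worked example

Simulate one knockout-like cell, measure it, and classify simulated MEA
units:

```r
library(sacmorph)

a <- gen_arbor(n_primary = 4, target_radius = 150, branch_rate = 0.666,
               hypertrophic = TRUE, seed = 1)
m <- morphometry(a)
round(c(length_um = m$total_length, branch_points = m$n_branch_points,
        field_area_um2 = m$field_area, max_caliber_um = m$max_caliber), 2)
#>      length_um  branch_points field_area_um2 max_caliber_um
#>       34071.57         413.00       47541.73           1.50

r <- gen_mea_responses(50, frac_ds = 0.3, seed = 2)
rec <- classify_units(r)
table(rec$is_dsgc)
#> FALSE  TRUE
#>    35    15

fisher_exact_two_sided(13, 3, 1, 11)
#> [1] 0.000341006
```

The first block reports a cell with ~34 mm of dendrite, 413 branch points,
a 4.8 × 10⁴ µm² field, and a 1.50 µm hypertrophic dendrite (above the 1 µm
threshold). The classifier recovers the 15 direction-selective units among
50 simulated ones, and the Fisher test on a 13/16-versus-1/12 contingency
gives p = 0.000341, printing as 0.0003.

## Package layout

- `R/` — generators (`gen_*`), morphometry, mosaic statistics, lamination
  profiles, puncta analysis, DSGC classification, statistics, cohort
  orchestration.
- `tests/testthat/` — unit, property and acceptance tests with brute-force
  oracles (sphere-crossing enumeration, all-pairs intersection and DRP
  histograms, Fisher enumeration).
- `vignettes/sacmorph-methods.Rmd` — the models, parameters, numerical
  conventions and limitations.
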