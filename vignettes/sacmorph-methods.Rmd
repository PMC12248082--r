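---
title: "Models and methods behind sacmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sacmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sacmorph)
```

`sacmorph` quantifies starburst amacrine cell (SAC) biology along five
axes — single-cell dendrite morphometry, mosaic spacing, IPL lamination,
synaptic puncta compartmentalization, and direction-selective ganglion
cell (DSGC) classification — and pairs every analysis with a seeded
generator that produces inputs with the statistical structure the analysis
assumes. This vignette records the models, the parameters that matter, the
numerical conventions, and the known limits of what the synthetic data can
show.

## The synthetic arbor model

Reconstructed SACs are near-planar trees with a handful of primary
dendrites leaving the soma at roughly even angles and terminating near a
common rim. `gen_arbor()` emulates this with a biased random walk per
primary dendrite: at each step of `step_len` µm the heading picks up
Gaussian wiggle (SD 0.3 rad) and is then blended with the outward radial
unit vector with weight `radial_bias` (default 0.7; 1 grows straight
radial spokes, 0 a free planar walk capped at a step budget). Growth stops
when the path reaches `target_radius`, with the final step clipped onto
the rim, so branch tips never exceed the target radius.

Branching is a Poisson process along each primary path: each step draws
`rpois(branch_rate * step_len)` events at uniform positions within the
step, each event becoming an interior node that spawns a side branch. Side
branches deflect by 0.4–1.0 rad, grow by the same walk, terminate at the
rim, and do not branch again. This first-order branching scheme is a
deliberate choice: if both daughters kept branching, the expected number
of branch points would grow exponentially with `branch_rate × radius`
(a supercritical branching walk), whereas with terminal side branches the
expected branch-point count is exactly `branch_rate` times the summed
primary path length. Branch counts therefore scale linearly with
`branch_rate` — doubling the rate doubles branching while the convex-hull
field area, pinned by `target_radius`, stays put. That is precisely the
dissociation (more branch points, unchanged field) that makes the
control/knockout contrast interesting, and it makes the generator's rate
parameter directly interpretable as branch density per µm.

Caliber tapers linearly from `caliber_taper[1]` (default 0.8 µm) at the
soma to `caliber_taper[2]` (0.3 µm) at the rim, so a healthy cell never
trips the 1 µm hypertrophy threshold. With `hypertrophic = TRUE` one
randomly chosen primary carries a proximal-half diameter drawn uniformly
from 1.2–2.0 µm; only the exceedance threshold (1 µm) is established for
real cells, so the distribution above it is a modeling choice. Out-of-plane
structure is per-node Gaussian z jitter (`z_jitter_sd`, default 0.5 µm) —
a flat-plane approximation of a gently undulating arbor.

Genotype presets (`genotype_preset()`): the control preset uses 4
primaries, a 150 µm radius, and `branch_rate = 0.333`/µm, which lands near
200 branch points per cell; the knockout-like preset doubles the branch
rate and draws a hypertrophic dendrite with probability 0.8. These are
qualitative presets that mirror the *direction* of the reported dendrite
phenotypes, not fitted magnitudes.

## Morphometry conventions

* **Total length** sums parent-to-child Euclidean segment lengths,
  excluding soma-internal segments (both endpoints typed soma). The
  soma-to-first-dendrite stem does count.
* **Branch points** are dendrite nodes with ≥ 2 children; the soma never
  counts, however many primaries it bears.
* **Sholl profiles** use spheres in 3-D centered on the soma centroid,
  radii at fixed steps (1 µm default). A segment crosses radius `r` when
  its endpoint distances straddle `r`, and an endpoint exactly at `r`
  counts as *outside* — one fixed boundary rule so a crossing at a node is
  never double-counted. SAC arbors are near-planar, so 2-D versus 3-D
  spheres differ negligibly, but the 3-D rule is stated for determinism.
  The normalized profile averages counts over ten successive 10% spans of
  the cell's radial extent (the maximum node distance from the soma
  centroid); empty bins report 0.
* **Self-crossings** count unordered pairs of non-adjacent segments whose
  xy projections properly cross with interpolated z values within `z_tol`
  (default 0.5 µm, emulating a single confocal z-plane; exposed because
  stack spacing varies between datasets). Pairs sharing a node are
  branching, not crossing, and are excluded. The implementation buckets
  segments on a grid at least one segment length wide, so only same- or
  adjacent-cell pairs are tested; tests verify exact agreement with an
  all-pairs oracle.
* **Hypertrophy** takes the maximum diameter over dendrite nodes farther
  than 5 µm from the soma center (so the somatic taper cannot trigger the
  rule) and applies a strict `> 1 µm` comparison: a caliber of exactly
  1 µm is not hypertrophic.
* **Degenerate geometry**: the convex hull needs three non-collinear
  dendrite nodes; the soma area falls back to the largest nodal disc when
  fewer than three soma nodes (or a collinear outline) are present.

## Mosaic statistics

The nearest-neighbor regularity index is `mean(d_NN)/sd(d_NN)` with the
n−1 SD. For a Poisson process the Rayleigh nearest-neighbor law gives
≈ 1.91; hard-core mosaics score higher. Because the index drifts with
intensity and edge effects, the regularity index *ratio* divides by the
median index of matched CSR patterns (same n, same window, default 99;
seeded), reproducing the "compared to a random distribution"
normalization of mosaic tooling whose exact formula is not public — the
ratio ≈ 1 for CSR input and exceeds 1 for regular mosaics.

The density recovery profile follows Rodieck's construction with border
correction by restriction: only points at least `max_radius` from every
window edge serve as reference points, every ordered (reference, other)
pair is binned by distance, and annulus densities divide counts by
`n_ref × annulus area`. The effective radius converts the central deficit
into the radius of an equivalent hard step,
`r_eff = sqrt(deficit/(π·D))`, accumulating the deficit from zero up to
the first annulus at or above the mean density `D`. With an ideal
hard-core pattern at exclusion `dmin`, the deficit equals `π·D·dmin²` and
`r_eff → dmin` within a bin width.

`gen_mosaic()` produces both regimes: dart throwing (random sequential
placement) below its jamming density (~55% disc coverage), and, for
denser requests, a perturbed triangular lattice at pitch `1.005 × dmin`
randomized by hard-core Metropolis relocation moves (30 sweeps per
point). Near-jamming patterns therefore retain lattice-like order — they
are valid hard-core configurations but not samples of the equilibrium
Gibbs process; at the densities used in tests and demonstrations this
distinction is immaterial to the statistics above.

## Lamination and intensity profiles

`bin_lamination()` divides normalized IPL depth into 20 equal sections
and reports intensity *fractions* (sum 1), making sections of different
absolute thickness and staining strength comparable. Section `k` collects
samples in `((k−1)/20, k/20]` with depth 0 assigned to section 1. Depth
orientation is a convention (0 and 1 are the two IPL borders); profiles
symmetric about mid-depth bin symmetrically. The synthetic generator
places Gaussian bands at configurable depths — defaults 0.3 and 0.7
stand in for the two SAC bands (S2/S4), whose true numeric depths are not
pinned down; treat the defaults as placeholders, not anatomy. A
`band_concentration()` summary (fraction of intensity within ±1 bin of
the two non-adjacent profile peaks) turns binned profiles into a scalar
for group comparison; all-zero profiles raise an error rather than
dividing by zero.

## Puncta quantification

Puncta are filtered by volume-equivalent sphere diameter
`d = (6V/π)^(1/3)` with strict exclusion below 0.5 µm (a punctum exactly
at 0.5 µm stays). Whether the original size cut was diameter- or
volume-based is not recoverable, so the diameter reading is the package's
documented convention, overridable via `min_diameter`. Distances from the
soma are straight-line Euclidean (not path length along the dendrite —
a known limitation listed below), normalized by the parent arbor's radial
extent and clipped at 1.05 with clip events counted.
`compartmentalization_fraction()` reports the fraction beyond a boundary
(default 2/3: the outer third). The generator places puncta uniformly per
unit dendritic length beyond `inner_boundary`, so generator and analysis
agree by construction at the boundary.

## DSGC classification

The pipeline is count-based and stimulus-agnostic: per-epoch spike counts
for evenly spaced directions (an even count, default 12 at 30°, so an
exact opposite direction always exists). Steps, with their threshold
conventions:

1. **Spike floor**: units below 400 total spikes are dropped (inclusive
   at 400: "a minimum of" reads as ≥).
2. **DSI**: preferred direction is the argmax of per-direction mean
   counts (ties break toward the smaller angle, for determinism), null is
   its opposite, `DSI = (P−N)/(P+N)`.
3. **Tuning fit**: least squares of
   `r(θ) = b + a·exp(κ(cos(θ−µ)−1))` on the per-direction means, with
   amplitude and κ parameterized on the log scale (keeping both
   positive) and Nelder-Mead multi-start — µ seeded at every observed
   direction × two κ starts, best SSE wins, deterministic start order.
   Fit quality is R² about the mean of means; a flat cell (zero variance)
   is defined to have quality 0 and κ = 0 rather than erroring.
4. **Classification**: DSI > 0.37 and fit quality > 0.5 (both strict,
   "greater than") and mean preferred-direction spikes ≥ 10 (inclusive).
   Failing units are recorded with a reason code; a batch never aborts.
5. **Tuning width**: `FWHM = 2·acos(1 − ln2/κ)` in degrees for
   κ ≥ ln2/2; flatter curves never fall to half amplitude and report
   360°. Tests pin the closed form against numeric root finding to
   < 0.1°.

The response generator draws Poisson counts at
`epoch_dur × (baseline + amplitude·exp(κ(cos(θ−µ)−1)))` for
direction-selective units (µ uniform over the direction set) and at the
baseline for the rest, keeping ground-truth labels alongside so
classification sensitivity and specificity can be measured directly.

## Statistics layer

The exact two-sided Fisher test enumerates all 2×2 tables with the
observed margins via log-factorials and sums the probabilities of tables
no more probable than the observed one (relative tie tolerance 1e-7).
This sum-of-small-probabilities convention is the one that reproduces the
canonical contingency result used in the package's demonstration
(13/16 versus 1/12 → p = 0.000341, printing as 0.0003); mid-p and
tail-doubling conventions would differ and are intentionally not offered.
Group comparisons delegate to the standard machinery: pooled-variance
Student's t by default (Welch by flag), one-way ANOVA with Tukey HSD, and
Kruskal-Wallis with tie correction; summaries are mean ± SEM. Sholl
profiles are compared per cell by trapezoidal area under the 10
normalized bins against bin midpoints, then a t-test on per-cell AUCs.

## The cohort demonstration

`run_cohort_study()` chains the pieces: generate `n` control and `n`
knockout-preset arbors, measure each, compare groups, and run the Fisher
test on the hypertrophic contingency. One master seed governs a run;
per-cell child seeds come from a fixed linear-congruential splitting
rule, so any cell regenerates in isolation and two runs of one
configuration are byte-identical (reports carry no timestamps).
Hypertrophic counts can be forced exactly (for reproducing a printed
contingency deterministically) or drawn per cell from the preset
probability.

## Problem sizes and numerical choices

Simulation-based checks in the test suite use: 200 seeds × 500 points for
CSR regularity-index calibration; 2000-point windows for DRP flatness
(with the double-counting variance factor of 2 in the standard-error
bound, since each unordered interior pair enters the ordered-pair count
twice); 1500-point hard-core patterns for effective-radius recovery; 200
units × 5 epochs for classifier label recovery; 500 noisy units at 50
epochs for von Mises µ recovery; 100 random arbors against the Sholl
oracle and ~300-segment arbors against the all-pairs crossing oracle.
These sizes give stable statistics at interactive runtimes and are stated
here as the package's chosen study conditions.

Tolerances worth knowing: float rounding of clipped branch tips makes
crossing counts at exactly the radial extent boundary-sensitive (interior
radii are exact); the von Mises fit recovers noiseless parameters to
1e-3; the MEA layout builder allows 0.5% slack on the quoted array span
because published array dimensions are rounded (a 64 × 60 µm grid of
21 µm electrodes is 3801 µm, quoted as 3.8 mm).

## What passing tests do and do not show

The generators reproduce the *statistical structure* the analyses assume:
radially symmetric planar trees, hard-core point processes, von
Mises-modulated Poisson spiking, Gaussian lamination bands,
distally-biased puncta. They do not reproduce image noise, tracing
errors, spike-sorting contamination, fasciculation, or the
self-avoidance/tiling interactions of real SAC dendrites. Passing the
suite therefore certifies the measurement chain — given clean,
well-formed inputs the quantities are computed correctly — not that any
biological claim holds. Distances to puncta are Euclidean rather than
along-arbor; cross-population (two-mosaic) correlograms and spike-time
(as opposed to count) analyses are out of scope.
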