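---
title: "Donor-space anomaly detection for small-cohort proteomics"
author: "evanomaly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Donor-space anomaly detection for small-cohort proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evanomaly)
```

## The problem

Label-free quantification experiments on primary cells often have very few
biological replicates — three donors in the motivating extracellular-vesicle
(EV) study, where mesenchymal stromal cells were cultured on bioactive glass
discs doped with silver, copper or tellurium ions. With n = 3 per group, a
t-test has little power, single observations dominate every estimate, and
proteins whose behavior is genuinely unusual may sit nowhere near the
significance threshold. `evanomaly` implements a descriptive alternative:
instead of testing mean differences, it asks which proteins *move the most*
between conditions when each protein is represented by its actual per-donor
measurements.

The key construction is **donor space**: for D donors, each protein in each
condition is a point in D dimensions whose coordinates are the log
abundances of that protein in each donor. Because the same donors are
measured in every condition, a protein's displacement between two
conditions is a straight-line (Euclidean) distance between paired points,
and donor identity cancels out of the displacement.

## The procedure

For each comparison (reference condition vs treatment condition) the
pipeline runs four stages:

1. **Log transform.** Raw peak areas span orders of magnitude; the log
   compresses the dynamic range so geometry is not dominated by a few very
   abundant proteins. Base 2 is the default so that downstream log fold
   changes read in doublings; the choice of base only rescales all
   coordinates (and is recorded in the output), so it never changes which
   proteins are flagged — a property the test suite asserts via scale
   equivariance of the threshold.
2. **Density filter (OPTICS).** All donor-space points from all conditions
   are pooled and ordered with OPTICS; flat clusters are extracted at a
   radius `eps` (DBSCAN-equivalent extraction), and only the primary
   cluster is kept. This restricts the analysis to the dominant population
   of proteins with similar, cleanly measured expression, and discards
   secondary clouds — e.g. populations near the detection floor or with
   non-positive peaks — that represent different regimes of the
   measurement process.
3. **Isolation forest.** Within each condition, every retained point is
   scored by how easily random axis-parallel splits isolate it. Points
   isolated in few splits are extremes of the per-condition point cloud;
   the top `contamination` fraction per condition is kept, and a protein
   is eligible if it is an outlier in *either* condition of the comparison
   (a protein extreme in just one condition can still move far).
4. **Displacement threshold.** For eligible proteins the per-protein
   displacement d is computed and thresholded at
   `tau = mean(d) + k * sd(d)` over the whole eligible set; proteins
   strictly above tau are reported as *extremely changing*. Under
   normality about 68% of values lie within one SD of the mean, which is
   the intuition behind the default k = 1.

The descriptive layer then attaches, per reported protein, the two-sample
t-test p-value and its tier (`sig` p < 0.05, `marginal` 0.05 ≤ p < 0.1,
`ns` otherwise), the log fold change (difference of mean log abundances),
the within-group variance and coefficient of variation per condition, and
the absolute variance difference. Across biomaterials, Venn region counts
summarize which extremely changing proteins are shared; within a
comparison, a quadratic fit of d against logFC summarizes the expected
U-shaped relation (movement grows with fold change in either direction).

```{r example, eval = FALSE}
gt <- generate_table(synthetic_spec(seed = 1))
run <- run_pipeline(gt$table, comparison_spec("ctrl", "doped"), seed = 1)
run$comparisons$ctrl_vs_doped$anomaly_set
```

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `log_base` | 2 | — | logFC reads in doublings; any base gives the same flags |
| `min_pts` | 50 | points | core-point neighborhood size used on the motivating three-donor table; at a few hundred proteins per condition it demands clusters of substantial size |
| `eps` | derived | log units | extraction radius; see below |
| `n_trees` | 500 | trees | Monte-Carlo error of the isolation score is negligible at this depth; duplicated points score identically |
| `subsample` | 256 | points | standard isolation-forest subsample; clamped to n with a warning |
| `contamination` | 0.10 | fraction | per condition, roughly the visually colored minority of a three-donor scoring plot; eligibility, not the final call |
| `k` | 1 | SDs | the published cut-off; exposed because the cut-off level may reasonably be adjusted |
| `sd_ddof` | 1 | — | sample SD, the small-n convention used throughout the variance tables |

**The extraction radius.** The radius 0.05 used by the motivating study
(kept as the default of `extract_clusters()`) is tied to the scale of that
study's log-abundance matrix. On any other table `run_pipeline()` derives
a radius with `suggest_eps()`: twice the 0.99 quantile of the per-point
distance to the `min_pts`-th nearest neighbor. The rationale is that the
radius must *admit the sparse tail of the primary cluster* — the extreme
points there are exactly the anomaly candidates the later stages score —
while staying well below the separation between expression regimes.
A radius near the typical neighbor distance would trim the tail and
silently remove true anomalies before they were ever scored.

**Cluster selection and membership.** The primary cluster is the most
populous one whose member points have strictly positive raw peak areas in
all donors (falling back to plain size with a warning), formalizing the
idea that the retained population is the cleanly measured one. A protein
enters a comparison only if its points lie in the primary cluster in
*both* conditions, so no displacement mixes a filtered point with an
unfiltered one; `membership = "either"` relaxes this.

## The synthetic generator

The paper-scale data behind the motivating study are not publicly
deposited, so the package ships a generator whose defaults describe a
realistic three-donor label-free experiment:

* log2 peak areas around 20 with a between-protein SD of 0.5 — the
  generator emulates the *density-selected homogeneous cluster* the
  pipeline operates on after filtering, not a whole proteome, whose
  between-protein spread would be far larger;
* global per-donor offsets with SD 0.5 (donor effects shift all points
  rigidly and cancel from displacements);
* per-cell noise SD 0.4 log2 units, i.e. roughly 30% CV, a typical
  replicate-level figure for label-free quantification;
* 2% planted anomalies shifted by six noise SDs (2.4 log2 units, random
  sign) in the doped condition only, mirroring the design assumption that
  expression changes against the matched control are attributable to the
  doping;
* a 20% contaminant cloud offset by −10 log2 units — about three orders
  of magnitude lower raw abundance, near the detection floor — which the
  density filter must reject.

For null proteins the displacement has a closed form (`noise_sd * sqrt(2)`
times a chi-distributed factor; `expected_null_distance()`), giving an
analytic anchor for the simulation tests. The tested properties — recall
of at least 0.9 for planted anomalies over five seeds at 500 proteins,
at least 95% contaminant exclusion, and agreement of the mean null
displacement with the closed form within 2% at 2000 proteins — are the
problem sizes the acceptance checks use throughout.

What the generator does **not** emulate: missing-value mechanisms of
match-between-runs, intensity-dependent noise, correlated protein
modules, isotope or acquisition artifacts. Passing the recovery tests
therefore shows the pipeline's stages compose correctly and detect
planted multiplicative shifts above the noise floor; it does not certify
performance on real matrices with structured missingness.

## Numerical choices and degenerate inputs

* **Determinism.** OPTICS breaks queue ties by (reachability, input
  index); the forest takes an integer seed and restores the caller's RNG
  state; one pipeline seed fans out to fixed per-condition seeds. Two
  runs with the same inputs are byte-identical on disk (no timestamps).
* **Neighborhood convention.** The core distance is the distance to the
  `min_pts`-th nearest *other* point; the point itself is not counted.
* **Border points.** Extraction walks the OPTICS ordering; a leftover
  point that still has a core point within `eps` is attached to its
  nearest core's cluster, so the result matches a direct DBSCAN run up to
  the border-point ambiguity DBSCAN itself leaves open.
* **Ties at the threshold.** `d > tau` is strict: a protein exactly at
  the threshold is not flagged.
* **Zero variance.** A t-test on two constant equal groups returns p = 1;
  constant unequal groups return the p = 0 limit with a warning. A zero
  mean makes the CV undefined (`NA`). Constant distances give sd = 0,
  tau = d, and an empty flag set.
* **Non-positive peak areas** cannot be log-transformed; the default
  policy drops the protein (treating it as not analyzable rather than
  imputing), with per-cell blanking and epsilon-flooring as alternatives.
  Every removal is recorded with a reason.
* **Missing values.** A protein with an incomplete donor vector in a
  condition emits no point there and is excluded from comparisons
  touching that condition; nothing is imputed.
* **Quadratic fit.** Ordinary least squares via `lm()`; all-equal x is a
  rank-deficiency error, constant y has R² defined as 0.

## Known limitations

* The Euclidean metric is the right notion of displacement for three
  coordinates; for large cohorts a different metric may be preferable, as
  high-dimensional distances concentrate.
* The mean + k·SD threshold is a single global rule; visible gaps in the
  sorted-distance profile may suggest protein-specific judgments that the
  package intentionally does not automate.
* Flagged proteins are *descriptively* extreme, not statistically
  significant: the t-test tiers are reported alongside precisely because
  the two notions can disagree, and the pipeline is meant to accompany,
  not replace, inference.
* With only three donors, the within-group variance and CV columns are
  themselves noisy; they are reported to guide interpretation, not to
  rank proteins.
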