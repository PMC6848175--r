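---
title: "Statistical methods for subcortical connectome group analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for subcortical connectome group analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`subconn` analyses structural connectomes over 18 subcortical regions: for
each subject a symmetric, nonnegative 18 × 18 matrix whose entry (i, j) is
the number of tractography streamlines (NOS) connecting region i and region
j. This vignette documents the statistical model, the tunable parameters and
their defaults, what the synthetic generator does and does not emulate, and
the numerical and design choices a user should know before trusting a
result.

## Data model and filtering

The atlas (`subcortical_atlas()`) fixes a canonical region order — the
FreeSurfer `aseg` listing, left hemisphere before right — and thereby a
canonical flattening of the 153 undirected edges (`edge_index()`,
`edge_flatten()`). Matrix CSV files carry ROI-label headers and are validated
by label, not position, when read back.

Directed streamline counts are symmetrized by summation:
`out[i, j] = raw[i, j] + raw[j, i]`. Probabilistic tractography produces
spurious low-count connections, so an edge enters analysis only if its NOS is
strictly positive in at least half of the subjects, pooled across groups
(`apply_detection_filter()`, `min_fraction = 0.5`). "Detected" means NOS > 0:
zero streamlines is the only natural absence criterion at the subject level.
The filter is computed once on the pooled sample, because group-specific
filters would make the tested edge set depend on the hypothesis being tested.
The number of surviving edges is reported (`n_tested`) rather than assumed to
be 153.

For display, `edge_zscore_summary()` standardizes each edge across all
subjects pooled (so group differences remain visible in the standardized
scale) and averages over an edge set; zero-variance edges are excluded with a
warning.

## Edge-wise GLM and permutation inference

For each edge, the group effect is the partial F statistic of the group
factor in a general linear model with nuisance covariates (gender by
default):

$$F = \frac{(\mathrm{RSS}_0 - \mathrm{RSS}_1)/(k-1)}{\mathrm{RSS}_1/(N-p)}$$

where model 1 contains intercept, group indicators and covariates, and model
0 omits the group indicators. With no covariates this is the one-way ANOVA
F; it is invariant under affine rescaling of the response, so raw streamline
counts and rescaled counts give identical statistics.

Significance comes from Monte-Carlo permutation: group labels are shuffled
while covariate values stay attached to their subjects, and
$p = (b + 1)/(m + 1)$ with `b` the number of permuted statistics at least as
extreme as the observed one. The +1 convention avoids exactly-zero p-values
and makes the attainable floor `1/(m + 1)`; with the default m = 10000 the
floor is about 1e-4. Simple label permutation (rather than Freedman–Lane
residual permutation) is the default because it is transparent, exactly
enumerable on small samples (`permutation_p(..., exact = TRUE)`), and valid
here: the covariate is a covariate of no interest, not a confounder of the
permuted factor, in the default generator. A permuted label vector can by
chance be collinear with a covariate; the pivoted QR then absorbs the group
effect and that draw contributes F = 0 rather than an error.

Multiplicity is controlled by Benjamini–Hochberg FDR (`bh_fdr()`, wrapping
`stats::p.adjust`) at q = 0.05 across all tested edges, and across the pair ×
edge family for post-hoc contrasts (`pairwise_posthoc()`, covariate-adjusted
two-group t with two-tailed permutation p).

## Threshold-free enhancement over graph components

Rather than choosing a single cluster-forming threshold (as classical
network-based statistics requires), each edge's F is replaced by

$$\mathrm{score}(e) = \sum_{h} e_h(e)^{E} \, h^{H} \, \Delta h$$

summed over an equally spaced threshold grid, where the *extension*
$e_h(e)$ is the number of edges in the connected component containing `e`
among edges with statistic ≥ h (and 0 below threshold). Components are taken
over nodes joined by suprathreshold edges; extension counts component
*edges*, the network-based-statistics notion of cluster size. Strong effects
that are topologically clustered are amplified relative to isolated spikes
of the same height.

Parameter choices:

* **Exponents** `E = 0.5`, `H = 3.0`. These follow the threshold-free
  cluster-enhancement literature for edge statistics; both are configurable,
  and results at the defaults define this package's reference behavior. With
  `H = 3`, an isolated edge with statistic `s` has the closed-form limit
  `s^4/4` as the grid refines — the test suite recovers it to 0.1% at 1e5
  steps.
* **Grid**: 100 equal steps from 0 (exclusive) to the maximum observed
  statistic, recomputed per permutation from that permutation's own maximum
  (`grid_max = "adaptive"`). A self-scaling grid keeps the discrete integral
  comparable across permutations whose F ranges differ; a fixed shared
  maximum (`grid_max = <number>`) is available for studies of the grid policy
  itself. Under the adaptive grid, multiplying all statistics by c > 0
  multiplies every score by exactly c^(H+1).
* **Ties**: thresholds are closed (statistic ≥ h), applied with a relative
  tolerance of 1e-12 × grid maximum so a statistic lying exactly on a grid
  point (always true of the maximum) cannot drop out through floating-point
  rounding.
* **Null and correction**: each edge's p-value compares its observed score
  with its *own* permutation distribution, followed by FDR — not a
  max-statistic FWE correction — because edge-wise FDR-corrected p-values are
  the reporting convention this package follows. A consequence worth knowing:
  enhancement couples neighboring edges, so a null edge adjacent to a true
  component inherits part of its extension, and the FDR-significant set can
  contain such hangers-on. The calibration test under the global null shows
  no such inflation (the coupling needs true signal); on signal-bearing
  synthetic cohorts the significant set typically contains the ten seeded
  edges plus zero to a few adjacent ones.

The per-threshold component sweep is the computational hot spot
(permutations × thresholds × edges); it is implemented in C++
(union-find) while `suprathreshold_extension()` provides an independent
igraph-based R surface used by the test oracles.

## Synthetic cohorts

Subject-level imaging data are not redistributable, so the generator
produces cohorts with the statistical structure the analysis assumes, from
published group summary statistics:

* Three groups at the study sizes HC 54, PD 65, MSA 31, with the study's
  male/female splits (26/28, 48/17, 19/12) assigned deterministically by
  largest-remainder rounding.
* Ten edges carry group-specific normal NOS distributions with the published
  per-group means and SDs (`nos_group_params()`; units: streamlines, on the
  1e6 scale of the source tables). They involve the putamen, pallidum,
  ventral diencephalon, thalamus and cerebellar white matter, bilaterally,
  with MSA lowest on every edge.
* The remaining 143 edges share one group-invariant parameterization, mean
  1.0e6 and SD 0.25e6 — invented values chosen once to match the magnitude of
  the published edges, so that any detected group signal must come from the
  ten seeded edges.
* Values are drawn from normals truncated below at zero by inverse-CDF
  sampling, because streamline counts cannot be negative. Empirical means
  therefore match the *truncated* target mean, which differs noticeably from
  the untruncated mean only where the floor is within ~1.5 SD of it — in
  practice the weak ventral-diencephalon–contralateral-cerebellum edge, where
  the MSA parameters put ~13% of the normal mass below zero.
* Edges are sampled independently: the source tables publish only marginal
  means and SDs, so no covariance can be honored. An `equicorrelation`
  option adds a common within-subject correlation for robustness
  experiments (then sampling falls back to correlated normals censored at
  the floor, trading exact marginal truncation for the requested
  dependence).
* Gender is generated but has no edge effect by default, so covariate
  adjustment is exercised under the null; `gender_effect` (in SD units)
  simulates a genuine confound.

What passing tests on these cohorts show: the chain detects effects of the
published size and direction at the published sample sizes, controls its
error rates under the null, and never leaks test subjects into training.
What they cannot show: behavior under the dependence, skewness, site effects
and detection-filter censoring of real tractography counts — real NOS are
integer, right-skewed and strongly correlated between edges sharing a
region. The generator's published F statistics are *not* targeted: one-way
ANOVA on the published means/SDs/ns does not reproduce the published
per-edge F values (e.g. the left pallidum–putamen edge gives ≈ 15 versus a
published 5.2), so whatever transformation produced those table statistics
is unstated, and the generator is parameterized by means/SDs only.

## Nested leave-one-out classification

`loocv_classify()` implements the nested scheme: for each of N folds, the
held-out subject is removed *before anything else happens*. On the N−1
training subjects: (1) the TFNBS two-group comparison selects the
FDR-significant edges; if none pass, the `k_fallback = 10` edges with the
highest enhanced scores are used (the fallback is this package's choice —
some behavior must be defined when a fold selects nothing); (2) recursive
feature elimination ranks features by repeatedly refitting a linear SVM at
C = 1 and dropping the smallest squared weight, and the retained size is the
one maximizing stratified 5-fold inner-CV accuracy, ties toward fewer
features; (3) the SVM cost is grid-searched over 10^(−3..3) by the same
inner CV, ties toward the smallest cost (the widest margin); (4) the tuned
model predicts the held-out subject. Features are standardized with
training-fold statistics only — required for comparable penalization across
edges spanning orders of magnitude, and restated on the held-out subject
using the training parameters.

Reported metrics: raw accuracy (correct/total), sensitivity (MSA recall),
specificity (recall of the comparison class), and balanced accuracy (their
mean). Balanced accuracy is the reference summary: with 31 MSA versus 65 PD
the raw accuracy of a degenerate always-PD classifier would be 0.68, and the
per-contrast summary tables this package mirrors are arithmetically
consistent with the balanced definition.

Feature stability is reported at two stages: `stage1_stability` (how often
an edge survives the within-fold TFNBS selection) and `stability` (how often
it survives RFE into the final model). On synthetic cohorts at the study
conditions, the strong seeded edges are stage-1-stable in essentially all
folds, while the weakest seeded effects (standardized differences near 0.4)
fall below the attainable BH threshold inside folds and are selected
intermittently — stability claims should be read against effect size.
Within folds the selection TFNBS runs 1000 permutations by default
(configurable): the BH cutoff for ~10 discoveries among 153 edges is ~3e-3,
so the permutation floor must lie below it, and 1000 is the smallest round
count that satisfies this with headroom at tractable cost.

Scalar per-ROI features (FA, MD, volume) flow through the same pipeline with
stage 1 replaced by a per-feature permutation GLM F with FDR; multimodal
combinations concatenate standardized feature blocks before RFE.

## Numerical choices and degenerate inputs

* Constant responses give F = 0 (a 0/0 resolved to "no signal"), and
  permutation p = 1.
* Zero-variance features are dropped from standardization; a fold whose
  selected features are all constant errors out rather than guessing.
* Exact permutation enumeration is available for n ≤ 8 and is the oracle
  against which the Monte-Carlo path is tested.
* All randomness flows from explicit seeds; per-fold sub-seeds make folds
  reproducible independently of execution order, and reruns of
  `run_pipeline()` with the same configuration and seed are byte-identical.

## Problem sizes used in the test suite

Property tests run on 5-node graphs (against brute-force component oracles)
and cohorts of 10–30 subjects; the parameter-recovery and classification
tests run one full-size cohort (150 subjects) with 10000 omnibus
permutations and 1000 within-fold permutations respectively. These sizes
were chosen to exercise the full-scale code paths once while keeping the
default test run short.

## Known limitations

* Edge-wise FDR after enhancement is approximate under signal (see above);
  a max-statistic FWE mode is deliberately out of scope.
* The generator cannot validate robustness to the dependence structure of
  real tractography counts, only to the marginal structure it models.
* LOOCV has high variance relative to k-fold schemes; with 31 subjects in
  the smallest group, per-fold metrics move in steps of 1/31.
* The published per-edge F values are not reproducible from the published
  summaries and are not targeted anywhere.
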