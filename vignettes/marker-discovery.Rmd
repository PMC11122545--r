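---
title: "Methods: qPCR marker discovery for ustekinumab response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: qPCR marker discovery for ustekinumab response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uskit)
```

## The problem and the data

Ustekinumab blocks the p40 subunit shared by IL-12 and IL-23, but only
roughly half of ulcerative colitis patients reach clinical remission
within six months. The pipeline in this package looks for baseline
mucosal expression markers that distinguish eventual responders from
non-responders, starting from threshold-cycle (Ct) values of an 84-gene
inflammatory-response qPCR array plus five housekeeping genes (ACTB,
B2M, GAPDH, HPRT1, RPLP0). A Ct value is the PCR cycle at which a well's
fluorescence crosses threshold; expression is proportional to `2^-Ct`,
so *lower* Ct means *higher* expression. Response labels (clinical
remission: total Mayo score ≤ 2 with no subscore > 1 at six months) are
taken as given.

## Differential expression by ΔΔCt

Within each sample, `ΔCt(g) = Ct(g) - mean(Ct over housekeeping genes)`
and relative expression is `2^-ΔCt`. Using the arithmetic mean of
housekeeping Ct values equals dividing expression by the geometric mean
of the housekeeping expressions — the convention of the standard array
analysis software. Any per-sample global shift (pipetting efficiency,
input amount) cancels exactly; this invariance is asserted as a test.

The fold change of gene *g* is the ratio of group means,

    FC(g) = mean over non-responders of 2^-ΔCt  /  mean over responders,

with responders as the control group, and is reported as the **fold
regulation**: `FC` when `FC ≥ 1`, otherwise `-1/FC`, so a 24.3-fold
down-regulation prints as −24.3. Significance uses a two-sided
pooled-variance Student's t-test on the per-sample `2^-ΔCt` values
(`var_equal = FALSE` switches to Welch). Two flags are set per gene:
`significant` at nominal `p < 0.05` and `dysregulated` at
`|fold regulation| ≥ 2`. Candidate genes for the network stage are the
dysregulated set plus any forced inclusions (`select_candidates()`).

Deliberate conventions, chosen to match how the vendor software defines
the method, each configurable:

* group means are taken *before* the ratio (not a mean of per-sample
  ratios);
* the t-test pools variances (the software's equal-variance test);
* no multiple-testing correction by default — the method reports nominal
  per-gene p-values; `p_adjust = "BH"` is available;
* degenerate zero-variance genes give `p = 1` when the group means agree
  and the smallest positive double (with a warning) when they differ.

A `log2(1/ΔCt)` display transform is available in `plot.dgea()` because
some array reports draw expression figures on that scale; it is
dimensionally odd (most likely a shorthand for `2^-ΔCt` on a log axis)
and is never used in any computation.

## Co-expression networks and centrality

Correlation method selection is *normality-gated*: a Shapiro–Wilk test
per gene per group at α = 0.05 selects Spearman if any gene in any group
rejects normality, else Pearson. Constant genes cannot be tested and
count as non-normal with a warning. In practice `2^-ΔCt` values are
log-normal-like and the gate selects Spearman. Because the rank
correlation is invariant under per-gene monotone transforms, it is
identical whether computed on `2^-ΔCt` or on ΔCt (asserted as a test).

Within each response group separately, the candidate genes are
correlated against the full panel. Edges keep pairs with `|rho| > 0.9`
(strict by the stated filter wording; an inclusive flag exists) with the
signed correlation retained as an edge attribute. Nodes are the genes
incident to at least one surviving edge — genes without strong
correlations drop out, so the graph order itself reflects co-expression
activity.

Centralities are computed on the **unweighted** thresholded graph:
degree centrality (DC) is the integer number of co-expression partners
(hubs), and betweenness centrality (BC) is exact shortest-path
betweenness normalized by `(n-1)(n-2)/2` with `n` the graph order
(bottlenecks), giving values in [0, 1]. Published DC values for such
networks are integers and BC values fall in [0, 1], consistent with
unweighted normalized conventions; using `|rho|` as a distance would be
a different, undocumented analysis. Graphs with fewer than three nodes
have all BC = 0. Hub and bottleneck ranks are dense and tie-aware
(equal values share a rank, no gaps), ties broken alphabetically only
for display order, and top-*k* reports include every gene tied at the
k-th rank. `compare_groups()` reports shared/unique top hubs and
bottlenecks plus per-gene DC/BC deltas, treating genes absent from one
group's graph as DC 0 / BC 0.

The betweenness implementation is cross-checked in the test suite
against a brute-force all-shortest-paths enumeration oracle on hundreds
of random graphs of up to 7 nodes, and Spearman against a
Pearson-on-average-ranks oracle at 1e-12.

## Response classification

`split_cohort()` makes a stratified train/test split with the training
share rounded up *within each class*: at n = 36 (22/14) and a 0.6
fraction this gives ⌈13.2⌉ + ⌈8.4⌉ = 14 + 9 = 23 training and 13 test
samples, matching the published 23/13 protocol (a plain 60% of 36 would
be 22). Five stratified CV folds are dealt over the training ids.

`train_models()` supplies **all** target-gene expressions as features
(no pre-filtering by the DGEA — the classifiers must find the signal),
with non-response as the positive class, since non-response is the event
being predicted. The five learners are specified by contract rather than
by vendor implementation, as the original hyperparameters were never
published: two gradient-boosted tree profiles (`xgboost`: depth 3,
learning rate 0.3; `gbm`: the classic stochastic profile — depth 2,
learning rate 0.1, 80% row subsampling), a random forest (`drf`),
extremely randomized trees (`xrt`), and an elastic-net logistic
regression (`glm`, α = 0.5). Each is tuned over a small grid by mean CV
AUC on the split's folds (the elastic net picks its penalty by
cross-validated deviance, with fold AUCs recomputed at the selected
penalty, because five folds of a 23-sample set are too small for
per-fold AUC curves), refit on the full training set, and scored once on
the held-out test set with the rank-based AUC (ties count one half;
verified against pair enumeration). Feature importances
(gain/impurity/|coefficient|) are normalized to sum one per model so the
cross-algorithm consensus (`consensus_features()`, mean normalized
importance) is scale-free. Everything is deterministic given the seed.

With a 13-sample test set, a single AUC is a coarse statistic: one
sample falling inside a decision gap moves it by 1/16. Tree learners
that place split thresholds *at* observed training values are
particularly exposed. Performance claims in the tests are therefore
made at the median over 20 generator seeds, never from one cohort.

## The synthetic cohort generator

`generate_cohort()` draws

    Ct(s, g) = baseline[g] - I(s in NR) * log2(FC_g)
               + sum over modules of loading * L_m(s) + eps(s, g)

where `FC_g` is the fold change implied by the planted fold regulation,
`L_m(s)` is a standard-normal per-sample factor shared by all genes of a
module (applied only within the module's scope group), and `eps` is
i.i.d. Gaussian well noise. Housekeeping genes get their own baseline
plus noise. The defaults:

* **group sizes 22/14** and **planted fold regulations** equal to the
  published dysregulated set (CXCL2 +6.95 … IL23A −24.3, TNFSF14 +1.38,
  all other genes 1) — `study_cohort_spec()`;
* **noise sd 0.5 cycles**: a standard qPCR error magnitude; the source
  study reports no dispersion, so recovery properties are checked over
  seeds rather than calibrated to data;
* **baselines 25 (targets) / 20 (housekeeping) cycles**: realistic but
  arbitrary; the global-shift invariance makes downstream results
  insensitive to them;
* **two co-expression modules** mirroring the group-specific hub
  structure: BCL6/CRP/CCR1/CCL16 scoped to responders and
  CCL11/CCL22/IL23R to non-responders, single factor, equal loadings —
  the simplest construction with tunable rank correlation;
* **module loading 3.0 cycles** (six times the well noise). This choice
  matters: two module genes have population Pearson correlation
  `(λ²+σ_hk²)/(λ²+σ²+σ_hk²)` (the σ_hk term is the shared housekeeping-
  mean noise), which at a loading of only 3× the noise is ≈ 0.90 —
  *exactly at* the edge cutoff, where the population Spearman (≈ 0.89)
  is already below it and edge survival is a coin flip. At 6× the noise
  the population Spearman is ≈ 0.97 and module pairs reliably clear the
  strict 0.9 cutoff at n = 22, which is what the modules exist to
  emulate. The test suite also measures hub recovery at the 3× boundary,
  where it documents the breakdown rather than hiding it.

What the generator does *not* emulate: PCR efficiency curves, primer
and plate batch effects, undetermined-well patterns, non-Gaussian Ct
error, correlated effect sizes, or any dependence between clinical
covariates and expression. Passing tests show the pipeline recovers
planted structure under this idealized error model — not that the
biological claims hold on real cohorts.

Two generator-driven simulation designs deserve note:

* **Null calibration.** The shared housekeeping-mean noise correlates
  all genes of a cohort, so the significant fraction of a single
  10,000-gene null cohort has standard deviation ≈ 0.03 around a
  well-calibrated marginal rate: one cohort is a draw of the shared
  factor, not a calibration estimate. The type-I check therefore spreads
  10,000 null genes over 50 independent 200-gene cohorts.
* **Separable cohorts** for the classifier checks plant only the three
  largest published effects (IL23A −24.3, CCR2 −16.86, IL23R −13.59) at
  low noise (sd 0.1), so importance rankings must concentrate on genes
  that actually carry signal.

## Clinical baseline statistics

`chi_square_test()` is the Pearson chi-square *without* continuity
correction — the convention under which published two-group baseline
p-values reproduce from their printed counts; a Yates flag exists.
`pooled_t_from_summary()` computes the equal-variance two-sample t
directly from n/mean/SD triples (Welch optional) and equals the
raw-data test exactly (asserted on simulated data). Ordinal scores
(Mayo) report group medians without a test by default; a Wilcoxon
rank-sum option is labelled as an extension. `baseline_cohort()` bundles
a fully synthetic 36-sample record set whose categorical counts match
the published table exactly and whose continuous variables are
moment-matched (exact group mean and SD), so summary-based and raw-data
tests agree. Known reproduction limits, documented rather than patched:
the published smoking-status p-value is not a plain chi-square of its
counts (possibly Fisher or simulation), and the WBC/platelet/hemoglobin
rows do not reproduce from their printed summaries under either t
variant (possibly missing data); these rows are excluded from the
reproduction checks.

## Problem sizes and runtime

The test suite and `scripts/acceptance.R` use: 500 random graphs (≤ 7
nodes) for the betweenness oracle, 1,000 vector pairs for the Spearman
oracle, 50 × 200 genes for null calibration, 200 cohorts for
fold-regulation and hub recovery, 20 seeds for the separability
simulation and 25 label permutations for the permutation null. These
sizes give Monte-Carlo standard errors well inside the asserted margins
while keeping the default run in minutes on one core.

## Known limitations

* The pipeline treats response labels as fixed ground truth; label noise
  propagates directly into every stage.
* Centrality is computed on one hard-thresholded graph; results near the
  0.9 cutoff are sensitive to sampling noise in the correlations (see
  the loading discussion above). No soft-thresholding (WGCNA-style) or
  community detection is attempted.
* With 36 samples, classifier AUCs and importance rankings are
  qualitative; the package reports them with CV summaries but makes no
  claim of generalization.
* The bundled 84-gene panel pads the named study genes with synthetic
  `IRG` placeholders because the commercial array's full membership is
  not part of the published record; users supply their own panel file
  for real arrays.
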