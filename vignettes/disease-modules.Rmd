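---
title: "Discovering AMD disease modules from two-tissue transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering AMD disease modules from two-tissue transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amdmodules)
```

## The analysis in one paragraph

Donor eyes graded from normal through pre-AMD (hard drusen, MD1; soft
drusen, MD2) and dry AMD to the late forms (geographic atrophy, GA;
choroidal neovascularization, CNV; mixed GA-CNV) are profiled in two
tissues — RPE-choroid and neural retina — at two sites each (macula,
extramacula). After normalization and contaminant filtering, every
AMD/pre-AMD grouping is tested against age-matched normals in 21
two-class comparisons per tissue. Significant genes are summarized in a
signed significance-score matrix which is consensus-clustered; clusters
dominated by the same phenotype and direction merge into *disease
modules*. Modules are then validated two ways: a top-k module gene panel
must classify disease state under cross-validation with a permutation
null, and a module's protein-association connectivity must exceed a
Monte-Carlo null for random gene sets of the same size.

## Statistical model and procedure

### Normalization

Raw linear signals are scaled per sample to *net intensity*: each value is
its percentage of the sample total × 100,000, so every array sums to
100,000 and values are comparable across arrays. Tissues are quantile
normalized jointly for the cross-tissue filters (so that between-tissue
tests see identical marginal distributions) and separately for the
within-tissue comparisons, then log2 transformed. Quantile normalization
averages tied rank means, is idempotent, and makes the column
distributions exactly equal as multisets.

### Contaminant and variance filters

Sectioned eye tissue cross-contaminates: retina transcripts bleed into
RPE-choroid punches and vice versa. A probe is flagged as a contaminant of
tissue T when it is enriched in the *other* tissue (Q ≤ 0.02, permuted
P ≤ 0.01, fold ≥ 1.5) and nearly absent in T — linear mean below 100
net-intensity units (≈ 6.64 log2). Gender-specific probes (for example
X-inactivation transcripts) are flagged at Q ≤ 1e-4, permuted P ≤ 1e-3,
fold ≥ 1.5 in a pooled male-versus-female comparison. Probes with linear
sample variance ≤ 5 are excluded as unmeasurably flat. The variance
threshold is meaningful on the linear net-intensity scale, where the
typical probe mean is `1e5 / n_probes`; on the log2 scale a variance of 5
would remove essentially every probe, so the pipeline applies the floor to
the linear quantile-normalized matrix.

### Differential expression

Each comparison is an unpaired two-sided Welch t-test. P-values are
adjusted by permutation: class labels are shuffled (Fisher-Yates) 1,000
times, the same shuffle applied to all probes in an iteration, and the
permuted p is the plain fraction of shuffles with |t| at least the
observed |t| (an optional +1 correction is available). False discovery
rates use the Storey-Tibshirani q-value: `q_(i) = min_{j>=i} pi0 m p_(j)/j`
with `pi0` estimated on the lambda grid 0, 0.05, …, 0.95 by a df-3
smoothing spline evaluated at the largest lambda; vectors shorter than 100
fall back to `pi0 = 1` (where the estimator is too noisy to help). Fold
change is the symmetric geometric form `2^|Δ mean log2|`. We chose this
over the ratio of arithmetic linear means deliberately: arithmetic means
are asymmetric under dilution — a −1.5 log2 shift in half of a pooled
group's samples gives an arithmetic fold of 1.48 while the same +1.5 shift
gives 1.91 — which would systematically drop down-regulated modules at the
1.5-fold reporting gate in pooled-region comparisons. A gene is *reported*
for a comparison when permuted P < 0.1 and fold ≥ 1.5.

### The significance matrix and consensus clustering

Reported genes get a signed score `S_ij = ±(−log10 P_ij)`; everything else
is 0. Permutation p-values of exactly 0 are capped at `log10(n_perm) + 1`
(4 for 1,000 permutations) — order-preserving, no infinities. Probes of
one gene are collapsed by averaging. The matrix is normalized for
clustering in three passes: columns to unit variance, rows to unit sum of
squares, columns to unit sum of squares (column variance first, then the
row/column sum-of-squares passes; the order is config-exposed).

Clustering is an ensemble: each of 500 base runs is k-means with k drawn
uniformly from 2…min(15, ⌈√n⌉) and 3 random restarts; the co-association
matrix (fraction of runs in which two genes share a cluster) is
thresholded at 0.995 — the complement of the 0.005 ensemble confidence —
and connected components of the thresholded graph are the consensus
clusters. Restarts matter: with single-start k-means, local optima pull
true module peers' co-association to ≈ 0.97–0.99, below threshold.

Module assembly labels each cluster with its dominant (tissue, phenotype)
column group — the largest mean |S| with a consistent sign, scope columns
averaged — and merges same-label clusters into `"<tissue> <phenotype>
<Up|Down>"` modules. Two safeguards reflect how capped, thresholded scores
behave:

* **Near-ties resolve toward the most general grouping** (Global ⊃ MD ⊃
  specific classes). A gene up-regulated in every phenotype hits the score
  cap in all 21 comparisons; all seven groups then tie exactly, and the
  only defensible label is Global, not the alphabetically or
  hierarchically first specific class.
* **A dominant group needs support in ≥ 2 of its 3 scope columns, and a
  cluster needs ≥ 2 genes.** After row normalization every
  single-nonzero-column profile collapses to the same unit basis vector,
  so false-positive reports sharing one comparison co-cluster perfectly;
  requiring multi-column support discards them, because any real signal in
  a scoped comparison also appears in the pooled-region comparison.

Genes appearing in both the GA and CNV module of a tissue/direction carry
a `shared_ga_cnv` flag, mirroring the mixed GA-CNV donors contributing to
both groups.

### Biomarker cross-validation

Disease-state prediction uses the module's top k genes (ranked by mean
|S| over the Global comparisons), log2, median-centered per gene,
optionally with donor age appended (z-scored on each training fold; the
encoding of age is not otherwise constrained). Folds are stratified 3-fold;
the classifier is pluggable behind a `fit`/`predict` contract, defaulting
to a linear-kernel SVM with default regularization. Panel size is chosen
by running the cross-validation on every consecutive head of the ranked
list and taking the smallest k at the maximum accuracy.

Significance permutes class labels against the *fixed* out-of-fold
predictions — models are never refit, which is what makes very deep nulls
(10^7 in the reference configuration; 10,000 by default here for desk use)
affordable. The default p is the conservative "fraction equal to or
exceeding" form. Because accuracy is a coarse statistic, ties between
permuted and observed accuracy carry real mass (a near-constant predictor
ties with *every* permutation), so the inclusive p bunches near 1 under
the null. The `tie_break = "randomized"` option splits tie mass uniformly,
the standard construction under which a discrete permutation p-value is
exactly uniform under the null; calibration studies use it, headline
results keep the conservative form.

### Connectivity enrichment

For a module with n genes matched in a protein-association graph, the
average node degree is `D = 2·(induced edges)/n`. The null is Monte-Carlo:
10,000 uniform draws of 50, 100, 200, 300 and 400 nodes; `E(D)` at level α
is the per-size (1−α) quantile, and an ordinary least-squares line through
the five per-size quantiles gives `E(D)` as a function of module size
(on a complete graph the line is exactly `D = n − 1`, a useful exactness
check). A module is enriched at α when its observed D exceeds the fitted
`E(D)`. We read "expected node degree for P = α" as the (1−α) null
quantile — the only reading that yields one line per significance level.
Interactome assembly unions per-source edge tables after per-source score
thresholds (0.7 "high confidence" for database edges by default, 0.4
optionally), removes self-edges, and keeps for each unordered pair the
annotation of its highest-precedence source (curated PPI > pathway-tool
edges > database/experimental > text-mining). Gene-set overlap
significance is the upper-tail hypergeometric probability, which
reproduces the published interactome overlap values.

## What the synthetic cohorts emulate — and what they do not

`simulate_study()` draws one sample per (donor, tissue, region) with the
reference design's donor counts per class as defaults (31 Normal / 7 MD1 /
4 MD2 / 17 DryAMD / 2 GA / 4 CNV / 3 GA-CNV). Per-gene baselines are
log-normal (log2 mean 6, sd 1.5 — matching the regime in which 100 linear
units ≈ 6.64 log2), residual noise is N(0, 0.5) on log2, and values are
returned on the net-intensity scale. Planted structure:

* **Modules** shift the configured phenotype/region/tissue samples by a
  log2 effect (default four RPE-choroid modules at 1.5: DryAMD Up, CNV Up,
  GA Down, and a 20-gene Global Up signature). GA and CNV plantings also
  shift mixed GA-CNV donors — a mixed eye carries both programs, which is
  exactly why the analysis pools them. Planted genes draw their baseline
  from the left-truncated (mean − 1 sd) expression distribution: a module
  planted on transcripts below the detection floor cannot be recovered by
  any method and would only re-test the variance filter.
* **Contaminants** (5% of genes, half per tissue) are expressed at log2
  N(9, 0.5) in their own tissue and at linear mean 20 — well under the
  100 cutoff — in the other.
* **Gender genes** (10) are shifted ±3 log2 between male and female
  donors.

Defaults plant *tissue-wide* (both-region) modules. A region-restricted
module at effect 1.5 is diluted to a ≈ 1.68-fold shift in the
pooled-region comparison, directly at the 1.5-fold reporting gate, so
around 15% of its genes stochastically lose that column and fragment into
single-column profiles that module assembly (correctly) refuses; recovery
of such gate-marginal modules is intentionally partial, and unit tests
exercise that regime separately.

The generator does **not** emulate: dye-swap/two-color structure, probe
sequence effects, batch or cohort effects, correlated gene-gene noise, or
age-phenotype confounding (ages are uniform in 60–95 across classes).
Passing recovery tests therefore demonstrate the pipeline's statistical
machinery under clean planted truth, not robustness to the full messiness
of real array data.

## Numerical choices and degenerate inputs

* Permuted p-values may be exactly 0 (plain fraction); the score cap turns
  those into finite matrix entries. `permute_p(..., add_one = TRUE)` gives
  the never-zero variant.
* Welch test with both variances zero: equal means give t = 0, p = 1;
  different means are an error (degenerate variance).
* Zero-variance columns in clustering normalization are left unscaled with
  a warning; all-zero rows stay zero (no division by zero).
* Quantile normalization of a single sample is the identity, with a
  warning.
* `k_range` for the base k-means runs is clipped to the number of distinct
  rows; duplicated rows always co-associate at 1.
* Module sizes outside the fitted null grid trigger an extrapolation
  warning rather than an error.
* All stage seeds derive from one master seed; each generator stage uses a
  private RNG stream so stages are reproducible independently of calling
  order, and reruns with the same config are byte-identical (manifest
  checksums verify this).

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run the pipeline at 10
donors/class, 2,400 probes / 2,000 genes over 20 seeds for module
recovery; 200 replicates × 1,000 permutations for null calibration; and a
2,000-node mean-degree-12 background with 10,000 Monte-Carlo draws per
size for the degree null. These sizes were chosen so the whole validation
runs comfortably on a laptop while leaving the statistical conclusions
(recovery rates, calibration, false-positive rates) stable across seeds.

## Known limitations

* The consensus-clustering engine is an interface-compatible substitute
  for the self-organizing-map ensemble used in the original analysis; the
  pipeline's contribution is the significance-matrix construction and the
  module concept, and the clustering engine is pluggable.
* The hard report threshold (P < 0.1, fold ≥ 1.5) makes gene membership
  near the gate stochastic; Jaccard recovery of gate-marginal modules
  saturates below 1 for structural reasons discussed above.
* The permutation null for the classifier conditions on the fitted
  predictions; it tests label-prediction association, not the variability
  of the fitting procedure itself.
* q-value estimation of `pi0` needs a few hundred p-values to be useful;
  below that the estimator silently uses `pi0 = 1` (Benjamini-Hochberg
  behavior).
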