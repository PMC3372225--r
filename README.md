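# amdmodules

Disease-module discovery from age-related macular degeneration (AMD)
transcriptomes.

## What this package does

Age-related macular degeneration is graded on an ordinal scale from
pre-clinical drusen deposits (MD1, MD2) through dry AMD to the late forms,
geographic atrophy (GA) and choroidal neovascularization (CNV, "wet" AMD).
Expression profiling of donor eyes in two tissues — the RPE-choroid complex
and the neural retina, each punched at the macula and an extramacular
control site — asks which gene programs track which disease stage.

`amdmodules` implements that analysis as a tested, reusable pipeline:

1. **Normalization** — net-intensity scaling (each sample's signals as a
   percentage of its total × 100,000), quantile normalization, log2.
2. **Contaminant filtering** — probes enriched in the opposing tissue
   (Q ≤ 0.02, permuted P ≤ 0.01, fold ≥ 1.5) with a linear mean < 100 in
   the affected tissue are cross-tissue contaminants; gender-specific
   probes (Q ≤ 1e-4, permuted P ≤ 1e-3, fold ≥ 1.5) and low-variance
   probes are also removed.
3. **Combinatorial differential expression** — 7 phenotype groupings
   (MD1, MD2, MD, DryAMD, GA, CNV, Global) × 3 region scopes = 21
   two-class Welch-t comparisons per tissue against age-matched (≥ 60 y)
   normals, with permutation-adjusted p-values (1,000 Fisher-Yates label
   shuffles) and Storey-Tibshirani q-values.
4. **Disease modules** — each reported gene/comparison gets a signed
   significance score `S_ij = ±(−log10 P_ij)` (0 when not reported); the
   42-column gene × comparison matrix is normalized and consensus-clustered
   (500-run ensemble, 0.995 co-association); clusters sharing a dominant
   (tissue, phenotype, direction) are merged into named disease modules
   such as `RPE-choroid Global Up`.
5. **Biomarker validation** — top-k module genes (k chosen by iterative
   cross-validated panel search, k = 20 default) feed a stratified 3-fold
   linear-SVM cross-validation; significance by label permutation against
   fixed predictions.
6. **Network enrichment** — a module's average node degree
   `D = 2·edges/nodes` in a protein-association graph is compared to a
   Monte-Carlo null: `E(D)` is the per-size (1−α) quantile of D over
   10,000 random draws at sizes 50–400, fitted as a line in module size.
   Interactome assembly deduplicates multi-source edge tables under the
   dominance series PPI > IPA > STRING-db/exp > STRING-text. Gene-set
   overlaps use the upper-tail hypergeometric (Fisher) test.

A synthetic-cohort generator (`cohort_config()` / `simulate_study()`)
plants disease modules, cross-tissue contaminants and gender-specific
genes with known truth, so the whole pipeline is testable end to end
without any external data.

## Worked example

```r
library(amdmodules)

cfg <- cohort_config(
  donors_per_class = setNames(rep(10L, 7), phenotype_levels()),
  seed = 1L
)
sim <- simulate_study(cfg)
sim$study
#> expression_study: 2 tissue matrix/matrices
#>   RPE-choroid: 2400 probes x 140 samples
#>   retina: 2400 probes x 140 samples
#>   phenotypes: CNV, DryAMD, GA, GA-CNV, MD1, MD2, Normal

run <- run_pipeline(sim$study, pipeline_config(seed = 2L))
table(run$modules$module)
#>  RPE-choroid CNV Down    RPE-choroid CNV Up RPE-choroid DryAMD Up
#>                     2                    29                    27
#>   RPE-choroid GA Down RPE-choroid Global Up  RPE-choroid MD2 Down
#>                    28                    20                     7
run$classifier
#> cross-validated accuracy: 100.0% (3 folds: 100.0%, 100.0%, 100.0%)
#> permutation p-value: 0 (10000 permutations)
```

The four large modules match the planted truth in `sim$truth` (Jaccard
≈ 0.9–1.0 per module at the default 1.5 log2 planted effect; the two small
extra modules are correlated false-positive clusters, a known behavior of
hard report thresholds at small group sizes). All planted contaminants are
flagged, and the planted 20-gene global disease signature separates AMD
from normal donors perfectly, with a permutation p-value at the resolution
floor.

Network enrichment on a synthetic background:

```r
g    <- simulate_background_graph(2000, 12, seed = 3)
g2   <- embed_module_edges(g, g$nodes[1:100], 0.2, seed = 4)
null <- monte_carlo_degree_null(g2, reps = 10000, seed = 5)
module_enrichment(g$nodes[1:100], g2, null, name = "planted")
#>    module n_nodes     D   ED_0.05 enriched_0.05   ED_0.01 enriched_0.01
#> 1 planted     100 19.88 0.8444411          TRUE 0.9347352          TRUE
```

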