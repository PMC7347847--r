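# gliopanel

Discovery of discriminatory gene-expression panels for subtyping diffuse
astrocytic gliomas — diffuse astrocytoma (DA, WHO grade II), anaplastic
astrocytoma (AA, grade III) and glioblastoma (GBM, grade IV) — from log2
probe-by-sample expression matrices. The package is aimed at analysts who
have RMA-normalized (or comparable log2) multi-cohort array data with group
and batch labels and want a tested, reproducible implementation of the full
panel-discovery chain, plus a synthetic-cohort generator with known ground
truth to validate every stage without any external data.

## The workflow

Given a study `X` (J probes × I samples) with group and batch labels:

1. **Batch adjustment** (`combat_adjust`): parametric empirical-Bayes
   location/scale correction. Per gene, batch effects `γ̂, δ̂²` are
   estimated on standardized data and shrunk toward method-of-moments
   priors shared across genes (normal on γ, inverse-gamma on δ²);
   `pca_scores` visualizes the stabilization.
2. **CUR-leverage probe selection** (`svd_leverages`, `top_k`): probes are
   ranked by `l_j = (1/R) Σ_{r≤R} v_jr²`, the mean squared
   right-singular-vector loading over the first R components of the
   probe-centered SVD, with R the numerical rank by default; the top-k most
   variable probes are kept.
3. **Differential expression** (`pairwise_test`, `bh_adjust`,
   `select_panel`): per-probe moderated t (empirical-Bayes posterior
   variance `(d₀s₀² + ds²)/(d₀+d)`, prior fitted by moments),
   Benjamini–Hochberg correction within each pairwise comparison (DA vs
   GBM, AA vs GBM, DA vs AA), and a fold-change filter `FC = 2^|Δlog2| ≥ 4`;
   surviving probes collapse to a unique gene panel.
4. **NMF consensus clustering** (`nmf_factorize`, `consensus_cluster`):
   `X ≈ WH` by Lee–Seung multiplicative updates; `H` columns give sample
   memberships, `W` columns gene contributions. Consensus over random
   restarts plus cophenetic correlation selects the number of clusters.
5. **Canonical (MANOVA) biplot** (`fit_canonical_biplot`): axes solving
   `B u = λ W u` (between- vs pooled within-group scatter) display samples,
   group means and gene vectors with maximal group discrimination.
6. **LDA validation** (`fit_lda`, `classify`): pooled-covariance Gaussian
   discriminant trained on the discovery cohort classifies an independent
   validation cohort; confusion matrix and accuracy are reported.

`run_pipeline(pipeline_config(...))` executes the chain end to end with a
run manifest; the numbered scripts under `analysis/` are narrative drivers
that write every stage's tables under `results/`.

## Worked example

```r
library(gliopanel)

spec <- simulation_spec(seed = 42L)   # 19 DA / 28 AA / 108 GBM, sd 0.5
sim <- simulate_study(spec)
sim$study
#> expression_study: 1028 probes (527 genes) x 155 samples
#> groups: DA=19, AA=28, GBM=108

lev <- svd_leverages(sim$study)
sel <- subset_probes(sim$study, top_k(lev, 200))
records <- rbind(pairwise_test(sel, "DA", "GBM"),
                 pairwise_test(sel, "AA", "GBM"),
                 pairwise_test(sel, "DA", "AA"))
panel <- select_panel(records, alpha = 0.05, fc_min = 4)
panel
#> gene_panel: 20 genes, 29 probes

ps <- subset_probes(sel, unlist(panel$probes))
cc <- consensus_cluster(ps$matrix, k_range = 2:4, n_restarts = 10, seed = 1)
cc
#> consensus_result: cophenetic correlation by rank
#>     k2     k3     k4
#> 1.0000 0.9880 0.9482
#> recommended K: 2

fit <- nmf_factorize(ps$matrix, k = cc$recommended_k, seed = 1)
table(cluster = assign_clusters(fit), group = sim$study$group)
#>        group
#> cluster  DA  AA GBM
#>       1   0   0 108
#>       2  19  28   0

valid <- simulate_study(simulation_spec(
  n_per_group = c(DA = 14, AA = 24, GBM = 75), seed = 43L))$study
common <- intersect(unlist(panel$probes), valid$probe_ids)
classify(fit_lda(subset_probes(sel, common)), subset_probes(valid, common))
#>      predicted
#> true  DA AA GBM
#>   DA  14  0   0
#>   AA   0 24   0
#>   GBM  0  0  75
#> accuracy: 1.000 (113/113)
```

Reading the output: at this noise level the leverage cut retains 20 of the
27 planted panel genes; consensus NMF prefers two clusters and co-clusters
all DA and AA samples apart from GBM (the cophenetic correlation drops as K
grows); and the panel transfers cleanly to an independent validation-sized
cohort. The `analysis/` drivers run the same chain on two-batch cohorts
with injected batch effects, where the adjustment step is exercised too.

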