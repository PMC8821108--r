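# hapattern

Histone acetylation in tumors is governed by a small panel of regulator
genes — acetyltransferase *writers*, deacetylase *erasers*, and
acetyl-mark–binding *readers*. Cohorts of tumors split into distinct
transcriptional **patterns** of this machinery, and the pattern a sample
belongs to carries prognosis, tumor-microenvironment composition, and
drug-response information. `hapattern` is an R package for the complete
analysis:

1. **Pattern discovery** — resampling consensus clustering of samples on a
   regulator panel (k-means inner clusterer on per-gene z-scores, 1000
   subsample repetitions, delta-area/PAC model selection over *k*).
2. **Signature construction** — one-vs-rest moderated-*t* differential
   expression between patterns (empirical-Bayes variance shrinkage;
   BH-adjusted *p* < 0.001 and |FC| > 1.5), followed by a univariate Cox
   screen keeping prognosis-relevant genes.
3. **HAscore** — each sample's coordinate on PC1 plus PC2 of the z-scored
   signature-gene matrix,

   HAscore(s) = Σ_{j∈{1,2}} u_{sj} d_j,   signs fixed so high score = high
   signature expression.

4. **Downstream association** — maximally selected log-rank cutpoint to
   dichotomize the score; Kaplan–Meier, log-rank, and Efron-tie Cox models;
   ssGSEA enrichment of TME/pathway gene sets; EMT score
   (mean mesenchymal − mean epithelial expression); Spearman screens of
   drug AUC (hits at |Rs| > 0.3, FDR < 0.05); chi-square/Fisher tests of
   clinical features.

A synthetic cohort generator (`simulate_cohort()`,
`simulate_drug_response()`) produces cohorts with a known three-pattern
latent structure, proportional-hazards survival, and planted drug
correlations, so every stage can be validated against ground truth. It is
intended for method validation and teaching, not as a model of RNA-seq
noise.

## Worked example

```r
library(hapattern)

cohort <- simulate_cohort(cohort_config(seed = 7))      # 30/30/60 samples
cc <- consensus_cluster(cohort$expression,
                        attr(cohort, "regulator_genes"),
                        k_range = 2:6, reps = 200, seed = 3)
glance(cc)
#> # A tibble: 1 × 5
#>   chosen_k   pac n_samples k_min k_max
#>      <int> <dbl>     <int> <int> <int>
#> 1        3     0       120     2     6
adjusted_rand_index(tidy(cc)$cluster, cohort$truth$pattern)
#> [1] 1
```

The consensus run picks three patterns with zero ambiguity (PAC = 0) and
recovers the simulated labels exactly (ARI = 1). Building the score and
testing survival separation:

```r
de   <- moderated_de(cohort$expression, cohort$truth$pattern)
sig  <- prognostic_screen(cohort$expression, cohort$clinical,
                          select_degs(de))        # 156 genes retained
hs   <- hascore(cohort$expression, sig)
tapply(hs, cohort$truth$pattern, mean)
#>           A           B           C
#> -15.4119464  15.2135994   0.0991735

grp <- dichotomize_score(hs, cohort$clinical$os_time,
                         cohort$clinical$os_event)
logrank_test(cohort$clinical$os_time, cohort$clinical$os_event, grp)
#> # A tibble: 1 × 3
#>   statistic    df            p
#>       <dbl> <int>        <dbl>
#> 1      29.1     1 0.0000000705
```

Mean HAscore orders the patterns B > C > A — the high-activity pattern B
carries the highest score — and the high-score group has clearly worse
survival (log-rank χ² = 29.1, p ≈ 7 × 10⁻⁸). `cox_fit()` on the simulated
latent risk returns a hazard ratio of 2.26 per SD (true generating value:
e^0.7 ≈ 2.01; n = 120).

The whole analysis is one call once inputs are on disk
(`write_cohort()` shows the expected TSV/GMT layout):

```r
cfg <- pipeline_config(expression = "expression.tsv",
                       clinical = "clinical.tsv",
                       regulators = "regulators.txt",
                       gene_sets_gmt = "sets.gmt", emt_gmt = "emt.gmt",
                       drug_auc = "drug_auc.tsv", seed = 5)
res <- run_pipeline(cfg, "results/")   # 11 stages, manifest.tsv, all TSV
```

A YAML file with the same fields works too: `run_pipeline("run.yaml",
"results/")`. Reruns with the same config and seed are byte-identical.

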