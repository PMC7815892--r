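# imputeBench

Spike-in benchmarking of missing-value imputation for label-free
proteomics.

Label-free proteomic abundance matrices are riddled with missing values
(MVs), and the mechanism matters: entries missing at random (MAR) and
entries censored near the detection limit (missing not at random, MNAR)
call for very different imputation strategies. This package lets you
measure, rather than guess, how an imputation method behaves under a
controlled MAR/MNAR mixture. It is aimed at proteomics and metabolomics
analysts choosing an imputer for differential-expression work, and at
method developers who need a ground-truth benchmark.

The package implements the full evaluation loop:

1. **Synthetic spike-in benchmark** (`generate_benchmark()`): a
   three-species mixture — constant 70% human background, E. coli at
   5/7.5/10/12.5% and yeast at 25/22.5/20/17.5% of protein mass across
   four groups A–D of eight replicates — so every protein's intergroup
   fold change is known by design (E. coli 1.5/2/2.5, yeast 0.9/0.8/0.7,
   human 1, versus control group A). Group-mean scalings are enforced
   exactly; per-entry log-normal noise emulates measurement error.
2. **Controlled amputation** (`simulate_missingness()`): total MV rate α
   and MNAR share β. MNAR entries are censored below a stochastic
   threshold `T ~ N(q_α(D), 0.3)` gated by Bernoulli(β) trials; MAR
   entries are uniform. Counts are enforced exactly:
   `round(Nα)` missing, `round(Nαβ)` of them MNAR, for every seed.
3. **Seven imputers** (`impute()`): lowest of detection (LOD),
   downshifted normal (ND, `N(μ−2.2σ, (0.3σ)²)`), k-nearest neighbours
   (k = 6), local least squares (k = 150), iterative random forest
   (missForest-style, ntree = 100), iterative SVD and Bayesian PCA
   (nPCs = 2) — all implemented in-package behind one dispatch interface.
4. **Scoring** (`nrmse_abundance()`, `nrmse_ratios()`, `de_test()`,
   `confusion_counts()`, `roc_curve()`): NRMSE of abundances and of
   intergroup ratios, pooled-variance t-tests with Benjamini–Hochberg
   adjustment, true positives and the false altered-protein discovery
   rate `FADR = FP/(TP+FP)`, and repeat-averaged ROC curves.
5. **Orchestration** (`run_benchmark()`): the 3 MV-rate × 3 MNAR-rate
   grid with mask repeats, identical masks shared across methods within a
   repeat, aggregated into a `benchmark_report`.

A thin command-line front end is installed as `exec/bench`
(`generate`, `ampute`, `impute`, `benchmark` subcommands).

## Worked example

```r
library(imputeBench)

# 500-protein benchmark at the designed species mix, 4 groups x 8 replicates
x <- generate_benchmark(n_proteins = c(ecoli = 89, yeast = 81, human = 330),
                        seed = 1)

# 20% missing values, half of them abundance-dependent (MNAR)
md <- simulate_missingness(log2_transform(x),
                           missingness_spec(alpha = 0.2, beta = 0.5, seed = 7))
md
#> Masked dataset: 500 proteins x 32 samples
#>   missing: 20.0% of entries (MNAR share 50.0%), 0 rows dropped
#>   spec: alpha = 0.2, beta = 0.5, sigma_T = 0.3, seed = 7

imp <- impute(md, "RF")
nrmse_abundance(imp, md$truth, md$mask)
#> [1] 0.1552428

ratios <- intergroup_ratios(imp$values, md$groups, "A")
nrmse_ratios(ratios, x$design, md$species)
#> [1] 0.3792613

de <- de_test(imp$values, md$groups == "A", md$groups == "D",
              species = md$species, comparison = "D/A")
confusion_counts(de)
#> TP 127  FP 8  FN 43  TN 322 | FADR 0.059  TPR 0.747  FPR 0.024
```

Reading the numbers: the random-forest imputer reconstructs the deleted
log2 intensities with an error of ~0.16 standard deviations of the true
values (NRMSE 0 = perfect, ~1 = mean imputation); the designed fold
changes are recovered with ratio NRMSE 0.38; and in the D-vs-A comparison
127 of 170 spiked proteins are detected at adjusted p < 0.05 with 8
background false positives, i.e. a false altered-protein discovery rate
of 5.9% for this single mask.

For the full study loop, `run_benchmark()` repeats this over the
3 × 3 condition grid and any subset of the seven methods:

```r
cfg <- benchmark_config(methods = c("LOD", "ND", "RF"), n_repeats = 3,
                        n_proteins = c(ecoli = 89, yeast = 81, human = 330))
report <- run_benchmark(cfg)
summary(report)
```

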