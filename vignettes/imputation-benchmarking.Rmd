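---
title: "Benchmarking missing-value imputation with synthetic spike-in proteomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking missing-value imputation with synthetic spike-in proteomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imputeBench)
```

## The problem

Label-free quantitative proteomics matrices are incomplete: a protein that
is quantified in one run may be absent from another, either for reasons
unrelated to its abundance (missing at random, MAR) or because it sits near
the instrument's detection limit (missing not at random, MNAR --
left-censoring). Imputation is routine, but different imputers embody very
different assumptions about the missingness mechanism, and choosing badly
distorts both the imputed abundances and every downstream
differential-expression (DE) call.

`imputeBench` evaluates imputation the way spike-in studies do: it builds a
benchmark in which the truth is known by construction, deletes entries
under a controlled MAR/MNAR mixture, imputes with seven standard methods,
and scores the result at three levels -- reconstruction error, fold-change
error, and DE-detection quality.

## The synthetic spike-in benchmark

The generator emulates a three-species mixture experiment: a constant
human background (70% of protein mass in every group) with E. coli rising
(5, 7.5, 10, 12.5%) and yeast falling (25, 22.5, 20, 17.5%) across four
groups A--D of eight replicates. Relative to the control group A this
designs fold changes of 1.5/2/2.5 for E. coli, 0.9/0.8/0.7 for yeast, and
1 for human proteins.

Each entry is generated as

$$ V_{ij} = B_i \cdot S_{s(i),j} \cdot \varepsilon_{ij} $$

* $B_i$, a per-protein baseline drawn once from a log-normal,
  $\log_2 B_i \sim N(20, 2)$. The location is an arbitrary intensity
  offset; the scale of 2 (log2 units) gives the broad dynamic range over
  which a threshold of standard deviation 0.3 is a *soft* censoring
  boundary rather than a hard cut.
* $S_{s,j}$, a per-sample scaling of species $s$: the designed mass
  fraction times $(1 + e_j)$, with $e_j$ drawn at coefficient of variation
  0.05 and then **mean-centered within each group**. Centering makes the
  group mean of the scalings equal the designed fraction exactly in every
  dataset, not just in expectation, so the designed intergroup ratios are
  reproduced to machine precision -- a deterministic anchor for testing.
  If the CV is so large that a factor would be non-positive the vector is
  redrawn, and generation fails loudly after `max_resample` attempts.
* $\varepsilon_{ij}$, per-entry multiplicative measurement noise,
  $\log_2 \varepsilon \sim N(0, 0.3)$ by default. A log2 standard
  deviation of 0.3 corresponds to roughly a 20--25% intensity CV, a
  realistic technical-plus-analytical noise level for label-free
  quantification. This term matters: without it all proteins of a species
  are exactly proportional across samples, the matrix is essentially
  low-rank, and structure-based imputers are unrealistically flawless.
  When a test needs the deterministic design anchor instead (exact group
  ratios), it sets `noise_sd = 0` explicitly.

`significance_audit()` closes the loop on the design contract: it applies
the evaluation module's own pooled t-test to per-sample species totals, so
a generated dataset whose intended contrasts are not significant can be
rejected and regenerated.

What the generator does **not** emulate: peptide-level evidence and
peptide-to-protein roll-up, correlated biological modules within a
species (all within-species correlation comes from the shared scaling),
batch structure, and acquisition physics. Conclusions from this benchmark
therefore speak to how imputers handle abundance-dependent censoring on
realistically noisy matrices, not to every covariance pattern of real
data.

## Controlled amputation

Missingness is parameterized by the total missing rate $\alpha$ and the
MNAR share $\beta$. On the log2 matrix $D$ with $N$ entries:

1. a threshold matrix $T_{ij} \sim N(q_\alpha(D), \sigma_T)$ with
   $q_\alpha$ the $\alpha$-quantile of all values and $\sigma_T = 0.3$;
2. a Bernoulli($\beta$) success matrix $P$;
3. entries with $D_{ij} < T_{ij}$ and $P_{ij} = 1$ are MNAR candidates.

The stated counts -- $N\alpha\beta$ MNAR and $N\alpha(1-\beta)$ MAR -- are
treated as *hard targets*: candidates are uniformly subsampled to exactly
$\mathrm{round}(N\alpha\beta)$, and if too few exist the quantile level is
raised in steps of 0.01 and $T$ redrawn. MAR entries are then drawn
uniformly from the remaining observed entries. This makes the realized
rates exact for every seed, which in turn makes rate checks deterministic;
the alternative reading (stochastic expected counts) would only agree in
expectation. Rows left with no observed value are removed (across all
samples, not per group), and the retained ground truth travels with the
mask and a per-entry MNAR/MAR provenance label.

Two conventions worth noting: the quantile is computed over *all* values
rather than per sample, and the whole pipeline operates on log2
intensities -- a threshold spread of 0.3 is only meaningful on the log
scale. The MAR step can still hit low-abundance entries by chance; no
correction is applied for that.

## The seven imputers

All imputers fill only missing entries; observed values pass through
bit-identically, which is asserted as an invariant in the tests.

* **LOD** -- global observed minimum. **ND** -- draws from
  $N(\mu_m - 2.2\sigma_m,\ (0.3\sigma_m)^2)$ where $\mu_m, \sigma_m$ are
  the mean and standard deviation of all observed values; a per-sample
  variant is available since a widely used desktop tool computes the
  statistics per column. Both are left-censored strategies: correct when
  missingness is censoring, badly biased when it is not.
* **kNN** (k = 6) -- neighbours are *proteins*; distance is Euclidean over
  co-observed samples, scaled by $\sqrt{n_{cols}/n_{shared}}$ so that
  sparse overlaps are not spuriously close; the imputed value is the
  unweighted mean of the k nearest neighbours observed in the target
  sample. The distance and aggregation rules are this package's
  concretization; only k itself is the tuned parameter.
* **LLS** (k = 150) -- the most similar proteins by absolute Pearson
  correlation over the target's observed samples form an (under)determined
  linear system solved by the minimum-norm pseudoinverse; missing entries
  are predicted from the neighbours' values in the missing samples. At
  realistic missing rates almost no protein is fully observed, so
  neighbour values come from a row-mean-initialized working copy
  (all-variables strategy); only the target's own observed values
  constrain the fit. Degenerate targets fall back to row means, counted in
  the diagnostics.
* **RF** (ntree = 100) -- missForest-style chained random forests with
  samples as variables: initialize with column means, visit columns by
  increasing missing count, regress each on the others over its observed
  rows, predict its missing rows, and sweep until the normalized squared
  change between sweeps increases (previous sweep returned), drops below
  `tol`, or `max_iter` is reached. The additional `tol` stop exists
  because the change typically collapses to ~1e-4 after two sweeps and
  further sweeps only cost time; `mtry` is the usual
  $\lfloor\sqrt{p-1}\rfloor$.
* **SVD** (npcs = 2) -- EM-style completion: column-center, truncate to
  rank npcs, refill missing entries, iterate to `tol`.
* **BPCA** (npcs = 2) -- variational Bayesian probabilistic PCA with an
  automatic-relevance-determination prior on the loading columns; per-row
  posterior scores are computed from that row's observed entries, missing
  entries are filled with their posterior expectation, and loadings, noise
  precision and ARD precisions are re-estimated each sweep. The ARD prior
  lets surplus components shrink to zero, so npcs acts as a cap rather
  than an exact rank. Convergence is declared on the relative change of
  the noise precision.

Convergence tolerances (`tol = 1e-3`, `max_iter = 100`, RF 10) are this
package's choices; results are insensitive to tightening them. Exact
numeric parity with the historical reference implementations of kNN/LLS
(different distance metrics and aggregation rules) is explicitly not a
goal; the algorithmic family and tuned parameters are what is reproduced.

## Scoring

* **NRMSE of abundances**: RMSE over the originally-missing entries
  divided by the standard deviation (n−1) of the true values at those
  entries, on the log2 scale. Restricting to missing entries matters --
  observed entries are unchanged and would dilute any error toward zero.
  0 is perfect; ~1 is as good as imputing the mean of the missing truths.
* **NRMSE of intergroup ratios**: observed post-imputation fold changes
  ($2^{\Delta \overline{\log_2}}$) versus the designed fold changes, same
  normalization, on the linear ratio scale (the designed ratios are linear
  numbers), over all labeled proteins including the ratio-1 background --
  background proteins dominate real matrices and a method that distorts
  them should pay for it.
* **DE testing**: per-protein two-sample pooled-variance Student's t-test
  (two-sided) with Benjamini--Hochberg adjustment per comparison,
  significance at adjusted p < 0.05. Zero pooled variance is resolved as
  p = 1 for equal means and p = 0 otherwise. Spiked species called
  significant are true positives, background calls are false positives,
  and the false altered-protein discovery rate is
  $\mathrm{FADR} = FP/(TP+FP)$, 0 when nothing is called.
* **ROC curves**: thresholds sweep the *adjusted* p-values (consistent
  with the DE call); per-threshold TPR/FPR are averaged component-wise
  across mask repeats (vertical averaging), the curve is anchored at
  (0,0) and (1,1), and AUC is trapezoidal.

## Orchestration and reproducibility

`run_benchmark()` executes the grid of 3 MV rates × 3 MNAR shares ×
repeats × methods. Within one (condition, repeat) every method receives
the *identical* masked dataset (amputation seed = base seed + repeat), so
method contrasts are paired; the report records a mask fingerprint per
cell so this can be audited. Every stage is a pure function of its seed;
a failed cell is recorded and the grid continues.

Desk-scale problem sizes used by this package's own test suite: a
1,500-protein benchmark (species mix preserved) with five mask seeds for
the method-ranking checks, and an 800-protein benchmark with three repeats
of the full nine-condition grid for the RF false-discovery check. These
sizes keep the suite quick while leaving all per-cell sample sizes (32
samples, 8 per group) at the design's values.

## Known limitations

* The baseline abundance distribution is a placeholder log-normal; real
  spike-in intensity distributions are heavier-tailed. Users calibrating
  against their own data can change `log2_location`/`log2_scale`.
* Within-species correlation is entirely the shared per-sample scaling;
  real proteomes contain correlated modules at many scales, which local
  imputers exploit. Structure-based imputers are therefore somewhat
  flattered on this benchmark.
* The DE test is deliberately the plain equal-variance Student's t, the
  most common choice in spike-in evaluations -- not a moderated
  (limma-style) test.
* Peptide-level simulation and roll-up are out of scope.
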