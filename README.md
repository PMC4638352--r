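# methrisk

Promoter CpG methylation patterns as a prognostic signal: per-gene
canonical-correlation pattern scores, permutation-calibrated survival
screening, and a multivariable-Cox **methylation risk score (MRS)** with
Kaplan–Meier risk-group comparison, receptor-status stratification, and
transfer of the fitted score to methylation-only or reduced-probe cohorts.

## Who this is for

Cancer epigenomics analysts working with array methylation (450K/27K-style
beta values), matched expression, and overall-survival follow-up — and
anyone who wants a tested, seeded reference implementation of
permutation-FDR survival screening over methylation pattern scores.

## The method

For each gene with promoter CpG block $X$ ($n \times p$ beta values) and
expression $y$, canonical correlation analysis finds weights
$\hat\alpha$ maximizing $|\mathrm{cor}(X\alpha, y)|$ under
$\mathrm{Var}(X\alpha) = 1$; with univariate $y$ the attained correlation
$r(U, V)$ is the multiple correlation coefficient, and the sign of the
expression scaling $\hat\beta$ records the regulatory direction. The
per-sample **methylation pattern score** is
$\mathrm{MPS}_k = \sum_j \hat\alpha_j x_{kj}$ (training-mean centered).

Genes are screened in two permutation-calibrated stages:

1. median-split log-rank, requiring $p < 0.05$ *and* an empirical
   $p = (1 + \#\{p_b \le p_{obs}\})/(B+1) < 0.01$ over $B = 100$ label
   permutations (at $B = 100$: the observed $p$ undercuts all permutations);
2. univariate Cox on the continuous MPS, keeping genes below the cutoff
   $p_0$, the largest threshold with permutation-estimated
   $\mathrm{FDR} = \frac{\frac{1}{B}\sum_b \#\{p^{(b)} \le p_0\}}{\#\{p_{obs} \le p_0\}} \le 0.01$.

Surviving genes enter one multivariable Cox model; genes with Wald
$p < 0.01$ are retained and refitted, giving
$\mathrm{MRS}_k = \sum_j c_j\,\mathrm{MPS}_{jk}$. The median-split MRS
groups are compared by Kaplan–Meier five-year survival and log-rank test,
overall and within ER/PR/Her2 strata. The fitted object carries each
featured gene's $\hat\alpha$ and training means, so `predict()` scores
cohorts that have methylation only, including reduced-probe platforms.

A seeded synthetic-cohort generator (`simulate_cohort()`) produces
methylation/expression/survival data with planted prognostic genes and
full ground truth, driving all tests and examples — no array download
involved.

## Worked example

```r
library(methrisk)

co  <- simulate_cohort(sim_config(seed = 42))   # 200 samples, 300 genes, 6 planted
fit <- mrs_fit(co$meth, co$expr, co$pmap, co$clin, screen_config(seed = 42))
print(fit)
#> Methylation risk score model: 5 featured genes (0 protective, 5 risk)
#> Cascade: 300 eligible -> 6 (log-rank stage) -> 5 (Cox FDR stage) -> 5 featured
#> Training median-MRS split at 0.03443; 5-year survival low 68.4% vs high 9.4% (log-rank p = 5.1e-24)
```

The cascade line mirrors the screening funnel: 300 eligible genes, 6 pass
the permutation log-rank stage, 5 survive the Cox FDR stage and the
multivariable fit — all 5 are planted genes (compare `co$truth`). The
median-split MRS groups separate five-year survival 68.4% vs 9.4%.
`summary(fit)` prints the per-gene coefficients, hazard ratios and
confidence intervals; `predict(fit, new_meth, clin = new_clin)` transfers
the score to a methylation-only cohort, with `reduced_panel = TRUE` for
platforms missing featured genes.

A file-based stage-by-stage pipeline with the same functionality is
available via `run_subcommand()` or the wrapper script
`inst/cli/mrs-pipeline.R`
(`simulate → mps → screen → fit → score → km → report`).

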