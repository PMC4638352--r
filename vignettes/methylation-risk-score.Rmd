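---
title: "Promoter methylation patterns and the methylation risk score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter methylation patterns and the methylation risk score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methrisk)
```

## The problem

A gene's promoter typically carries several CpG probes on methylation
arrays, and their joint configuration — the *methylation pattern* — can
regulate transcription more informatively than the average beta value. This
package scores that pattern per gene, screens genes for association with
overall survival, and combines the survivors into a single prognostic
index, the methylation risk score (MRS). The fitted score depends only on
methylation, so it transfers to cohorts with no expression data and to
reduced-probe platforms (the 450K-to-27K situation).

## The model

### Methylation pattern score

For one gene with promoter CpG block $X$ ($n \times p$ beta values) and
expression $y$, we seek weights $\alpha$ maximizing
$|\mathrm{cor}(X\alpha, y)|$ subject to $\mathrm{Var}(X\alpha) = 1$. This
is canonical correlation analysis specialized to a univariate right-hand
side: the solution direction is $\Sigma_{XX}^{-1}\Sigma_{Xy}$ and the
attained correlation $r$ is the multiple correlation coefficient of $y$ on
$X$. The per-sample score is
$\mathrm{MPS}_k = \sum_j \hat\alpha_j (x_{kj} - \bar x_j)$.

Because $(\alpha, \beta)$ and $(-\alpha, -\beta)$ are equivalent, a
convention is needed. We orient $\alpha$ so the canonical variate
correlates non-negatively with mean promoter methylation; the sign of the
expression scaling that then makes the canonical correlation non-negative
is reported as the regulatory direction (negative: hypermethylation goes
with lower expression). Only this sign is identifiable after the
unit-variance normalization; the magnitude $1/\mathrm{sd}(y)$ is not
stored as a coefficient claim.

Centering is by training means, which are stored with the weights; scores
on new cohorts reuse them, which is what makes the MPS transferable. The
equal-weight (average-methylation) combination lies inside the CCA search
space, so $r \ge |\mathrm{cor}(\bar X, y)|$ always — the package asserts
this across simulated genes rather than reporting it as an empirical
finding about any particular data set.

### Survival screen

Genes are screened in two stages, each calibrated by permutation rather
than by an analytic null:

1. **Median-split log-rank.** Samples are split at the per-gene median MPS
   (ties at the median go to the low group). A gene passes if its log-rank
   p-value is below 0.05 *and* below every one of $B = 100$ label
   permutations — equivalently, the add-one empirical p-value
   $(1 + \#\{p_b \le p_{obs}\})/(B+1)$ is below 0.01. The add-one form
   avoids zero p-values; at $B = 100$ the two phrasings coincide.
2. **Univariate Cox with a permutation FDR cutoff.** Each surviving gene's
   continuous MPS enters a univariate Cox model (Efron ties). The survival
   labels are permuted another 100 times — one shared permutation per
   round across all genes, preserving their correlation — and the cutoff
   $p_0$ is the largest observed p-value at which

   $$\widehat{\mathrm{FDR}}(p_0) = \frac{\tfrac1B\sum_b \#\{p^{(b)} \le p_0\}}
   {\#\{p_{obs} \le p_0\}} \le 0.01 .$$

   Counting is inclusive at the candidate ($\le p_0$), so the gene defining
   the cutoff can itself pass; genes additionally need raw Cox $p < 0.05$.

### Risk score

A single multivariable Cox model is fitted on all screened genes jointly;
genes with Wald $p < 0.01$ are retained and the model is refitted on the
retained set (an optional ridge-stabilized fit, penalty $10^{-3}$, backs
the selection step if the joint fit diverges — never silently). The MRS is
$\mathrm{MRS}_k = \sum_j c_j \, \mathrm{MPS}_{jk}$ with the refitted
coefficients $c_j$; negative-$c_j$ genes are protective, positive risk.
High/low groups are split at the median MRS and compared by Kaplan–Meier
curves with the five-year (1825-day) survival probability and a log-rank
test, overall and within each receptor stratum (ER/PR/Her2).

When transferring to a new cohort, each featured gene's MPS is rebuilt from
the stored weights and training means on the shared probes (sub-vectors of
$\alpha$ when some probes are absent; whole genes dropped under the
reduced-panel flag, as in a 27K application where two of twelve genes are
missing). By default the new cohort is split at its own median — a
28-sample external set groups internally — and a flag reuses the training
threshold instead, since either convention is defensible.

## The synthetic cohort generator

`simulate_cohort()` produces data with exactly the structure the analysis
assumes, plus ground truth for recovery tests. Per gene: a latent Gaussian
factor shared by the gene's 2–15 promoter CpGs plus probe noise (SD 0.3 on
the logit scale), pushed through a logistic link, keeps within-promoter
beta values correlated and strictly inside (0,1); expression is an
intercept plus a signed weighted sum of the logit-scale CpG values plus
Gaussian noise, the sign negative with probability `direction_mix`
(default 0.5, since real promoters show both regulatory directions).
Survival is exponential with log-hazard `effect_size` per standard
deviation of the true pattern score, summed over the planted genes — the
simplest model satisfying the proportional-hazards assumption the
downstream Cox stages make. Censoring is independent exponential with the
rate solved (exactly, for exponential event times) so the expected censored
fraction equals `censor_rate`. Receptor labels are Bernoulli(0.5),
independent of hazard unless `receptor_effect` is set, so receptor
stratification can be tested under null and alternative.

Defaults: 200 samples, 300 genes, 6 planted, `effect_size = 1.2`,
`noise_sd = 0.5` (canonical correlations mostly 0.4–0.9, the range
retained genes show on arrays), 30% censoring, baseline hazard $1/1825$
per day so mean survival sits at the five-year horizon. The planted-signal
design follows a power calculation: with $k$ planted genes of per-SD
log-hazard $c$ the other $k-1$ act as an omitted frailty of variance
$(k-1)c^2$ that attenuates every marginal screen, so the combined
linear-predictor spread must stay moderate for single-gene stages to have
power at all; 6 genes at 1.2 keep each gene marginally detectable at
$n = 200$ while the combined effect remains clinically plausible.
Each gene draws from its own seed-derived substream, so enlarging the gene
set never perturbs earlier genes.

What the generator does *not* emulate: realistic 450K probe densities,
batch and cell-composition effects, copy-number confounding, non-linear
methylation–expression coupling, or informative censoring. Tests passing
on these cohorts demonstrate correctness of the machinery and calibration
of its error control, not clinical validity on array data.

## Numerical choices

- Covariance inversion uses an SVD pseudoinverse with relative tolerance
  $10^{-8}$; `ridge = TRUE` adds $10^{-6}\,\mathrm{tr}(\Sigma_{XX})/p$ to
  the diagonal instead. Genes whose promoter CpGs are all near-constant
  (variance $< 10^{-10}$) are skipped with a message, not errored.
- Time is in days internally; the five-year horizon is 1825 days.
- Median ties: `> median` is high, `<= median` low, in both the per-gene
  MPS split and the MRS split.
- Cox ties use the Efron approximation. The permutation stores (100 rounds
  x all genes) run through compiled Newton iterations with Breslow ties —
  identical to Efron when event times are distinct, as with continuous
  simulated times — and the test suite asserts agreement with
  `survival::coxph`/`survdiff` on tied and untied data; all observed,
  user-facing statistics come from the survival package.
- Samples missing the survival outcome are dropped first, then any CpG or
  gene column with a missing value (listwise per model for clinical
  covariates, logged). `filter_missing()` is idempotent.

## Problem sizes in the test suite

The packaged checks run at desk scale, chosen as the smallest sizes at
which each property is statistically meaningful: oracle comparisons on
blocks of 2–3 CpGs; dominance of the canonical over the average-methylation
correlation across 250 simulated genes; null calibration of the screen at
500 genes x 100 permutations on a 200-sample cohort; and the FDR-stage
recovery experiment with 20 planted genes among 500 at $n = 800$ and
per-gene log-hazard 0.5 per SD — sized by a power calculation so each
planted gene is marginally detectable at the permutation-FDR threshold
despite the attenuation induced by the other planted genes (a combined
linear-predictor SD of 2.2; implausibly larger spreads make marginal
per-gene screens powerless, which is a property of marginal screening, not
of the implementation).

## Limitations

Univariate-expression CCA only (no multi-gene canonical blocks, no sparse
CCA); no time-dependent covariates or competing risks; promoter membership
is taken from the map as given, with no TSS/strand arithmetic; the
multivariable fit with many screened genes and few events can be unstable —
the package reports the ridge fallback loudly when selection needed it.
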