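---
title: "Weighted functional-burden scores and TRD prediction: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted functional-burden scores and TRD prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(trdburden)
```

This vignette explains the statistical machinery inside `trdburden`: the
burden-score model, the predictor-selection and prediction procedures, the
design of the synthetic-cohort generator, and the numerical choices made
where the design was genuinely open. It states no empirical result beyond
what the test suite and `scripts/acceptance.R` themselves compute.

## 1. The burden score

Treatment-resistant depression (TRD) is defined here as failure of at least
two adequate antidepressant treatments in the current episode; response
requires a current MADRS below 22 together with at least a 50% decrease
from episode onset and at most one failed adequate treatment
(`define_outcome()`). The scientific question is whether the burden of
functionally relevant variation predicts TRD versus response.

For a subject and a unit (exome, gene, or pathway) the score is the sum
over member variants of `v_all * w_s * w_f`:

* `v_all` — the subject's alternative-allele count (0/1/2; missing
  genotypes contribute 0, a conservative choice since no imputation happens
  inside scoring);
* `w_s` — a per-variant functional score. Eigen is the default source;
  CADD and sequence-ontology scores are selectable. Negative Eigen values
  are used as-is (no truncation), so scores can be negative;
* `w_f` — the Beta density at the variant's alternative-allele frequency:
  `dbeta(alt_freq, 1, 25)` for rare variants and `dbeta(alt_freq, 0.5,
  0.5)` for common ones. The weight uses the *unfolded* alternative-allele
  frequency, exactly as the formula is written, while rare/common
  classification uses the folded MAF against the threshold `1/sqrt(2n)`
  (0.02 at n = 1209). We evaluate the normalized Beta density (R's
  `dbeta`), the natural reading of the weighting function.

Frequencies come from the annotation table, not from the scored sample, so
a subject's score never depends on which variants happen to segregate in
the cohort partition being scored — training, testing and replication
partitions are scored on one frequency scale.

Common variants are LD-clumped before scoring (`ld_clump_common()`): greedy
selection in descending `w_s`, removing candidates whose genotype r² with a
kept variant within the window exceeds the threshold. Defaults r² = 0.5 and
250 kb follow Plink v1.9's clump defaults; both are exposed. Pathway scores
count a variant once per pathway even when member genes overlap.

Quality-control operations mirror standard practice: subjects outside five
sample SDs of the exome-wide score are excluded before downstream
modelling, and `genotype_concordance_qc()` flags subjects whose non-major-
homozygote concordance between two genotype sources is at or below 0.90
(rare) / 0.95 (common). Scores are covariate-adjusted by per-unit OLS
residuals on three ancestry PCs plus recruitment-centre contrasts; aliased
centre columns are dropped with a warning.

## 2. Predictor selection: CAT scores and local FDR

Units (gene or pathway scores) are screened for TRD-vs-response signal with
correlation-adjusted t-scores: `cat = R^(-1/2) t`, where `t` are
two-sample t-scores with analytically shrunken pooled variances (target =
median variance) and `R` is the pooled correlation matrix shrunk toward the
identity with the analytic Schaefer–Strimmer intensity
`lambda = sum Var(r_ij) / sum r_ij^2`. `R^(-1/2)` is the symmetric inverse
square root by eigendecomposition (eigenvalues floored at 1e-10). With a
single unit, or full shrinkage, CAT reduces to the t-score. Zero-variance
units get t = 0 with a warning.

Each unit's local false discovery rate — the posterior probability of
being non-informative given its CAT score — is `min(1, pi0 f0(s) /
f(s))`:

* the marginal `f` is a Lindsey-method Poisson fit to the score histogram
  combining a log-quadratic baseline (exactly the normal family) with
  natural-spline terms; **BIC decides whether the spline terms are kept**.
  Under a complete null the fit collapses to its fitted normal and the lfdr
  is near 1 everywhere, which keeps lone extreme order statistics from
  masquerading as signal — the known failure mode of flexible tail
  estimates at a few hundred units;
* the empirical null `f0` is Normal with median location and scale matched
  on the central 80% (10–90% quantile distance), so a minority of
  informative tail units cannot inflate it. A theoretical N(0,1) null is
  available; with fewer than 50 units the empirical fit is refused and the
  selection loop falls back to the theoretical null;
* `pi0` is count-matched on the central 90% null interval with a one-sided
  upper confidence correction, clamped at 1, so pure sampling noise cannot
  push it below 1 under a complete null.

Selection runs five-fold CV repeated 100 times for pathways (500 rounds)
and 20 times for genes (100 rounds); folds are stratified by outcome and
round r derives its fold assignment from `seed + r`. A unit passes a round
when its lfdr, computed on the retained four-fifths only, is below 0.8; it
is selected when it passes in strictly more than 50% of rounds. The
held-out fifth never enters the computation, so selection cannot leak
test-partition information.

## 3. Prediction, clinical score, evaluation

**Gradient boosting.** Selected unit scores (optionally plus the clinical
risk score) feed gradient-boosted trees with binomial deviance, shrinkage
0.1 and minimum terminal-node size 10 — these two hyperparameters are part
of the method's contract. The number of trees (50–500 by 50) and
interaction depth (1–3) are tuned by repeated stratified five-fold CV
maximizing mean held-out AUC; ties prefer the simpler model. The engine is
xgboost (`lambda = 0`, no subsampling, single-threaded for bit
reproducibility); the tuning loop itself is implemented in the package, and
one booster per fold is trained at the maximum tree count with intermediate
predictions sliced out, so the grid costs one fit per depth. Importances
are total split-gain attributions normalized to sum to 100.

**Clinical risk score.** One multivariable logistic model of the outcome on
the candidate clinical variables (suicidal risk, previous episodes, chronic
depression, MADRS pessimism and interest-activity factors) on training rows
only; variables with Wald p below `alpha / n candidates` are retained with
their Wald z as weight. "Independently associated" is read as mutually
adjusted; a univariate-screen mode exists behind a flag. A subject's score
is `sum(value x z) / number of retained variables available`, which keeps
subjects with partially missing data. The per-subject denominator means a
missing variable changes the denominator even when its value would have
been 0 — asserted explicitly in the tests.

**Evaluation.** AUC is the Mann–Whitney statistic (ties one half) with
DeLong structural-component variance and a normal-approximation 95% CI
clipped to [0, 1]; model comparisons use the paired DeLong test. Both are
backed by pROC with a fixed direction (an AUC below 0.5 is reported as
such), and validated in the tests against exhaustive pair counting and a
stratified bootstrap. Sensitivity/specificity/PPV/NPV use a threshold
chosen by Youden's J on training predictions and frozen for testing — the
reporting rule is not dictated by the AUC machinery, so we document this
package-level choice. The total genetic score is the importance-weighted
sum of a model's unit scores; the extreme-percentile analysis retains
subjects at or below / at or above the chosen percentiles (30/70 by
default; 20/80 and 10/90 suit larger replication-style samples), computed
with the linear-interpolation quantile convention, boundaries inclusive.

The 70/30 split is stratified by outcome with per-class rounding and a
largest-remainder correction toward the overall target. With class sizes
504/416/289 this yields 846 training subjects; printed splits from other
software can differ by one or two subjects because library-specific
rounding is not standardized, so exact reproduction of any particular
split total is a non-goal.

## 4. The synthetic-cohort generator

The generator emulates the statistical structure the analysis assumes, not
any real dataset:

* **Cohort scale.** 1209 subjects, outcome mix 504/416/289
  (TRD/non-response/response), eight recruitment centres with N(0, 0.1)
  liability effects — adjusting for centre only makes sense if the
  simulation induces centre structure.
* **Variants.** 300 genes with 6 rare + 2 common variants each. Rare
  alternative-allele frequencies are drawn below `1/sqrt(2n)` from a
  Beta-skewed spectrum; common folded MAFs are uniform above it, with 10%
  of alternative alleles being the major allele to exercise folding.
  Eigen-like scores follow the mixture `0.8 |N(0, 0.3)| + 0.2 |N(2, 1)|`
  (mass near zero plus a heavy right tail); CADD-like scores are a noisy
  monotone transform; SO scores sit on the 0.1–1.0 grid. No distributional
  facts about real Eigen or MAF spectra are being reconstructed — these
  are stated conventions.
* **LD.** Optional within-gene Gaussian-copula AR(1) latents with
  configurable r²; genotypes are binomial(2, f) marginally either way.
  There is no coalescent-style haplotype structure.
* **Outcome.** Latent liability = `genetic_effect x burden_z +
  clinical_effect x clin_z + centre effect + N(0, 1)`, with classes cut at
  empirical liability quantiles to match the target mix. `burden_z` is the
  standardized weighted rare-variant burden over the causal pathways,
  computed with the same Eigen x Beta(1, 25) weighting the pipeline
  estimates — so the planted signal is recoverable in principle, and the
  generative "Bayes AUC" (the AUC of the systematic liability component,
  TRD vs response) is an honest ceiling for any predictor built from the
  data. The centre effect is excluded from that systematic component
  because the analysis treats centre as a nuisance covariate.
* **Clinical variables.** Five independent risk factors (binary suicidal
  risk, Poisson episode count, binary chronicity, two continuous MADRS
  factors) whose weighted sum plus residual noise *is* the clinical
  liability. Making them independent contributors — rather than noisy
  proxies of one latent factor — matches the intended situation of several
  clinical variables each independently associated with outcome, and keeps
  the multivariable Bonferroni screen meaningful.
* **Effect sizes.** Defaults `genetic_effect = 0.38` over 4 causal
  pathways and `clinical_effect = 0.32` were calibrated once so the
  generative Bayes AUC for TRD vs response is about 0.75 — the
  discrimination level of a combined clinical-genetic predictor worth
  studying — with the clinical component slightly the stronger, as is
  typical for TRD risk factors. MADRS trajectories and failed-treatment
  counts are generated consistently with the outcome rule, so
  `define_outcome()` round-trips on simulated phenotypes; a secondary
  trial-history mode generates per-treatment outcomes for
  phenotype-definition tests.
* **Tail mode.** `genetic_model = "tail"` restricts the genetic effect to
  subjects beyond the 85th percentile of absolute burden, concentrating
  signal in the extremes of the genetic score distribution; this is the
  regime in which the extreme-percentile analysis should outperform the
  whole-sample AUC.

What passing tests on these cohorts does **not** show: robustness to real
LD and population stratification beyond supplied PCs, to annotation error
in `w_s`, to genotype missingness patterns of real platforms, or to
phenotype misclassification — none of which the generator emulates.

## 5. Numerical choices and degenerate inputs

* Beta weights error on frequencies of exactly 0 or 1 when a shape
  parameter is below 1 (unbounded density) rather than returning Inf.
* A zero standard deviation disables outlier exclusion; constant features
  give p = 1 in association tests; all-equal score vectors give lfdr = 1.
* Quasi-separated multinomial fits are re-fit with a small ridge penalty
  (`decay = 0.01`) and flagged — never a silent NA.
* LFDR histograms use at most `3 sqrt(m)` bins (minimum 20) and spline
  df 4 below 500 units, 5 above; these were fixed from the estimator's
  null-calibration behaviour described in section 2.
* Ties in LD clumping break by (chromosome, position, variant id); ties in
  Youden thresholds take the smallest threshold; ties in GBM tuning take
  the smaller depth, then fewer trees.
* All simulation draws run under seeds derived from the configuration seed
  with fixed offsets, and the caller's RNG state is restored afterwards;
  two runs from one config are bit-identical.

## 6. Problem sizes in the tests and acceptance script

The test suite and `scripts/acceptance.R` exercise the pipeline at sizes
chosen to make the statistical properties measurable while keeping runs
quick: planted-design selection at n = 800 with 200 units; null
calibration of the full pipeline at n = 800 with 10 selection repeats and
a reduced tuning grid over 20 seeds; generator-truth recovery at n = 2000
with the full 100-repeat selection; DeLong type-I error at n = 200 over
1000 replicates; tail-mode comparisons at n = 2000 over 10 seeds. The
full-scale settings (500 selection rounds, 100-repeat GBM tuning) remain
the package defaults.

## 7. Known limitations

* The burden score is a sum of weighted allele counts; it cannot represent
  interactions between variants within a unit, and the total genetic score
  linearizes a tree ensemble, ignoring its interactions by construction.
* The empirical-null LFDR is conservative by design (BIC-gated marginal,
  upper-bounded pi0); weak diffuse signal below the BIC detection limit is
  ignored.
* Multinomial group tests assume independent subjects; family or cryptic
  relatedness structure is out of scope.
* The generator's clinical module draws treatment class independently of
  everything else, so class-specific analyses on synthetic data test
  plumbing, not confounding by indication.
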