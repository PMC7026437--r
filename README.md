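# trdburden

Weighted functional-burden scoring of rare and common genetic variants and
prediction of treatment-resistant depression (TRD).

About 30% of patients with major depressive disorder fail to respond to two
or more adequate antidepressant treatments. `trdburden` implements, as a
tested R package plus analysis workflow, a pipeline for asking whether the
exome-wide burden of functionally relevant variants — aggregated within
genes or pathways — predicts TRD versus response, alone and alongside
clinical risk factors. It is aimed at statistical geneticists and
pharmacogenomics researchers who want the full procedure (scoring,
screening, boosting, ROC evaluation) reproducible end-to-end on synthetic
cohorts with known ground truth.

## The method

For each subject and analysis unit (whole exome, gene, or pathway) the
burden score is

    score = sum over member variants of  v_all x w_s x w_f

where `v_all` is the subject's alternative-allele count, `w_s` a composite
functional score (Eigen by default; CADD or sequence-ontology scores as
alternatives), and `w_f = dbeta(alt_freq, 1, 25)` for rare variants
(MAF < 1/sqrt(2n), i.e. 0.02 at n = 1209) or `dbeta(alt_freq, 0.5, 0.5)`
for common variants, which are first LD-clumped in descending `w_s` order.
Scores are adjusted for three ancestry principal components and recruitment
centre; subjects more than 5 SD from the exome-wide score mean are
excluded.

Downstream, the pipeline:

1. screens units with correlation-adjusted t-scores (CAT,
   `R^(-1/2) t` with Schaefer–Strimmer shrinkage) and an empirical-null
   local false discovery rate, keeping units with LFDR < 0.8 in more than
   50% of repeated five-fold CV rounds (500 rounds for pathways, 100 for
   genes);
2. trains gradient-boosted tree models (shrinkage 0.1, minimum node size
   10; trees and depth tuned by repeated stratified CV on AUC) on the
   selected scores, with and without a z-weighted clinical risk score
   (`sum(value x z) / n available` per subject);
3. evaluates on a held-out 30% stratified split with DeLong AUC confidence
   intervals, paired DeLong model comparisons, confusion metrics at the
   training Youden threshold, and an extreme-percentile analysis of the
   importance-weighted total genetic score (subjects at or below the 30th /
   at or above the 70th percentile).

A synthetic-cohort generator (`sim_config()`, `simulate_cohort()`) provides
GSRD-like cohorts — 1209 subjects, outcome mix 504/416/289
(TRD/non-response/response), multicentre structure, planted causal pathways
and clinical risk factors — with ground truth for recovery tests.

## Worked example

```r
library(trdburden)
res <- run_pipeline(sim_config(n_subjects = 2000, seed = 1),
                    selection_repeats = 100, gbm_repeats = 20)
```

This simulates a cohort with four causal pathways (generative Bayes AUC
0.742 for TRD vs response), scores and adjusts 60 pathway burden scores,
selects predictors, and evaluates on the held-out test set. The run above
prints (via `analysis/04_predict_evaluate.R`):

```
generative Bayes AUC:        0.742
genetic predictors only:     AUC 0.63 (0.57-0.68)
genetic + clinical score:    AUC 0.71 (0.66-0.76)
clinical score only:         AUC 0.66 (0.61-0.72)
extreme percentiles (30/70): AUC 0.69 (0.62-0.76)
selected pathways (5): PATHWAY020, PATHWAY030, PATHWAY047, PATHWAY049, PATHWAY057
```

Four of the five selected pathways are the planted causal ones; the
genetic+clinical model approaches the generative ceiling (0.71 vs 0.742),
and adding the clinical score improves on genetics alone — the qualitative
pattern the method is designed to expose. The numbered scripts under
`analysis/` walk through the same workflow step by step (simulation,
scoring and association scans, predictor selection, prediction and
evaluation), writing tables under `results/`.

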