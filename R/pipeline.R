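#' Map analysis units to member rare/common variant ids
#'
#' @param variants Variant table.
#' @param gene_sets Named list of pathways (for `unit = "pathway"`).
#' @param unit `"gene"`, `"pathway"` or `"exome"`.
#' @param variant_class `"rare_only"` or `"rare_plus_common"`.
#' @param rare_maf_threshold MAF threshold defining rare.
#' @return Named list unit -> character vector of variant ids (a variant
#'   appears once per unit even when shared by overlapping genes).
#' @export
unit_membership <- function(variants, gene_sets = NULL,
                            unit = c("pathway", "gene", "exome"),
                            variant_class = c("rare_only", "rare_plus_common"),
                            rare_maf_threshold = 0.02) {
  unit <- match.arg(unit)
  variant_class <- match.arg(variant_class)
  v <- if (variant_class == "rare_only") {
    variants[variants$maf < rare_maf_threshold, , drop = FALSE]
  } else variants
  if (unit == "exome") return(list(exome = v$variant_id))
  if (unit == "gene") return(split(v$variant_id, v$gene))
  stopifnot(!is.null(gene_sets))
  lapply(gene_sets, function(genes) unique(v$variant_id[v$gene %in% genes]))
}

config_digest <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(deparse(x), collapse = ""), f)
  unname(tools::md5sum(f))
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Simulate -> score -> adjust -> split -> select -> clinical fit -> boost
#' -> evaluate. Burden scores for the chosen unit/variant class are
#' covariate-adjusted (3 PCs + centre), subjects outside `outlier_sd`
#' standard deviations of the exome-wide score are removed, the cohort is
#' split 70/30 stratified by outcome, and predictors for TRD vs response
#' are chosen by repeated CAT/LFDR selection on the training set. A
#' z-weighted clinical risk score is fitted on the training set, GBMs are
#' trained with and without it, and all models are evaluated on the held-out
#' test set with DeLong CIs, paired DeLong comparisons against the clinical
#' score, confusion metrics at the training Youden threshold, and an
#' extreme-percentile analysis of the importance-weighted total genetic
#' score.
#'
#' If the selection step returns no unit, the `fallback_top_k` units with
#' the highest selection frequency are used (with a warning) so the
#' downstream model remains defined.
#'
#' @param config A [sim_config()].
#' @param unit,variant_class Scoring unit and variant class (defaults:
#'   pathway scores over rare variants).
#' @param selection_repeats CV repeats for predictor selection (100 for
#'   pathways, 20 for genes).
#' @param gbm_repeats CV repeats for GBM tuning.
#' @param gbm_grid Tuning grid passed to [train_gbm()].
#' @param clinical_alpha FWER for the clinical-score Bonferroni screen.
#' @param extreme_pcts Percentile bounds for the extreme-score analysis.
#' @param fallback_top_k Predictors to keep when selection is empty.
#' @param outlier_sd Exome-score outlier exclusion threshold (SDs).
#' @param permute_labels Permute the outcome labels across subjects (seeded)
#'   before any analysis step; used for null-calibration checks.
#' @param out_dir Optional directory; when given, reports are written as
#'   CSV/JSON alongside a provenance log.
#' @return List with the cohort, score matrices, selection report, clinical
#'   spec, fitted models, per-model test evaluations, the extreme-percentile
#'   evaluation, and provenance metadata.
#' @export
run_pipeline <- function(config = sim_config(),
                         unit = "pathway",
                         variant_class = "rare_only",
                         selection_repeats = 100L,
                         gbm_repeats = 20L,
                         gbm_grid = list(n_trees = seq(50L, 500L, by = 50L), depth = 1:3),
                         clinical_alpha = 0.05,
                         extreme_pcts = c(30, 70),
                         fallback_top_k = 5L,
                         outlier_sd = 5,
                         permute_labels = FALSE,
                         out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cohort <- simulate_cohort(config)
  if (permute_labels) {
    cohort$phenotypes$outcome <- with_seed(config$seed + 808L,
                                           sample(cohort$phenotypes$outcome))
  }
  thr <- maf_threshold(config$n_subjects)
  scheme <- weighting_scheme("eigen", rare_maf_threshold = thr)

  membership <- unit_membership(cohort$variants, cohort$gene_sets,
                                unit = unit, variant_class = variant_class,
                                rare_maf_threshold = thr)
  raw <- unit_scores(cohort$genotypes, cohort$variants, scheme, membership)

  exome <- exome_wide_score(cohort$genotypes, cohort$variants, scheme)
  qc <- exclude_score_outliers(exome, k = outlier_sd)
  keep <- qc$kept
  phen <- cohort$phenotypes[match(keep, cohort$phenotypes$subject_id), , drop = FALSE]
  adj <- adjust_scores(
    unit_score_matrix(unclass(raw)[keep, , drop = FALSE],
                      attr(raw, "variant_class"), FALSE), phen)

  split <- stratified_split(phen$subject_id, phen$outcome, 0.7, seed = config$seed)
  is_train <- phen$subject_id %in% split$train
  lab <- phen$outcome
  use <- lab != "NONRESP"              # TRD vs response
  y <- as.integer(lab == "TRD")

  tr <- is_train & use
  te <- !is_train & use
  sel <- repeated_cv_select(unclass(adj)[tr, , drop = FALSE], y[tr],
                            selection_config(repeats = selection_repeats,
                                             seed = config$seed))
  chosen <- sel$unit[sel$selected]
  if (length(chosen) == 0) {
    chosen <- sel$unit[order(-sel$frequency, sel$unit)][seq_len(min(fallback_top_k, nrow(sel)))]
    warning("no unit passed selection; falling back to the top ",
            length(chosen), " by selection frequency")
  }

  clin_vars <- c("suicidal_risk", "n_prev_episodes", "chronic_depression",
                 "madrs_pessimism", "madrs_interest")
  clin_spec <- suppressWarnings(
    fit_clinical_weights(phen[tr, , drop = FALSE], y[tr], clin_vars,
                         alpha = clinical_alpha))
  clin_score <- clinical_risk_score(phen, clin_spec)

  Xg <- unclass(adj)[, chosen, drop = FALSE]
  Xgc <- cbind(Xg, clinical_score = clin_score)

  gbm_gen <- train_gbm(Xg[tr, , drop = FALSE], y[tr], repeats = gbm_repeats,
                       grid = gbm_grid, seed = config$seed)
  gbm_gc <- train_gbm(Xgc[tr, , drop = FALSE], y[tr], repeats = gbm_repeats,
                      grid = gbm_grid, seed = config$seed)

  pred_gen_tr <- predict(gbm_gen, Xg[tr, , drop = FALSE])
  pred_gen_te <- predict(gbm_gen, Xg[te, , drop = FALSE])
  pred_gc_te <- predict(gbm_gc, Xgc[te, , drop = FALSE])
  clin_te <- clin_score[te]

  thr_youden <- youden_threshold(pred_gen_tr, y[tr])
  eval_genetic <- evaluate_model(pred_gen_te, y[te], thr_youden,
                                 comparisons = list(clinical = clin_te))
  eval_gc <- evaluate_model(pred_gc_te, y[te],
                            youden_threshold(predict(gbm_gc, Xgc[tr, , drop = FALSE]), y[tr]),
                            comparisons = list(clinical = clin_te))
  eval_clinical <- roc_auc_delong(clin_te, y[te])

  total <- total_genetic_score(unclass(adj)[, chosen, drop = FALSE], gbm_gen)
  te_ids <- phen$subject_id[te]
  ext_ids <- extreme_percentile_subset(total[te_ids], extreme_pcts[1], extreme_pcts[2])
  ext_idx <- match(ext_ids, te_ids)
  eval_extreme <- if (length(unique(y[te][ext_idx])) == 2L) {
    roc_auc_delong(pred_gen_te[ext_idx], y[te][ext_idx])
  } else NULL

  provenance <- list(seed = config$seed, config_md5 = config_digest(config),
                     package_version = as.character(utils::packageVersion("trdburden")),
                     n_train = sum(is_train), n_test = sum(!is_train),
                     n_excluded_outliers = length(qc$excluded),
                     unit = unit, variant_class = variant_class,
                     selection_rounds = sel$n_rounds[1],
                     n_selected = sum(sel$selected))

  result <- list(cohort = cohort, scores = adj, selection = sel,
                 selected_units = chosen, clinical_spec = clin_spec,
                 clinical_score = clin_score,
                 split = split, labels = y, use = use, train = tr, test = te,
                 model_genetic = gbm_gen, model_genetic_clinical = gbm_gc,
                 total_genetic_score = total,
                 eval_genetic = eval_genetic,
                 eval_genetic_clinical = eval_gc,
                 eval_clinical = eval_clinical,
                 eval_extreme = eval_extreme,
                 provenance = provenance)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(sel, file.path(out_dir, "selection_report.csv"), row.names = FALSE)
    write_clinical_spec(clin_spec, file.path(out_dir, "clinical_spec.json"))
    utils::write.csv(data.frame(subject_id = names(total), total_genetic_score = total),
                     file.path(out_dir, "total_genetic_score.csv"), row.names = FALSE)
    evals <- list(genetic = eval_genetic, genetic_clinical = eval_gc,
                  clinical = eval_clinical, extreme = eval_extreme)
    jsonlite::write_json(evals, file.path(out_dir, "evaluation.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}
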