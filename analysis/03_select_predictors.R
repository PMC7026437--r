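#!/usr/bin/env Rscript

# Predictor selection on the training partition: repeated five-fold CAT +
# local-FDR screening of adjusted pathway scores for TRD vs response
# (100 repeats = 500 rounds, as for pathway predictors).

library(trdburden)

out <- "results"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 1)
co <- simulate_cohort(cfg)
thr <- maf_threshold(cfg$n_subjects)
scheme <- weighting_scheme("eigen", rare_maf_threshold = thr)

exome <- exome_wide_score(co$genotypes, co$variants, scheme)
keep <- exclude_score_outliers(exome, k = 5)$kept
phen <- co$phenotypes[match(keep, co$phenotypes$subject_id), ]
membership <- unit_membership(co$variants, co$gene_sets, "pathway",
                              "rare_only", thr)
raw <- unit_scores(co$genotypes, co$variants, scheme, membership)
adj <- adjust_scores(
  structure(unclass(raw)[keep, , drop = FALSE],
            variant_class = attr(raw, "variant_class"), adjusted = FALSE,
            class = class(raw)), phen)

sp <- stratified_split(phen$subject_id, phen$outcome, 0.7, seed = cfg$seed)
tr <- phen$subject_id %in% sp$train & phen$outcome != "NONRESP"
y <- as.integer(phen$outcome == "TRD")

sel <- repeated_cv_select(unclass(adj)[tr, ], y[tr],
                          selection_config(repeats = 100, seed = cfg$seed))
write.csv(sel, file.path(out, "selection_report.csv"), row.names = FALSE)

cat(sprintf("selection over %d rounds: %d of %d pathways selected\n",
            sel$n_rounds[1], sum(sel$selected), nrow(sel)))
print(sel[sel$selected, c("unit", "mean_cat", "frequency")], row.names = FALSE)
cat("planted causal pathways:",
    paste(co$truth$causal_pathway_ids, collapse = ", "), "\n")
hit <- intersect(sel$unit[sel$selected], co$truth$causal_pathway_ids)
cat(sprintf("recovered %d of %d causal pathways\n",
            length(hit), length(co$truth$causal_pathway_ids)))
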