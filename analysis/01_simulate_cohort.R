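#!/usr/bin/env Rscript

# Simulate the default GSRD-like synthetic cohort and write it out in the
# standard interchange formats (VCF genotypes, TSV annotations, GMT gene
# sets, CSV phenotypes), together with the planted ground truth.

library(trdburden)

out <- "results/cohort"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 1)
co <- simulate_cohort(cfg)

write_vcf(co$genotypes, co$variants, file.path(out, "genotypes.vcf"))
write_annotation_tsv(co$variants, file.path(out, "annotations.tsv"))
write_gmt(co$gene_sets, file.path(out, "pathways.gmt"))
write_phenotypes_csv(co$phenotypes, file.path(out, "phenotypes.csv"))
jsonlite::write_json(
  list(causal_pathways = co$truth$causal_pathway_ids,
       bayes_auc = co$truth$bayes_auc, seed = cfg$seed),
  file.path(out, "ground_truth.json"), auto_unbox = TRUE, digits = NA)

cat(sprintf("cohort: %d subjects, %d variants (%d rare), %d pathways\n",
            nrow(co$genotypes), nrow(co$variants),
            sum(co$variants$maf < maf_threshold(cfg$n_subjects)),
            length(co$gene_sets)))
print(table(co$phenotypes$outcome))
cat(sprintf("planted causal pathways: %s\n",
            paste(co$truth$causal_pathway_ids, collapse = ", ")))
cat(sprintf("generative Bayes AUC (TRD vs response): %.3f\n", co$truth$bayes_auc))
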