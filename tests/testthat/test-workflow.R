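test_that("outcome definition applies the MADRS response rule and failure counts", {
  expect_equal(define_outcome(40, 18, 1), "RESP")       # <22 and >=50% drop
  expect_equal(define_outcome(40, 21, 2), "TRD")        # 47.5% drop, 2 failures
  expect_equal(define_outcome(30, 22, 1), "NONRESP")    # boundary: 22 is not <22
  expect_equal(define_outcome(40, 20, 0), "RESP")
  expect_equal(define_outcome(40, 21, 1), "NONRESP")    # 21 < 22 but drop < 50%
  expect_equal(define_outcome(42, 21, 0), "RESP")       # inclusive 50% boundary, <22
  expect_warning(out <- define_outcome(40, 30, 0), "unclassifiable")
  expect_equal(out, "UNCLASSIFIABLE")
  expect_error(define_outcome(0, 10, 1), "madrs_baseline")
})

test_that("stratified split balances classes and partitions the cohort", {
  set.seed(51)
  outc <- rep(c("TRD", "NONRESP", "RESP"), c(504, 416, 289))
  ids <- sprintf("P%04d", seq_along(outc))
  sp <- stratified_split(ids, outc, 0.7, seed = 1)
  expect_setequal(c(sp$train, sp$test), ids)
  expect_length(intersect(sp$train, sp$test), 0)
  tr_counts <- table(outc[ids %in% sp$train])[c("TRD", "NONRESP", "RESP")]
  expect_equal(as.numeric(tr_counts), c(353, 291, 202))
  expect_equal(length(sp$train), 846)

  sp2 <- stratified_split(sprintf("q%d", 1:20), rep(c("A", "B"), each = 10), 0.5, seed = 2)
  expect_equal(sum(rep(c("A", "B"), each = 10)[sprintf("q%d", 1:20) %in% sp2$train] == "A"), 5)
  expect_length(sp2$train, 10)
  expect_error(stratified_split(1:4, c("A", "A", "B", "B")), "3 subjects")
})

test_that("treatment subsetting drops combination therapy and is idempotent", {
  frame <- data.frame(subject_id = 1:8,
                      treatment_class = c("5HT", "5HT", "NA", "combo", "combo",
                                          "other", "NA", "5HT"))
  only5 <- subset_by_treatment(frame, "5HT")
  expect_true(all(only5$treatment_class == "5HT"))
  both <- subset_by_treatment(frame, c("5HT", "NA", "combo"))
  expect_setequal(unique(both$treatment_class), c("5HT", "NA"))
  expect_identical(subset_by_treatment(both, c("5HT", "NA")), both)
  expect_error(subset_by_treatment(frame, "nonexistent"), "empty")
})

test_that("imputation-quality filter applies strict class-specific cutoffs", {
  v <- data.frame(variant_id = sprintf("v%d", 1:6),
                  maf = c(0.01, 0.01, 0.3, 0.3, 0.01, 0.3),
                  info_r2 = c(0.60, 0.61, 0.30, 0.31, NA, 0.9))
  expect_message(kept <- imputation_quality_filter(v, 0.02), "missing")
  expect_setequal(kept$variant_id, c("v2", "v4", "v6"))
  # brute-force equivalence
  vv <- v[!is.na(v$info_r2), ]
  want <- vv$variant_id[ifelse(vv$maf < 0.02, vv$info_r2 > 0.60, vv$info_r2 > 0.30)]
  expect_setequal(kept$variant_id, want)
})

test_that("file formats round-trip: VCF, annotation TSV, GMT, phenotype CSV", {
  cfg <- sim_config(n_subjects = 25, n_genes = 8, n_pathways = 50,
                    genes_per_pathway = 3, seed = 52)
  co <- simulate_cohort(cfg)

  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(co$genotypes, co$variants, vcf)
  g2 <- read_vcf_genotypes(vcf)
  expect_identical(unclass(co$genotypes)[rownames(g2), colnames(g2)],
                   unclass(g2)[, ])

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_annotation_tsv(co$variants, tsv)
  v2 <- read_annotation_tsv(tsv)
  expect_equal(v2$variant_id, co$variants$variant_id)
  expect_equal(v2$alt_freq, co$variants$alt_freq, tolerance = 1e-12)

  gmt <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(co$gene_sets, gmt)
  gs2 <- read_gmt(gmt)
  expect_equal(gs2[names(co$gene_sets)], co$gene_sets)

  csv <- withr::local_tempfile(fileext = ".csv")
  write_phenotypes_csv(co$phenotypes, csv)
  p2 <- read_phenotypes_csv(csv)
  expect_equal(p2$outcome, co$phenotypes$outcome)
  expect_equal(p2$madrs_pessimism, co$phenotypes$madrs_pessimism, tolerance = 1e-6)
})

test_that("the pipeline is reproducible end-to-end and writes its reports", {
  cfg <- sim_config(n_subjects = 400, n_genes = 60, n_pathways = 50, seed = 53)
  out_dir <- withr::local_tempdir()
  r1 <- suppressWarnings(run_pipeline(cfg, selection_repeats = 3, gbm_repeats = 2,
                                      gbm_grid = list(n_trees = 50L, depth = 1L),
                                      out_dir = out_dir))
  r2 <- suppressWarnings(run_pipeline(cfg, selection_repeats = 3, gbm_repeats = 2,
                                      gbm_grid = list(n_trees = 50L, depth = 1L)))
  expect_identical(r1$selection, r2$selection)
  expect_identical(r1$eval_genetic, r2$eval_genetic)
  expect_identical(r1$total_genetic_score, r2$total_genetic_score)
  expect_identical(r1$provenance$config_md5, r2$provenance$config_md5)
  expect_true(all(file.exists(file.path(out_dir,
    c("selection_report.csv", "clinical_spec.json",
      "total_genetic_score.csv", "evaluation.json", "provenance.json")))))
  expect_equal(r1$provenance$seed, 53)
  # adjusted scores are centered
  expect_lt(max(abs(colMeans(unclass(r1$scores)))), 1e-8)
})
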