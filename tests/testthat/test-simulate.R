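test_that("variant table respects the rare/common frequency threshold", {
  cfg <- sim_config(n_subjects = 1209, n_genes = 40, seed = 2)
  v <- simulate_variant_table(cfg)
  thr <- 1 / sqrt(2 * 1209)
  rare <- v$maf < thr
  expect_equal(sum(rare), 40 * cfg$variants_per_gene_rare)
  expect_true(all(v$maf[rare] < 0.0203))
  expect_true(all(v$maf[!rare] > thr))
  expect_true(all(v$maf == pmin(v$alt_freq, 1 - v$alt_freq)))
  expect_true(all(table(v$gene) == cfg$variants_per_gene_rare + cfg$variants_per_gene_common))
  expect_true(all(v$so_score %in% seq(0.1, 1, by = 0.1)))
  expect_true(all(v$sift >= 0 & v$sift <= 1, na.rm = TRUE))
  expect_true(all(v$polyphen >= 0 & v$polyphen <= 1, na.rm = TRUE))
})

test_that("a zero rare stratum yields a common-only table", {
  cfg <- sim_config(n_subjects = 500, n_genes = 10, variants_per_gene_rare = 0, seed = 3)
  v <- simulate_variant_table(cfg)
  expect_true(all(v$maf > maf_threshold(500)))
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(n_subjects = 150, n_genes = 20, n_pathways = 50, seed = 7)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$variants, b$variants)
  expect_identical(unclass(a$genotypes), unclass(b$genotypes))
  expect_identical(a$gene_sets, b$gene_sets)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$truth, b$truth)
})

test_that("genotype frequencies calibrate to the generating frequencies", {
  cfg <- sim_config(n_subjects = 10000, n_genes = 5, variants_per_gene_rare = 2,
                    variants_per_gene_common = 2, n_pathways = 2,
                    genes_per_pathway = 2, n_causal_pathways = 1, seed = 5)
  v <- simulate_variant_table(cfg)
  v$alt_freq[1] <- 0.3; v$maf[1] <- 0.3
  g <- simulate_genotypes(v, cfg)
  means <- colMeans(unclass(g))
  expect_gte(means[v$variant_id[1]], 0.58)
  expect_lte(means[v$variant_id[1]], 0.62)
  err <- abs(means / 2 - v$alt_freq)
  bound <- 3 * sqrt(v$alt_freq * (1 - v$alt_freq) / (2 * 10000))
  expect_true(all(err < bound))
  expect_error(simulate_genotypes(transform(v, alt_freq = 0), cfg), "strictly")
})

test_that("LD control: independent variants decorrelate, copula mode correlates", {
  cfg <- sim_config(n_subjects = 5000, n_genes = 2, variants_per_gene_rare = 0,
                    variants_per_gene_common = 4, n_pathways = 2,
                    genes_per_pathway = 1, n_causal_pathways = 1, seed = 6,
                    ld_r2 = 0)
  v <- simulate_variant_table(cfg)
  g <- unclass(simulate_genotypes(v, cfg))
  ids <- v$variant_id[v$gene == v$gene[1]]
  expect_lt(abs(cor(g[, ids[1]], g[, ids[2]])), 0.05)

  cfg_ld <- sim_config(n_subjects = 5000, n_genes = 2, variants_per_gene_rare = 0,
                       variants_per_gene_common = 4, n_pathways = 2,
                       genes_per_pathway = 1, n_causal_pathways = 1, seed = 6,
                       ld_r2 = 0.8)
  gld <- unclass(simulate_genotypes(v, cfg_ld))
  # extreme allele frequencies attenuate genotype correlation, so judge LD on
  # the moderate-frequency variants of the gene
  mod <- ids[v$alt_freq[match(ids, v$variant_id)] > 0.1 &
               v$alt_freq[match(ids, v$variant_id)] < 0.9]
  r2 <- cor(gld[, mod])^2
  expect_gt(max(r2[upper.tri(r2)]), 0.3)
})

test_that("outcome classes match the target mix and the null case carries no signal", {
  cfg <- sim_config(n_subjects = 1209, class_mix = c(0.42, 0.34, 0.24), seed = 8,
                    n_genes = 60, n_pathways = 50)
  co <- simulate_cohort(cfg)
  counts <- table(co$phenotypes$outcome)[c("TRD", "NONRESP", "RESP")]
  expect_true(all(abs(counts - c(508, 411, 290)) <= 0.03 * 1209))

  cfg0 <- sim_config(n_subjects = 2000, genetic_effect = 0, clinical_effect = 0,
                     n_genes = 60, n_pathways = 50, seed = 9)
  co0 <- simulate_cohort(cfg0)
  ph <- co0$phenotypes
  use <- ph$outcome != "NONRESP"
  auc_burden <- pair_auc_fast(co0$truth$causal_burden[use], ph$outcome[use] == "TRD")
  expect_lt(abs(auc_burden - 0.5), 0.04)
})

test_that("the generative Bayes AUC increases with the genetic effect", {
  aucs <- vapply(c(0.3, 0.6, 0.9), function(g) {
    simulate_cohort(sim_config(n_subjects = 1500, genetic_effect = g,
                               n_genes = 60, n_pathways = 50,
                               clinical_effect = 0.2, seed = 10))$truth$bayes_auc
  }, numeric(1))
  expect_true(all(diff(aucs) > 0))
  expect_true(all(aucs >= 0.5 & aucs <= 1))
})

test_that("a logistic fit on the true burden recovers the generative effect", {
  cfg <- sim_config(n_subjects = 2500, genetic_effect = 0.5, clinical_effect = 0.2,
                    n_genes = 80, n_pathways = 50, seed = 11)
  co <- simulate_cohort(cfg)
  ph <- co$phenotypes
  use <- ph$outcome != "NONRESP"
  dat <- data.frame(y = as.integer(ph$outcome[use] == "TRD"),
                    b = co$truth$causal_burden[use])
  fit <- glm(y ~ b, data = dat, family = binomial())
  est <- coef(summary(fit))["b", ]

  # oracle: the implied log-odds per SD of burden under the liability-threshold
  # generator, computed by refitting on a fresh large cohort's latent draws
  cfg2 <- sim_config(n_subjects = 20000, genetic_effect = 0.5, clinical_effect = 0.2,
                     n_genes = 80, n_pathways = 50, seed = 12)
  co2 <- simulate_cohort(cfg2)
  use2 <- co2$phenotypes$outcome != "NONRESP"
  ref <- glm(y ~ b, family = binomial(),
             data = data.frame(y = as.integer(co2$phenotypes$outcome[use2] == "TRD"),
                               b = co2$truth$causal_burden[use2]))
  se_ref <- coef(summary(ref))["b", "Std. Error"]
  expect_lt(abs(est["Estimate"] - coef(ref)["b"]),
            2 * sqrt(est["Std. Error"]^2 + se_ref^2))
})

test_that("outcome fields are internally consistent with the phenotype rule", {
  co <- simulate_cohort(sim_config(n_subjects = 400, n_genes = 40, n_pathways = 50, seed = 13))
  ph <- co$phenotypes
  derived <- define_outcome(ph$madrs_baseline, ph$madrs_current,
                            ph$n_failed_adequate_treatments)
  expect_equal(derived, ph$outcome)
})

test_that("the trial-history generator produces classifiable outcomes", {
  th <- simulate_treatment_history(200, seed = 4)
  expect_true(all(th$outcome %in% c("RESP", "NONRESP", "TRD", "UNCLASSIFIABLE")))
  resp <- th$outcome == "RESP"
  expect_true(all(th$madrs_current[resp] < 22))
  expect_true(all(th$madrs_current[resp] <= 0.5 * th$madrs_baseline[resp]))
  expect_true(all(th$n_failed_adequate_treatments[th$outcome == "TRD"] >= 2))
})
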