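test_that("rare-variant MAF threshold follows 1/sqrt(2n)", {
  expect_equal(maf_threshold(1209), 1 / sqrt(2418))
  expect_equal(round(maf_threshold(1209), 2), 0.02)
  expect_equal(maf_threshold(50), 0.1)
  expect_equal(maf_threshold(2), 0.5)
  expect_error(maf_threshold(0), "count")
})

test_that("rare/common partition is strict, exhaustive and disjoint", {
  v <- tiny_variants(10)
  v$maf <- c(0.019, 0.02, 0.021, 0.001, 0.3, 0.5, 0.0199, 0.02000001, 0.1, 0.049)
  part <- partition_rare_common(v, 0.02)
  expect_true("v01" %in% part$rare)           # 0.019 < 0.02
  expect_true("v02" %in% part$common)         # boundary goes common
  expect_length(intersect(part$rare, part$common), 0)
  expect_setequal(c(part$rare, part$common), v$variant_id)
  expect_error(partition_rare_common(v, 0.6), "0.5")
})

test_that("frequency weights are the Beta densities in closed form", {
  expect_equal(frequency_weight(1e-12, c(1, 25)), 25 * (1 - 1e-12)^24,
               tolerance = 1e-12)
  expect_equal(frequency_weight(0.5, c(0.5, 0.5)), 2 / pi, tolerance = 1e-12)
  expect_equal(frequency_weight(0.02, c(1, 25)), 25 * 0.98^24, tolerance = 1e-12)
  # arcsine symmetry
  f <- runif(20, 0.01, 0.99)
  expect_equal(frequency_weight(f, c(0.5, 0.5)),
               frequency_weight(1 - f, c(0.5, 0.5)))
  expect_error(frequency_weight(0, c(0.5, 0.5)), "unbounded")
})

test_that("Beta(1,25) weight strictly decreases and Beta(0.5,0.5) grows at the edges", {
  x <- seq(0.001, 0.999, length.out = 200)
  w_rare <- frequency_weight(x, c(1, 25))
  expect_true(all(diff(w_rare) < 0))
  w_com <- frequency_weight(x, c(0.5, 0.5))
  half <- x <= 0.5
  expect_true(all(diff(w_com[half]) < 0))        # increases toward 0
  expect_true(all(diff(w_com[!half]) > 0))       # increases toward 1
})

test_that("unit scores match the hand-evaluated formula and the brute-force oracle", {
  # one subject, one rare variant: 1 x 0.5 x 25 * 0.99^24
  v <- tiny_variants(1)
  v$alt_freq <- 0.01; v$maf <- 0.01; v$eigen <- 0.5
  g <- genotype_matrix(matrix(1L, 1, 1, dimnames = list("S1", "v01")))
  sch <- weighting_scheme("eigen", rare_maf_threshold = 0.02)
  s <- unit_scores(g, v, sch, list(G01 = "v01"))
  expect_equal(s[1, 1], 0.5 * 25 * 0.99^24, tolerance = 1e-12)

  # zero genotypes give zero scores
  g0 <- genotype_matrix(matrix(0L, 2, 1, dimnames = list(c("S1", "S2"), "v01")))
  expect_true(all(unit_scores(g0, v, sch, list(G01 = "v01")) == 0))

  # random 20 x 50 instance vs triple loop, mixed rare/common, with missing
  set.seed(42)
  v <- tiny_variants(50, n_gene = 10, seed = 7)
  g <- tiny_genotypes(v, n_subj = 20, seed = 8)
  gm <- unclass(g); gm[sample(length(gm), 30)] <- NA
  g <- genotype_matrix(gm)
  membership <- split(v$variant_id, v$gene)
  got <- unit_scores(g, v, sch, membership)
  want <- brute_force_scores(g, v, sch, membership)
  expect_equal(unclass(got)[, colnames(want)], want, tolerance = 1e-12)
})

test_that("scores are linear in genotypes and independent of other samples", {
  sch <- weighting_scheme("eigen", rare_maf_threshold = 0.02)
  v <- tiny_variants(12, n_gene = 3, seed = 3)
  membership <- split(v$variant_id, v$gene)
  set.seed(9)
  G1 <- matrix(sample(0:1, 5 * 12, TRUE), 5, 12,
               dimnames = list(sprintf("S%d", 1:5), v$variant_id))
  G2 <- matrix(sample(0:1, 5 * 12, TRUE), 5, 12, dimnames = dimnames(G1))
  s1 <- unit_scores(genotype_matrix(G1), v, sch, membership)
  s2 <- unit_scores(genotype_matrix(G2), v, sch, membership)
  s12 <- unit_scores(genotype_matrix(G1 + G2), v, sch, membership)
  expect_equal(unclass(s12), unclass(s1) + unclass(s2), tolerance = 1e-12)

  # a subject's score must not react to other subjects' genotypes
  G1b <- G1; G1b[2:5, ] <- 2L - G1b[2:5, ]
  s1b <- unit_scores(genotype_matrix(G1b), v, sch, membership)
  expect_equal(unclass(s1b)[1, ], unclass(s1)[1, ])
})

test_that("exome-wide score sums gene scores and handles an empty rare set", {
  sch <- weighting_scheme("eigen", rare_maf_threshold = 0.02)
  v <- tiny_variants(12, n_gene = 3, seed = 3)
  g <- tiny_genotypes(v, 6, seed = 4)
  rare_ids <- v$variant_id[v$maf < 0.02]
  gene_scores <- unit_scores(g, v, sch,
                             split(rare_ids, v$gene[match(rare_ids, v$variant_id)]))
  ex <- exome_wide_score(g, v, sch)
  expect_equal(unname(unclass(ex)[, 1]), unname(rowSums(gene_scores)))

  v_common <- v; v_common$maf <- 0.3; v_common$alt_freq <- 0.3
  ex0 <- exome_wide_score(g, v_common, sch)
  expect_true(all(unclass(ex0) == 0))
})

test_that("score outlier exclusion applies the k-SD rule computed once", {
  x <- c(a = 0, b = 0, c = 0, d = 0, e = 100)
  res <- exclude_score_outliers(x, k = 5)
  # mean 20, sd ~44.7: 100 lies within 5 SD, nobody excluded
  expect_length(res$excluded, 0)
  expect_equal(res$bounds[2], mean(x) + 5 * sd(x))

  res2 <- exclude_score_outliers(c(a = 1, b = 1, c = 1), k = 5)
  expect_length(res2$excluded, 0)   # zero SD: no exclusions

  x3 <- c(rnorm(100), big = 50)
  names(x3) <- c(sprintf("s%03d", 1:100), "big")
  expect_equal(exclude_score_outliers(x3, k = 5)$excluded, "big")
})

test_that("LD clumping keeps the highest-scoring variant of a correlated pair", {
  v <- tiny_variants(3, n_gene = 1, seed = 5)
  v$alt_freq <- c(0.3, 0.3, 0.4); v$maf <- v$alt_freq
  v$eigen <- c(0.9, 0.4, 0.2)
  v$pos <- c(1000L, 2000L, 3000L)
  set.seed(6)
  base <- sample(0:2, 200, TRUE)
  G <- cbind(v01 = base, v02 = base, v03 = sample(0:2, 200, TRUE))
  rownames(G) <- sprintf("S%03d", 1:200)
  g <- genotype_matrix(G)
  kept <- ld_clump_common(v, g, r2_max = 0.5, window_kb = 250)
  expect_true("v01" %in% kept)
  expect_false("v02" %in% kept)   # duplicated column, lower functional score
  expect_true("v03" %in% kept)

  # post-hoc check on a random instance: no kept pair in-window with r2 > max
  set.seed(7)
  v2 <- tiny_variants(20, n_gene = 4, seed = 7)
  v2$alt_freq <- runif(20, 0.1, 0.5); v2$maf <- v2$alt_freq
  G2 <- matrix(sample(0:2, 100 * 20, TRUE), 100, 20,
               dimnames = list(sprintf("S%03d", 1:100), v2$variant_id))
  blk <- sample(0:2, 100, TRUE)
  G2[, 5] <- blk; G2[, 6] <- ifelse(runif(100) < 0.9, blk, sample(0:2, 100, TRUE))
  g2 <- genotype_matrix(G2)
  kept2 <- ld_clump_common(v2, g2, r2_max = 0.5, window_kb = 250)
  for (i in seq_along(kept2)) {
    for (j in seq_len(i - 1L)) {
      a <- kept2[i]; b <- kept2[j]
      ra <- v2[v2$variant_id == a, ]; rb <- v2[v2$variant_id == b, ]
      if (ra$chrom == rb$chrom && abs(ra$pos - rb$pos) <= 250000) {
        expect_lte(cor(G2[, a], G2[, b])^2, 0.5)
      }
    }
  }
})

test_that("covariate adjustment centers, decorrelates and recovers planted PC effects", {
  set.seed(11)
  n <- 2000
  cov <- data.frame(subject_id = sprintf("S%04d", 1:n),
                    pc1 = rnorm(n), pc2 = rnorm(n), pc3 = rnorm(n),
                    centre = sample(sprintf("C%d", 1:4), n, TRUE))
  noise <- rnorm(n)
  y <- 2.0 * cov$pc1 + noise
  sc <- unit_score_matrix <- structure(matrix(y, ncol = 1,
                                              dimnames = list(cov$subject_id, "u1")),
                                       variant_class = "rare_only", adjusted = FALSE,
                                       class = c("unit_score_matrix", "matrix", "array"))
  adj <- adjust_scores(sc, cov)
  expect_lt(abs(mean(adj)), 1e-8)
  expect_lt(abs(cor(unclass(adj)[, 1], cov$pc1)), 1e-10)
  expect_lt(abs(cor(unclass(adj)[, 1], cov$pc2)), 1e-10)
  expect_equal(var(unclass(adj)[, 1]), var(noise), tolerance = 0.05)

  # constant covariates reduce to centering
  cov0 <- cov; cov0$pc1 <- 0; cov0$pc2 <- 0; cov0$pc3 <- 0; cov0$centre <- "C1"
  expect_warning(adj0 <- adjust_scores(sc, cov0), "aliased")
  expect_equal(unname(unclass(adj0)[, 1]), unname(y - mean(y)), tolerance = 1e-10)
})

test_that("genotype concordance QC counts only non-major-homozygote entries", {
  v <- tiny_variants(10, n_gene = 2, seed = 12)
  v$alt_freq <- rep(0.01, 10); v$maf <- v$alt_freq
  g <- tiny_genotypes(v, 5, seed = 13)
  qc <- genotype_concordance_qc(g, g, v, "rare")
  expect_true(all(qc$concordance[!qc$unassessable] == 1))
  expect_false(any(qc$excluded))

  # 10 informative, 9 matching -> 0.90 -> excluded at the <=0.90 boundary
  A <- matrix(0L, 1, 10, dimnames = list("S1", v$variant_id))
  B <- A
  A[1, 1:10] <- 1L        # all informative in A
  B[1, 1:9] <- 1L         # 9 agree, one disagrees (B has major hom there)
  qc2 <- genotype_concordance_qc(genotype_matrix(A), genotype_matrix(B), v, "rare")
  expect_equal(qc2$concordance, 0.9)
  expect_true(qc2$excluded)

  # all-major-homozygote subject is unassessable
  Z <- matrix(0L, 1, 10, dimnames = list("S1", v$variant_id))
  qc3 <- genotype_concordance_qc(genotype_matrix(Z), genotype_matrix(Z), v, "rare")
  expect_true(qc3$unassessable)
})
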