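# Small deterministic fixtures built in code.

# A hand-sized variant table: n_var variants over n_gene genes, alternating
# rare/common frequencies, fixed annotations.
tiny_variants <- function(n_var = 6, n_gene = 2, seed = 1) {
  set.seed(seed)
  gene <- rep(sprintf("G%02d", seq_len(n_gene)), length.out = n_var)
  alt_freq <- rep(c(0.01, 0.30), length.out = n_var)
  data.frame(
    variant_id = sprintf("v%02d", seq_len(n_var)),
    chrom = "1", pos = seq_len(n_var) * 1000L,
    ref = "A", alt = "G",
    gene = gene, alt_freq = alt_freq, maf = pmin(alt_freq, 1 - alt_freq),
    eigen = seq(0.1, by = 0.1, length.out = n_var),
    cadd = seq(1, by = 1, length.out = n_var),
    so_score = rep(c(0.9, 0.5), length.out = n_var),
    sift = rep(c(0.01, 0.5), length.out = n_var),
    polyphen = rep(c(0.9, 0.1), length.out = n_var),
    stringsAsFactors = FALSE
  )
}

tiny_genotypes <- function(variants, n_subj = 4, seed = 1) {
  set.seed(seed)
  counts <- matrix(sample(0:2, n_subj * nrow(variants), replace = TRUE,
                          prob = c(0.7, 0.2, 0.1)),
                   nrow = n_subj,
                   dimnames = list(sprintf("S%02d", seq_len(n_subj)),
                                   variants$variant_id))
  genotype_matrix(counts)
}

# Brute-force burden score: explicit triple loop over subject, unit, variant.
brute_force_scores <- function(genotypes, variants, scheme, membership) {
  G <- unclass(genotypes)
  ws_col <- switch(scheme$functional_source,
                   eigen = "eigen", cadd = "cadd", so = "so_score")
  out <- matrix(0, nrow(G), length(membership),
                dimnames = list(rownames(G), names(membership)))
  for (i in seq_len(nrow(G))) {
    for (u in seq_along(membership)) {
      acc <- 0
      for (vid in unique(membership[[u]])) {
        row <- which(variants$variant_id == vid)
        cnt <- G[i, vid]
        if (is.na(cnt)) cnt <- 0
        beta <- if (variants$maf[row] < scheme$rare_maf_threshold) {
          scheme$rare_beta
        } else scheme$common_beta
        acc <- acc + cnt * variants[[ws_col]][row] *
          stats::dbeta(variants$alt_freq[row], beta[1], beta[2])
      }
      out[i, u] <- acc
    }
  }
  out
}

# Brute-force AUC: count concordant pairs, ties as 1/2.
pair_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  cases <- scores[labels]; ctrls <- scores[!labels]
  tot <- 0
  for (a in cases) for (b in ctrls) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(cases) * length(ctrls))
}

# rank-formula AUC for larger vectors (equivalent to pair counting)
pair_auc_fast <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  (sum(rank(scores)[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# planted two-class design for selection tests
planted_design <- function(n = 800, p = 200, k = 10, shift = 0.5, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- sprintf("u%03d", seq_len(p))
  y <- rep(0:1, length.out = n)
  X[y == 1, seq_len(k)] <- X[y == 1, seq_len(k)] + shift
  list(X = X, y = y, informative = colnames(X)[seq_len(k)])
}
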