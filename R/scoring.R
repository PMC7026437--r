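#' Rare-variant minor-allele-frequency threshold
#'
#' Rare variants are those with MAF below `1 / sqrt(2 * n)`, where `n` is the
#' number of subjects in the discovery sample. At n = 1209 this gives 0.0203,
#' i.e. 0.02 at two decimals.
#'
#' @param n_subjects Number of subjects (a positive count).
#' @return The MAF threshold, a value in (0, 0.5].
#' @export
#' @examples
#' maf_threshold(1209)
maf_threshold <- function(n_subjects) {
  if (!is.numeric(n_subjects) || length(n_subjects) != 1L ||
      is.na(n_subjects) || n_subjects < 1) {
    stop("`n_subjects` must be a single count >= 1")
  }
  1 / sqrt(2 * n_subjects)
}

#' Partition variants into rare and common by folded MAF
#'
#' Rare means `maf < threshold` (strict); the partition is exhaustive and
#' disjoint.
#'
#' @param variants A variant table (see [simulate_variant_table()]) with
#'   columns `variant_id` and `maf`.
#' @param threshold MAF threshold in (0, 0.5).
#' @return A list with character vectors `rare` and `common` of variant ids.
#' @export
partition_rare_common <- function(variants, threshold) {
  stopifnot(is.data.frame(variants), all(c("variant_id", "maf") %in% names(variants)))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 0.5) {
    stop("`threshold` must be in (0, 0.5)")
  }
  rare <- variants$maf < threshold
  list(rare = variants$variant_id[rare], common = variants$variant_id[!rare])
}

#' Beta-density frequency weight
#'
#' The frequency weight of a variant is the Beta(a, b) probability density
#' evaluated at its alternative-allele frequency: `dbeta(alt_freq, a, b)`.
#' Rare variants use Beta(1, 25), which up-weights low-frequency alleles
#' (weight 25 as the frequency approaches 0); common variants use the
#' arcsine-like Beta(0.5, 0.5), which is symmetric and mildly up-weights
#' both frequency extremes.
#'
#' @param alt_freq Alternative-allele frequency, in (0, 1). Vectorised.
#' @param beta_params Length-2 numeric `c(a, b)`, both positive.
#' @return Numeric vector of weights.
#' @export
#' @examples
#' frequency_weight(0.02, c(1, 25))
#' frequency_weight(0.5, c(0.5, 0.5))  # 2/pi
frequency_weight <- function(alt_freq, beta_params) {
  stopifnot(is.numeric(beta_params), length(beta_params) == 2L, all(beta_params > 0))
  if (any(!is.finite(alt_freq))) stop("`alt_freq` must be finite")
  bad_edge <- (alt_freq <= 0 & beta_params[1] < 1) | (alt_freq >= 1 & beta_params[2] < 1)
  if (any(bad_edge)) {
    stop("Beta density unbounded at the boundary for shape < 1; alt_freq must be in (0, 1)")
  }
  if (any(alt_freq < 0 | alt_freq > 1)) stop("`alt_freq` must lie in (0, 1)")
  stats::dbeta(alt_freq, beta_params[1], beta_params[2])
}

#' Construct a variant weighting scheme
#'
#' Bundles the functional-score source and the Beta frequency-weight
#' parameters used by [unit_scores()].
#'
#' @param functional_source One of `"eigen"`, `"cadd"`, `"so"` — the
#'   annotation column used as the functional weight w_s.
#' @param rare_beta Beta parameters for rare variants (default `c(1, 25)`).
#' @param common_beta Beta parameters for common variants (default
#'   `c(0.5, 0.5)`).
#' @param rare_maf_threshold MAF below which a variant is treated as rare;
#'   typically [maf_threshold()] of the discovery sample size.
#' @return An object of class `weighting_scheme`.
#' @export
weighting_scheme <- function(functional_source = c("eigen", "cadd", "so"),
                             rare_beta = c(1, 25),
                             common_beta = c(0.5, 0.5),
                             rare_maf_threshold = 0.02) {
  functional_source <- match.arg(functional_source)
  stopifnot(length(rare_beta) == 2L, all(rare_beta > 0),
            length(common_beta) == 2L, all(common_beta > 0))
  if (rare_maf_threshold <= 0 || rare_maf_threshold >= 0.5) {
    stop("`rare_maf_threshold` must be in (0, 0.5)")
  }
  structure(list(functional_source = functional_source,
                 rare_beta = rare_beta,
                 common_beta = common_beta,
                 rare_maf_threshold = rare_maf_threshold),
            class = "weighting_scheme")
}

# Per-variant composite weight w_s * w_f for the variants in `variants`,
# in table order. Rare/common status (folded MAF vs the scheme threshold)
# selects the Beta parameters; w_f is always evaluated at the unfolded
# alternative-allele frequency.
variant_weights <- function(variants, scheme) {
  stopifnot(inherits(scheme, "weighting_scheme"))
  ws_col <- switch(scheme$functional_source,
                   eigen = "eigen", cadd = "cadd", so = "so_score")
  if (!ws_col %in% names(variants)) {
    stop("annotation column '", ws_col, "' missing from variant table")
  }
  ws <- variants[[ws_col]]
  rare <- variants$maf < scheme$rare_maf_threshold
  wf <- numeric(nrow(variants))
  wf[rare]  <- frequency_weight(variants$alt_freq[rare], scheme$rare_beta)
  wf[!rare] <- frequency_weight(variants$alt_freq[!rare], scheme$common_beta)
  ws * wf
}

#' Weighted burden scores per analysis unit
#'
#' For each subject and unit (gene, pathway, or the whole exome) the burden
#' score is the sum over member variants of
#' `alt-allele count x functional score x frequency weight`. The frequency
#' weight comes from the alternative-allele frequency stored in the variant
#' table, never from the genotypes of the scored sample, so scores are
#' comparable across training, testing and replication partitions. Missing
#' genotypes contribute 0. A variant shared by several genes of one pathway
#' is counted once per pathway.
#'
#' @param genotypes A `genotype_matrix` (see [simulate_genotypes()] /
#'   [genotype_matrix()]): subjects x variants alt-allele counts in
#'   \{0, 1, 2\}, `NA` for missing.
#' @param variants Variant table with `variant_id`, `alt_freq`, `maf` and the
#'   functional-score column named by the scheme.
#' @param scheme A [weighting_scheme()].
#' @param membership Named list mapping unit id to a character vector of
#'   member variant ids.
#' @return A `unit_score_matrix`: numeric matrix subjects x units with
#'   attributes `variant_class` and `adjusted`.
#' @export
unit_scores <- function(genotypes, variants, scheme, membership) {
  stopifnot(inherits(genotypes, "genotype_matrix"), is.list(membership))
  if (is.null(names(membership)) || anyDuplicated(names(membership))) {
    stop("`membership` must be a uniquely named list of unit -> variant ids")
  }
  all_members <- unique(unlist(membership, use.names = FALSE))
  missing_v <- setdiff(all_members, variants$variant_id)
  if (length(missing_v)) {
    stop("membership references unknown variants: ", paste(utils::head(missing_v, 5), collapse = ", "))
  }
  missing_g <- setdiff(all_members, colnames(genotypes))
  if (length(missing_g)) {
    stop("membership references variants absent from the genotype matrix: ",
         paste(utils::head(missing_g, 5), collapse = ", "))
  }
  w <- variant_weights(variants, scheme)
  names(w) <- variants$variant_id

  counts <- unclass(genotypes)
  counts[is.na(counts)] <- 0
  out <- matrix(0, nrow(counts), length(membership),
                dimnames = list(rownames(counts), names(membership)))
  for (j in seq_along(membership)) {
    ids <- unique(membership[[j]])
    if (length(ids)) {
      out[, j] <- counts[, ids, drop = FALSE] %*% w[ids]
    }
  }
  rare <- all(variants$maf[variants$variant_id %in% all_members] < scheme$rare_maf_threshold)
  unit_score_matrix(out, variant_class = if (rare) "rare_only" else "rare_plus_common",
                    adjusted = FALSE)
}

#' @rdname unit_scores
#' @details [exome_wide_score()] is [unit_scores()] with a single unit,
#'   `"exome"`, whose members are all rare variants in the table.
#' @export
exome_wide_score <- function(genotypes, variants, scheme) {
  rare_ids <- variants$variant_id[variants$maf < scheme$rare_maf_threshold]
  unit_scores(genotypes, variants, scheme, list(exome = rare_ids))
}

# light S3 container: numeric matrix + score metadata
unit_score_matrix <- function(x, variant_class, adjusted) {
  stopifnot(is.matrix(x), is.numeric(x))
  structure(x, variant_class = variant_class, adjusted = adjusted,
            class = c("unit_score_matrix", "matrix", "array"))
}

#' @exportS3Method base::print
print.unit_score_matrix <- function(x, ...) {
  cat(sprintf("unit_score_matrix: %d subjects x %d units (%s, %s)\n",
              nrow(x), ncol(x), attr(x, "variant_class"),
              if (isTRUE(attr(x, "adjusted"))) "covariate-adjusted" else "raw"))
  invisible(x)
}

#' Exclude subjects with extreme burden scores
#'
#' Flags subjects whose score lies more than `k` sample standard deviations
#' from the sample mean (both computed once, on the full set). A zero
#' standard deviation excludes nobody.
#'
#' @param scores Numeric vector of per-subject scores (one unit), named by
#'   subject id, or a single-column `unit_score_matrix`.
#' @param k Number of standard deviations (default 5).
#' @return List with `kept` and `excluded` subject ids and the numeric
#'   `bounds` used.
#' @export
exclude_score_outliers <- function(scores, k = 5) {
  if (is.matrix(scores)) {
    stopifnot(ncol(scores) == 1L)
    scores <- stats::setNames(scores[, 1L], rownames(scores))
  }
  if (length(scores) < 2L) stop("need at least 2 subjects")
  ids <- names(scores)
  if (is.null(ids)) ids <- as.character(seq_along(scores))
  m <- mean(scores)
  s <- stats::sd(scores)
  if (s == 0) {
    return(list(kept = ids, excluded = character(0), bounds = c(m, m)))
  }
  out <- abs(scores - m) > k * s
  list(kept = ids[!out], excluded = ids[out], bounds = c(m - k * s, m + k * s))
}

#' Greedy LD clumping of common variants by functional score
#'
#' Candidates are visited in descending functional-score order (ties broken
#' by chromosome, position, then variant id); a candidate is dropped when its
#' genotype r-squared with an already-kept variant on the same chromosome
#' within `window_kb` exceeds `r2_max`.
#'
#' @param variants Variant table restricted to the candidates (needs
#'   `variant_id`, `chrom`, `pos`, and the functional column of `scheme`).
#' @param genotypes `genotype_matrix` covering the candidates.
#' @param r2_max Maximum allowed squared correlation, in (0, 1].
#' @param window_kb Window in kilobases within which LD is checked.
#' @param scheme A [weighting_scheme()] naming the functional source
#'   (default Eigen).
#' @return Character vector of kept variant ids.
#' @export
ld_clump_common <- function(variants, genotypes, r2_max = 0.5, window_kb = 250,
                            scheme = weighting_scheme()) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (r2_max <= 0 || r2_max > 1) stop("`r2_max` must be in (0, 1]")
  ws_col <- switch(scheme$functional_source,
                   eigen = "eigen", cadd = "cadd", so = "so_score")
  ord <- order(-variants[[ws_col]], variants$chrom, variants$pos, variants$variant_id)
  v <- variants[ord, , drop = FALSE]
  G <- unclass(genotypes)
  kept <- character(0)
  kept_chrom <- character(0)
  kept_pos <- numeric(0)
  win <- window_kb * 1000
  for (i in seq_len(nrow(v))) {
    id <- v$variant_id[i]
    near <- kept[kept_chrom == v$chrom[i] & abs(kept_pos - v$pos[i]) <= win]
    ok <- TRUE
    for (kid in near) {
      r <- suppressWarnings(stats::cor(G[, id], G[, kid], use = "pairwise.complete.obs"))
      if (!is.na(r) && r^2 > r2_max) { ok <- FALSE; break }
    }
    if (ok) {
      kept <- c(kept, id)
      kept_chrom <- c(kept_chrom, v$chrom[i])
      kept_pos <- c(kept_pos, v$pos[i])
    }
  }
  kept
}

#' Adjust unit scores for ancestry and recruitment centre
#'
#' Replaces each unit's scores with the least-squares residuals of a
#' regression on the first three principal components and recruitment-centre
#' indicator contrasts (plus intercept). Aliased centre columns in a
#' rank-deficient design are dropped with a warning.
#'
#' @param scores A `unit_score_matrix` (subjects x units).
#' @param covariates Data frame with one row per scored subject (matched by
#'   `subject_id` against the score rownames) containing `pc1`, `pc2`, `pc3`
#'   and `centre`.
#' @return A `unit_score_matrix` with `adjusted = TRUE`; column means are
#'   zero by construction.
#' @export
adjust_scores <- function(scores, covariates) {
  stopifnot(inherits(scores, "unit_score_matrix"),
            all(c("subject_id", "pc1", "pc2", "pc3", "centre") %in% names(covariates)))
  idx <- match(rownames(scores), covariates$subject_id)
  if (anyNA(idx)) stop("covariates missing for some scored subjects")
  cov <- covariates[idx, , drop = FALSE]
  if (anyNA(cov[, c("pc1", "pc2", "pc3", "centre")])) {
    stop("covariates must be complete for scored subjects")
  }
  centre <- factor(cov$centre)
  X <- if (nlevels(centre) > 1) {
    stats::model.matrix(~ pc1 + pc2 + pc3 + centre, data = cbind(cov, centre = centre))
  } else {
    stats::model.matrix(~ pc1 + pc2 + pc3, data = cov)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    warning("rank-deficient adjustment design; dropping aliased columns: ",
            paste(dropped, collapse = ", "))
  }
  res <- qr.resid(qrX, unclass(scores))
  dimnames(res) <- dimnames(scores)
  unit_score_matrix(res, variant_class = attr(scores, "variant_class"), adjusted = TRUE)
}

#' Cross-platform genotype-concordance QC
#'
#' Per-subject concordance between two genotype sources, computed only over
#' variants where at least one source shows a non-major-homozygote genotype
#' (the major allele is taken from the variant table's `alt_freq`). Subjects
#' with concordance at or below 0.90 (rare variants) or 0.95 (common
#' variants) are flagged for exclusion; subjects with no informative
#' overlapping genotypes are flagged `unassessable`.
#'
#' @param a,b `genotype_matrix` objects sharing subjects and variants.
#' @param variants Variant table giving `alt_freq` for the shared variants.
#' @param variant_class `"rare"` or `"common"`, selecting the threshold.
#' @return Data frame: `subject_id`, `n_informative`, `concordance`,
#'   `excluded`, `unassessable`.
#' @export
genotype_concordance_qc <- function(a, b, variants, variant_class = c("rare", "common")) {
  variant_class <- match.arg(variant_class)
  thr <- if (variant_class == "rare") 0.90 else 0.95
  subj <- intersect(rownames(a), rownames(b))
  vars <- intersect(colnames(a), colnames(b))
  if (!length(subj) || !length(vars)) stop("matrices share no subjects or no variants")
  A <- unclass(a)[subj, vars, drop = FALSE]
  B <- unclass(b)[subj, vars, drop = FALSE]
  af <- variants$alt_freq[match(vars, variants$variant_id)]
  if (anyNA(af)) stop("variant table missing alt_freq for shared variants")
  # major-homozygote genotype count: 0 when the ref allele is major, 2 otherwise
  major_hom <- ifelse(af < 0.5, 0L, 2L)
  MH <- matrix(major_hom, nrow = length(subj), ncol = length(vars), byrow = TRUE)
  informative <- (!is.na(A) & !is.na(B)) & (A != MH | B != MH)
  n_inf <- rowSums(informative)
  agree <- rowSums(informative & (A == B))
  conc <- ifelse(n_inf > 0, agree / n_inf, NA_real_)
  data.frame(subject_id = subj,
             n_informative = n_inf,
             concordance = conc,
             excluded = !is.na(conc) & conc <= thr,
             unassessable = n_inf == 0,
             row.names = NULL, stringsAsFactors = FALSE)
}
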