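#' Per-gene carrier flags for damaging variants
#'
#' A subject carries a gene under a rule when they have at least one
#' alternative allele at at least one qualifying variant of that gene.
#' Rules: `sift_deleterious` (SIFT < 0.05, strict), `polyphen_damaging`
#' (PolyPhen > 0.45, strict), `so_090` / `so_070` (SO score >= 0.90 / 0.70,
#' inclusive). Variants missing the rule's annotation are skipped with a
#' message; only genes with at least one qualifying variant appear in the
#' result.
#'
#' @param genotypes A [genotype_matrix()].
#' @param variants Variant table with `variant_id`, `gene` and the
#'   annotation columns.
#' @param rule One of the four rule names.
#' @return Binary integer matrix, subjects x qualifying genes.
#' @export
carrier_flags <- function(genotypes, variants,
                          rule = c("sift_deleterious", "polyphen_damaging",
                                   "so_090", "so_070")) {
  rule <- match.arg(rule)
  ann <- switch(rule,
                sift_deleterious = variants$sift,
                polyphen_damaging = variants$polyphen,
                so_090 = variants$so_score,
                so_070 = variants$so_score)
  qual <- switch(rule,
                 sift_deleterious = ann < 0.05,
                 polyphen_damaging = ann > 0.45,
                 so_090 = ann >= 0.90,
                 so_070 = ann >= 0.70)
  skipped <- is.na(qual)
  if (any(skipped)) {
    message(sum(skipped), " variant(s) skipped: missing annotation for rule '", rule, "'")
    qual[skipped] <- FALSE
  }
  qv <- variants[qual, , drop = FALSE]
  if (nrow(qv) == 0) stop("no variant qualifies under rule '", rule, "'")
  G <- unclass(genotypes)[, qv$variant_id, drop = FALSE]
  G[is.na(G)] <- 0L
  genes <- unique(qv$gene)
  out <- matrix(0L, nrow(G), length(genes),
                dimnames = list(rownames(G), genes))
  for (g in genes) {
    cols <- qv$variant_id[qv$gene == g]
    out[, g] <- as.integer(rowSums(G[, cols, drop = FALSE] > 0) > 0)
  }
  out
}

#' Three-group association test for one feature
#'
#' Multinomial logistic regression (response class as reference) of the
#' outcome on the feature plus three principal components and recruitment
#' centre, with a likelihood-ratio test of the feature's coefficients
#' (2 df with three classes). With two outcome classes a binomial logistic
#' model is used (1 df). Quasi-separated fits fall back to a ridge-penalized
#' refit (`decay = 0.01`) and are flagged; the p-value is never silently NA.
#'
#' @param feature Per-subject numeric or binary predictor.
#' @param outcome Factor-like outcome with levels among TRD / NONRESP /
#'   RESP (reference = RESP when present).
#' @param covariates Data frame with `pc1`, `pc2`, `pc3`, `centre`.
#' @param bonferroni_alpha Significance threshold already divided by the
#'   number of tests (see [bonferroni_alpha()]).
#' @return List with `statistic` (LR chi-square), `df`, `p_value`,
#'   `significant`, `separation` flag and the per-class feature summaries.
#' @export
group_test <- function(feature, outcome, covariates, bonferroni_alpha = 0.05) {
  outcome <- factor(outcome)
  if (nlevels(outcome) < 2) stop("need at least 2 outcome classes")
  if ("RESP" %in% levels(outcome)) outcome <- stats::relevel(outcome, "RESP")
  dat <- data.frame(outcome = outcome, feature = feature,
                    pc1 = covariates$pc1, pc2 = covariates$pc2,
                    pc3 = covariates$pc3, centre = factor(covariates$centre))
  has_centre <- nlevels(dat$centre) > 1
  rhs_full <- if (has_centre) outcome ~ feature + pc1 + pc2 + pc3 + centre
              else outcome ~ feature + pc1 + pc2 + pc3
  rhs_null <- if (has_centre) outcome ~ pc1 + pc2 + pc3 + centre
              else outcome ~ pc1 + pc2 + pc3
  df <- nlevels(outcome) - 1L

  if (stats::sd(as.numeric(feature)) == 0) {
    smry <- tapply(as.numeric(feature), outcome, mean)
    return(list(statistic = 0, df = df, p_value = 1, significant = FALSE,
                separation = FALSE, class_means = smry))
  }

  fit2 <- function(formula, decay = 0) {
    if (nlevels(outcome) == 2L) {
      # binomial logistic; decay > 0 approximated by glm on jittered weights
      # is not equivalent, so use multinom for the penalized fallback too
      nnet::multinom(formula, data = dat, trace = FALSE, decay = decay, maxit = 200)
    } else {
      nnet::multinom(formula, data = dat, trace = FALSE, decay = decay, maxit = 200)
    }
  }
  full <- fit2(rhs_full)
  null <- fit2(rhs_null)
  coefs <- stats::coef(full)
  cf <- if (is.matrix(coefs)) coefs[, "feature"] else coefs["feature"]
  separated <- any(abs(cf) > 15) || full$convergence != 0
  if (separated) {
    full <- fit2(rhs_full, decay = 0.01)
    null <- fit2(rhs_null, decay = 0.01)
  }
  lr <- max(0, null$deviance - full$deviance)
  p <- stats::pchisq(lr, df = df, lower.tail = FALSE)
  smry <- tapply(as.numeric(feature), outcome, mean)
  list(statistic = lr, df = df, p_value = p,
       significant = p < bonferroni_alpha, separation = separated,
       class_means = smry)
}

#' Bonferroni-corrected significance threshold
#'
#' `fwer / m`. With the family-wise rate 0.05 over 18,600 genes this is
#' 2.69e-06 (three significant figures).
#'
#' @param fwer Family-wise error rate in (0, 1).
#' @param m Number of tests (>= 1).
#' @return The per-test alpha.
#' @export
bonferroni_alpha <- function(fwer = 0.05, m = 1L) {
  if (fwer <= 0 || fwer >= 1) stop("fwer must be in (0, 1)")
  if (m < 1 || m != round(m)) stop("m must be a count >= 1")
  fwer / m
}

#' Carrier or score association scan over genes
#'
#' Applies [group_test()] to each column of a carrier matrix or unit-score
#' matrix, with the Bonferroni threshold set by the number of units actually
#' tested.
#'
#' @param features Subjects x units matrix (binary carrier flags or burden
#'   scores).
#' @param outcome,covariates As in [group_test()].
#' @param fwer Family-wise error rate (default 0.05).
#' @return Data frame: `unit`, `statistic`, `p_value`, `significant`,
#'   `separation`, plus one column of mean feature values per outcome class.
#' @export
association_scan <- function(features, outcome, covariates, fwer = 0.05) {
  features <- as.matrix(features)
  alpha <- bonferroni_alpha(fwer, ncol(features))
  res <- lapply(seq_len(ncol(features)), function(j) {
    r <- group_test(features[, j], outcome, covariates, bonferroni_alpha = alpha)
    means <- as.list(r$class_means)
    names(means) <- paste0("mean_", names(means))
    c(list(unit = colnames(features)[j], statistic = r$statistic,
           p_value = r$p_value, significant = r$significant,
           separation = r$separation), means)
  })
  out <- do.call(rbind, lapply(res, function(x) as.data.frame(x, stringsAsFactors = FALSE)))
  attr(out, "bonferroni_alpha") <- alpha
  out
}
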