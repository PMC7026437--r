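#' AUC with DeLong 95% confidence interval
#'
#' The AUC is the Mann-Whitney statistic (ties counted 1/2; positive class
#' is the label 1/TRUE, typically TRD) with variance from DeLong's
#' structural-components method and a normal-approximation 95% interval
#' clipped to \[0, 1\]. Backed by `pROC` with a fixed direction, so an AUC
#' below 0.5 is reported as such rather than flipped.
#'
#' @param scores Numeric predictor values.
#' @param labels Binary labels (1/TRUE = case).
#' @return List with `auc`, `ci_low`, `ci_high`, `n`.
#' @export
roc_auc_delong <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) != 2L) stop("both classes must be present")
  r <- pROC::roc(response = labels, predictor = as.numeric(scores),
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  ci <- as.numeric(pROC::ci.auc(r, method = "delong"))
  list(auc = ci[2], ci_low = max(0, ci[1]), ci_high = min(1, ci[3]),
       n = length(labels))
}

#' Paired DeLong test for two correlated AUCs
#'
#' Two-sided test of `AUC(a) - AUC(b) = 0` for two score vectors on the same
#' subjects, using the paired structural-component covariance. When the
#' variance of the difference is zero the p-value is 1 if the AUCs are equal
#' and an error otherwise.
#'
#' @param scores_a,scores_b Score vectors over the same subjects.
#' @param labels Binary labels (1/TRUE = case).
#' @return List with `p`, `auc_a`, `auc_b`.
#' @export
delong_paired_test <- function(scores_a, scores_b, labels) {
  stopifnot(length(scores_a) == length(scores_b))
  labels <- as.integer(as.logical(labels))
  ra <- pROC::roc(labels, as.numeric(scores_a), levels = c(0, 1),
                  direction = "<", quiet = TRUE)
  rb <- pROC::roc(labels, as.numeric(scores_b), levels = c(0, 1),
                  direction = "<", quiet = TRUE)
  auc_a <- as.numeric(ra$auc); auc_b <- as.numeric(rb$auc)
  tt <- suppressWarnings(tryCatch(
    pROC::roc.test(ra, rb, method = "delong", paired = TRUE),
    error = function(e) NULL))
  p <- if (!is.null(tt)) as.numeric(tt$p.value) else NaN
  if (is.nan(p) || is.na(p)) {
    if (isTRUE(all.equal(auc_a, auc_b))) p <- 1
    else stop("zero variance of the AUC difference with unequal AUCs")
  }
  list(p = p, auc_a = auc_a, auc_b = auc_b)
}

#' Youden-optimal classification threshold
#'
#' The score threshold (predicted positive means `score >= threshold`)
#' maximizing sensitivity + specificity - 1; on ties the smallest threshold
#' is returned. Meant to be fitted on training predictions and frozen for
#' testing.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (1/TRUE = case).
#' @return A single threshold value.
#' @export
youden_threshold <- function(scores, labels) {
  labels <- as.logical(labels)
  cand <- sort(unique(as.numeric(scores)))
  n1 <- sum(labels); n0 <- sum(!labels)
  best_t <- cand[1]; best_j <- -Inf
  for (t in cand) {
    sens <- sum(scores >= t & labels) / n1
    spec <- sum(scores < t & !labels) / n0
    j <- sens + spec - 1
    if (j > best_j + 1e-12) { best_j <- j; best_t <- t }
  }
  best_t
}

#' Confusion-matrix metrics at a threshold
#'
#' Standard 2x2 ratios with predicted positive defined as
#' `score >= threshold`; the positive class is the label 1/TRUE (TRD). An
#' empty predicted-positive (or predicted-negative) set yields `NA` for the
#' undefined predictive value.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (1/TRUE = case).
#' @param threshold Classification threshold (e.g. from
#'   [youden_threshold()] on the training partition).
#' @return List with `sensitivity`, `specificity`, `ppv`, `npv`.
#' @export
confusion_metrics <- function(scores, labels, threshold) {
  labels <- as.logical(labels)
  pos <- scores >= threshold
  tp <- sum(pos & labels); fn <- sum(!pos & labels)
  tn <- sum(!pos & !labels); fp <- sum(pos & !labels)
  list(sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_)
}

#' Assemble an evaluation report for one model on one test partition
#'
#' @param pred Test-set predictions of the model of interest.
#' @param labels Test-set binary labels (1 = TRD).
#' @param threshold Frozen classification threshold (training Youden).
#' @param comparisons Optional named list of other score vectors on the same
#'   subjects (e.g. `clinical`, `genetic_clinical`) to compare with the
#'   paired DeLong test.
#' @return List with `n`, `auc`, `ci_low`, `ci_high`, the four confusion
#'   metrics, `threshold`, and `comparison_p` (named numeric).
#' @export
evaluate_model <- function(pred, labels, threshold, comparisons = list()) {
  a <- roc_auc_delong(pred, labels)
  cm <- confusion_metrics(pred, labels, threshold)
  cp <- vapply(comparisons, function(s) delong_paired_test(pred, s, labels)$p,
               numeric(1))
  c(list(n = a$n, auc = a$auc, ci_low = a$ci_low, ci_high = a$ci_high,
         threshold = threshold), cm, list(comparison_p = cp))
}
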