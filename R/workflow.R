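#' Derive the three-class treatment outcome
#'
#' Response requires a current MADRS score below 22, a decrease of at least
#' 50% from the score at the onset of the episode (inclusive boundary:
#' `madrs_current <= 0.5 * madrs_baseline`), and not more than one failed
#' adequate antidepressant treatment. TRD is failure of at least two
#' adequate treatments during the episode; non-response is exactly one
#' failed adequate treatment without meeting the response criteria. A
#' MADRS non-responder with zero failed adequate treatments cannot be
#' classified and is returned as `"UNCLASSIFIABLE"` with a warning.
#'
#' @param madrs_baseline MADRS at the onset of the current episode (> 0).
#' @param madrs_current Current MADRS score.
#' @param n_failed_adequate Number of failed adequate antidepressant
#'   treatments during the current episode.
#' @return One of `"RESP"`, `"NONRESP"`, `"TRD"`, `"UNCLASSIFIABLE"`.
#'   Vectorised over its arguments.
#' @export
define_outcome <- function(madrs_baseline, madrs_current, n_failed_adequate) {
  if (any(madrs_baseline <= 0)) stop("madrs_baseline must be > 0")
  if (any(n_failed_adequate < 0 | n_failed_adequate != round(n_failed_adequate))) {
    stop("n_failed_adequate must be a non-negative count")
  }
  madrs_resp <- madrs_current < 22 & madrs_current <= 0.5 * madrs_baseline
  out <- ifelse(n_failed_adequate >= 2, "TRD",
                ifelse(madrs_resp, "RESP",
                       ifelse(n_failed_adequate == 1, "NONRESP", "UNCLASSIFIABLE")))
  if (any(out == "UNCLASSIFIABLE")) {
    warning(sum(out == "UNCLASSIFIABLE"),
            " subject(s) unclassifiable (non-response with 0 failed adequate treatments); exclude them")
  }
  out
}

#' Stratified 70/30 split
#'
#' Splits subjects into training and testing sets balanced over the outcome
#' classes: each class contributes `round(fraction * class size)` training
#' subjects, then single subjects are moved between sets (largest-remainder
#' order) so the training total matches `round(fraction * n)` as closely as
#' per-class integer counts permit. Assignment within a class is random
#' under `seed`.
#'
#' @param subject_id Character vector of subject ids.
#' @param outcome Parallel vector of class labels.
#' @param train_fraction Training proportion (default 0.7).
#' @param seed Integer seed.
#' @return List with character vectors `train` and `test`.
#' @export
stratified_split <- function(subject_id, outcome, train_fraction = 0.7, seed = 1L) {
  stopifnot(length(subject_id) == length(outcome))
  tab <- table(outcome)
  if (any(tab < 3)) stop("need at least 3 subjects per class")
  with_seed(seed + 606L, {
    target_total <- round(train_fraction * length(subject_id))
    k <- as.numeric(round(train_fraction * tab))
    # largest-remainder correction toward the overall target
    rem <- train_fraction * as.numeric(tab) - k
    delta <- target_total - sum(k)
    if (delta != 0) {
      ord <- order(if (delta > 0) -rem else rem)
      for (i in seq_len(abs(delta))) {
        j <- ord[(i - 1L) %% length(ord) + 1L]
        k[j] <- k[j] + sign(delta)
        k[j] <- min(max(k[j], 1), as.numeric(tab)[j] - 1)
      }
    }
    train <- character(0)
    for (j in seq_along(tab)) {
      ids <- subject_id[outcome == names(tab)[j]]
      train <- c(train, sample(ids, k[j]))
    }
    list(train = sort(train), test = sort(setdiff(subject_id, train)))
  })
}

#' Subset a phenotype frame by treatment class
#'
#' Keeps rows whose `treatment_class` is in `classes`. Subjects on combined
#' serotonergic-noradrenergic treatment (`"combo"`) are excluded from
#' class-specific analyses regardless of `classes`.
#'
#' @param frame Phenotype data frame with a `treatment_class` column.
#' @param classes Character vector of classes to keep (e.g. `"5HT"`).
#' @param drop_combo Drop `"combo"` rows even if requested (default TRUE
#'   when `classes` is a strict subset of all classes).
#' @return The filtered data frame.
#' @export
subset_by_treatment <- function(frame, classes, drop_combo = TRUE) {
  stopifnot("treatment_class" %in% names(frame))
  keep_classes <- if (drop_combo) setdiff(classes, "combo") else classes
  out <- frame[frame$treatment_class %in% keep_classes, , drop = FALSE]
  if (nrow(out) == 0) stop("treatment-class subset is empty")
  out
}

#' Imputation-quality filter for replication-style data
#'
#' Keeps common variants with imputation R-squared strictly above 0.30 and
#' rare variants strictly above 0.60. Variants with a missing info score are
#' dropped with a message.
#'
#' @param variants Variant table with columns `variant_id`, `maf` and
#'   `info_r2` in \[0, 1\].
#' @param rare_maf_threshold MAF threshold separating rare from common.
#' @return The filtered variant table.
#' @export
imputation_quality_filter <- function(variants, rare_maf_threshold = 0.02) {
  stopifnot(all(c("variant_id", "maf", "info_r2") %in% names(variants)))
  miss <- is.na(variants$info_r2)
  if (any(miss)) {
    message(sum(miss), " variant(s) dropped: missing imputation info score")
    variants <- variants[!miss, , drop = FALSE]
  }
  rare <- variants$maf < rare_maf_threshold
  keep <- (rare & variants$info_r2 > 0.60) | (!rare & variants$info_r2 > 0.30)
  variants[keep, , drop = FALSE]
}
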