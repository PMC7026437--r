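#' Fit the z-weighted clinical risk score
#'
#' One multivariable logistic regression of the binary outcome on all
#' candidate clinical variables (training rows only); variables whose Wald
#' p-value survives Bonferroni correction over the candidate family are
#' retained with their Wald z-statistic as weight. A univariate-screen mode
#' (one logistic model per candidate) is available behind
#' `mode = "univariate"`.
#'
#' @param clinical Data frame of candidate variables (training subjects).
#' @param outcome Binary outcome vector (1/TRUE = case, e.g. TRD).
#' @param candidates Character vector of column names to consider.
#' @param alpha Family-wise error rate before Bonferroni division
#'   (default 0.05).
#' @param mode `"multivariable"` (default) or `"univariate"`.
#' @return An object of class `clinical_score_spec`: named numeric
#'   `weights`, plus fitting metadata (`mode`, `alpha`, `bonferroni_m`,
#'   `p_values`).
#' @export
fit_clinical_weights <- function(clinical, outcome, candidates,
                                 alpha = 0.05,
                                 mode = c("multivariable", "univariate")) {
  mode <- match.arg(mode)
  missing_c <- setdiff(candidates, names(clinical))
  if (length(missing_c)) stop("candidates absent from data: ", paste(missing_c, collapse = ", "))
  y <- as.integer(as.logical(outcome))
  m <- length(candidates)
  thr <- alpha / m

  if (mode == "multivariable") {
    dat <- cbind(data.frame(.y = y), clinical[candidates])
    fit <- stats::glm(.y ~ ., data = dat, family = stats::binomial())
    sm <- summary(fit)$coefficients
    rows <- match(candidates, rownames(sm))
    z <- sm[rows, "z value"]
    p <- sm[rows, "Pr(>|z|)"]
  } else {
    z <- p <- numeric(m)
    for (j in seq_len(m)) {
      fit <- stats::glm(y ~ x, data = data.frame(y = y, x = clinical[[candidates[j]]]),
                        family = stats::binomial())
      sm <- summary(fit)$coefficients
      z[j] <- sm["x", "z value"]
      p[j] <- sm["x", "Pr(>|z|)"]
    }
  }
  names(z) <- names(p) <- candidates
  keep <- !is.na(p) & p < thr
  if (!any(keep)) {
    warning("no candidate survives Bonferroni; clinical score is identically 0")
  }
  structure(list(weights = z[keep], p_values = p, mode = mode,
                 alpha = alpha, bonferroni_m = m),
            class = "clinical_score_spec")
}

#' Compute the clinical risk score
#'
#' For each subject, the sum over non-missing retained variables of
#' `value x z-weight`, divided by the number of retained variables
#' available in that subject. Subjects with all retained variables missing
#' get `NA` and are flagged.
#'
#' @param data Data frame containing the retained variables.
#' @param spec A `clinical_score_spec` from [fit_clinical_weights()].
#' @return Numeric vector of scores (attribute `undefined`: row indices with
#'   all retained variables missing). An empty spec yields all zeros.
#' @export
clinical_risk_score <- function(data, spec) {
  stopifnot(inherits(spec, "clinical_score_spec"))
  w <- spec$weights
  if (length(w) == 0) {
    return(structure(rep(0, nrow(data)), undefined = integer(0)))
  }
  missing_v <- setdiff(names(w), names(data))
  if (length(missing_v)) stop("data lacks retained variables: ", paste(missing_v, collapse = ", "))
  V <- as.matrix(data[names(w)])
  avail <- !is.na(V)
  V[!avail] <- 0
  num <- as.numeric(V %*% w)
  den <- rowSums(avail)
  score <- ifelse(den > 0, num / den, NA_real_)
  if (any(den == 0)) {
    warning(sum(den == 0), " subject(s) with all retained variables missing; score undefined")
  }
  structure(score, undefined = which(den == 0))
}

#' Serialize / read a clinical score spec as JSON
#'
#' @param spec A `clinical_score_spec`.
#' @param path File path.
#' @return `read_clinical_spec` returns the spec; `write_clinical_spec`
#'   returns `path` invisibly.
#' @export
write_clinical_spec <- function(spec, path) {
  stopifnot(inherits(spec, "clinical_score_spec"))
  payload <- unclass(spec)
  payload$weights <- as.list(payload$weights)     # keep names through JSON
  payload$p_values <- as.list(payload$p_values)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_clinical_spec
#' @export
read_clinical_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$weights <- unlist(x$weights)
  if (is.null(x$weights)) x$weights <- stats::setNames(numeric(0), character(0))
  x$p_values <- unlist(x$p_values)
  structure(x, class = "clinical_score_spec")
}
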