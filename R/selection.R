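#' Correlation-adjusted t-scores (CAT scores)
#'
#' The CAT score decorrelates the vector of two-sample t-statistics:
#' `cat = R^(-1/2) %*% t`, where `t` contains shrunken-variance t-scores and
#' `R` is a shrinkage-regularized correlation matrix. Both shrinkage
#' intensities are the analytic (Schaefer-Strimmer) estimates:
#' the variance target is the median pooled variance with
#' `lambda_v = sum(Var(v_j)) / sum((v_j - median)^2)`, and the correlation
#' matrix shrinks toward the identity with
#' `lambda_c = sum(Var(r_ij)) / sum(r_ij^2)` over off-diagonal pairs, both
#' clamped to \[0, 1\]. `R^(-1/2)` is the symmetric inverse square root via
#' eigendecomposition. When the shrunken correlation is the identity
#' (e.g. `lambda_c = 1`, or a single unit) the CAT scores equal the
#' t-scores.
#'
#' @param X Numeric matrix, subjects x units.
#' @param y Binary labels (logical, or any two-level vector); the CAT sign
#'   convention is mean(level2) - mean(level1) over `sort(unique(y))`.
#' @return Numeric vector of CAT scores, named by unit.
#' @export
cat_scores <- function(X, y) {
  X <- as.matrix(X)
  g <- as.integer(factor(y))
  if (length(unique(g)) != 2L) stop("y must contain exactly two classes")
  n1 <- sum(g == 1L); n2 <- sum(g == 2L)
  if (n1 < 3L || n2 < 3L) stop("need at least 3 subjects per class")
  n <- n1 + n2
  p <- ncol(X)

  m1 <- colMeans(X[g == 1L, , drop = FALSE])
  m2 <- colMeans(X[g == 2L, , drop = FALSE])
  Xc <- X
  Xc[g == 1L, ] <- sweep(X[g == 1L, , drop = FALSE], 2, m1)
  Xc[g == 2L, ] <- sweep(X[g == 2L, , drop = FALSE], 2, m2)
  df <- n - 2L
  v <- colSums(Xc^2) / df

  zero_var <- v <= 0
  if (any(zero_var)) warning(sum(zero_var), " zero-variance unit(s); t set to 0")

  # analytic variance shrinkage toward the median pooled variance
  w2 <- Xc^2
  var_v <- colSums(sweep(w2, 2, colMeans(w2))^2) * n / ((n - 1)^3)
  v_target <- stats::median(v)
  denom_v <- sum((v - v_target)^2)
  lambda_v <- if (denom_v > 0) min(1, max(0, sum(var_v) / denom_v)) else 1
  v_shrunk <- lambda_v * v_target + (1 - lambda_v) * v

  t_scores <- (m2 - m1) / sqrt(v_shrunk * (1 / n1 + 1 / n2))
  t_scores[zero_var | v_shrunk <= 0] <- 0

  if (p == 1L) return(stats::setNames(t_scores, colnames(X)))

  sdv <- sqrt(v)
  sdv[zero_var] <- 1
  Z <- sweep(Xc, 2, sdv, "/")
  Z[, zero_var] <- 0
  R <- crossprod(Z) / df
  diag(R) <- 1

  # analytic correlation shrinkage toward the identity
  M1 <- crossprod(Z) / n
  M2 <- crossprod(Z^2) / n
  var_r <- (M2 - M1^2) * n^2 / ((n - 1)^3)
  off <- upper.tri(R)
  denom_c <- sum(R[off]^2)
  lambda_c <- if (denom_c > 0) min(1, max(0, sum(var_r[off]) / denom_c)) else 1
  R_shrunk <- (1 - lambda_c) * R
  diag(R_shrunk) <- 1

  if (lambda_c >= 1) return(stats::setNames(t_scores, colnames(X)))
  eig <- eigen(R_shrunk, symmetric = TRUE)
  ev <- pmax(eig$values, 1e-10)
  R_inv_sqrt <- eig$vectors %*% (t(eig$vectors) / sqrt(ev))
  stats::setNames(as.numeric(R_inv_sqrt %*% t_scores), colnames(X))
}

#' Local false discovery rate from a vector of scores
#'
#' Estimates, for each unit, the posterior probability of being
#' non-informative given its (CAT) score:
#' `lfdr(s) = min(1, pi0 * f0(s) / f(s))`. The marginal density `f` is a
#' Poisson fit (Lindsey's method) to the score histogram, combining a
#' log-quadratic baseline (the normal family) with natural-spline terms for
#' non-null structure; BIC decides whether the spline terms are kept, so a
#' complete-null score vector collapses to its fitted normal and yields
#' lfdr near 1 throughout. The empirical null `f0` is Normal with location
#' and scale fitted by central matching on the middle 80% of the
#' distribution (median and 10-90% quantile-based scale, which ignore a
#' minority of informative tail units), or the theoretical N(0, 1) when
#' `null = "theoretical"`. The null mass `pi0 <= 1` is fitted by count
#' matching on the central 90% null interval.
#'
#' @param scores Numeric vector of scores (at least 50 for the empirical
#'   null).
#' @param null `"empirical"` (central matching) or `"theoretical"` (N(0,1)).
#' @param bins,df Histogram resolution and natural-spline degrees of
#'   freedom for the marginal fit; the bin count is reduced for small score
#'   vectors.
#' @return Numeric vector of lfdr values in \[0, 1\].
#' @export
local_fdr <- function(scores, null = c("empirical", "theoretical"),
                      bins = 90, df = 5) {
  null <- match.arg(null)
  m <- length(scores)
  if (stats::sd(scores) == 0) return(rep(1, m))
  if (null == "empirical" && m < 50) {
    stop("empirical-null lfdr needs >= 50 units; use null = 'theoretical'")
  }
  rng <- range(scores)
  pad <- 0.1 * diff(rng) + 1e-8
  bins <- max(20, min(bins, ceiling(3 * sqrt(m))))
  breaks <- seq(rng[1] - pad, rng[2] + pad, length.out = bins + 1)
  width <- diff(breaks)[1]
  counts <- graphics::hist(scores, breaks = breaks, plot = FALSE)$counts
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  sp_df <- if (m < 500) 4 else min(df, max(3, bins %/% 8))
  # nested marginal fits: the log-quadratic model is the normal family, the
  # spline terms add non-null structure; BIC decides whether the data
  # support any structure beyond the null shape
  f_quad <- suppressWarnings(stats::glm(counts ~ mids + I(mids^2),
                                        family = stats::poisson()))
  f_full <- suppressWarnings(stats::glm(
    counts ~ mids + I(mids^2) + splines::ns(mids, df = sp_df),
    family = stats::poisson()))
  fit <- if (stats::BIC(f_full) < stats::BIC(f_quad)) f_full else f_quad
  f_hat <- function(s) {
    lam <- suppressWarnings(stats::predict(fit, newdata = data.frame(mids = s),
                                           type = "response"))
    pmax(lam / (m * width), 1e-12)
  }
  if (null == "theoretical") {
    mu0 <- 0; s0 <- 1
  } else {
    mu0 <- stats::median(scores)
    s0 <- (stats::quantile(scores, 0.90, names = FALSE) -
             stats::quantile(scores, 0.10, names = FALSE)) / (2 * stats::qnorm(0.90))
    if (s0 <= 0) return(rep(1, m))
  }
  # pi0 by count matching on the central 90% null interval; the upper
  # confidence bound keeps the estimate from dipping below 1 by pure
  # sampling noise under a complete null
  tgt <- 2 * stats::pnorm(1.645) - 1
  ph <- mean(abs(scores - mu0) <= 1.645 * s0)
  pi0 <- min(1, ph / tgt + 1.645 * sqrt(ph * (1 - ph) / m) / tgt)
  pmin(1, pmax(0, pi0 * stats::dnorm(scores, mu0, s0) / f_hat(scores)))
}

#' Selection configuration
#'
#' @param folds Cross-validation folds (default 5).
#' @param repeats Repeats of the fold loop: 100 for pathway scores, 20 for
#'   gene scores (500 and 100 rounds in total).
#' @param lfdr_threshold A unit passes a round when its lfdr is strictly
#'   below this value (default 0.8).
#' @param frequency_threshold A unit is selected when it passes in strictly
#'   more than this fraction of rounds (default 0.5).
#' @param seed Integer seed; round `r` derives its fold assignment from
#'   `seed + r`.
#' @param null Null model passed to [local_fdr()]; `"auto"` uses the
#'   empirical null when at least 50 units are scored, theoretical
#'   otherwise.
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(folds = 5L, repeats = 100L, lfdr_threshold = 0.8,
                             frequency_threshold = 0.5, seed = 1L,
                             null = c("auto", "empirical", "theoretical")) {
  null <- match.arg(null)
  if (folds < 2) stop("folds must be >= 2")
  if (lfdr_threshold <= 0 || lfdr_threshold >= 1 ||
      frequency_threshold <= 0 || frequency_threshold >= 1) {
    stop("thresholds must be in (0, 1)")
  }
  structure(list(folds = as.integer(folds), repeats = as.integer(repeats),
                 lfdr_threshold = lfdr_threshold,
                 frequency_threshold = frequency_threshold,
                 seed = as.integer(seed), null = null),
            class = "selection_config")
}

# stratified fold labels: within each class, balanced 1..folds assignment
stratified_folds <- function(y, folds) {
  f <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    if (length(idx) < folds) stop("a class has fewer subjects than folds")
    f[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  f
}

#' Repeated cross-validated CAT + LFDR predictor selection
#'
#' For each of `folds x repeats` rounds, one fold is left out and CAT scores
#' plus local FDR are computed on the remaining subjects. A unit passes a
#' round when its lfdr is below `lfdr_threshold`; units passing in more than
#' `frequency_threshold` of the rounds are selected. Folds are stratified by
#' outcome, so every retained partition contains both classes. The held-out
#' fifth never enters the computation.
#'
#' @param X Numeric matrix, subjects x units (training partition only).
#' @param y Binary labels parallel to the rows of `X`.
#' @param config A [selection_config()].
#' @return A `selection_report` data frame: `unit`, `mean_cat`,
#'   `pass_count`, `n_rounds`, `frequency`, `selected`.
#' @export
repeated_cv_select <- function(X, y, config = selection_config()) {
  stopifnot(inherits(config, "selection_config"))
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("unit", seq_len(ncol(X)))
  if (length(unique(y)) != 2L) stop("labels must be binary")
  null <- config$null
  if (null == "auto") null <- if (ncol(X) >= 50) "empirical" else "theoretical"

  n_rounds <- config$folds * config$repeats
  pass <- integer(ncol(X))
  cat_sum <- numeric(ncol(X))
  for (r in seq_len(config$repeats)) {
    fold <- with_seed(config$seed + r, stratified_folds(y, config$folds))
    for (k in seq_len(config$folds)) {
      keep <- fold != k
      cs <- cat_scores(X[keep, , drop = FALSE], y[keep])
      lf <- local_fdr(cs, null = null)
      pass <- pass + (lf < config$lfdr_threshold)
      cat_sum <- cat_sum + cs
    }
  }
  freq <- pass / n_rounds
  structure(data.frame(unit = colnames(X),
                       mean_cat = cat_sum / n_rounds,
                       pass_count = pass,
                       n_rounds = n_rounds,
                       frequency = freq,
                       selected = freq > config$frequency_threshold,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("selection_report", "data.frame"))
}
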