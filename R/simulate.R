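#' Subjects x variants genotype container
#'
#' A thin wrapper around an integer matrix of alternative-allele counts in
#' \{0, 1, 2\} (`NA` = missing), with subject ids as rownames and variant ids
#' as colnames.
#'
#' @param counts Integer matrix of allele counts.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(counts) {
  stopifnot(is.matrix(counts))
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry subject ids (rownames) and variant ids (colnames)")
  }
  vals <- counts[!is.na(counts)]
  if (length(vals) && (any(vals < 0) || any(vals > 2) || any(vals != round(vals)))) {
    stop("allele counts must be integers in {0, 1, 2}")
  }
  storage.mode(counts) <- "integer"
  structure(counts, class = c("genotype_matrix", "matrix", "array"))
}

#' @exportS3Method base::print
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d subjects x %d variants (%.2f%% missing)\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

# evaluate `code` under set.seed(seed) without disturbing the caller's RNG
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Configuration of a synthetic cohort
#'
#' Defines the generating conditions for a synthetic cohort of depressed
#' patients with exome-style rare variants, array-style common variants,
#' pathway structure with planted causal pathways, clinical risk factors and
#' a three-class treatment outcome (TRD / non-response / response).
#'
#' Defaults emulate a GSRD-like discovery cohort: 1209 subjects, outcome mix
#' 504/416/289, multicentre recruitment, and moderate genetic plus clinical
#' effects calibrated so that the generative Bayes AUC for TRD vs response
#' is about 0.75.
#'
#' @param n_subjects,n_genes,variants_per_gene_rare,variants_per_gene_common
#'   Cohort and variant-panel sizes.
#' @param n_pathways,genes_per_pathway,n_causal_pathways Pathway structure;
#'   causal pathways carry the planted burden effect.
#' @param genetic_effect Log-odds-scale liability effect per SD of causal
#'   pathway burden.
#' @param clinical_effect Liability effect per SD of the latent clinical
#'   liability.
#' @param centre_count Number of recruitment centres (centre effects are
#'   N(0, 0.1) on the liability scale).
#' @param seed Integer seed threaded through every draw.
#' @param class_mix Target proportions of (TRD, non-response, response),
#'   summing to 1.
#' @param ld_r2 Target squared correlation of adjacent within-gene latent
#'   variables (Gaussian-copula AR(1)); 0 means independent variants.
#' @param genetic_model `"linear"` (burden enters the liability linearly) or
#'   `"tail"` (only subjects in the outer tails of the causal burden carry
#'   the genetic effect, concentrating signal in the score extremes).
#' @param tail_quantile For `genetic_model = "tail"`: absolute-burden
#'   quantile above which the effect applies (default 0.85, i.e. the outer
#'   ~30% of subjects).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 1209,
                       n_genes = 300,
                       variants_per_gene_rare = 6,
                       variants_per_gene_common = 2,
                       n_pathways = 60,
                       genes_per_pathway = 8,
                       n_causal_pathways = 4,
                       genetic_effect = 0.35,
                       clinical_effect = 0.32,
                       centre_count = 8,
                       seed = 1L,
                       class_mix = c(504, 416, 289) / 1209,
                       ld_r2 = 0,
                       genetic_model = c("linear", "tail"),
                       tail_quantile = 0.85) {
  genetic_model <- match.arg(genetic_model)
  counts <- c(n_subjects = n_subjects, n_genes = n_genes,
              variants_per_gene_common = variants_per_gene_common,
              n_pathways = n_pathways, genes_per_pathway = genes_per_pathway,
              centre_count = centre_count)
  if (any(counts < 1) || any(counts != round(counts))) {
    stop("all counts must be integers >= 1 (got ", paste(names(counts)[counts < 1], collapse = ", "), ")")
  }
  if (variants_per_gene_rare < 0 || n_causal_pathways < 0) {
    stop("variants_per_gene_rare and n_causal_pathways must be >= 0")
  }
  if (n_causal_pathways > n_pathways) stop("n_causal_pathways must be <= n_pathways")
  if (genes_per_pathway > n_genes) stop("genes_per_pathway must be <= n_genes")
  if (length(class_mix) != 3L || any(class_mix <= 0) || any(class_mix >= 1) ||
      abs(sum(class_mix) - 1) > 1e-9) {
    stop("class_mix must be 3 proportions in (0,1) summing to 1")
  }
  if (ld_r2 < 0 || ld_r2 >= 1) stop("ld_r2 must be in [0, 1)")
  structure(list(n_subjects = as.integer(n_subjects), n_genes = as.integer(n_genes),
                 variants_per_gene_rare = as.integer(variants_per_gene_rare),
                 variants_per_gene_common = as.integer(variants_per_gene_common),
                 n_pathways = as.integer(n_pathways),
                 genes_per_pathway = as.integer(genes_per_pathway),
                 n_causal_pathways = as.integer(n_causal_pathways),
                 genetic_effect = genetic_effect, clinical_effect = clinical_effect,
                 centre_count = as.integer(centre_count), seed = as.integer(seed),
                 class_mix = as.numeric(class_mix), ld_r2 = ld_r2,
                 genetic_model = genetic_model, tail_quantile = tail_quantile),
            class = "sim_config")
}

#' Simulate a per-variant annotation table
#'
#' Rare variants get alternative-allele frequencies below the sample-size
#' threshold `1/sqrt(2n)`; common variants above it. Functional annotations:
#' Eigen-like scores from the mixture `0.8*|N(0,0.3)| + 0.2*|N(2,1)|`, a
#' CADD-like score correlated with it, a sequence-ontology score on the grid
#' \{0.1, ..., 1.0\}, and SIFT / PolyPhen in \[0, 1\] with a small missing
#' fraction. Every variant belongs to exactly one gene.
#'
#' @param config A [sim_config()].
#' @return A data frame (one row per variant) with columns `variant_id`,
#'   `chrom`, `pos`, `ref`, `alt`, `gene`, `alt_freq`, `maf`, `eigen`,
#'   `cadd`, `so_score`, `sift`, `polyphen`.
#' @export
simulate_variant_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 101L, {
    thr <- maf_threshold(config$n_subjects)
    n_rare <- config$n_genes * config$variants_per_gene_rare
    n_common <- config$n_genes * config$variants_per_gene_common
    genes <- sprintf("GENE%04d", seq_len(config$n_genes))

    # rare: skewed toward very low frequency, strictly below the threshold
    f_rare <- thr * stats::rbeta(n_rare, 0.6, 1.8)
    f_rare <- pmin(pmax(f_rare, 1e-5), thr * (1 - 1e-9))
    # common: folded MAF uniform above the threshold; a minority of alt
    # alleles are the major allele (alt_freq > 0.5) to exercise folding
    maf_common <- stats::runif(n_common, thr * 1.0001, 0.5)
    flip <- stats::runif(n_common) < 0.1
    f_common <- ifelse(flip, 1 - maf_common, maf_common)

    alt_freq <- c(f_rare, f_common)
    gene <- c(rep(genes, each = config$variants_per_gene_rare),
              rep(genes, each = config$variants_per_gene_common))
    n <- length(alt_freq)

    gene_chrom <- as.character(sample(1:22, config$n_genes, replace = TRUE))
    gene_start <- sample.int(5e7, config$n_genes)
    idx <- match(gene, genes)
    within <- stats::ave(seq_len(n), gene, FUN = seq_along)
    pos <- gene_start[idx] + within * 500L

    eig_hi <- stats::runif(n) < 0.2
    eigen <- ifelse(eig_hi, abs(stats::rnorm(n, 2, 1)), abs(stats::rnorm(n, 0, 0.3)))
    cadd <- pmax(0, 8 + 5 * as.numeric(scale(eigen)) + stats::rnorm(n, 0, 3))
    so_score <- sample(seq(0.1, 1, by = 0.1), n, replace = TRUE,
                       prob = c(6, 5, 4, 3, 3, 2, 2, 2, 1.5, 1.5))
    sift <- stats::runif(n)
    polyphen <- stats::rbeta(n, 0.7, 0.7)
    sift[stats::runif(n) < 0.05] <- NA
    polyphen[stats::runif(n) < 0.05] <- NA

    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))

    tab <- data.frame(
      variant_id = sprintf("var%05d", seq_len(n)),
      chrom = gene_chrom[idx], pos = pos, ref = ref, alt = alt,
      gene = gene, alt_freq = alt_freq,
      maf = pmin(alt_freq, 1 - alt_freq),
      eigen = eigen, cadd = cadd, so_score = so_score,
      sift = sift, polyphen = polyphen,
      row.names = NULL, stringsAsFactors = FALSE
    )
    tab[order(tab$chrom, tab$pos, tab$variant_id), , drop = FALSE]
  })
}

#' Simulate genotypes from a variant table
#'
#' Allele counts are binomial(2, alt_freq) per variant. When `config$ld_r2 >
#' 0`, within-gene LD is induced by a Gaussian-copula AR(1) on latent
#' normals: adjacent variants of a gene share latent correlation
#' `sqrt(ld_r2)`, then counts are obtained by the binomial quantile
#' transform.
#'
#' @param variants Variant table from [simulate_variant_table()].
#' @param config A [sim_config()].
#' @return A [genotype_matrix()] of size `n_subjects` x `nrow(variants)`.
#' @export
simulate_genotypes <- function(variants, config) {
  stopifnot(inherits(config, "sim_config"))
  if (any(variants$alt_freq <= 0 | variants$alt_freq >= 1)) {
    stop("variant frequencies must lie strictly in (0, 1)")
  }
  with_seed(config$seed + 202L, {
    n <- config$n_subjects
    m <- nrow(variants)
    subj <- sprintf("S%04d", seq_len(n))
    rho <- sqrt(config$ld_r2)
    if (rho == 0) {
      counts <- matrix(stats::rbinom(n * m, 2L, rep(variants$alt_freq, each = n)),
                       nrow = n, ncol = m)
    } else {
      counts <- matrix(0L, n, m)
      for (g in unique(variants$gene)) {
        cols <- which(variants$gene == g)
        k <- length(cols)
        Z <- matrix(stats::rnorm(n * k), n, k)
        if (k > 1) {
          for (j in 2:k) Z[, j] <- rho * Z[, j - 1] + sqrt(1 - rho^2) * Z[, j]
        }
        U <- stats::pnorm(Z)
        for (j in seq_len(k)) {
          counts[, cols[j]] <- stats::qbinom(U[, j], 2L, variants$alt_freq[cols[j]])
        }
      }
    }
    dimnames(counts) <- list(subj, variants$variant_id)
    genotype_matrix(counts)
  })
}

#' Simulate pathway gene sets
#'
#' Draws `n_pathways` gene sets of `genes_per_pathway` genes each (sampled
#' without replacement within a pathway; pathways may overlap).
#'
#' @param config A [sim_config()].
#' @return Named list mapping pathway id to a character vector of genes.
#' @export
simulate_gene_sets <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 303L, {
    genes <- sprintf("GENE%04d", seq_len(config$n_genes))
    sets <- lapply(seq_len(config$n_pathways), function(i) {
      sort(sample(genes, config$genes_per_pathway))
    })
    names(sets) <- sprintf("PATHWAY%03d", seq_len(config$n_pathways))
    sets
  })
}

# Mann-Whitney AUC with ties counted 1/2; labels logical or 0/1 (1 = case).
auc_mw <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes required")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Simulate the three-class treatment outcome and clinical variables
#'
#' Builds a latent resistance liability
#' `genetic_effect * burden_z + clinical_effect * clin_z + centre_effect +
#' N(0, 1)`, where `burden_z` is the standardized weighted rare-variant
#' burden over the causal pathways (same Eigen x Beta(1,25) weighting the
#' scoring pipeline estimates) and `clin_z` a standardized clinical
#' liability built as a weighted sum of five independent clinical risk
#' factors (suicidal risk, number of previous episodes, chronic depression,
#' MADRS pessimism and interest-activity factors) plus residual variation.
#' Outcome classes are cut from the liability to match `class_mix` (highest
#' liability = TRD, lowest = response). MADRS baseline/current scores and
#' the count of failed adequate treatments are generated consistently with
#' the outcome definition, and 3 ancestry PCs plus centre labels are
#' emitted.
#'
#' Under `genetic_model = "tail"` only subjects whose absolute standardized
#' burden exceeds its `tail_quantile` quantile carry the genetic effect.
#'
#' @param genotypes A [genotype_matrix()].
#' @param variants Matching variant table.
#' @param gene_sets Named list of pathways (see [simulate_gene_sets()]).
#' @param config A [sim_config()].
#' @return List with `phenotypes` (data frame, one row per subject) and
#'   `truth` (causal pathway ids, latent liability components, and the
#'   generative Bayes AUC for TRD vs response).
#' @export
simulate_outcome <- function(genotypes, variants, gene_sets, config) {
  stopifnot(inherits(config, "sim_config"), inherits(genotypes, "genotype_matrix"))
  if (!all(unlist(gene_sets) %in% variants$gene)) {
    stop("gene sets reference genes absent from the variant table")
  }
  if (config$n_causal_pathways == 0 && config$genetic_effect != 0) {
    stop("genetic_effect != 0 requires at least one causal pathway")
  }
  with_seed(config$seed + 404L, {
    n <- nrow(genotypes)
    subj <- rownames(genotypes)

    causal <- if (config$n_causal_pathways > 0) {
      sort(sample(names(gene_sets), config$n_causal_pathways))
    } else character(0)
    causal_genes <- unique(unlist(gene_sets[causal]))
    thr <- maf_threshold(config$n_subjects)
    cv <- variants$variant_id[variants$gene %in% causal_genes & variants$maf < thr]

    scheme <- weighting_scheme("eigen", rare_maf_threshold = thr)
    burden <- if (length(cv)) {
      raw <- unit_scores(genotypes, variants, scheme, list(causal = cv))[, 1L]
      if (stats::sd(raw) > 0) as.numeric(scale(raw)) else rep(0, n)
    } else rep(0, n)

    if (config$genetic_model == "tail" && length(cv)) {
      cut <- stats::quantile(abs(burden), config$tail_quantile)
      b_eff <- ifelse(abs(burden) > cut, burden, 0)
      b_eff <- if (stats::sd(b_eff) > 0) as.numeric(scale(b_eff)) else b_eff
    } else {
      b_eff <- burden
    }

    # clinical risk factors are independent variables, each contributing its
    # own effect; the clinical liability is their weighted sum plus residual
    # variation not captured by the recorded variables
    suicidal_risk <- stats::rbinom(n, 1, 0.3)
    n_prev_episodes <- stats::rpois(n, 2)
    chronic_depression <- stats::rbinom(n, 1, 0.25)
    madrs_pessimism <- stats::rnorm(n)
    madrs_interest <- stats::rnorm(n)
    zs <- function(x) if (stats::sd(x) > 0) as.numeric(scale(x)) else rep(0, n)
    clin_raw <- 0.55 * zs(suicidal_risk) + 0.55 * zs(n_prev_episodes) +
      0.50 * zs(chronic_depression) + 0.60 * zs(madrs_pessimism) +
      0.55 * zs(madrs_interest) + 0.35 * stats::rnorm(n)
    clin <- zs(clin_raw)
    centre <- sample.int(config$centre_count, n, replace = TRUE)
    centre_eff <- stats::rnorm(config$centre_count, 0, 0.1)

    # predictable signal excludes the centre effect, which the analysis
    # treats as a nuisance covariate and regresses out
    signal <- config$genetic_effect * b_eff + config$clinical_effect * clin
    liability <- signal + centre_eff[centre] + stats::rnorm(n)

    # class thresholds at empirical liability quantiles -> counts match the
    # target mix up to rounding
    qs <- stats::quantile(liability, cumsum(config$class_mix[c(3, 2)]), type = 1)
    outcome <- ifelse(liability <= qs[1], "RESP",
                      ifelse(liability <= qs[2], "NONRESP", "TRD"))

    # MADRS trajectories and failed-treatment counts consistent with outcome
    madrs_baseline <- pmax(round(stats::rnorm(n, 34.4, 7.4)), 14)
    resp <- outcome == "RESP"
    cap <- pmin(21.9, 0.5 * madrs_baseline)
    madrs_current <- integer(n)
    madrs_current[resp] <- floor(stats::runif(sum(resp), 0.2, 0.999) * cap[resp])
    madrs_current[!resp] <- ceiling(madrs_baseline[!resp] *
                                      stats::runif(sum(!resp), 0.55, 1.05)) + 1L
    n_failed <- integer(n)
    n_failed[resp] <- stats::rbinom(sum(resp), 1, 0.4)
    n_failed[outcome == "NONRESP"] <- 1L
    n_failed[outcome == "TRD"] <- sample(2:4, sum(outcome == "TRD"), replace = TRUE,
                                         prob = c(0.6, 0.3, 0.1))

    treatment_class <- sample(c("5HT", "NA", "combo", "other"), n, replace = TRUE,
                              prob = c(0.50, 0.30, 0.16, 0.04))

    phen <- data.frame(
      subject_id = subj,
      outcome = outcome,
      pc1 = stats::rnorm(n), pc2 = stats::rnorm(n), pc3 = stats::rnorm(n),
      centre = sprintf("C%02d", centre),
      treatment_class = treatment_class,
      madrs_baseline = madrs_baseline, madrs_current = madrs_current,
      suicidal_risk = suicidal_risk, n_prev_episodes = n_prev_episodes,
      chronic_depression = chronic_depression,
      madrs_pessimism = madrs_pessimism, madrs_interest = madrs_interest,
      n_failed_adequate_treatments = n_failed,
      row.names = NULL, stringsAsFactors = FALSE
    )

    tr <- outcome != "NONRESP"
    truth <- list(
      causal_pathway_ids = causal,
      liability = liability,
      signal = signal,
      causal_burden = burden,
      clinical_liability = clin,
      bayes_auc = auc_mw(signal[tr], outcome[tr] == "TRD")
    )
    list(phenotypes = phen, truth = truth)
  })
}

#' Simulate a full cohort
#'
#' Convenience wrapper running [simulate_variant_table()],
#' [simulate_genotypes()], [simulate_gene_sets()] and [simulate_outcome()]
#' under one configuration.
#'
#' @param config A [sim_config()].
#' @return List with `variants`, `genotypes`, `gene_sets`, `phenotypes`,
#'   `truth` and the `config` used.
#' @export
simulate_cohort <- function(config = sim_config()) {
  variants <- simulate_variant_table(config)
  genotypes <- simulate_genotypes(variants, config)
  gene_sets <- simulate_gene_sets(config)
  out <- simulate_outcome(genotypes, variants, gene_sets, config)
  list(variants = variants, genotypes = genotypes, gene_sets = gene_sets,
       phenotypes = out$phenotypes, truth = out$truth, config = config)
}

#' Simulate a per-treatment trial history
#'
#' Secondary generator mode for phenotype-definition tests: each subject
#' receives 1-4 adequate treatments; each non-final treatment fails, and the
#' final MADRS trajectory determines response. The derived
#' (`madrs_baseline`, `madrs_current`, failed-treatment count) triples feed
#' [define_outcome()] directly.
#'
#' @param n_subjects Number of subjects.
#' @param seed Integer seed.
#' @return Data frame with `subject_id`, `madrs_baseline`, `madrs_current`,
#'   `n_failed_adequate_treatments` and the derived `outcome`.
#' @export
simulate_treatment_history <- function(n_subjects = 100, seed = 1L) {
  with_seed(seed + 505L, {
    n_treat <- sample(1:4, n_subjects, replace = TRUE, prob = c(0.35, 0.3, 0.25, 0.1))
    baseline <- pmax(round(stats::rnorm(n_subjects, 34, 7)), 14)
    responded <- stats::runif(n_subjects) < 0.45
    cap <- pmin(21.9, 0.5 * baseline)
    current <- ifelse(responded,
                      floor(stats::runif(n_subjects, 0.2, 0.999) * cap),
                      ceiling(baseline * stats::runif(n_subjects, 0.55, 1.05)) + 1L)
    # every treatment before the last failed; the last fails unless responded
    n_failed <- ifelse(responded, n_treat - 1L, n_treat)
    out <- data.frame(subject_id = sprintf("T%04d", seq_len(n_subjects)),
                      madrs_baseline = baseline, madrs_current = current,
                      n_failed_adequate_treatments = n_failed,
                      stringsAsFactors = FALSE)
    out$outcome <- vapply(seq_len(n_subjects), function(i) {
      define_outcome(out$madrs_baseline[i], out$madrs_current[i],
                     out$n_failed_adequate_treatments[i])
    }, character(1))
    out
  })
}
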