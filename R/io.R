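#' Write genotypes as VCF
#'
#' Minimal VCF 4.2 with unphased diploid GT fields; 1-based positions from
#' the variant table.
#'
#' @param genotypes A [genotype_matrix()].
#' @param variants Variant table providing `chrom`, `pos`, `ref`, `alt` for
#'   every genotyped variant.
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genotypes, variants, path) {
  v <- variants[match(colnames(genotypes), variants$variant_id), , drop = FALSE]
  if (anyNA(v$variant_id)) stop("variant table missing entries for genotyped variants")
  gt_code <- c("0/0", "0/1", "1/1")
  G <- unclass(genotypes)
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(G)), collapse = "\t"))
  body <- vapply(seq_len(ncol(G)), function(j) {
    g <- G[, j]
    gs <- ifelse(is.na(g), "./.", gt_code[g + 1L])
    paste(c(v$chrom[j], v$pos[j], v$variant_id[j], v$ref[j], v$alt[j],
            ".", "PASS", ".", "GT", gs), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read a genotype matrix from a VCF
#'
#' Counts alternative alleles in the GT field (phased and unphased treated
#' identically); `./.` becomes `NA`. Only bi-allelic records are accepted.
#'
#' @param path VCF file path.
#' @return A [genotype_matrix()] (subjects x variants).
#' @export
read_vcf_genotypes <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (any(grepl(",", vcfR::getALT(vcf), fixed = TRUE))) {
    stop("multi-allelic records found; split them upstream")
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  counts <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("|", "/", gt, fixed = TRUE)
  counts[clean == "0/0"] <- 0L
  counts[clean %in% c("0/1", "1/0")] <- 1L
  counts[clean == "1/1"] <- 2L
  genotype_matrix(t(counts))
}

#' Read and write the per-variant annotation table (TSV)
#'
#' @param variants Variant table.
#' @param path File path.
#' @return `read_annotation_tsv` returns the table; writers return `path`
#'   invisibly.
#' @export
write_annotation_tsv <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation_tsv
#' @export
read_annotation_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(chrom = "character"))
  req <- c("variant_id", "gene", "alt_freq", "maf")
  miss <- setdiff(req, names(tab))
  if (length(miss)) stop("annotation TSV missing columns: ", paste(miss, collapse = ", "))
  tab
}

#' Read and write gene sets in GMT format
#'
#' Reading is delegated to `fgsea::gmtPathways`; writing emits the standard
#' tab-separated `name<TAB>description<TAB>gene...` lines.
#'
#' @param gene_sets Named list of character vectors.
#' @param path File path.
#' @return `read_gmt` returns a named list; `write_gmt` returns `path`
#'   invisibly.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(names(gene_sets), function(nm) {
    paste(c(nm, "synthetic", gene_sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Read and write the phenotype/clinical table (CSV)
#'
#' @param phenotypes Phenotype data frame.
#' @param path File path.
#' @return `read_phenotypes_csv` returns the data frame; the writer returns
#'   `path` invisibly.
#' @export
write_phenotypes_csv <- function(phenotypes, path) {
  utils::write.csv(phenotypes, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes_csv
#' @export
read_phenotypes_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a pipeline configuration from YAML
#'
#' Recognized top-level blocks mirror [run_pipeline()]'s arguments (e.g.
#' `sim`, `selection`, `gbm`, `evaluation`); `sim` fields are passed to
#' [sim_config()].
#'
#' @param path YAML file path.
#' @return A named list.
#' @export
read_pipeline_config <- function(path) {
  yaml::read_yaml(path)
}
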