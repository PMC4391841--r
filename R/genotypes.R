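# Containers for unphased genotypes and prepared phenotypes.

#' Construct a genotype dataset
#'
#' @param G n x m matrix of alternate-allele counts (0, 1, 2) or imputed
#'   dosages in [0, 2]; missing genotypes as NA.
#' @param snp_meta optional data.frame with one row per SNP: columns
#'   \code{chrom}, \code{pos} (1-based base pairs), \code{id}, \code{ref},
#'   \code{alt}. A default is synthesized when absent.
#' @param sample_ids optional character vector of n sample identifiers.
#' @return An object of class \code{genotype_dataset}.
#' @export
genotype_dataset <- function(G, snp_meta = NULL, sample_ids = NULL) {
  G <- as.matrix(G)
  ok <- G[!is.na(G)]
  if (length(ok) && (min(ok) < 0 || max(ok) > 2))
    stop("genotype dosages must lie in [0, 2] (or NA when missing)")
  n <- nrow(G); m <- ncol(G)
  if (is.null(snp_meta)) {
    snp_meta <- data.frame(chrom = rep("1", m), pos = seq_len(m) * 1000L,
                           id = paste0("snp", seq_len(m)),
                           ref = rep("A", m), alt = rep("B", m),
                           stringsAsFactors = FALSE)
  }
  if (nrow(snp_meta) != m) stop("snp_meta must have one row per SNP")
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(n))
  if (length(sample_ids) != n) stop("sample_ids must have length n")
  structure(list(G = G, snp_meta = snp_meta, sample_ids = sample_ids,
                 n = n, m = m),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("Genotype dataset: %d samples x %d SNPs (%d missing calls)\n",
              x$n, x$m, sum(is.na(x$G))))
  invisible(x)
}

#' Mean-impute missing genotypes
#'
#' Replaces missing calls by the per-SNP mean allele count. Designs are
#' always built on imputed genotypes; I/O never imputes.
#'
#' @param data a \code{genotype_dataset}.
#' @return A \code{genotype_dataset} with no missing entries.
#' @export
impute_missing <- function(data) {
  stopifnot(inherits(data, "genotype_dataset"))
  G <- data$G
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- mu[idx[, 2L]]
    data$G <- G
  }
  data
}

#' Subset a genotype dataset by SNP index
#'
#' @param data a \code{genotype_dataset}.
#' @param snps integer vector of SNP (column) indices to keep.
#' @return A \code{genotype_dataset} restricted to the selected SNPs.
#' @export
subset_snps <- function(data, snps) {
  stopifnot(inherits(data, "genotype_dataset"))
  genotype_dataset(data$G[, snps, drop = FALSE],
                   data$snp_meta[snps, , drop = FALSE],
                   data$sample_ids)
}

#' Construct a phenotype vector
#'
#' @param y numeric trait values.
#' @param standardized logical; if TRUE, \code{y} must have mean 0 and
#'   variance 1 (tolerance 1e-8).
#' @return An object of class \code{phenotype_vector}.
#' @export
phenotype_vector <- function(y, standardized = FALSE) {
  y <- as.numeric(y)
  if (standardized) {
    if (abs(mean(y)) > 1e-8 || abs(stats::var(y) - 1) > 1e-8)
      stop("standardized phenotype must have mean 0, variance 1")
  }
  structure(list(y = y, standardized = standardized, n = length(y)),
            class = "phenotype_vector")
}

#' Standardize a phenotype to mean 0, variance 1
#'
#' @param y numeric vector or \code{phenotype_vector}.
#' @return A standardized \code{phenotype_vector}.
#' @export
standardize_phenotype <- function(y) {
  if (inherits(y, "phenotype_vector")) y <- y$y
  s <- stats::sd(y)
  if (s == 0) stop("phenotype has zero variance")
  phenotype_vector((y - mean(y)) / s, standardized = TRUE)
}
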