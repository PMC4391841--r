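# Design matrix construction for the regression-based association models.
# All designs are functions of the unphased genotype matrix; missing
# genotypes must be imputed beforehand.

new_design_matrix <- function(X, design_kind, labels = colnames(X)) {
  X <- as.matrix(X)
  if (ncol(X) < 1L) stop("design must have at least one column")
  colnames(X) <- labels
  structure(list(X = X, design_kind = design_kind, q = ncol(X)),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("Design matrix (%s): %d x %d\n", x$design_kind,
              nrow(x$X), x$q))
  invisible(x)
}

#' Additive design: one allele-count column per SNP
#'
#' @param data a \code{genotype_dataset} without missing entries
#'   (see [impute_missing()]).
#' @return A \code{design_matrix} with q = m columns.
#' @export
design_additive <- function(data) {
  stopifnot(inherits(data, "genotype_dataset"))
  if (anyNA(data$G)) stop("impute missing genotypes before building designs")
  if (data$m < 1L) stop("empty SNP set")
  new_design_matrix(data$G, "additive", data$snp_meta$id)
}

#' Interaction design: allele counts plus all pairwise genotype products
#'
#' @inheritParams design_additive
#' @return A \code{design_matrix} with q = m + choose(m, 2) columns.
#' @export
design_interaction <- function(data) {
  stopifnot(inherits(data, "genotype_dataset"))
  if (anyNA(data$G)) stop("impute missing genotypes before building designs")
  if (data$m < 2L) stop("interaction design needs at least 2 SNPs")
  G <- data$G
  colnames(G) <- data$snp_meta$id
  new_design_matrix(cbind(G, pairwise_products(G)), "interaction")
}

#' Genotypic design: indicators over multilocus genotype classes
#'
#' Each of the 3^m possible multilocus genotypes is a category; each row
#' carries a single 1 in the column of its observed class. Only observed
#' classes yield columns (unobserved classes would be all-zero).
#'
#' @inheritParams design_additive
#' @param genotypic_max refuse more SNPs than this (3^m columns grow fast).
#' @return A \code{design_matrix} of genotype-class indicators.
#' @export
design_genotypic <- function(data, genotypic_max = 8L) {
  stopifnot(inherits(data, "genotype_dataset"))
  if (anyNA(data$G)) stop("impute missing genotypes before building designs")
  if (data$m > genotypic_max)
    stop("genotypic design over ", data$m, " SNPs would have 3^",
         data$m, " columns; use the additive or interaction design, or ",
         "raise genotypic_max")
  cls <- apply(round(data$G), 1L, paste0, collapse = " ")
  new_design_matrix(class_indicators(cls), "genotypic")
}

# one-hot indicator matrix over observed class labels
class_indicators <- function(cls) {
  lev <- sort(unique(cls))
  X <- matrix(0, length(cls), length(lev), dimnames = list(NULL, lev))
  X[cbind(seq_along(cls), match(cls, lev))] <- 1
  X
}

#' Build the design for a named model family
#'
#' Convenience dispatcher used by the simulation engine and the CLI.
#' \code{"haplotype_prob"} runs the EM phasing step and uses the expected
#' haplotype counts; \code{"vc"} is handled separately (see [grm()]).
#'
#' @inheritParams design_additive
#' @param model one of \code{"additive"}, \code{"interaction"},
#'   \code{"genotypic"}, \code{"haplotype_prob"}.
#' @return A \code{design_matrix}.
#' @export
build_design <- function(data, model = c("additive", "interaction",
                                         "genotypic", "haplotype_prob")) {
  model <- match.arg(model)
  switch(model,
         additive = design_additive(data),
         interaction = design_interaction(data),
         genotypic = design_genotypic(data),
         haplotype_prob = {
           dos <- em_haplotype_dosages(data)
           new_design_matrix(dos$M, "haplotype_prob")
         })
}
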