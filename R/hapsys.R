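# Haplotype systems: the generative population model behind all simulations.
#
# A haplotype system is a set of k distinct haplotypes over m biallelic SNPs
# (allele codes 0 = reference, 1 = alternate), a population frequency vector
# pi, and optionally a vector beta of per-copy haplotype effects on a
# quantitative trait.  Individuals are formed by Hardy-Weinberg random mating
# (two independent haplotype draws), so every population-level quantity can
# be computed by exact enumeration of the k(k+1)/2 diplotypes.

#' Construct a haplotype system
#'
#' @param H k x m matrix of 0/1 allele codes, one row per haplotype. Rows
#'   must be distinct. A vector is taken as a single-SNP system (k x 1).
#' @param pi length-k vector of haplotype frequencies (non-negative, summing
#'   to 1 within 1e-12).
#' @param beta optional length-k vector of haplotype effects, in trait units
#'   per haplotype copy.
#' @return An object of class \code{haplotype_system} with elements
#'   \code{H}, \code{pi}, \code{beta}, \code{k}, \code{m}.
#' @examples
#' hs <- haplotype_system(rbind(c(0,0), c(0,1), c(1,0), c(1,1)),
#'                        pi = c(0.10, 0.30, 0.15, 0.45))
#' allele_frequencies(hs)
#' @export
haplotype_system <- function(H, pi, beta = NULL) {
  H <- as.matrix(H)
  storage.mode(H) <- "integer"
  if (!all(H %in% c(0L, 1L))) stop("H entries must be 0/1 allele codes")
  k <- nrow(H); m <- ncol(H)
  if (k > 2^m) stop("more haplotypes than 2^m possible over ", m, " SNPs")
  key <- apply(H, 1L, paste0, collapse = "")
  if (anyDuplicated(key)) stop("haplotype rows must be distinct")
  pi <- as.numeric(pi)
  if (length(pi) != k) stop("pi must have one frequency per haplotype")
  if (any(pi < 0)) stop("pi entries must be non-negative")
  if (abs(sum(pi) - 1) > 1e-12) stop("pi must sum to 1 (tolerance 1e-12)")
  if (!is.null(beta)) {
    beta <- as.numeric(beta)
    if (length(beta) != k) stop("beta must have one effect per haplotype")
  }
  rownames(H) <- key
  structure(list(H = H, pi = pi, beta = beta, k = k, m = m),
            class = "haplotype_system")
}

#' @export
print.haplotype_system <- function(x, ...) {
  cat(sprintf("Haplotype system: %d haplotypes over %d SNPs\n", x$k, x$m))
  tab <- data.frame(haplotype = rownames(x$H), frequency = x$pi)
  if (!is.null(x$beta)) tab$effect <- x$beta
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Convert diplotype copy-counts to unphased genotypes
#'
#' Multiplies the n x k diplotype matrix by the haplotype allele matrix,
#' giving per-SNP alternate-allele counts.
#'
#' @param sample a \code{diplotype_sample} (see [sample_diplotypes()]).
#' @return A \code{genotype_dataset} with entries in 0..2.
#' @export
genotypes_from_diplotypes <- function(sample) {
  stopifnot(inherits(sample, "diplotype_sample"))
  sys <- sample$panel
  if (ncol(sample$D) != sys$k) stop("diplotype/haplotype dimension mismatch")
  G <- sample$D %*% sys$H
  storage.mode(G) <- "integer"
  genotype_dataset(G)
}

#' Per-SNP alternate-allele frequencies implied by a haplotype system
#'
#' @param system a \code{haplotype_system}.
#' @return Numeric vector xi of length m, xi_l = sum_i pi_i H_il.
#' @export
allele_frequencies <- function(system) {
  stopifnot(inherits(system, "haplotype_system"))
  as.numeric(crossprod(system$H, system$pi))
}

#' Pairwise linkage disequilibrium between two SNPs of a haplotype system
#'
#' Computes D = P(1,1) - xi_a * xi_b, the normalized D' and the squared
#' allelic correlation r2 from the population haplotype frequencies.
#'
#' @param system a \code{haplotype_system}.
#' @param snp_a,snp_b distinct SNP (column) indices.
#' @return A list with elements \code{D}, \code{D_prime}, \code{r2}.
#' @export
pairwise_ld <- function(system, snp_a, snp_b) {
  stopifnot(inherits(system, "haplotype_system"))
  if (snp_a == snp_b) stop("snp_a and snp_b must differ")
  xi <- allele_frequencies(system)
  xa <- xi[snp_a]; xb <- xi[snp_b]
  if (xa <= 0 || xa >= 1 || xb <= 0 || xb >= 1)
    stop("LD undefined for a monomorphic SNP")
  p11 <- sum(system$pi[system$H[, snp_a] == 1L & system$H[, snp_b] == 1L])
  D <- p11 - xa * xb
  dmax <- if (D >= 0) min(xa * (1 - xb), (1 - xa) * xb)
          else        min(xa * xb, (1 - xa) * (1 - xb))
  list(D = D,
       D_prime = if (dmax == 0) 0 else D / dmax,
       r2 = D^2 / (xa * (1 - xa) * xb * (1 - xb)))
}

#' Trait variance generated by haplotype effects
#'
#' Variance of D beta under Hardy-Weinberg random mating:
#' sum_i beta_i^2 2 pi_i (1 - pi_i) - 4 sum_{i<j} beta_i beta_j pi_i pi_j,
#' i.e. twice the per-draw variance of the haplotype effect.
#'
#' @param system a \code{haplotype_system} with \code{beta} present.
#' @return The genetic variance sigma^2_H; total trait variance under the
#'   generative model is sigma^2_H + 1.
#' @export
haplotype_variance <- function(system) {
  stopifnot(inherits(system, "haplotype_system"))
  if (is.null(system$beta)) stop("haplotype effects (beta) are required")
  b <- system$beta; p <- system$pi
  2 * (sum(b^2 * p) - sum(b * p)^2)
}

# quadratic form matrix A with haplotype_variance(beta) = beta' A beta
hap_variance_matrix <- function(system) {
  p <- system$pi
  2 * (diag(p, nrow = length(p)) - tcrossprod(p))
}

# Exact HWE diplotype enumeration: all unordered pairs with positive mass.
# Returns list(prob, hap1, hap2, counts [atoms x k], G [atoms x m]).
enumerate_diplotypes <- function(system) {
  k <- system$k
  idx <- which(upper.tri(matrix(0, k, k), diag = TRUE), arr.ind = TRUE)
  u <- idx[, 1L]; v <- idx[, 2L]
  prob <- ifelse(u == v, system$pi[u]^2, 2 * system$pi[u] * system$pi[v])
  keep <- prob > 0
  u <- u[keep]; v <- v[keep]; prob <- prob[keep]
  counts <- matrix(0, length(u), k)
  counts[cbind(seq_along(u), u)] <- counts[cbind(seq_along(u), u)] + 1
  counts[cbind(seq_along(v), v)] <- counts[cbind(seq_along(v), v)] + 1
  list(prob = prob, hap1 = u, hap2 = v, counts = counts,
       G = counts %*% system$H)
}

# Design row builder over enumerated diplotype atoms for a given design kind.
# For haplotype_prob the rows are posterior expected haplotype counts given
# the unphased genotype, under the system's own frequencies.
atom_design <- function(system, en, design_kind) {
  G <- en$G
  switch(design_kind,
    additive = G,
    interaction = cbind(G, pairwise_products(G)),
    genotypic = {
      cls <- apply(G, 1L, paste0, collapse = ",")
      class_indicators(cls)
    },
    haplotype_prob = {
      cls <- apply(G, 1L, paste0, collapse = ",")
      M <- matrix(0, nrow(G), system$k)
      for (cc in unique(cls)) {
        at <- which(cls == cc)
        w <- en$prob[at] / sum(en$prob[at])
        mrow <- colSums(en$counts[at, , drop = FALSE] * w)
        M[at, ] <- matrix(mrow, length(at), system$k, byrow = TRUE)
      }
      M
    },
    stop("unsupported design_kind: ", design_kind)
  )
}

# K (q x k): weighted covariance between design columns and diplotype counts;
# C (q x q): weighted covariance of the design.  sigma2_X(beta) = b' K'C^- K b.
captured_variance_operator <- function(system, design_kind) {
  en <- enumerate_diplotypes(system)
  X <- atom_design(system, en, design_kind)
  w <- en$prob
  Xc <- sweep(X, 2L, colSums(X * w))
  Dc <- sweep(en$counts, 2L, colSums(en$counts * w))
  C <- crossprod(Xc, Xc * w)
  K <- crossprod(Xc, Dc * w)
  Cinv <- pseudo_inverse(C)
  list(S = crossprod(K, Cinv %*% K), C = C, K = K)
}

#' Population variance captured by an association design
#'
#' Projects the generative haplotype signal D beta onto the span of a chosen
#' design (computed from the unphased genotype), using exact expectations
#' over the Hardy-Weinberg diplotype distribution -- no sampling noise.
#' This is the population analogue of the fitted genetic variance of the
#' corresponding regression model.
#'
#' @param system a \code{haplotype_system} with \code{beta}.
#' @param design_kind one of \code{"additive"}, \code{"interaction"},
#'   \code{"genotypic"}, \code{"haplotype_prob"}.
#' @return sigma^2_X, with 0 <= sigma^2_X <= haplotype_variance(system).
#' @export
population_captured_variance <- function(system,
    design_kind = c("additive", "interaction", "genotypic",
                    "haplotype_prob")) {
  stopifnot(inherits(system, "haplotype_system"))
  design_kind <- match.arg(design_kind)
  if (is.null(system$beta)) stop("haplotype effects (beta) are required")
  op <- captured_variance_operator(system, design_kind)
  drop(crossprod(system$beta, op$S %*% system$beta))
}

pairwise_products <- function(G) {
  m <- ncol(G)
  if (m < 2) stop("interaction design needs at least 2 SNPs")
  pr <- utils::combn(m, 2L)
  out <- G[, pr[1L, ], drop = FALSE] * G[, pr[2L, ], drop = FALSE]
  colnames(out) <- paste0("x", pr[1L, ], ":x", pr[2L, ])
  out
}

pseudo_inverse <- function(A, tol = 1e-10) {
  e <- eigen(A, symmetric = TRUE)
  pos <- e$values > tol * max(e$values, 0)
  if (!any(pos)) return(matrix(0, nrow(A), ncol(A)))
  e$vectors[, pos, drop = FALSE] %*%
    (t(e$vectors[, pos, drop = FALSE]) / e$values[pos])
}

#' Write / read a haplotype system as TSV
#'
#' Plain-text serialization used by scenario configuration files: columns
#' \code{haplotype} (allele string), \code{frequency}, optionally
#' \code{effect}.
#'
#' @param system a \code{haplotype_system}.
#' @param path file path.
#' @return \code{read_haplotype_system} returns a \code{haplotype_system};
#'   \code{write_haplotype_system} returns \code{path} invisibly.
#' @export
write_haplotype_system <- function(system, path) {
  stopifnot(inherits(system, "haplotype_system"))
  tab <- data.frame(haplotype = rownames(system$H), frequency = system$pi)
  if (!is.null(system$beta)) tab$effect <- system$beta
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_haplotype_system
#' @export
read_haplotype_system <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = c(haplotype = "character"))
  H <- do.call(rbind, lapply(strsplit(tab$haplotype, ""), as.integer))
  haplotype_system(H, tab$frequency,
                   beta = if ("effect" %in% names(tab)) tab$effect)
}
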