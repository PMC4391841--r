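# EM estimation of haplotype frequencies and posterior haplotype dosages
# from unphased genotypes, assuming Hardy-Weinberg equilibrium.
#
# The E-step assigns each individual posterior weights over the ordered
# haplotype pairs compatible with its genotype, proportional to
# pi_u * pi_v; the M-step re-estimates pi from the expected counts.  Work
# is done on distinct genotype classes, so cost scales with the number of
# classes (at most 3^m), not with n.

# Enumerate the haplotype pairs compatible with one genotype row.
# het positions split into 2^(h-1) unordered phase configurations.
compatible_pairs <- function(g) {
  m <- length(g)
  het <- which(g == 1L)
  base <- integer(m)
  base[g == 2L] <- 1L
  if (length(het) == 0L) {
    return(list(h1 = matrix(base, 1L), h2 = matrix(base, 1L)))
  }
  nh <- length(het)
  # first het position fixed to allele 1 on h1 to enumerate unordered pairs
  combos <- as.matrix(expand.grid(rep(list(0:1), nh - 1L)))
  h1 <- matrix(base, nrow = max(1L, nrow(combos)), ncol = m, byrow = TRUE)
  h1[, het[1L]] <- 1L
  if (nh > 1L)
    h1[, het[-1L]] <- combos
  h2 <- h1
  h2[, het] <- 1L - h1[, het]
  list(h1 = h1, h2 = h2)
}

#' Expected haplotype counts from unphased genotypes (EM under HWE)
#'
#' @param data a \code{genotype_dataset} with no missing entries and a
#'   modest SNP count (compatible phase pairs are enumerated).
#' @param max_snps refuse more SNPs than this.
#' @param tol convergence threshold on max |delta pi-hat|.
#' @param max_iter iteration cap; non-convergence returns the best estimate
#'   with \code{converged = FALSE}.
#' @return An object of class \code{haplotype_dosage}: \code{M} (n x k
#'   expected haplotype counts, rows summing to 2), \code{haplotypes} (k x m
#'   allele matrix), \code{em_frequencies} (pi-hat), \code{loglik} (trace),
#'   \code{converged}, \code{n_iter}.
#' @export
em_haplotype_dosages <- function(data, max_snps = 12L, tol = 1e-8,
                                 max_iter = 1000L) {
  stopifnot(inherits(data, "genotype_dataset"))
  G <- round(data$G)
  if (anyNA(G)) stop("impute missing genotypes before EM phasing")
  m <- ncol(G)
  if (m > max_snps)
    stop("EM phasing over ", m, " SNPs exceeds max_snps = ", max_snps)
  cls_key <- apply(G, 1L, paste0, collapse = "")
  classes <- unique(cls_key)
  cls_idx <- match(cls_key, classes)
  cls_n <- tabulate(cls_idx, length(classes))
  n <- nrow(G)

  # per-class compatible pair lists, over a shared haplotype universe
  hap_key <- character(0)
  pair_u <- vector("list", length(classes))
  pair_v <- vector("list", length(classes))
  hap_rows <- list()
  hap_id <- function(hmat) {
    keys <- apply(hmat, 1L, paste0, collapse = "")
    new <- setdiff(keys, hap_key)
    if (length(new)) {
      hap_key <<- c(hap_key, new)
      for (kk in new) hap_rows[[kk]] <<- as.integer(strsplit(kk, "")[[1]])
    }
    match(keys, hap_key)
  }
  for (ci in seq_along(classes)) {
    g <- as.integer(strsplit(classes[ci], "")[[1]])
    cp <- compatible_pairs(g)
    pair_u[[ci]] <- hap_id(cp$h1)
    pair_v[[ci]] <- hap_id(cp$h2)
  }
  k <- length(hap_key)
  H <- do.call(rbind, hap_rows[hap_key])
  rownames(H) <- hap_key

  pi_hat <- rep(1 / k, k)
  loglik <- numeric(0)
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    counts <- numeric(k)
    ll <- 0
    for (ci in seq_along(classes)) {
      u <- pair_u[[ci]]; v <- pair_v[[ci]]
      w <- pi_hat[u] * pi_hat[v] * ifelse(u == v, 1, 2)
      sw <- sum(w)
      ll <- ll + cls_n[ci] * log(max(sw, .Machine$double.xmin))
      w <- if (sw > 0) w / sw else rep(1 / length(w), length(w))
      for (j in seq_along(u)) {
        counts[u[j]] <- counts[u[j]] + cls_n[ci] * w[j]
        counts[v[j]] <- counts[v[j]] + cls_n[ci] * w[j]
      }
    }
    loglik <- c(loglik, ll)
    pi_new <- counts / (2 * n)
    delta <- max(abs(pi_new - pi_hat))
    pi_hat <- pi_new
    if (delta < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  if (!converged)
    warning("EM did not converge within ", max_iter, " iterations")

  # final E-step at the converged frequencies -> class-level dosage rows
  Mcls <- matrix(0, length(classes), k)
  for (ci in seq_along(classes)) {
    u <- pair_u[[ci]]; v <- pair_v[[ci]]
    w <- pi_hat[u] * pi_hat[v] * ifelse(u == v, 1, 2)
    sw <- sum(w)
    w <- if (sw > 0) w / sw else rep(1 / length(w), length(w))
    for (j in seq_along(u)) {
      Mcls[ci, u[j]] <- Mcls[ci, u[j]] + w[j]
      Mcls[ci, v[j]] <- Mcls[ci, v[j]] + w[j]
    }
  }
  M <- Mcls[cls_idx, , drop = FALSE]
  colnames(M) <- hap_key
  structure(list(M = M, haplotypes = H, em_frequencies = pi_hat,
                 loglik = loglik, converged = converged, n_iter = it),
            class = "haplotype_dosage")
}

#' Posterior expected haplotype counts at fixed frequencies
#'
#' The single E-step of the phasing EM: for one unphased genotype row,
#' weights each compatible ordered haplotype pair proportionally to
#' pi_u * pi_v and returns the posterior expected copy-count of each
#' haplotype in \code{system}. Haplotypes compatible with the genotype but
#' absent from \code{system} are treated as frequency 0.
#'
#' @param g integer genotype row (allele counts over m SNPs).
#' @param system a \code{haplotype_system} supplying H and pi.
#' @return Named numeric vector of expected counts over the system's
#'   haplotypes, summing to 2.
#' @export
expected_haplotype_counts <- function(g, system) {
  stopifnot(inherits(system, "haplotype_system"))
  cp <- compatible_pairs(as.integer(g))
  keys <- rownames(system$H)
  k1 <- match(apply(cp$h1, 1L, paste0, collapse = ""), keys)
  k2 <- match(apply(cp$h2, 1L, paste0, collapse = ""), keys)
  pi_of <- function(i) ifelse(is.na(i), 0, system$pi[ifelse(is.na(i), 1L, i)])
  w <- pi_of(k1) * pi_of(k2) * ifelse(!is.na(k1) & !is.na(k2) & k1 == k2, 1, 2)
  if (sum(w) == 0) stop("genotype incompatible with every system haplotype")
  w <- w / sum(w)
  out <- stats::setNames(numeric(system$k), keys)
  for (j in seq_along(w)) {
    if (!is.na(k1[j])) out[k1[j]] <- out[k1[j]] + w[j]
    if (!is.na(k2[j])) out[k2[j]] <- out[k2[j]] + w[j]
  }
  out
}

#' @export
print.haplotype_dosage <- function(x, ...) {
  cat(sprintf(
    "Haplotype dosages: %d samples x %d haplotypes (EM %sconverged in %d iterations)\n",
    nrow(x$M), ncol(x$M), if (x$converged) "" else "NOT ", x$n_iter))
  invisible(x)
}
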