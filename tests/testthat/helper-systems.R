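# Shared fixture builders (all fixtures are generated in code).

H4 <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))

# the two 2-SNP frequency sets used throughout: LE (r2 = 0) and LD
sys_le <- function(beta = NULL)
  haplotype_system(H4, c(0.10, 0.30, 0.15, 0.45), beta = beta)

sys_uniform <- function(beta = NULL)
  haplotype_system(H4, rep(0.25, 4), beta = beta)

# 2-SNP system with both allele frequencies 0.5 and exact pairwise r2
sys_exact_r2 <- function(r2, beta = NULL) {
  d <- sqrt(r2 * 0.25 * 0.25)
  haplotype_system(H4, c(0.25 + d, 0.25 - d, 0.25 - d, 0.25 + d),
                   beta = beta)
}

random_system <- function(m = 2, k = 4, with_beta = TRUE) {
  k <- min(k, 2^m)
  repeat {
    H <- matrix(sample(0:1, k * m, replace = TRUE), k, m)
    if (!anyDuplicated(apply(H, 1, paste0, collapse = "")) &&
        all(apply(H, 2, function(x) length(unique(x)) > 1))) break
  }
  p <- stats::rgamma(k, 1) + 0.05
  haplotype_system(H, p / sum(p),
                   beta = if (with_beta) stats::rnorm(k))
}

# independent-SNP genotype dataset on a 1-chromosome map
random_genotypes <- function(n, m, maf = 0.3, spacing = 2000) {
  G <- matrix(stats::rbinom(n * m, 2, maf), n, m)
  genotype_dataset(G, data.frame(
    chrom = rep("1", m), pos = seq_len(m) * spacing,
    id = paste0("snp", seq_len(m)), ref = "A", alt = "B",
    stringsAsFactors = FALSE))
}
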