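# Synthetic phased haplotype panels with tunable LD decay and MAF
# spectrum, and window scenarios that draw individuals from a panel.
#
# The generator is a latent Gaussian threshold model: each haplotype is an
# AR(1) Gaussian process along the chromosome whose adjacent-site
# correlation decays exponentially with base-pair distance, dichotomized
# at the quantile of the target allele frequency.  This produces
# monotonically decaying pairwise LD and an exact MAF spectrum; it does
# not model recombination hotspots, mutation age or haplotype sharing.

#' Generate a synthetic phased haplotype panel
#'
#' @param n_haplotypes number of phased haplotypes (2 per diploid sample
#'   when exported).
#' @param n_snps number of SNPs.
#' @param ld_decay_bp distance scale L of the latent AR(1) correlation
#'   exp(-d/L) between adjacent SNPs (base pairs).
#' @param maf_range allele-frequency bounds; per-SNP target frequencies
#'   are drawn uniformly within them.
#' @param bp_spacing mean spacing between adjacent SNPs (positions are
#'   cumulative sums of uniform gaps on [0.5, 1.5] x spacing).
#' @param chrom chromosome label.
#' @param seed integer seed; the panel is deterministic given it.
#' @return An object of class \code{haplotype_panel}: \code{haps}
#'   (n_haplotypes x n_snps 0/1 matrix), \code{snp_meta}, \code{maf}
#'   (realized alternate-allele frequencies).
#' @export
generate_fixture_panel <- function(n_haplotypes = 1000L, n_snps = 200L,
                                   ld_decay_bp = 20000, maf_range = c(0.05, 0.5),
                                   bp_spacing = 2000, chrom = "1",
                                   seed = 1L) {
  if (n_haplotypes < 2L || n_snps < 1L) stop("positive sizes required")
  set.seed(seed)
  gaps <- stats::runif(n_snps, 0.5, 1.5) * bp_spacing
  pos <- round(cumsum(gaps))
  freq <- stats::runif(n_snps, maf_range[1L], maf_range[2L])
  rho <- exp(-diff(pos) / ld_decay_bp)
  Z <- matrix(stats::rnorm(n_haplotypes * n_snps), n_haplotypes, n_snps)
  for (j in seq_len(n_snps - 1L))
    Z[, j + 1L] <- rho[j] * Z[, j] + sqrt(1 - rho[j]^2) * Z[, j + 1L]
  haps <- matrix(0L, n_haplotypes, n_snps)
  haps[Z < matrix(stats::qnorm(freq), n_haplotypes, n_snps, byrow = TRUE)] <- 1L
  meta <- data.frame(chrom = rep(chrom, n_snps), pos = pos,
                     id = paste0("snp", seq_len(n_snps)),
                     ref = rep("A", n_snps), alt = rep("B", n_snps),
                     stringsAsFactors = FALSE)
  structure(list(haps = haps, snp_meta = meta, maf = colMeans(haps),
                 n_haplotypes = n_haplotypes, n_snps = n_snps),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("Phased haplotype panel: %d haplotypes x %d SNPs\n",
              x$n_haplotypes, x$n_snps))
  invisible(x)
}

# empirical r2 between two panel SNP columns (haplotype-level LD)
panel_r2 <- function(haps, a, b) {
  xa <- mean(haps[, a]); xb <- mean(haps[, b])
  if (xa <= 0 || xa >= 1 || xb <= 0 || xb >= 1) return(NA_real_)
  d <- mean(haps[, a] * haps[, b]) - xa * xb
  d^2 / (xa * (1 - xa) * xb * (1 - xb))
}

# MAF filter + greedy r2 pruning on the haplotype panel
filter_panel_snps <- function(panel, maf_min = 0.01, r2_max = 0.8) {
  maf <- pmin(panel$maf, 1 - panel$maf)
  keep <- which(maf > maf_min)
  kept <- integer(0)
  for (j in keep) {
    ok <- TRUE
    for (i in kept) {
      if (panel_r2(panel$haps, i, j) > r2_max) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, j)
  }
  kept
}

#' Panel-window simulation scenario
#'
#' Selects a window of \code{window_size} SNPs from a phased panel
#' (restricted to MAF > \code{maf_min} and greedily pruned to maximum
#' pairwise r2 \code{r2_max}), designates two adjacent window SNPs as
#' causal, assigns haplotype effects over the causal pair's 4 observed
#' haplotypes via [effect_path()] at the requested non-additivity, and
#' returns a \code{scenario_config} whose replicates draw individuals as
#' random pairs of panel haplotypes. LD between the causal pair and the
#' nuisance SNPs is whatever the panel provides.
#'
#' @param panel a \code{haplotype_panel}.
#' @param window_size SNPs per window.
#' @param sigma2_H haplotype variance of the causal pair.
#' @param tau_prime target non-additivity.
#' @param causal_offset position of the first causal SNP within the
#'   window (default: centered).
#' @param mask_causal hide the two causal SNPs from fitting.
#' @param maf_min,r2_max panel filters.
#' @inheritParams scenario_config
#' @return A \code{scenario_config} with \code{type = "panel"}.
#' @export
panel_window_scenario <- function(panel, window_size = 100L,
                                  sigma2_H = 0.006, tau_prime = 0,
                                  causal_offset = NULL,
                                  mask_causal = FALSE, maf_min = 0.01,
                                  r2_max = 0.8, n = 5000L,
                                  n_replicates = 10000L,
                                  models = c("additive", "vc"),
                                  alpha = 1e-4, seed = 1L) {
  stopifnot(inherits(panel, "haplotype_panel"))
  kept <- filter_panel_snps(panel, maf_min, r2_max)
  if (length(kept) < window_size)
    stop("panel too small after MAF/LD filters: ", length(kept),
         " SNPs left for a window of ", window_size)
  win <- kept[seq_len(window_size)]
  if (is.null(causal_offset)) causal_offset <- window_size %/% 2L
  causal <- win[c(causal_offset, causal_offset + 1L)]
  # causal-pair haplotype system from empirical panel frequencies
  key <- paste0(panel$haps[, causal[1L]], panel$haps[, causal[2L]])
  tab <- table(key)
  H2 <- do.call(rbind, lapply(strsplit(names(tab), ""), as.integer))
  sys2 <- haplotype_system(H2, as.numeric(tab) / sum(tab))
  beta <- effect_path(sys2, sigma2_H, tau_prime)
  cfg <- scenario_config(haplotype_system(H2, sys2$pi, beta = beta),
                         n = n, n_replicates = n_replicates,
                         models = models, alpha = alpha,
                         mask = if (mask_causal)
                           match(causal, win) else integer(0),
                         seed = seed)
  cfg$type <- "panel"
  cfg$panel <- panel
  cfg$window_snps <- win
  cfg$causal_snps <- causal
  cfg$hap_key <- key
  cfg
}
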