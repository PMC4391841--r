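# Simulation engine: Hardy-Weinberg sampling from haplotype systems,
# phenotype generation under the haplotype model, nuisance-SNP extension at
# target LD, rare-variant tagging scenarios, and replicate scenario runs.

#' Sample diplotypes from a haplotype system
#'
#' Draws two independent haplotypes per individual from the population
#' frequencies (Hardy-Weinberg random mating).
#'
#' @param system a \code{haplotype_system}.
#' @param n number of individuals.
#' @return An object of class \code{diplotype_sample}: \code{D} (n x k
#'   copy-counts, rows summing to 2) and \code{panel} (the system).
#' @export
sample_diplotypes <- function(system, n) {
  stopifnot(inherits(system, "haplotype_system"))
  k <- system$k
  h1 <- sample.int(k, n, replace = TRUE, prob = system$pi)
  h2 <- sample.int(k, n, replace = TRUE, prob = system$pi)
  D <- matrix(0L, n, k)
  idx1 <- cbind(seq_len(n), h1)
  D[idx1] <- D[idx1] + 1L
  idx2 <- cbind(seq_len(n), h2)
  D[idx2] <- D[idx2] + 1L
  structure(list(D = D, panel = system, n = n), class = "diplotype_sample")
}

#' Simulate a quantitative trait under the haplotype model
#'
#' y = D beta + epsilon with standard normal errors, so the population
#' proportion of variance explained is sigma2_H / (sigma2_H + 1).
#'
#' @param sample a \code{diplotype_sample}.
#' @param system the generating \code{haplotype_system} with \code{beta}
#'   (defaults to the sample's own panel).
#' @return A \code{phenotype_vector} (unstandardized).
#' @export
simulate_phenotype <- function(sample, system = sample$panel) {
  stopifnot(inherits(sample, "diplotype_sample"))
  if (is.null(system$beta)) stop("haplotype effects (beta) are required")
  y <- as.numeric(sample$D %*% system$beta) + stats::rnorm(sample$n)
  phenotype_vector(y)
}

#' Extend a haplotype system with nuisance SNPs at target LD
#'
#' Appends SNPs with zero effect to a causal haplotype system so that every
#' SNP pair involving a nuisance SNP has squared allelic correlation equal
#' to \code{target_r2} (to 1e-6) and nuisance allele frequencies equal to
#' \code{xi_nuisance}. The causal sub-distribution is preserved exactly, so
#' LD among the causal SNPs themselves remains whatever the causal system
#' implies. Solved by penalized least squares over the joint haplotype
#' frequency simplex (softmax parametrization, quasi-Newton, multiple
#' starts); an infeasible target is reported with the worst-violated pair
#' rather than silently approximated.
#'
#' @param system the causal \code{haplotype_system}.
#' @param n_nuisance number of nuisance SNPs to append.
#' @param target_r2 target pairwise r2 (0 gives an exact product-measure
#'   construction).
#' @param xi_nuisance alternate-allele frequencies for the nuisance SNPs
#'   (recycled; default: the mean causal allele frequency).
#' @param tol maximum tolerated |r2 - target| after optimization.
#' @param n_starts number of optimizer starts beyond the product measure.
#' @return An enlarged \code{haplotype_system}; beta (if present) is
#'   extended by zeros on nuisance-only dimensions, so the haplotype
#'   variance is unchanged.
#' @export
extend_with_nuisance <- function(system, n_nuisance, target_r2 = 0,
                                 xi_nuisance = NULL, tol = 1e-6,
                                 n_starts = 8L) {
  stopifnot(inherits(system, "haplotype_system"))
  if (n_nuisance < 1L) return(system)
  if (target_r2 < 0 || target_r2 >= 1) stop("target_r2 must be in [0, 1)")
  if (is.null(xi_nuisance)) xi_nuisance <- mean(allele_frequencies(system))
  xi_n <- rep_len(xi_nuisance, n_nuisance)
  k0 <- system$k; m0 <- system$m
  combos <- as.matrix(expand.grid(rep(list(0:1), n_nuisance)))[,
    seq_len(n_nuisance), drop = FALSE]
  nc <- nrow(combos)
  Hnew <- cbind(system$H[rep(seq_len(k0), each = nc), , drop = FALSE],
                combos[rep(seq_len(nc), times = k0), , drop = FALSE])
  causal_of <- rep(seq_len(k0), each = nc)
  # exact product measure: independence <=> r2 = 0 with every causal SNP
  bern <- apply(combos, 1L, function(a)
    prod(ifelse(a == 1L, xi_n, 1 - xi_n)))
  q_prod <- system$pi[causal_of] * bern[rep(seq_len(nc), times = k0)]
  make_system <- function(q) {
    keep <- q > 1e-14
    haplotype_system(Hnew[keep, , drop = FALSE], q[keep] / sum(q[keep]),
                     beta = if (!is.null(system$beta))
                       system$beta[causal_of[keep]])
  }
  if (target_r2 == 0) return(make_system(q_prod))

  mtot <- m0 + n_nuisance
  pairs <- utils::combn(mtot, 2L)
  pairs <- pairs[, pairs[2L, ] > m0, drop = FALSE]  # nuisance-involving
  objective <- function(theta) {
    q <- exp(theta - max(theta)); q <- q / sum(q)
    marg <- rowsum(q, causal_of)
    marg <- marg[order(as.numeric(rownames(marg))), 1L]
    xi <- as.numeric(crossprod(Hnew, q))
    pen <- sum((marg - system$pi)^2) + sum((xi[-seq_len(m0)] - xi_n)^2)
    r2dev <- apply(pairs, 2L, function(pr) {
      a <- pr[1L]; b <- pr[2L]
      xa <- xi[a]; xb <- xi[b]
      if (xa <= 0 || xa >= 1 || xb <= 0 || xb >= 1) return(1)
      p11 <- sum(q[Hnew[, a] == 1L & Hnew[, b] == 1L])
      d <- p11 - xa * xb
      d^2 / (xa * (1 - xa) * xb * (1 - xb)) - target_r2
    })
    sum(r2dev^2) + 25 * pen
  }
  best <- NULL
  theta0 <- log(pmax(q_prod, 1e-8))
  starts <- c(list(theta0),
              lapply(seq_len(n_starts), function(i)
                theta0 + stats::rnorm(length(theta0), sd = 0.5)))
  for (th in starts) {
    fit <- stats::optim(th, objective, method = "BFGS",
                        control = list(maxit = 2000L, reltol = 1e-16))
    if (is.null(best) || fit$value < best$value) best <- fit
    if (best$value < (tol / 10)^2) break
  }
  q <- exp(best$par - max(best$par)); q <- q / sum(q)
  out <- make_system(q)
  xi <- allele_frequencies(out)
  worst <- 0; worst_pair <- c(NA, NA)
  full_pairs <- utils::combn(out$m, 2L)
  full_pairs <- full_pairs[, full_pairs[2L, ] > m0, drop = FALSE]
  for (j in seq_len(ncol(full_pairs))) {
    pr <- full_pairs[, j]
    dev <- abs(pairwise_ld(out, pr[1L], pr[2L])$r2 - target_r2)
    if (dev > worst) { worst <- dev; worst_pair <- pr }
  }
  if (worst > tol)
    stop(sprintf(paste0("could not reach r2 = %g for SNP pair (%d, %d): ",
                        "residual deviation %.3g; the target may be ",
                        "infeasible at these frequencies"),
                 target_r2, worst_pair[1L], worst_pair[2L], worst))
  out
}

#' Scenario configuration
#'
#' Bundles the generative system, the sample size, the replicate count,
#' masked SNPs, the models to fit and the significance threshold for a
#' simulation experiment.
#'
#' @param system generating \code{haplotype_system} with \code{beta}.
#' @param n individuals per replicate.
#' @param n_replicates number of replicates.
#' @param models character vector among \code{"additive"},
#'   \code{"interaction"}, \code{"genotypic"}, \code{"haplotype_prob"},
#'   \code{"vc"}.
#' @param alpha significance threshold used for empirical power.
#' @param mask integer indices of SNPs hidden from fitting (still part of
#'   the generative model).
#' @param seed master seed; per-replicate streams are spawned from it.
#' @return An object of class \code{scenario_config}.
#' @export
scenario_config <- function(system, n = 5000L, n_replicates = 10000L,
                            models = "additive", alpha = 5e-5,
                            mask = integer(0), seed = 1L) {
  stopifnot(inherits(system, "haplotype_system"))
  if (n_replicates < 1L) stop("n_replicates must be at least 1")
  bad <- setdiff(models, c("additive", "interaction", "genotypic",
                           "haplotype_prob", "vc"))
  if (length(bad)) stop("unknown model(s): ", paste(bad, collapse = ", "))
  structure(list(system = system, n = as.integer(n),
                 n_replicates = as.integer(n_replicates), models = models,
                 alpha = alpha, mask = as.integer(mask),
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' Rare-variant tagging scenario
#'
#' A single rare causal SNP (frequency f) resides exclusively on the 1-1
#' haplotype of two common SNPs in mutual linkage equilibrium, so the
#' tagging haplotype has D' = 1 and r2 = \code{r2_hap} with the rare
#' allele. The common-pair 1-1 haplotype frequency is h = f / (r2 (1 - f)
#' + f) and each common SNP has allele frequency sqrt(h); at r2 = 1 this
#' collapses to h = f. The rare effect is sized so 2 f (1 - f) beta^2 =
#' \code{variance_explained}. By default the rare SNP is masked (only the
#' common SNPs are "genotyped"); unmask it to study the directly-typed
#' variant.
#'
#' @param variance_explained phenotypic variance attributed to the rare SNP
#'   (the trait has residual variance 1).
#' @param f_rare rare allele frequency (must be <= 0.01; default (1/24)^2,
#'   which at r2_hap = 1 puts each common-SNP r2 with the rare SNP at
#'   1/25 = 0.04).
#' @param r2_hap r2 between the tagging haplotype and the rare allele.
#' @param n_common_extra additional common nuisance SNPs in linkage
#'   equilibrium (frequency \code{xi_extra}).
#' @param xi_extra allele frequency of the extra nuisance SNPs.
#' @param mask_rare hide the rare SNP from fitting (default TRUE).
#' @inheritParams scenario_config
#' @return A \code{scenario_config}; the generative system spans the two
#'   common SNPs, the rare SNP, and any nuisance SNPs (in that order).
#' @export
rare_tagging_scenario <- function(variance_explained, f_rare = (1 / 24)^2,
                                  r2_hap = 1, n_common_extra = 0L,
                                  xi_extra = 0.2, mask_rare = TRUE,
                                  n = 5000L, n_replicates = 10000L,
                                  models = c("additive", "haplotype_prob"),
                                  alpha = 5e-5, seed = 1L) {
  if (f_rare > 0.01) stop("f_rare must be at most 0.01 (a rare variant)")
  if (r2_hap <= 0 || r2_hap > 1) stop("r2_hap must be in (0, 1]")
  f <- f_rare
  h <- f / (r2_hap * (1 - f) + f)
  p <- sqrt(h)
  if (h >= 1) stop("inconsistent (f_rare, r2_hap) geometry")
  H <- rbind(c(0, 0, 0), c(0, 1, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, 1))
  pi <- c((1 - p)^2, p * (1 - p), p * (1 - p), h - f, f)
  keep <- pi > 1e-14
  H <- H[keep, , drop = FALSE]; pi <- pi[keep]
  beta_r <- sqrt(variance_explained / (2 * f * (1 - f)))
  beta <- H[, 3L] * beta_r
  sys <- haplotype_system(H, pi, beta = beta)
  if (n_common_extra > 0L)
    sys <- extend_with_nuisance(sys, n_common_extra, target_r2 = 0,
                                xi_nuisance = xi_extra)
  scenario_config(sys, n = n, n_replicates = n_replicates, models = models,
                  alpha = alpha, mask = if (mask_rare) 3L else integer(0),
                  seed = seed)
}

# One replicate draw: observed genotypes (masked SNPs removed) and the raw
# trait. Haplotype-system scenarios draw diplotypes from the system;
# panel scenarios draw random pairs of panel haplotypes over the window,
# with the trait generated from the causal pair's haplotype effects.
replicate_draw <- function(config) {
  if (identical(config$type, "panel")) {
    nh <- config$panel$n_haplotypes
    h1 <- sample.int(nh, config$n, replace = TRUE)
    h2 <- sample.int(nh, config$n, replace = TRUE)
    Hw <- config$panel$haps[, config$window_snps, drop = FALSE]
    Gm <- Hw[h1, , drop = FALSE] + Hw[h2, , drop = FALSE]
    sysmap <- match(config$hap_key, rownames(config$system$H))
    b <- config$system$beta
    y <- b[sysmap[h1]] + b[sysmap[h2]] + stats::rnorm(config$n)
    G <- genotype_dataset(Gm,
      config$panel$snp_meta[config$window_snps, , drop = FALSE])
  } else {
    smp <- sample_diplotypes(config$system, config$n)
    y <- simulate_phenotype(smp)$y
    G <- genotypes_from_diplotypes(smp)
  }
  if (length(config$mask))
    G <- subset_snps(G, setdiff(seq_len(G$m), config$mask))
  list(G = G, y = phenotype_vector(y))
}

# Fit one model on one replicate; returns c(raw, adj, p).
fit_one_model <- function(model, G, y) {
  if (model == "vc") {
    xi <- colMeans(G$G) / 2
    poly <- xi > 0 & xi < 1
    if (!any(poly)) return(c(NA, NA, NA))
    kin <- grm(subset_snps(G, which(poly)))
    he <- fit_vc_he(kin, y)
    pv <- vc_pvalue(kin, y)$p
    c(he$sigma2_g, he$sigma2_g, pv)
  } else {
    fit <- fit_linear(build_design(G, model), y)
    c(fit$sigma2_raw, fit$sigma2_adj, fit$p_value)
  }
}

#' Run a simulation scenario
#'
#' For each replicate: draw diplotypes, generate and standardize the trait,
#' fit each requested model on the observed (unmasked) genotypes, and
#' record the raw and adjusted genetic-variance estimates and the p-value.
#' Results are aggregated into per-model means, Monte-Carlo standard
#' errors, and empirical power at the configured alpha. Fully reproducible
#' from the master seed; a model failure within a replicate is recorded
#' (NA) rather than fatal.
#'
#' @param config a \code{scenario_config}.
#' @return An object of class \code{scenario_result}: a data.frame
#'   \code{summary} (model, mean_raw, mean_adj, se_raw, se_adj, power,
#'   n_ok) plus the per-replicate estimate arrays.
#' @export
run_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, config$n_replicates)
  models <- config$models
  raw <- adj <- pv <- matrix(NA_real_, config$n_replicates, length(models),
                             dimnames = list(NULL, models))
  for (r in seq_len(config$n_replicates)) {
    set.seed(rep_seeds[r])
    dr <- replicate_draw(config)
    ys <- standardize_phenotype(dr$y)
    for (j in seq_along(models)) {
      est <- tryCatch(fit_one_model(models[j], dr$G, ys),
                      error = function(e) c(NA, NA, NA))
      raw[r, j] <- est[1L]; adj[r, j] <- est[2L]; pv[r, j] <- est[3L]
    }
  }
  summarize_scenario(config, raw, adj, pv)
}

summarize_scenario <- function(config, raw, adj, pv) {
  models <- colnames(raw)
  mc_se <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_
  }
  summ <- data.frame(
    model = models,
    mean_raw = colMeans(raw, na.rm = TRUE),
    mean_adj = colMeans(adj, na.rm = TRUE),
    se_raw = apply(raw, 2L, mc_se),
    se_adj = apply(adj, 2L, mc_se),
    power = colMeans(pv < config$alpha, na.rm = TRUE),
    n_ok = colSums(!is.na(pv)),
    row.names = NULL)
  structure(list(summary = summ, raw = raw, adj = adj, p = pv,
                 alpha = config$alpha,
                 n_replicates = config$n_replicates),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("Scenario result over %d replicates (alpha = %g):\n",
              x$n_replicates, x$alpha))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a scenario result as TSV
#'
#' @param result a \code{scenario_result}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_scenario_result <- function(result, path) {
  stopifnot(inherits(result, "scenario_result"))
  utils::write.table(result$summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
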