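# Variance-component model: genomic relationship matrix, Haseman-Elston
# regression of squared trait differences, and testing of the quadratic
# form Q = y' Gamma y as a weighted sum of chi-square(1) variables.

#' Genomic relationship matrix from genotypes
#'
#' Normalizes each SNP to mean 0, variance 1 using sample allele
#' frequencies, z_il = (g_il - 2 xi_l) / sqrt(2 xi_l (1 - xi_l)), and forms
#' Gamma = Z Z' / m (the default scaling, on which the Haseman-Elston slope
#' converts to genetic variance as -v1/2) or the raw Z Z'.
#'
#' @param data a \code{genotype_dataset} without missing or monomorphic SNPs.
#' @param scaling \code{"mean"} for Z Z'/m (default) or \code{"raw"}.
#' @return An object of class \code{kinship_matrix} with elements
#'   \code{Gamma}, \code{Z}, \code{m_snps}, \code{scaling}.
#' @export
grm <- function(data, scaling = c("mean", "raw")) {
  stopifnot(inherits(data, "genotype_dataset"))
  scaling <- match.arg(scaling)
  G <- data$G
  if (anyNA(G)) stop("impute missing genotypes before computing the GRM")
  xi <- colMeans(G) / 2
  mono <- xi <= 0 | xi >= 1
  if (any(mono))
    stop("monomorphic SNP(s) in GRM: ",
         paste(data$snp_meta$id[mono], collapse = ", "))
  Z <- sweep(sweep(G, 2L, 2 * xi), 2L, sqrt(2 * xi * (1 - xi)), "/")
  m <- ncol(Z)
  Gamma <- tcrossprod(Z)
  if (scaling == "mean") Gamma <- Gamma / m
  structure(list(Gamma = Gamma, Z = Z, m_snps = m, scaling = scaling),
            class = "kinship_matrix")
}

#' Haseman-Elston estimate of regional genetic variance
#'
#' Regresses the squared pairwise trait differences (y_i - y_j)^2 over all
#' i < j pairs on the corresponding kinship entries Gamma_ij. With the
#' Gamma = Z Z'/m scaling the slope v1 relates to genetic variance as
#' sigma2_g = -v1 / 2; with raw Z Z' the same relation holds per-SNP and is
#' rescaled by m.
#'
#' @param kin a \code{kinship_matrix}.
#' @param y a standardized \code{phenotype_vector}.
#' @return List with \code{sigma2_g}, \code{v0}, \code{v1}.
#' @export
fit_vc_he <- function(kin, y) {
  stopifnot(inherits(kin, "kinship_matrix"))
  yv <- if (inherits(y, "phenotype_vector")) y$y else as.numeric(y)
  n <- length(yv)
  if (n < 3) stop("Haseman-Elston regression needs at least 3 individuals")
  ut <- upper.tri(kin$Gamma)
  g <- kin$Gamma[ut]
  dy2 <- (outer(yv, yv, "-")^2)[ut]
  vg <- stats::var(g)
  if (vg == 0) stop("kinship entries are constant over pairs")
  v1 <- stats::cov(dy2, g) / vg
  v0 <- mean(dy2) - v1 * mean(g)
  s2 <- -v1 / 2
  if (kin$scaling == "raw") s2 <- s2 * kin$m_snps
  list(sigma2_g = s2, v0 = v0, v1 = v1)
}

#' Tail probability of a weighted sum of chi-square(1) variables
#'
#' P(sum_i lambda_i chi2_1 > q) for non-negative weights, computed exactly
#' by the Ruben-Farebrother mixture-series representation (the weighted sum
#' is written as a proper mixture of central chi-square distributions whose
#' coefficients are accumulated until the residual mixture mass is below
#' 1e-12), with a Kuonen saddlepoint approximation as fallback when the
#' series is truncated before converging.
#'
#' @param q observed value of the quadratic form.
#' @param lambda eigenvalue weights (non-negative; zeros ignored).
#' @param method \code{"series"} (default) or \code{"saddlepoint"}.
#' @return List with \code{p} and \code{method} actually used.
#' @export
wchisq_pvalue <- function(q, lambda, method = c("series", "saddlepoint")) {
  method <- match.arg(method)
  lambda <- lambda[lambda != 0]
  if (!length(lambda)) stop("all weights are zero")
  if (any(lambda < 0)) stop("weights must be non-negative")
  if (q <= 0) return(list(p = 1, method = "exact"))
  if (method == "series") {
    p <- ruben_tail(q, lambda)
    if (is.finite(p))
      return(list(p = min(max(p, .Machine$double.xmin), 1),
                  method = "series"))
    method <- "saddlepoint"
  }
  list(p = saddlepoint_tail(q, lambda), method = "saddlepoint")
}

# Ruben (1962) / Moschopoulos mixture series for P(Q > q), lambda > 0:
# with theta1 = min(2 lambda), Q is a proper mixture over k of
# Gamma(rho + k, theta1) with non-negative coefficients C delta_k.
# Returns NA when the mixture mass 1 - 1e-12 is not reached in max_terms.
ruben_tail <- function(q, lambda, max_terms = 20000L, tol = 1e-12) {
  theta <- 2 * lambda          # Gamma scales, shape 1/2 each
  th1 <- min(theta)
  rho <- length(lambda) / 2
  lC <- 0.5 * sum(log(th1 / theta))
  g1 <- 1 - th1 / theta        # in [0, 1)
  gam <- numeric(max_terms)    # gamma_k = sum_i (1/2) g1^k / k
  pw <- rep(1, length(g1))
  delta <- numeric(max_terms + 1L)
  delta[1L] <- 1
  mass <- exp(lC)              # C * delta_0
  tail_p <- mass * stats::pgamma(q, shape = rho, scale = th1,
                                 lower.tail = FALSE)
  for (k in seq_len(max_terms)) {
    pw <- pw * g1
    gam[k] <- 0.5 * sum(pw) / k
    j <- seq_len(k)
    delta[k + 1L] <- sum(j * gam[j] * delta[k + 1L - j]) / k
    term_mass <- exp(lC) * delta[k + 1L]
    mass <- mass + term_mass
    tail_p <- tail_p + term_mass *
      stats::pgamma(q, shape = rho + k, scale = th1, lower.tail = FALSE)
    if (1 - mass < tol) return(tail_p + (1 - mass))
  }
  NA_real_
}

# Kuonen (1999) saddlepoint tail approximation.
saddlepoint_tail <- function(q, lambda) {
  if (q <= 0) return(1)
  mu <- sum(lambda)
  if (abs(q - mu) < 1e-12 * max(1, abs(mu))) return(0.5)
  K <- function(s) -0.5 * sum(log1p(-2 * s * lambda))
  K1 <- function(s) sum(lambda / (1 - 2 * s * lambda))
  K2 <- function(s) 2 * sum(lambda^2 / (1 - 2 * s * lambda)^2)
  lam_max <- max(lambda); lam_min <- min(lambda)
  upper <- if (lam_max > 0) 1 / (2 * lam_max) - 1e-10 else 1e6
  lower <- if (lam_min < 0) 1 / (2 * lam_min) + 1e-10 else -1e6
  s <- tryCatch(stats::uniroot(function(s) K1(s) - q, c(lower, upper),
                               tol = 1e-12)$root,
                error = function(e) NA_real_)
  if (!is.finite(s)) return(if (q > mu) 0 else 1)
  w <- sign(s) * sqrt(max(2 * (s * q - K(s)), 0))
  v <- s * sqrt(K2(s))
  if (abs(w) < 1e-8) return(0.5)
  p <- stats::pnorm(w + log(v / w) / w, lower.tail = FALSE)
  min(max(p, .Machine$double.xmin), 1)
}

#' Quadratic-form p-value for the variance-component test
#'
#' Tests Q = y' Gamma y against its null distribution, a weighted sum of
#' chi-square(1) variables with weights equal to the eigenvalues of Gamma
#' (for Gamma = Z Z'/m these are the nonzero eigenvalues of Z'Z/m, which is
#' how they are computed when Z is available). The tail probability is
#' evaluated exactly via [wchisq_pvalue()].
#'
#' @param kin a \code{kinship_matrix}.
#' @param y a standardized \code{phenotype_vector}.
#' @return List with \code{p}, \code{Q}, \code{lambda}, \code{method}.
#' @export
vc_pvalue <- function(kin, y) {
  stopifnot(inherits(kin, "kinship_matrix"))
  yv <- if (inherits(y, "phenotype_vector")) y$y else as.numeric(y)
  Zy <- crossprod(kin$Z, yv)
  Q <- sum(Zy^2) / if (kin$scaling == "mean") kin$m_snps else 1
  lambda <- vc_weights(kin)
  res <- wchisq_pvalue(Q, lambda)
  list(p = res$p, Q = Q, lambda = lambda, method = res$method)
}

# nonzero eigenvalue weights of Gamma via the small m x m cross-product
vc_weights <- function(kin) {
  ZtZ <- crossprod(kin$Z)
  if (kin$scaling == "mean") ZtZ <- ZtZ / kin$m_snps
  ev <- eigen(ZtZ, symmetric = TRUE, only.values = TRUE)$values
  ev[ev > 1e-12 * max(ev)]
}

#' Analytic power of the variance-component quadratic-form test
#'
#' Under the variance-component alternative Var(y) = sigma2_g Gamma +
#' sigma2_e I, the quadratic form Q = y' Gamma y is again a weighted sum of
#' chi-square(1) variables with weights lambda_i (sigma2_g lambda_i +
#' sigma2_e). Power is the alternative tail probability beyond the null
#' critical value, both evaluated by the same inversion as the test itself.
#'
#' @param lambda eigenvalue spectrum of Gamma under the null.
#' @param sigma2_g genetic variance under the alternative.
#' @param alpha significance level.
#' @param sigma2_e residual variance (default 1 - sigma2_g, a standardized
#'   trait).
#' @return Power in [0, 1].
#' @export
analytic_power_vc <- function(lambda, sigma2_g, alpha,
                              sigma2_e = 1 - sigma2_g) {
  if (!length(lambda) || any(!is.finite(lambda)))
    stop("invalid eigenvalue spectrum")
  lambda <- lambda[lambda > 0]
  mu <- sum(lambda)
  f <- function(lq) wchisq_pvalue(exp(lq), lambda)$p - alpha
  lq <- stats::uniroot(f, c(log(mu) - 20, log(mu) + 20), tol = 1e-12)$root
  q_crit <- exp(lq)
  alt <- lambda * (sigma2_g * lambda + sigma2_e)
  wchisq_pvalue(q_crit, alt)$p
}
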