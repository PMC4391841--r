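# Non-additivity of haplotype effects and analytic power.
#
# tau is the fraction of the haplotype-generated variance missed by the
# additive (per-allele) design; tau_max its maximum over effect vectors at
# the system's frequencies; tau' = tau / tau_max the normalized measure.
#
# Both sigma2_H = beta' A beta and the additively captured variance
# sigma2_G = beta' S beta are quadratic forms in beta, so tau is a
# generalized Rayleigh quotient and tau_max has a closed-form solution via
# the generalized eigenproblem of S with respect to A restricted to
# range(A) -- no numerical search is needed.

# Whitened operator: columns B span range(A) with beta = B w giving
# sigma2_H = |w|^2; M is the captured-variance form in w coordinates.
# With identifiable = TRUE, B is further restricted to effect vectors whose
# trait signal D beta is a function of the unphased genotype (equal values
# on every pair of diplotypes sharing a genotype class), i.e. effects with
# no pure-phase component -- the architectures whose variance a genotype-
# based design can capture in full.
nonadd_operators <- function(system, identifiable = FALSE, tol = 1e-12) {
  A <- hap_variance_matrix(system)
  S <- captured_variance_operator(system, "additive")$S
  e <- eigen(A, symmetric = TRUE)
  pos <- e$values > tol * max(e$values)
  B <- e$vectors[, pos, drop = FALSE] %*%
    diag(1 / sqrt(e$values[pos]), sum(pos))
  if (identifiable) {
    C <- phase_constraints(system)
    if (!is.null(C)) {
      CB <- C %*% B
      ns <- svd(CB, nu = 0, nv = ncol(CB))
      d_full <- c(ns$d, rep(0, ncol(CB) - length(ns$d)))
      null_cols <- d_full < 1e-10 * max(ns$d, 1)
      if (!any(null_cols))
        stop("no phase-identifiable polymorphic direction exists")
      B <- B %*% ns$v[, null_cols, drop = FALSE]
    }
  }
  M <- crossprod(B, S %*% B)
  M <- (M + t(M)) / 2
  list(A = A, S = S, B = B, M = M)
}

# rows are diplotype count-vector differences within a genotype class;
# C beta = 0 <=> D beta carries no phase information
phase_constraints <- function(system) {
  en <- enumerate_diplotypes(system)
  cls <- apply(en$G, 1L, paste0, collapse = ",")
  rows <- list()
  for (cc in unique(cls)) {
    at <- which(cls == cc)
    if (length(at) > 1L)
      for (j in at[-1L])
        rows[[length(rows) + 1L]] <- en$counts[j, ] - en$counts[at[1L], ]
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' Non-additivity profile of a haplotype system
#'
#' @param system a \code{haplotype_system} with \code{beta} and positive
#'   haplotype variance.
#' @param identifiable normalize by the maximum over phase-identifiable
#'   effect vectors instead of over all effect vectors (default FALSE).
#' @return An object of class \code{nonadd_profile}: \code{tau},
#'   \code{tau_max}, \code{tau_prime}, \code{sigma2_H}, \code{sigma2_G}.
#' @export
nonadditivity <- function(system, identifiable = FALSE) {
  stopifnot(inherits(system, "haplotype_system"))
  s2H <- haplotype_variance(system)
  if (s2H <= 0) stop("tau is undefined when the haplotype variance is 0")
  s2G <- population_captured_variance(system, "additive")
  tm <- tau_max(system, identifiable = identifiable)
  tau <- max(0, min(1, (s2H - s2G) / s2H))
  structure(list(tau = tau, tau_max = tm$tau_max,
                 tau_prime = if (tm$tau_max > 1e-9) tau / tm$tau_max
                             else 0,
                 sigma2_H = s2H, sigma2_G = s2G),
            class = "nonadd_profile")
}

#' @export
print.nonadd_profile <- function(x, ...) {
  cat(sprintf(
    "Non-additivity: tau = %.6g, tau_max = %.6g, tau' = %.6g (sigma2_H = %.6g)\n",
    x$tau, x$tau_max, x$tau_prime, x$sigma2_H))
  invisible(x)
}

#' Maximal non-additivity at given haplotype frequencies
#'
#' Maximizes tau over effect vectors beta (tau is invariant to the overall
#' scale of beta, so the constraint sigma2_H = target only fixes the length
#' of the returned vector). Solved exactly as 1 minus the smallest
#' eigenvalue of the whitened captured-variance operator.
#'
#' @param system a \code{haplotype_system} (beta ignored).
#' @param sigma2_H haplotype variance at which the maximizing effect vector
#'   is scaled (default 1; the maximum itself is scale-free).
#' @param identifiable restrict the maximization to phase-identifiable
#'   effect vectors, i.e. those whose trait signal is a function of the
#'   unphased genotype (default FALSE: maximize over all effect vectors).
#'   The unconstrained maximum places part of the effect variance in phase
#'   contrasts that no genotype-based design -- not even the saturated
#'   genotypic one -- can fully capture; note that for haplotype-linear
#'   traits over 2 SNPs the phase-identifiable subspace coincides with the
#'   additive span, so the constrained maximum is 0 there.
#' @return List with \code{tau_max} and the maximizing \code{beta_star}.
#' @export
tau_max <- function(system, sigma2_H = 1, identifiable = FALSE) {
  stopifnot(inherits(system, "haplotype_system"))
  op <- nonadd_operators(system, identifiable = identifiable)
  if (ncol(op$B) == 0) stop("degenerate system: no polymorphic direction")
  e <- eigen(op$M, symmetric = TRUE)
  r <- ncol(op$M)
  w <- e$vectors[, r]
  beta_star <- as.numeric(op$B %*% w) * sqrt(sigma2_H)
  list(tau_max = max(0, min(1, 1 - e$values[r])), beta_star = beta_star)
}

#' Effect vector with prescribed variance and non-additivity
#'
#' Constructs beta with haplotype_variance(beta) = sigma2_H (to 1e-10) and
#' tau_prime = target (to 1e-6), by interpolating between a strictly
#' additive effect vector and the maximally non-additive one (both
#' normalized to unit haplotype variance), rescaling, and solving the
#' interpolation weight by root bisection on the recomputed tau'.
#'
#' @param system a \code{haplotype_system} (beta ignored).
#' @param sigma2_H target haplotype variance.
#' @param tau_prime_target requested tau' in [0, 1].
#' @param identifiable passed to [tau_max()].
#' @return Numeric effect vector beta of length k.
#' @export
effect_path <- function(system, sigma2_H, tau_prime_target,
                        identifiable = FALSE) {
  stopifnot(inherits(system, "haplotype_system"))
  if (tau_prime_target < 0 || tau_prime_target > 1)
    stop("tau_prime_target must be in [0, 1]")
  tm <- tau_max(system, identifiable = identifiable)
  if (tm$tau_max <= 1e-9) {
    if (tau_prime_target > 0)
      stop("tau_max = 0 at these frequencies: the additive span is ",
           "complete and no tau' > 0 is attainable")
    return(additive_endpoint(system, sigma2_H))
  }
  A <- hap_variance_matrix(system)
  b1 <- tm$beta_star / sqrt(drop(crossprod(tm$beta_star, A %*% tm$beta_star)))
  b0 <- additive_endpoint(system, 1, align_to = b1, A = A)
  if (drop(crossprod(b0, A %*% b1)) < 0) b0 <- -b0
  scale_to <- function(b) b * sqrt(sigma2_H / drop(crossprod(b, A %*% b)))
  tp_at <- function(t) {
    b <- scale_to((1 - t) * b0 + t * b1)
    sys_b <- haplotype_system(system$H, system$pi, beta = b)
    s2H <- haplotype_variance(sys_b)
    s2G <- population_captured_variance(sys_b, "additive")
    ((s2H - s2G) / s2H) / tm$tau_max
  }
  if (tau_prime_target <= 0) return(scale_to(b0))
  if (tau_prime_target >= 1) return(scale_to(b1))
  root <- stats::uniroot(function(t) tp_at(t) - tau_prime_target,
                         c(0, 1), tol = 1e-12)$root
  scale_to((1 - root) * b0 + root * b1)
}

# A strictly additive effect vector (beta = H alpha) with unit haplotype
# variance, preferring the A-projection of a reference direction when it
# is non-degenerate.
additive_endpoint <- function(system, sigma2_H, align_to = NULL, A = NULL) {
  if (is.null(A)) A <- hap_variance_matrix(system)
  H <- system$H
  b <- NULL
  if (!is.null(align_to)) {
    HtAH <- crossprod(H, A %*% H)
    alpha <- pseudo_inverse(HtAH) %*% crossprod(H, A %*% align_to)
    cand <- as.numeric(H %*% alpha)
    if (drop(crossprod(cand, A %*% cand)) > 1e-10) b <- cand
  }
  if (is.null(b)) {
    for (j in seq_len(ncol(H))) {
      cand <- as.numeric(H[, j])
      if (drop(crossprod(cand, A %*% cand)) > 1e-10) { b <- cand; break }
    }
  }
  if (is.null(b)) stop("no polymorphic SNP to carry an additive effect")
  b * sqrt(sigma2_H / drop(crossprod(b, A %*% b)))
}

#' Analytic power of the joint F-test
#'
#' Power of the overall F-test of a regression design with df1 genetic
#' degrees of freedom at population variance proportion R^2, using the
#' non-central F distribution with non-centrality n R^2 / (1 - R^2).
#'
#' @param n sample size.
#' @param r2 population proportion of phenotypic variance explained.
#' @param df1 numerator degrees of freedom (design rank).
#' @param alpha significance level.
#' @param df2 denominator degrees of freedom (default n - df1 - 1).
#' @return Power in [0, 1]; equals alpha at r2 = 0.
#' @export
analytic_power_f <- function(n, r2, df1, alpha, df2 = n - df1 - 1) {
  if (df2 <= 0) stop("df2 must be positive")
  if (r2 < 0 || r2 >= 1) stop("r2 must lie in [0, 1)")
  ncp <- n * r2 / (1 - r2)
  fcrit <- stats::qf(1 - alpha, df1, df2)
  stats::pf(fcrit, df1, df2, ncp = ncp, lower.tail = FALSE)
}

#' Tabulate analytic F-test power over a grid
#'
#' @param n,r2,df1,alpha vectors; the full grid of combinations is
#'   evaluated.
#' @return data.frame with columns n, r2, df1, alpha, power.
#' @export
power_table <- function(n, r2, df1, alpha = 5e-5) {
  grid <- expand.grid(n = n, r2 = r2, df1 = df1, alpha = alpha,
                      KEEP.OUT.ATTRS = FALSE)
  grid$power <- mapply(analytic_power_f, n = grid$n, r2 = grid$r2,
                       df1 = grid$df1, alpha = grid$alpha)
  grid
}
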