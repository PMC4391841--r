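# Least-squares fitting of association designs with joint F-tests.

#' Fit a linear association model
#'
#' Regresses the (centered) phenotype on the centered design through a
#' rank-revealing pivoted QR decomposition, reports the joint F-test of all
#' genetic coefficients, and the fitted genetic variance on the raw and
#' small-sample-adjusted scales.
#'
#' The raw estimate is the explained sum of squares divided by n (equal to
#' R^2 when the phenotype is standardized); the adjusted estimate subtracts
#' the null expectation (1 - R^2) df1 / (n - df1 - 1) and may be negative.
#' The adjustment makes the estimator unbiased at the null, mirroring the
#' classical adjusted R^2.
#'
#' @param design a \code{design_matrix} (or plain matrix).
#' @param y a \code{phenotype_vector} (or numeric vector).
#' @param qr_tol relative tolerance of the pivoted QR used to determine the
#'   design rank; collinear columns beyond the rank are dropped and counted.
#' @return An object of class \code{model_fit}: coefficients (NA for dropped
#'   columns), \code{sigma2_raw}, \code{sigma2_adj}, \code{r2_raw},
#'   \code{r2_adj}, \code{f_stat}, \code{df1}, \code{df2}, \code{p_value},
#'   \code{n_dropped}, and a per-column coefficient table \code{coef_table}
#'   (estimate, se, t, p).
#' @export
fit_linear <- function(design, y, qr_tol = 1e-8) {
  X <- if (inherits(design, "design_matrix")) design$X else as.matrix(design)
  kind <- if (inherits(design, "design_matrix")) design$design_kind else "custom"
  yv <- if (inherits(y, "phenotype_vector")) y$y else as.numeric(y)
  n <- length(yv)
  if (nrow(X) != n) stop("design and phenotype dimensions differ")
  tss <- sum((yv - mean(yv))^2)
  if (tss == 0) stop("phenotype has zero variance")
  Xc <- sweep(X, 2L, colMeans(X))
  yc <- yv - mean(yv)
  qrx <- qr(Xc, tol = qr_tol)
  r <- qrx$rank
  if (r == 0L) stop("design has rank 0 after centering")
  df1 <- r
  df2 <- n - df1 - 1L
  if (df2 <= 0L) stop("not enough samples for the design rank")
  fitted <- qr.fitted(qrx, yc)
  ess <- min(sum(fitted^2), tss)
  r2 <- ess / tss
  f_stat <- if (r2 < 1) (r2 / df1) / ((1 - r2) / df2) else Inf
  p_value <- max(stats::pf(f_stat, df1, df2, lower.tail = FALSE),
                 .Machine$double.xmin)
  r2_adj <- r2 - (1 - r2) * df1 / df2
  # coefficients for retained columns; dropped (collinear) columns are NA
  coefs <- qr.coef(qrx, yc)
  kept <- !is.na(coefs)
  sigma2_res <- sum((yc - fitted)^2) / df2
  R <- qr.R(qrx)[seq_len(r), seq_len(r), drop = FALSE]
  XtXinv_diag <- rep(NA_real_, ncol(X))
  Rinv <- backsolve(R, diag(r))
  XtXinv_diag[qrx$pivot[seq_len(r)]] <- rowSums(Rinv^2)
  se <- sqrt(sigma2_res * XtXinv_diag)
  tval <- coefs / se
  coef_table <- data.frame(
    term = colnames(X) %||% paste0("x", seq_len(ncol(X))),
    beta = as.numeric(coefs), se = se, t = as.numeric(tval),
    p = 2 * stats::pt(abs(tval), df2, lower.tail = FALSE),
    stringsAsFactors = FALSE)
  structure(list(design_kind = kind, n = n,
                 B_hat = coefs,
                 sigma2_raw = ess / n,
                 sigma2_adj = ess / n - (tss - ess) / n * df1 / df2,
                 r2_raw = r2, r2_adj = r2_adj,
                 f_stat = f_stat, df1 = df1, df2 = df2, p_value = p_value,
                 n_dropped = sum(!kept), coef_table = coef_table),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf(
    "Model fit (%s): n = %d, df1 = %d, F = %.4g, p = %.4g\n",
    x$design_kind, x$n, x$df1, x$f_stat, x$p_value))
  cat(sprintf("  R2 raw = %.6g, adjusted = %.6g (%d collinear columns dropped)\n",
              x$r2_raw, x$r2_adj, x$n_dropped))
  invisible(x)
}

#' Write a model fit as TSV
#'
#' Writes the per-SNP coefficient table with model-level statistics in
#' commented header lines (F, df1, df2, p, r2_raw, r2_adj).
#'
#' @param fit a \code{model_fit}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_model_fit <- function(fit, path) {
  stopifnot(inherits(fit, "model_fit"))
  hdr <- sprintf("# model=%s F=%.10g df1=%d df2=%d p=%.10g r2_raw=%.10g r2_adj=%.10g",
                 fit$design_kind, fit$f_stat, fit$df1, fit$df2, fit$p_value,
                 fit$r2_raw, fit$r2_adj)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  suppressWarnings(utils::write.table(fit$coef_table, con, sep = "\t",
                                      quote = FALSE, row.names = FALSE))
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
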