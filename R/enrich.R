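# Enrichment of candidate loci among window results: ROC/AUC with a
# nonparametric (Mann-Whitney) p-value, and threshold-based enrichment
# odds ratios.

#' ROC AUC of window p-values against candidate labels
#'
#' Smaller p-values rank as more positive; ties are handled by midranks.
#' The AUC p-value uses the Mann-Whitney normal approximation with tie
#' correction, one-sided for enrichment (AUC > 0.5).
#'
#' @param p_values window p-values.
#' @param positive logical labels (TRUE = window encompasses a candidate).
#' @return List with \code{auc}, \code{auc_p}, \code{n_pos}, \code{n_neg}.
#' @export
roc_auc <- function(p_values, positive) {
  positive <- as.logical(positive)
  ok <- !is.na(p_values) & !is.na(positive)
  p_values <- p_values[ok]; positive <- positive[ok]
  n1 <- sum(positive); n2 <- sum(!positive)
  if (n1 == 0L || n2 == 0L)
    stop("need at least one positive and one negative window")
  r <- rank(p_values)                  # midranks, ascending (small = good)
  U <- n1 * n2 + n1 * (n1 + 1) / 2 - sum(r[positive])
  auc <- U / (n1 * n2)
  N <- n1 + n2
  ties <- table(p_values)
  tie_corr <- sum(ties^3 - ties) / (N * (N - 1))
  varU <- n1 * n2 / 12 * ((N + 1) - tie_corr)
  z <- if (varU > 0) (U - n1 * n2 / 2) / sqrt(varU) else 0
  list(auc = auc, auc_p = stats::pnorm(z, lower.tail = FALSE),
       n_pos = n1, n_neg = n2)
}

#' ROC curve points for external plotting
#'
#' One row per distinct p-value threshold: the true- and false-positive
#' rates of calling windows with p-values at or below it positive.
#'
#' @inheritParams roc_auc
#' @return data.frame with columns threshold, tpr, fpr.
#' @export
roc_points <- function(p_values, positive) {
  positive <- as.logical(positive)
  thr <- sort(unique(p_values))
  data.frame(threshold = thr,
             tpr = vapply(thr, function(t)
               mean(p_values[positive] <= t), numeric(1)),
             fpr = vapply(thr, function(t)
               mean(p_values[!positive] <= t), numeric(1)))
}

# brute-force AUC by exhaustive pair counting (oracle for roc_auc)
auc_by_pairs <- function(p_values, positive) {
  pp <- p_values[positive]; pn <- p_values[!positive]
  cmp <- outer(pp, pn, function(a, b) (a < b) + 0.5 * (a == b))
  mean(cmp)
}

#' Threshold-based enrichment odds ratio
#'
#' Cross-tabulates {p < threshold} against {window encompasses a
#' candidate}: counts (a, b, c, d) = (significant positive, significant
#' negative, non-significant positive, non-significant negative). The
#' odds ratio is the cross-product a d / (b c), its CI the Woolf log-OR
#' normal interval, and the p-value Fisher's exact test. When any cell is
#' zero the Haldane-Anscombe +0.5 correction is applied to the OR and CI
#' (flagged in the result).
#'
#' @param p_values window p-values.
#' @param positive logical candidate labels.
#' @param threshold significance threshold in (0, 1).
#' @return An object of class \code{enrichment_result} with fields
#'   \code{auc}-free: \code{threshold}, \code{counts} (a, b, c, d),
#'   \code{odds_ratio}, \code{or_ci_low}, \code{or_ci_high}, \code{or_p},
#'   \code{haldane}.
#' @export
enrichment_or <- function(p_values, positive, threshold = 0.01) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  positive <- as.logical(positive)
  ok <- !is.na(p_values) & !is.na(positive)
  p_values <- p_values[ok]; positive <- positive[ok]
  sig <- p_values < threshold
  a <- sum(sig & positive); b <- sum(sig & !positive)
  cc <- sum(!sig & positive); d <- sum(!sig & !positive)
  haldane <- any(c(a, b, cc, d) == 0)
  h <- if (haldane) 0.5 else 0
  or <- ((a + h) * (d + h)) / ((b + h) * (cc + h))
  se_log <- sqrt(1 / (a + h) + 1 / (b + h) + 1 / (cc + h) + 1 / (d + h))
  ci <- exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se_log)
  fp <- stats::fisher.test(matrix(c(a, b, cc, d), 2L, byrow = TRUE))$p.value
  structure(list(threshold = threshold,
                 counts = c(a = a, b = b, c = cc, d = d),
                 odds_ratio = or, or_ci_low = ci[1L], or_ci_high = ci[2L],
                 or_p = fp, haldane = haldane),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "Enrichment at p < %g: OR = %.3f (95%% CI %.3f-%.3f; Fisher p = %.4g)%s\n",
    x$threshold, x$odds_ratio, x$or_ci_low, x$or_ci_high, x$or_p,
    if (x$haldane) " [Haldane-corrected]" else ""))
  print(x$counts)
  invisible(x)
}

#' Label windows that encompass candidate positions
#'
#' A window is positive when at least one candidate base-pair position
#' lies within its inclusive bp span on the same chromosome.
#'
#' @param windows a window result data.frame with chrom, start_bp, end_bp.
#' @param candidate_meta data.frame with chrom, pos of candidates.
#' @return Logical vector, one entry per window.
#' @export
windows_encompassing <- function(windows, candidate_meta) {
  vapply(seq_len(nrow(windows)), function(i)
    any(candidate_meta$chrom == windows$chrom[i] &
          candidate_meta$pos >= windows$start_bp[i] &
          candidate_meta$pos <= windows$end_bp[i]),
    logical(1))
}

#' Per-offset AUC enrichment of candidate-centered windows
#'
#' For each center offset d, compares the p-values of windows centered d
#' SNPs from a candidate (positives) against all scan windows (negatives)
#' by ROC AUC, and reports the largest offset up to which every offset has
#' a significant one-sided AUC p-value, together with that offset's
#' genomic-distance summaries.
#'
#' @param centered output of [centered_scan()].
#' @param scan_p p-values of all scan windows (the reference set).
#' @param alpha significance level for the AUC p-value.
#' @return List with \code{per_offset} (offset, auc, auc_p, median
#'   distances) and \code{max_significant_offset} (-1 when offset 0 is
#'   already non-significant), plus its distance summaries.
#' @export
offset_enrichment <- function(centered, scan_p, alpha = 0.05) {
  res <- centered$results
  offs <- sort(unique(res$offset))
  per <- do.call(rbind, lapply(offs, function(d) {
    pp <- res$p_value[res$offset == d]
    ra <- roc_auc(c(pp, scan_p), c(rep(TRUE, length(pp)),
                                   rep(FALSE, length(scan_p))))
    data.frame(offset = d, auc = ra$auc, auc_p = ra$auc_p,
               n_windows = length(pp))
  }))
  per <- merge(per, centered$distance_summary, by = "offset", all.x = TRUE)
  per <- per[order(per$offset), ]
  rownames(per) <- NULL
  sig <- per$auc_p < alpha
  maxo <- -1L
  for (i in seq_along(sig)) {
    if (!sig[i]) break
    maxo <- per$offset[i]
  }
  out <- list(per_offset = per, max_significant_offset = maxo)
  if (maxo >= 0L) {
    row <- per[per$offset == maxo, ]
    out$median_center_kb <- row$median_center_kb
    out$median_boundary_kb <- row$median_boundary_kb
  }
  out
}
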