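# Empirical sliding-window pipeline: phenotype preparation, LD pruning,
# window construction and additive-model scans.

#' Prepare a phenotype for regional association scans
#'
#' Optionally log2-transforms the trait, trims samples whose value falls
#' outside the 1st-99th percentile range (removal, not clamping; a clamping
#' variant is available via \code{winsorize = "clamp"}), residualizes on
#' covariates and, when supplied, jointly on all candidate-SNP dosages, and
#' standardizes to mean 0, variance 1.
#'
#' @param trait numeric trait values.
#' @param covariates optional matrix/data.frame of covariates (e.g. age,
#'   sex).
#' @param candidate_genotypes optional matrix of candidate-SNP dosages to
#'   adjust for jointly (removes their main effects).
#' @param log2_transform log2-transform the (strictly positive) trait
#'   first.
#' @param winsorize \code{"trim"} (default: drop samples outside the
#'   percentile range), \code{"clamp"}, or \code{"none"}.
#' @param probs lower/upper percentile bounds used by winsorization.
#' @return A standardized \code{phenotype_vector} with attribute
#'   \code{"kept"} holding the retained sample indices.
#' @export
prepare_phenotype <- function(trait, covariates = NULL,
                              candidate_genotypes = NULL,
                              log2_transform = FALSE,
                              winsorize = c("trim", "clamp", "none"),
                              probs = c(0.01, 0.99)) {
  winsorize <- match.arg(winsorize)
  y <- as.numeric(trait)
  if (log2_transform) {
    if (any(y <= 0)) stop("log2 transform requires a strictly positive trait")
    y <- log2(y)
  }
  kept <- seq_along(y)
  if (winsorize != "none") {
    qs <- stats::quantile(y, probs, names = FALSE, type = 7)
    if (winsorize == "trim") {
      kept <- which(y >= qs[1L] & y <= qs[2L])
      if (!length(kept)) stop("all samples trimmed")
      y <- y[kept]
    } else {
      y <- pmin(pmax(y, qs[1L]), qs[2L])
    }
  }
  adj <- NULL
  if (!is.null(covariates)) {
    cv <- as.matrix(as.data.frame(covariates))[kept, , drop = FALSE]
    adj <- cv
  }
  if (!is.null(candidate_genotypes)) {
    cg <- as.matrix(candidate_genotypes)[kept, , drop = FALSE]
    adj <- if (is.null(adj)) cg else cbind(adj, cg)
  }
  if (!is.null(adj)) {
    qa <- qr(cbind(1, adj))
    if (qa$rank < ncol(adj) + 1L)
      warning("collinear covariate/candidate columns; using their span")
    y <- qr.resid(qa, y)
  }
  out <- standardize_phenotype(y)
  attr(out, "kept") <- kept
  out
}

#' Greedy windowed LD pruning
#'
#' Mirrors the classic windowed pairwise pruning: within each sliding
#' window of \code{window} SNPs (advancing by \code{step}), while any
#' retained pair has genotype correlation r2 above \code{r2_threshold}, the
#' later-position SNP of the offending pair is removed.
#'
#' @param data a \code{genotype_dataset} with \code{snp_meta} sorted by
#'   (chromosome, position).
#' @param window,step window size and step in SNPs.
#' @param r2_threshold maximum tolerated pairwise r2 within a window.
#' @return Integer indices of retained SNPs.
#' @export
ld_prune <- function(data, window = 100L, step = 50L, r2_threshold = 0.8) {
  stopifnot(inherits(data, "genotype_dataset"))
  G <- impute_missing(data)$G
  keep <- rep(TRUE, ncol(G))
  for (chr in unique(data$snp_meta$chrom)) {
    idx <- which(data$snp_meta$chrom == chr)
    starts <- seq(1L, length(idx), by = step)
    for (s in starts) {
      win <- idx[s:min(s + window - 1L, length(idx))]
      win <- win[keep[win]]
      if (length(win) < 2L) next
      sds <- apply(G[, win, drop = FALSE], 2L, stats::sd)
      win <- win[sds > 0]
      if (length(win) < 2L) next
      r2 <- stats::cor(G[, win, drop = FALSE])^2
      diag(r2) <- 0
      while (TRUE) {
        mx <- which(r2 == max(r2), arr.ind = TRUE)[1L, ]
        if (r2[mx[1L], mx[2L]] <= r2_threshold) break
        drop_local <- max(mx)  # later-position SNP removed, earlier kept
        keep[win[drop_local]] <- FALSE
        r2[drop_local, ] <- 0; r2[, drop_local] <- 0
      }
    }
  }
  which(keep)
}

#' Build sliding windows over SNP metadata
#'
#' Per chromosome, windows of \code{size} SNPs start at offsets 0, step,
#' 2 step, ...; trailing partial windows are dropped, so a chromosome with
#' m SNPs yields floor((m - size)/step) + 1 windows (0 when m < size).
#'
#' @param snp_meta SNP metadata data.frame (chrom, pos, id, ...), sorted by
#'   (chromosome, position).
#' @param size,step window size and step in SNPs.
#' @return A data.frame of class \code{window_set}: chrom, start_index,
#'   end_index (0-based half-open, within the chromosome's SNP list),
#'   start_bp, end_bp (inclusive), n_snps, and a list column \code{snps}
#'   of global SNP row indices.
#' @export
make_windows <- function(snp_meta, size = 100L, step = 50L) {
  if (size < 1L || step < 1L || step > size)
    stop("need size >= 1 and 1 <= step <= size")
  out <- list()
  for (chr in unique(snp_meta$chrom)) {
    idx <- which(snp_meta$chrom == chr)
    mc <- length(idx)
    if (mc < size) {
      warning("chromosome ", chr, " has fewer than ", size,
              " SNPs; no windows")
      next
    }
    starts0 <- seq(0L, mc - size, by = step)
    for (s in starts0) {
      gl <- idx[(s + 1L):(s + size)]
      out[[length(out) + 1L]] <- list(
        chrom = chr, start_index = s, end_index = s + size,
        start_bp = snp_meta$pos[gl[1L]], end_bp = snp_meta$pos[gl[size]],
        n_snps = size, snps = gl)
    }
  }
  if (!length(out)) return(empty_window_set())
  df <- data.frame(
    chrom = vapply(out, `[[`, character(1), "chrom"),
    start_index = vapply(out, `[[`, numeric(1), "start_index"),
    end_index = vapply(out, `[[`, numeric(1), "end_index"),
    start_bp = vapply(out, `[[`, numeric(1), "start_bp"),
    end_bp = vapply(out, `[[`, numeric(1), "end_bp"),
    n_snps = vapply(out, `[[`, numeric(1), "n_snps"),
    stringsAsFactors = FALSE)
  df$snps <- lapply(out, `[[`, "snps")
  class(df) <- c("window_set", "data.frame")
  df
}

empty_window_set <- function() {
  df <- data.frame(chrom = character(0), start_index = numeric(0),
                   end_index = numeric(0), start_bp = numeric(0),
                   end_bp = numeric(0), n_snps = numeric(0))
  df$snps <- list()
  class(df) <- c("window_set", "data.frame")
  df
}

#' Additive-model scan over a set of windows
#'
#' Fits the joint additive model of each window's SNPs on the prepared
#' phenotype and records the joint F-test p-value, the raw and adjusted
#' variance estimates, the number of collinear columns dropped, and
#' (optionally) the per-SNP multivariate coefficient p-values.
#'
#' @param data a \code{genotype_dataset}.
#' @param y a prepared \code{phenotype_vector} (see [prepare_phenotype()]).
#' @param windows a \code{window_set} from [make_windows()].
#' @param keep_coefs retain the per-SNP multivariate coefficient tables.
#' @return A data.frame with one row per window: window columns plus
#'   \code{p_value}, \code{r2_raw}, \code{r2_adj}, \code{n_dropped}; the
#'   coefficient tables, when kept, in attribute \code{"coef_tables"}.
#' @export
scan_windows <- function(data, y, windows, keep_coefs = FALSE) {
  stopifnot(inherits(data, "genotype_dataset"))
  data <- impute_missing(data)
  res <- data.frame(windows)[, c("chrom", "start_index", "end_index",
                                 "start_bp", "end_bp", "n_snps")]
  nw <- nrow(res)
  res$p_value <- res$r2_raw <- res$r2_adj <- NA_real_
  res$n_dropped <- NA_integer_
  coefs <- if (keep_coefs) vector("list", nw)
  for (i in seq_len(nw)) {
    fit <- tryCatch(
      fit_linear(design_additive(subset_snps(data, windows$snps[[i]])), y),
      error = function(e) NULL)
    if (is.null(fit)) next
    res$p_value[i] <- fit$p_value
    res$r2_raw[i] <- fit$r2_raw
    res$r2_adj[i] <- fit$r2_adj
    res$n_dropped[i] <- fit$n_dropped
    if (keep_coefs) coefs[[i]] <- fit$coef_table
  }
  if (keep_coefs) attr(res, "coef_tables") <- coefs
  res
}

# locate candidate SNPs among (pruned) metadata; ids may be snp ids or
# "chrom:pos" strings; best r2 proxy within proxy_window_bp when absent.
locate_candidates <- function(data, candidates, proxy_window_bp = 5e5) {
  meta <- data$snp_meta
  keyed <- paste0(meta$chrom, ":", meta$pos)
  out <- integer(length(candidates))
  for (i in seq_along(candidates)) {
    cand <- candidates[i]
    j <- match(cand, meta$id)
    if (is.na(j)) j <- match(cand, keyed)
    if (is.na(j) && grepl(":", cand)) {
      parts <- strsplit(cand, ":")[[1L]]
      near <- which(meta$chrom == parts[1L] &
                      abs(meta$pos - as.numeric(parts[2L])) <= proxy_window_bp)
      if (length(near)) {
        # best proxy by position only at this layer (no source genotypes
        # for an absent SNP); closest retained SNP
        j <- near[which.min(abs(meta$pos[near] - as.numeric(parts[2L])))]
      }
    }
    if (is.na(j)) stop("candidate not found and no proxy within ",
                       proxy_window_bp, " bp: ", cand)
    out[i] <- j
  }
  out
}

#' Remove candidate SNPs and their LD proxies
#'
#' Sensitivity-analysis filter: deletes every SNP with genotype r2 above
#' \code{r2_threshold} with a candidate SNP within \code{window_bp} base
#' pairs (the candidates themselves always match at r2 = 1), as an
#' alternative to adjusting the phenotype for the candidates.
#'
#' @param data a \code{genotype_dataset}.
#' @param candidates character vector of candidate ids (or "chrom:pos").
#' @param r2_threshold proxy definition (default 0.1).
#' @param window_bp search radius around each candidate (default 500 Kb).
#' @return Integer indices of retained SNPs.
#' @export
remove_candidate_proxies <- function(data, candidates, r2_threshold = 0.1,
                                     window_bp = 5e5) {
  stopifnot(inherits(data, "genotype_dataset"))
  data <- impute_missing(data)
  cand_idx <- locate_candidates(data, candidates)
  meta <- data$snp_meta
  drop <- rep(FALSE, data$m)
  for (ci in cand_idx) {
    near <- which(meta$chrom == meta$chrom[ci] &
                    abs(meta$pos - meta$pos[ci]) <= window_bp)
    g0 <- data$G[, ci]
    if (stats::sd(g0) == 0) { drop[ci] <- TRUE; next }
    for (j in near) {
      sj <- stats::sd(data$G[, j])
      r2 <- if (sj == 0) 0 else stats::cor(g0, data$G[, j])^2
      if (j == ci || r2 > r2_threshold) drop[j] <- TRUE
    }
  }
  which(!drop)
}

#' Candidate-centered sliding scan
#'
#' For each candidate SNP and each offset d = 0..max_offset, fits windows
#' of \code{size} SNPs whose center lies d SNPs away from the candidate,
#' in both directions, and summarizes the genomic distances involved: the
#' median |center - candidate| distance and the median minimal distance
#' between a window boundary and the candidate (0 when the candidate lies
#' inside the window span).
#'
#' The center of a window starting at within-chromosome 0-based index s is
#' index s + floor(size/2).
#'
#' @param data a \code{genotype_dataset}.
#' @param y a prepared \code{phenotype_vector}.
#' @param candidates character vector of candidate SNP ids (or
#'   "chrom:pos").
#' @param size window size in SNPs.
#' @param max_offset largest center offset, in SNPs.
#' @return List with \code{results} (one row per candidate x offset x
#'   direction: candidate, offset, direction, p_value, r2_adj, bp
#'   distances; offsets truncated at chromosome edges are flagged) and
#'   \code{distance_summary} (per offset: median center and boundary
#'   distances in Kb).
#' @export
centered_scan <- function(data, y, candidates, size = 100L,
                          max_offset = 100L) {
  stopifnot(inherits(data, "genotype_dataset"))
  data <- impute_missing(data)
  meta <- data$snp_meta
  cand_idx <- locate_candidates(data, candidates)
  half <- size %/% 2L
  rows <- list()
  for (ci in seq_along(cand_idx)) {
    gidx <- cand_idx[ci]
    chr <- meta$chrom[gidx]
    chr_rows <- which(meta$chrom == chr)
    pos_in_chr <- match(gidx, chr_rows)
    mc <- length(chr_rows)
    cand_bp <- meta$pos[gidx]
    for (d in 0:max_offset) {
      for (dir in if (d == 0L) 1L else c(-1L, 1L)) {
        center <- pos_in_chr + dir * d
        s <- center - half           # 1-based start in chromosome list
        truncated <- s < 1L || (s + size - 1L) > mc
        if (truncated) next
        gl <- chr_rows[s:(s + size - 1L)]
        fit <- tryCatch(
          fit_linear(design_additive(subset_snps(data, gl)), y),
          error = function(e) NULL)
        span <- range(meta$pos[gl])
        bdist <- if (cand_bp >= span[1L] && cand_bp <= span[2L]) 0
                 else min(abs(span - cand_bp))
        rows[[length(rows) + 1L]] <- data.frame(
          candidate = candidates[ci], offset = d, direction = dir,
          chrom = chr, start_bp = span[1L], end_bp = span[2L],
          p_value = if (is.null(fit)) NA_real_ else fit$p_value,
          r2_adj = if (is.null(fit)) NA_real_ else fit$r2_adj,
          center_bp_dist = abs(meta$pos[chr_rows[center]] - cand_bp),
          boundary_bp_dist = bdist,
          stringsAsFactors = FALSE)
      }
    }
  }
  results <- do.call(rbind, rows)
  ds <- do.call(rbind, lapply(split(results, results$offset), function(df)
    data.frame(offset = df$offset[1L],
               median_center_kb = stats::median(df$center_bp_dist) / 1000,
               median_boundary_kb = stats::median(df$boundary_bp_dist) / 1000)))
  ds <- ds[order(ds$offset), ]
  rownames(ds) <- NULL
  list(results = results, distance_summary = ds)
}
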