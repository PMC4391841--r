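# File I/O: PLINK bed/bim/fam and phased VCF.
#
# bed decoding follows the SNP-major 2-bit layout: per SNP, ceil(n/4)
# bytes, two bits per individual starting at the least significant pair;
# 00 = homozygous A1, 10 = heterozygous, 11 = homozygous A2, 01 = missing.
# Genotypes are returned as counts of the bim A1 allele (written here as
# the alternate allele), so 00 -> 2, 10 -> 1, 11 -> 0, 01 -> NA.

bed_magic <- as.raw(c(0x6c, 0x1b, 0x01))

# 256 x 4 lookup: byte value -> four A1 dosages (NA for missing)
bed_lookup <- local({
  code_to_dose <- c(`0` = 2, `1` = NA, `2` = 1, `3` = 0)
  lut <- matrix(NA_real_, 256L, 4L)
  for (b in 0:255) {
    codes <- bitwAnd(bitwShiftR(b, c(0L, 2L, 4L, 6L)), 3L)
    lut[b + 1L, ] <- code_to_dose[as.character(codes)]
  }
  lut
})

#' Read a PLINK bed/bim/fam fileset
#'
#' @param prefix path prefix; \code{prefix.bed}, \code{.bim}, \code{.fam}
#'   must exist.
#' @return A \code{genotype_dataset}; genotypes count the bim A1 allele,
#'   missing calls are NA.
#' @export
read_plink <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  if (!all(file.exists(paths)))
    stop("missing PLINK file(s): ",
         paste(paths[!file.exists(paths)], collapse = ", "))
  bim <- utils::read.table(paths[2L], header = FALSE,
                           colClasses = c("character", "character",
                                          "numeric", "numeric",
                                          "character", "character"))
  names(bim) <- c("chrom", "id", "cm", "pos", "a1", "a2")
  fam <- utils::read.table(paths[3L], header = FALSE,
                           colClasses = "character")
  n <- nrow(fam); m <- nrow(bim)
  bpp <- ceiling(n / 4)
  raw <- readBin(paths[1L], "raw", n = 3L + m * bpp)
  if (length(raw) < 3L + m * bpp) stop("truncated bed file")
  if (!identical(raw[1:3], bed_magic))
    stop("bad bed magic number / not SNP-major")
  body <- matrix(as.integer(raw[-(1:3)]), nrow = bpp)
  G <- matrix(NA_real_, n, m)
  for (j in seq_len(m)) {
    dose4 <- bed_lookup[body[, j] + 1L, , drop = FALSE]
    G[, j] <- as.vector(t(dose4))[seq_len(n)]
  }
  meta <- data.frame(chrom = bim$chrom, pos = bim$pos, id = bim$id,
                     ref = bim$a2, alt = bim$a1, stringsAsFactors = FALSE)
  genotype_dataset(G, meta, sample_ids = fam[[2L]])
}

#' Write a genotype dataset as PLINK bed/bim/fam
#'
#' The alternate allele is written as bim A1, so a round trip through
#' [read_plink()] reproduces the allele counts.
#'
#' @param data a \code{genotype_dataset}.
#' @param prefix output path prefix.
#' @return \code{prefix}, invisibly.
#' @export
write_plink <- function(data, prefix) {
  stopifnot(inherits(data, "genotype_dataset"))
  meta <- data$snp_meta
  bim <- data.frame(meta$chrom, meta$id, 0,
                    format(meta$pos, scientific = FALSE, trim = TRUE),
                    meta$alt, meta$ref)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  fam <- data.frame(data$sample_ids, data$sample_ids, 0, 0, 0, -9)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  n <- data$n
  dose_to_code <- function(g) {
    code <- rep(1L, length(g))          # missing
    code[!is.na(g) & g == 2] <- 0L
    code[!is.na(g) & g == 1] <- 2L
    code[!is.na(g) & g == 0] <- 3L
    code
  }
  pad <- (-n) %% 4L
  con <- file(paste0(prefix, ".bed"), "wb"); on.exit(close(con))
  writeBin(bed_magic, con)
  for (j in seq_len(data$m)) {
    code <- c(dose_to_code(data$G[, j]), rep(0L, pad))
    quads <- matrix(code, nrow = 4L)
    bytes <- quads[1L, ] + bitwShiftL(quads[2L, ], 2L) +
      bitwShiftL(quads[3L, ], 4L) + bitwShiftL(quads[4L, ], 6L)
    writeBin(as.raw(bytes), con)
  }
  invisible(prefix)
}

#' Write a haplotype panel as a phased VCF
#'
#' Plain-text VCF 4.2 with GT-only phased entries; haplotypes 2i-1 and 2i
#' form sample i.
#'
#' @param panel a \code{haplotype_panel} (even number of haplotypes).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_phased_vcf <- function(panel, path) {
  stopifnot(inherits(panel, "haplotype_panel"))
  nh <- panel$n_haplotypes
  if (nh %% 2L != 0L) stop("need an even number of haplotypes")
  ns <- nh %/% 2L
  ids <- paste0("s", seq_len(ns))
  meta <- panel$snp_meta
  gt <- matrix(paste0(t(panel$haps[seq(1L, nh, 2L), , drop = FALSE]), "|",
                      t(panel$haps[seq(2L, nh, 2L), , drop = FALSE])),
               nrow = panel$n_snps)
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", ids), collapse = "\t"),
             paste(meta$chrom, meta$pos, meta$id, meta$ref, meta$alt, ".",
                   "PASS", ".", "GT",
                   apply(gt, 1L, paste, collapse = "\t"), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a phased VCF as a haplotype panel
#'
#' Biallelic, fully phased records become panel rows (2 haplotypes per
#' sample); multi-allelic or unphased records are skipped and counted.
#' Parsing uses the vcfR package.
#'
#' @param path a VCF file.
#' @return A \code{haplotype_panel}; attribute \code{"n_skipped"} counts
#'   skipped records.
#' @export
read_phased_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = ncol(vcfR::getFIX(v)),
                dimnames = list(NULL, colnames(vcfR::getFIX(v))))
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- matrix(gt, nrow = nrow(fix))
  biallelic <- !grepl(",", fix[, "ALT"]) & fix[, "ALT"] != "."
  phased <- apply(gt, 1L, function(r)
    all(grepl("^[01]\\|[01]$", r)))
  keep <- biallelic & phased
  n_skipped <- sum(!keep)
  if (!any(keep)) stop("no phased biallelic records in ", path)
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  a1 <- t(apply(gt, 1L, function(r) as.integer(substr(r, 1L, 1L))))
  a2 <- t(apply(gt, 1L, function(r) as.integer(substr(r, 3L, 3L))))
  ns <- ncol(gt)
  haps <- matrix(0L, 2L * ns, nrow(gt))
  haps[seq(1L, 2L * ns, 2L), ] <- t(a1)
  haps[seq(2L, 2L * ns, 2L), ] <- t(a2)
  meta <- data.frame(chrom = fix[, "CHROM"],
                     pos = as.integer(fix[, "POS"]), id = fix[, "ID"],
                     ref = fix[, "REF"], alt = fix[, "ALT"],
                     stringsAsFactors = FALSE)
  out <- structure(list(haps = haps, snp_meta = meta,
                        maf = colMeans(haps), n_haplotypes = 2L * ns,
                        n_snps = nrow(gt)),
                   class = "haplotype_panel")
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Diploid genotypes from a phased panel
#'
#' Pairs haplotypes 2i-1 and 2i into sample i and sums allele counts.
#'
#' @param panel a \code{haplotype_panel} with an even number of
#'   haplotypes.
#' @return A \code{genotype_dataset}.
#' @export
panel_to_genotypes <- function(panel) {
  stopifnot(inherits(panel, "haplotype_panel"))
  nh <- panel$n_haplotypes
  if (nh %% 2L != 0L) stop("need an even number of haplotypes")
  G <- panel$haps[seq(1L, nh, 2L), , drop = FALSE] +
    panel$haps[seq(2L, nh, 2L), , drop = FALSE]
  genotype_dataset(G, panel$snp_meta)
}
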