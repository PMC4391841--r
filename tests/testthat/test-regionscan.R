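test_that("phenotype preparation standardizes and residualizes", {
  set.seed(71)
  y <- rnorm(200, mean = 5)
  out <- prepare_phenotype(y, winsorize = "none")
  expect_equal(mean(out$y), 0, tolerance = 1e-12)
  expect_equal(stats::var(out$y), 1, tolerance = 1e-12)
  # orthogonality to covariates and candidate dosages
  cv <- cbind(age = rnorm(200), sex = rbinom(200, 1, 0.5))
  cg <- matrix(rbinom(600, 2, 0.3), 200, 3)
  y2 <- 5 + 0.5 * cv[, 1] + 0.4 * cg[, 2] + rnorm(200)
  out2 <- prepare_phenotype(y2, covariates = cv, candidate_genotypes = cg,
                            winsorize = "none")
  for (v in list(cv[, 1], cv[, 2], cg[, 1], cg[, 2], cg[, 3]))
    expect_lt(abs(sum(out2$y * (v - mean(v)))), 1e-8)
})

test_that("trimming removes the tails and clamping bounds them", {
  y <- c(rnorm(300), 100, -100)
  out <- prepare_phenotype(y, winsorize = "trim")
  kept <- attr(out, "kept")
  expect_false(any(c(301L, 302L) %in% kept))
  expect_lte(length(kept), 298L)  # ~1% from each tail
  out2 <- prepare_phenotype(y, winsorize = "clamp")
  expect_equal(attr(out2, "kept"), seq_along(y))
  expect_error(prepare_phenotype(c(-1, 2, 3), log2_transform = TRUE),
               "positive")
})

test_that("planted candidate effects vanish after joint adjustment", {
  set.seed(72)
  n <- 600
  cg <- matrix(rbinom(n * 4, 2, 0.3), n, 4)
  # after joint OLS adjustment the residual is exactly orthogonal to each
  # candidate, so their univariate associations are annihilated...
  yy <- cg %*% c(0.3, -0.2, 0.25, 0.15) + rnorm(n)
  out <- prepare_phenotype(yy, candidate_genotypes = cg,
                           winsorize = "none")
  for (j in 1:4) {
    pj <- summary(stats::lm(out$y ~ cg[, j]))$coefficients[2, 4]
    expect_gt(pj, 0.99)
  }
  # ...while unadjusted, unassociated SNPs keep uniform p-values
  ps <- replicate(150, {
    yy <- cg %*% c(0.3, -0.2, 0.25, 0.15) + rnorm(n)
    out <- prepare_phenotype(yy, candidate_genotypes = cg,
                             winsorize = "none")
    x <- rbinom(n, 2, 0.3)
    summary(stats::lm(out$y ~ x))$coefficients[2, 4]
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("LD pruning removes duplicates and keeps independent SNPs", {
  set.seed(73)
  g <- random_genotypes(300, 12)
  g$G[, 7] <- g$G[, 6]                  # exact duplicate
  kept <- ld_prune(g, window = 10, step = 5, r2_threshold = 0.8)
  expect_true(6 %in% kept)
  expect_false(7 %in% kept)             # later-position copy removed
  g2 <- random_genotypes(400, 15)
  expect_equal(ld_prune(g2, window = 10, step = 5), seq_len(15))
})

test_that("no retained within-window pair exceeds the pruning threshold", {
  set.seed(74)
  panel <- generate_fixture_panel(n_haplotypes = 400, n_snps = 60,
                                  ld_decay_bp = 30000, seed = 12)
  g <- panel_to_genotypes(panel)
  kept <- ld_prune(g, window = 20, step = 10, r2_threshold = 0.5)
  idx <- kept
  for (s in seq(1, length(idx), by = 10)) {
    win <- idx[s:min(s + 19, length(idx))]
    if (length(win) < 2) next
    r2 <- stats::cor(g$G[, win])^2
    diag(r2) <- 0
    expect_lte(max(r2), 0.5 + 1e-12)
  }
})

test_that("window construction drops partial windows per chromosome", {
  meta <- data.frame(chrom = rep("1", 250), pos = seq_len(250) * 1000,
                     id = paste0("s", 1:250))
  w <- make_windows(meta, size = 100, step = 50)
  expect_equal(nrow(w), 4L)
  expect_equal(w$start_index, c(0, 50, 100, 150))
  expect_equal(w$end_index - w$start_index, rep(100, 4))
  w1 <- make_windows(meta[1:100, ], size = 100, step = 50)
  expect_equal(nrow(w1), 1L)
  expect_warning(w0 <- make_windows(meta[1:99, ], size = 100, step = 50),
                 "fewer")
  expect_equal(nrow(w0), 0L)
  # windows never span chromosomes; per-chromosome count formula
  meta2 <- data.frame(chrom = rep(c("1", "2"), c(130, 170)),
                      pos = c(seq_len(130), seq_len(170)) * 500,
                      id = paste0("s", 1:300))
  w2 <- make_windows(meta2, size = 50, step = 25)
  counts <- c(floor((130 - 50) / 25) + 1, floor((170 - 50) / 25) + 1)
  expect_equal(as.numeric(table(w2$chrom)[c("1", "2")]), counts)
})

test_that("window scans behave under the null and find planted signal", {
  set.seed(75)
  g <- random_genotypes(400, 120)
  wins <- make_windows(g$snp_meta, size = 40, step = 20)
  y0 <- standardize_phenotype(rnorm(400))
  res0 <- scan_windows(g, y0, wins)
  expect_equal(nrow(res0), nrow(wins))
  expect_true(all(res0$p_value > 0 & res0$p_value <= 1))
  # plant a strong signal inside the second window
  sig <- rowSums(g$G[, 45:50])
  y1 <- standardize_phenotype(sig / stats::sd(sig) * 0.6 + rnorm(400))
  res1 <- scan_windows(g, y1, wins)
  covering <- which(sapply(wins$snps, function(s) all(45:50 %in% s)))
  expect_true(which.min(res1$p_value) %in% covering)
})

test_that("scan results carry per-SNP coefficient tables on request", {
  set.seed(76)
  g <- random_genotypes(200, 40)
  wins <- make_windows(g$snp_meta, size = 20, step = 20)
  res <- scan_windows(g, standardize_phenotype(rnorm(200)), wins,
                      keep_coefs = TRUE)
  tabs <- attr(res, "coef_tables")
  expect_equal(length(tabs), 2L)
  expect_equal(nrow(tabs[[1]]), 20L)
})

test_that("centered scans report exact distances on a uniform map", {
  set.seed(77)
  g <- random_genotypes(120, 300, spacing = 2000)   # uniform 2 Kb spacing
  cs <- centered_scan(g, standardize_phenotype(rnorm(120)),
                      candidates = "snp150", size = 100, max_offset = 71)
  ds <- cs$distance_summary
  expect_equal(ds$median_center_kb[ds$offset == 71], 142)
  expect_equal(ds$median_center_kb[ds$offset == 0], 0)
  # candidate inside the window span at offset 0
  expect_equal(ds$median_boundary_kb[ds$offset == 0], 0)
  # both directions emitted for d > 0
  expect_equal(sum(cs$results$offset == 30), 2L)
  expect_setequal(cs$results$direction[cs$results$offset == 30], c(-1L, 1L))
  # offsets truncated at the chromosome edge are absent, not padded
  cs_edge <- centered_scan(g, standardize_phenotype(rnorm(120)),
                           candidates = "snp60", size = 100, max_offset = 40)
  expect_lt(sum(cs_edge$results$offset == 40), 2L)
})

test_that("the removal variant drops candidates and their LD proxies only", {
  set.seed(78)
  g <- random_genotypes(400, 30)
  g$G[, 11] <- g$G[, 10]                    # perfect proxy next door
  kept <- remove_candidate_proxies(g, "snp10", r2_threshold = 0.1)
  expect_false(10 %in% kept)
  expect_false(11 %in% kept)
  # independent SNPs survive
  expect_gt(length(kept), 20)
  # a proxy outside the search window survives even if correlated
  g2 <- random_genotypes(400, 3, spacing = 600000)
  g2$G[, 3] <- g2$G[, 1]
  kept2 <- remove_candidate_proxies(g2, "snp1", window_bp = 5e5)
  expect_equal(kept2, c(2L, 3L))
})

test_that("scans handle missing genotypes through mean imputation", {
  set.seed(79)
  g <- random_genotypes(150, 40)
  g$G[sample(length(g$G), 60)] <- NA
  wins <- make_windows(g$snp_meta, size = 20, step = 20)
  res <- scan_windows(g, standardize_phenotype(rnorm(150)), wins)
  expect_false(anyNA(res$p_value))
  cs <- centered_scan(g, standardize_phenotype(rnorm(150)), "snp20",
                      size = 10, max_offset = 2)
  expect_false(anyNA(cs$results$p_value))
})
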