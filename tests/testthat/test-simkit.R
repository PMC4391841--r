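test_that("diplotype sampling is HWE-consistent and seed-reproducible", {
  hs <- sys_le()
  set.seed(61)
  smp <- sample_diplotypes(hs, 1e5)
  expect_true(all(rowSums(smp$D) == 2))
  emp <- colSums(smp$D) / (2e5)
  se <- sqrt(hs$pi * (1 - hs$pi) / 2e5)
  expect_true(all(abs(emp - hs$pi) < 4 * se))
  set.seed(99); a <- sample_diplotypes(hs, 50)$D
  set.seed(99); b <- sample_diplotypes(hs, 50)$D
  expect_identical(a, b)
})

test_that("simulated phenotypes have the generative variance structure", {
  set.seed(62)
  hs <- sys_le(beta = effect_path(sys_le(), 0.1, 0))
  smp <- sample_diplotypes(hs, 5e4)
  y <- simulate_phenotype(smp)
  expect_equal(stats::var(y$y), 1.1, tolerance = 0.03)
  # pure-noise trait: uniform additive p-values
  hs0 <- sys_le(beta = rep(0, 4))
  ps <- replicate(200, {
    s <- sample_diplotypes(hs0, 150)
    fit_linear(design_additive(genotypes_from_diplotypes(s)),
               simulate_phenotype(s))$p_value
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("product-measure nuisance extension gives exact linkage equilibrium", {
  hs <- sys_le(beta = c(0.1, 0, -0.1, 0.2))
  ext <- extend_with_nuisance(hs, 2, target_r2 = 0, xi_nuisance = 0.35)
  expect_equal(ext$m, 4L)
  for (a in 1:2) for (b in 3:4)
    expect_equal(pairwise_ld(ext, a, b)$r2, 0, tolerance = 1e-12)
  expect_equal(pairwise_ld(ext, 3, 4)$r2, 0, tolerance = 1e-12)
  expect_equal(allele_frequencies(ext)[3:4], c(0.35, 0.35))
  expect_equal(haplotype_variance(ext), haplotype_variance(hs),
               tolerance = 1e-12)
})

test_that("nuisance extension reaches a nonzero LD target on every pair", {
  set.seed(63)
  hs <- sys_exact_r2(0.2, beta = c(0.1, 0, 0, -0.1))
  ext <- extend_with_nuisance(hs, 2, target_r2 = 0.2)
  prs <- utils::combn(4, 2)
  for (j in seq_len(ncol(prs))) {
    pr <- prs[, j]
    expect_lt(abs(pairwise_ld(ext, pr[1], pr[2])$r2 - 0.2), 1e-6)
  }
  expect_lt(abs(haplotype_variance(ext) - haplotype_variance(hs)), 1e-6)
})

test_that("rare tagging geometry matches its stated LD structure", {
  cfg <- rare_tagging_scenario(0.01, n_replicates = 10)
  sys <- cfg$system
  # commons in LE; tagging haplotype frequency equals the rare frequency
  expect_equal(pairwise_ld(sys, 1, 2)$r2, 0, tolerance = 1e-12)
  xi <- allele_frequencies(sys)
  expect_equal(xi[3], (1 / 24)^2, tolerance = 1e-12)
  ld13 <- pairwise_ld(sys, 1, 3)
  expect_equal(ld13$D_prime, 1, tolerance = 1e-12)
  expect_equal(ld13$r2, 0.04, tolerance = 1e-12)    # p/(1+p) at p = 1/24
  expect_equal(haplotype_variance(sys), 0.01, tolerance = 1e-12)
  # masked: two observed columns; unmasked: three
  dr <- regjoint:::replicate_draw(cfg)
  expect_equal(dr$G$m, 2L)
  cfg_u <- rare_tagging_scenario(0.01, mask_rare = FALSE, n_replicates = 10)
  expect_equal(regjoint:::replicate_draw(cfg_u)$G$m, 3L)
  # r2_hap < 1 geometry: tagging haplotype r2 with the rare allele
  cfg5 <- rare_tagging_scenario(0.01, r2_hap = 0.5, n_replicates = 10)
  f <- (1 / 24)^2
  h <- f / (0.5 * (1 - f) + f)
  tag_idx <- which(rownames(cfg5$system$H) %in% c("110", "111"))
  expect_equal(sum(cfg5$system$pi[tag_idx]), h, tolerance = 1e-12)
})

test_that("scenario runs are reproducible and record all replicates", {
  cfg <- rare_tagging_scenario(0.01, n = 400, n_replicates = 8, seed = 5,
                               models = c("additive", "haplotype_prob"))
  r1 <- run_scenario(cfg)
  r2 <- run_scenario(cfg)
  expect_identical(r1$summary, r2$summary)
  expect_equal(unname(r1$summary$n_ok), c(8L, 8L))
  expect_true(all(r1$summary$se_adj > 0))
})

test_that("null scenarios show no type-I inflation at alpha 0.05", {
  hs <- sys_le(beta = rep(0, 4))
  cfg <- scenario_config(hs, n = 250, n_replicates = 250,
                         models = c("additive", "vc"), alpha = 0.05,
                         seed = 64)
  res <- run_scenario(cfg)$summary
  ci <- 3 * sqrt(0.05 * 0.95 / 250)
  expect_true(all(abs(res$power - 0.05) < ci))
})

test_that("fixture panels have the requested MAF spectrum and decaying LD", {
  panel <- generate_fixture_panel(n_haplotypes = 600, n_snps = 120,
                                  ld_decay_bp = 15000, maf_range = c(0.1, 0.5),
                                  seed = 9)
  expect_true(all(panel$maf > 0.04 & panel$maf < 0.6))
  # binned mean r2 decreases with SNP distance
  r2s <- sapply(1:110, function(j) regjoint:::panel_r2(panel$haps, j, j + 1))
  r2l <- sapply(1:100, function(j) regjoint:::panel_r2(panel$haps, j, j + 20))
  expect_gt(mean(r2s, na.rm = TRUE), mean(r2l, na.rm = TRUE))
  expect_gt(mean(r2s, na.rm = TRUE), 0.2)
  # deterministic by seed
  p2 <- generate_fixture_panel(n_haplotypes = 600, n_snps = 120,
                               ld_decay_bp = 15000, maf_range = c(0.1, 0.5),
                               seed = 9)
  expect_identical(panel$haps, p2$haps)
})

test_that("panel-window scenarios respect filters and masking", {
  panel <- generate_fixture_panel(n_haplotypes = 500, n_snps = 80,
                                  ld_decay_bp = 4000, maf_range = c(0.08, 0.5),
                                  seed = 10)
  cfg <- panel_window_scenario(panel, window_size = 20, sigma2_H = 0.02,
                               tau_prime = 0, n = 300, n_replicates = 2,
                               mask_causal = TRUE, models = "additive",
                               seed = 11)
  expect_equal(length(cfg$window_snps), 20L)
  # MAF filter holds on the selected window
  maf <- pmin(panel$maf, 1 - panel$maf)[cfg$window_snps]
  expect_true(all(maf > 0.01))
  # pruning: no retained pair above r2 = 0.8
  prs <- utils::combn(cfg$window_snps, 2)
  r2 <- apply(prs, 2, function(pr)
    regjoint:::panel_r2(panel$haps, pr[1], pr[2]))
  expect_true(all(r2 <= 0.8 + 1e-12, na.rm = TRUE))
  # masked draw exposes window_size - 2 SNPs
  set.seed(1)
  dr <- regjoint:::replicate_draw(cfg)
  expect_equal(dr$G$m, 18L)
  r <- run_scenario(cfg)
  expect_equal(unname(r$summary$n_ok), 2L)
  expect_error(panel_window_scenario(panel, window_size = 500),
               "too small")
})

test_that("all models agree with the generative variance at tau' zero", {
  # population-level agreement surrogate at modest replicates: means within
  # 3 Monte-Carlo SE of sigma2_H/(sigma2_H + 1)
  hs <- sys_le()
  sys <- haplotype_system(hs$H, hs$pi, beta = effect_path(hs, 0.05, 0))
  cfg <- scenario_config(sys, n = 800, n_replicates = 60,
                         models = c("additive", "interaction", "genotypic",
                                    "haplotype_prob", "vc"),
                         alpha = 5e-5, seed = 65)
  res <- run_scenario(cfg)$summary
  target <- 0.05 / 1.05
  expect_true(all(abs(res$mean_adj - target) < 3 * res$se_adj))
})
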