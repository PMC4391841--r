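test_that("haplotype system construction enforces its invariants", {
  expect_error(haplotype_system(rbind(c(0, 2)), 1), "0/1")
  expect_error(haplotype_system(rbind(c(0, 0), c(0, 0)), c(0.5, 0.5)),
               "distinct")
  expect_error(haplotype_system(H4, c(0.3, 0.3, 0.3, 0.2)), "sum to 1")
  expect_error(haplotype_system(H4, rep(0.25, 4), beta = 1:3), "beta")
  hs <- sys_le()
  expect_equal(hs$k, 4L)
  expect_equal(hs$m, 2L)
})

test_that("genotypes are diplotype counts times haplotype alleles", {
  hs <- sys_uniform()
  # homozygote for the reference haplotype
  smp <- structure(list(D = rbind(c(2, 0, 0, 0)), panel = hs, n = 1L),
                   class = "diplotype_sample")
  expect_equal(as.numeric(genotypes_from_diplotypes(smp)$G), c(0, 0))
  # one 00 and one 11 copy: double heterozygote
  smp$D <- rbind(c(1, 0, 0, 1))
  expect_equal(as.numeric(genotypes_from_diplotypes(smp)$G), c(1, 1))
})

test_that("genotype conversion equals a brute-force per-individual sum", {
  set.seed(41)
  hs <- random_system(m = 3, k = 5)
  smp <- sample_diplotypes(hs, 50)
  G <- genotypes_from_diplotypes(smp)$G
  for (i in 1:50) {
    manual <- colSums(hs$H * smp$D[i, ])
    expect_equal(as.numeric(G[i, ]), manual)
  }
})

test_that("allele frequencies aggregate haplotype frequencies", {
  expect_equal(allele_frequencies(sys_le()), c(0.60, 0.75))
  one <- haplotype_system(rbind(c(1, 0, 1)), 1)
  expect_equal(allele_frequencies(one), c(1, 0, 1))
  full3 <- haplotype_system(as.matrix(expand.grid(0:1, 0:1, 0:1)),
                            rep(1 / 8, 8))
  expect_equal(allele_frequencies(full3), rep(0.5, 3))
})

test_that("pairwise LD reproduces the reference frequency sets", {
  expect_equal(pairwise_ld(sys_le(), 1, 2)$r2, 0, tolerance = 1e-12)
  hs_ld <- haplotype_system(H4, c(0.42, 0.18, 0.10, 0.30))
  expect_equal(pairwise_ld(hs_ld, 1, 2)$r2, 0.1947115, tolerance = 1e-6)
  expect_equal(pairwise_ld(sys_uniform(), 1, 2)$r2, 0)
  expect_error(pairwise_ld(sys_le(), 1, 1), "differ")
  mono <- haplotype_system(rbind(c(1, 0), c(1, 1)), c(0.5, 0.5))
  expect_error(pairwise_ld(mono, 1, 2), "monomorphic")
})

test_that("haplotype variance follows the frequency-weighted formula", {
  expect_equal(haplotype_variance(sys_le(beta = c(1, 0, 0, 0))), 0.18)
  expect_equal(haplotype_variance(sys_le(beta = rep(3, 4))), 0)
  expect_equal(haplotype_variance(sys_le(beta = rep(0, 4))), 0)
  expect_error(haplotype_variance(sys_le()), "beta")
})

test_that("haplotype variance equals exact diplotype enumeration", {
  set.seed(7)
  for (rep in 1:20) {
    hs <- random_system(m = 2, k = sample(3:4, 1))
    en <- regjoint:::enumerate_diplotypes(hs)
    vals <- as.numeric(en$counts %*% hs$beta)
    expect_equal(haplotype_variance(hs),
                 sum(en$prob * vals^2) - sum(en$prob * vals)^2,
                 tolerance = 1e-12)
  }
})

test_that("captured variance respects design nesting and the haplotype bound", {
  set.seed(11)
  for (rep in 1:15) {
    hs <- random_system(m = sample(2:3, 1), k = sample(3:6, 1))
    s2H <- haplotype_variance(hs)
    va <- population_captured_variance(hs, "additive")
    vi <- population_captured_variance(hs, "interaction")
    vg <- population_captured_variance(hs, "genotypic")
    vh <- population_captured_variance(hs, "haplotype_prob")
    expect_lte(va, vi + 1e-10)
    expect_lte(vi, vg + 1e-10)
    expect_lte(vh, vg + 1e-10)
    expect_lte(vg, s2H + 1e-10)
    expect_gte(va, -1e-12)
  }
})

test_that("strictly additive effects are fully captured by the additive design", {
  hs0 <- sys_le()
  alpha <- c(0.3, -0.7)
  hs <- haplotype_system(hs0$H, hs0$pi, beta = as.numeric(hs0$H %*% alpha))
  expect_equal(population_captured_variance(hs, "additive"),
               haplotype_variance(hs), tolerance = 1e-12)
})

test_that("genotypic captured variance is the variance of the class means", {
  hs <- sys_uniform(beta = c(0, 0, 0, 1))
  en <- regjoint:::enumerate_diplotypes(hs)
  vals <- as.numeric(en$counts %*% hs$beta)
  cls <- apply(en$G, 1, paste, collapse = ",")
  cm <- tapply(en$prob * vals, cls, sum) / tapply(en$prob, cls, sum)
  pg <- tapply(en$prob, cls, sum)
  expect_equal(population_captured_variance(hs, "genotypic"),
               sum(pg * cm^2) - sum(pg * cm)^2, tolerance = 1e-12)
})

test_that("additive captured variance matches a Monte-Carlo regression", {
  set.seed(3)
  hs <- sys_uniform(beta = c(0, 0, 0, 1))
  smp <- sample_diplotypes(hs, 2e5)
  G <- genotypes_from_diplotypes(smp)$G
  signal <- as.numeric(smp$D %*% hs$beta)
  fit <- stats::lm(signal ~ G)
  mc <- stats::var(stats::fitted(fit)) * (2e5 - 1) / 2e5
  expect_equal(population_captured_variance(hs, "additive"), mc,
               tolerance = 0.02)
})

test_that("sampled allele and LD frequencies agree with the population", {
  set.seed(19)
  hs <- sys_le()
  n <- 1e5
  smp <- sample_diplotypes(hs, n)
  emp_pi <- colSums(smp$D) / (2 * n)
  se <- sqrt(hs$pi * (1 - hs$pi) / (2 * n))
  expect_true(all(abs(emp_pi - hs$pi) < 4 * se))
  G <- genotypes_from_diplotypes(smp)$G
  xi_emp <- colMeans(G) / 2
  xi <- allele_frequencies(hs)
  expect_true(all(abs(xi_emp - xi) < 4 * sqrt(xi * (1 - xi) / (2 * n))))
})

test_that("haplotype systems round-trip through TSV", {
  hs <- sys_le(beta = c(0.1, -0.2, 0.3, 0))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_haplotype_system(hs, path)
  back <- read_haplotype_system(path)
  expect_equal(back$H, hs$H, ignore_attr = TRUE)
  expect_equal(back$pi, hs$pi)
  expect_equal(back$beta, hs$beta)
})
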