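test_that("tau is zero for strictly additive effects and scale-invariant", {
  hs0 <- sys_le()
  hs <- haplotype_system(hs0$H, hs0$pi,
                         beta = as.numeric(hs0$H %*% c(0.4, -0.2)))
  prof <- nonadditivity(hs)
  expect_equal(prof$tau, 0, tolerance = 1e-10)
  hs_na <- sys_uniform(beta = c(0, 0, 0, 1))
  p1 <- nonadditivity(hs_na)
  p2 <- nonadditivity(haplotype_system(hs_na$H, hs_na$pi,
                                       beta = -3.7 * hs_na$beta))
  expect_equal(p1$tau, p2$tau, tolerance = 1e-12)
  expect_error(nonadditivity(sys_le(beta = rep(0, 4))), "undefined")
})

test_that("tau equals one minus the additive projection from enumeration", {
  hs <- sys_uniform(beta = c(0, 0, 0, 1))
  s2H <- haplotype_variance(hs)
  s2G <- population_captured_variance(hs, "additive")
  expect_equal(nonadditivity(hs)$tau, (s2H - s2G) / s2H)
})

test_that("tau_max vanishes when the additive span saturates (k = 3)", {
  hs3 <- haplotype_system(rbind(c(0, 0), c(0, 1), c(1, 0)),
                          c(0.5, 0.3, 0.2))
  expect_lt(tau_max(hs3)$tau_max, 1e-10)
  expect_error(effect_path(hs3, 0.01, 0.5), "attainable")
  # tau' = 0 still constructible
  b <- effect_path(hs3, 0.01, 0)
  expect_equal(haplotype_variance(haplotype_system(hs3$H, hs3$pi, beta = b)),
               0.01, tolerance = 1e-10)
})

test_that("closed-form tau_max dominates a dense random search", {
  set.seed(51)
  for (rep in 1:5) {
    hs <- random_system(m = 2, k = 4, with_beta = FALSE)
    tm <- tau_max(hs, identifiable = FALSE)
    best <- 0
    for (i in 1:4000) {
      b <- rnorm(4)
      s <- haplotype_system(hs$H, hs$pi, beta = b)
      s2H <- haplotype_variance(s)
      if (s2H < 1e-8) next
      best <- max(best, (s2H - population_captured_variance(s, "additive")) / s2H)
    }
    expect_gte(tm$tau_max + 1e-6, best)
    # the maximizing vector attains the maximum
    s_star <- haplotype_system(hs$H, hs$pi, beta = tm$beta_star)
    t_star <- (haplotype_variance(s_star) -
                 population_captured_variance(s_star, "additive")) /
      haplotype_variance(s_star)
    expect_equal(t_star, tm$tau_max, tolerance = 1e-8)
  }
})

test_that("tau_max is invariant to the variance at which beta_star is scaled", {
  hs <- sys_le()
  expect_equal(tau_max(hs, sigma2_H = 1)$tau_max,
               tau_max(hs, sigma2_H = 0.006)$tau_max, tolerance = 1e-12)
})

test_that("the identifiable maximum never exceeds the unconstrained one,
           and its signal is genotype-expressible", {
  set.seed(53)
  for (rep in 1:5) {
    hs <- random_system(m = 2, k = 4, with_beta = FALSE)
    tid <- tau_max(hs, identifiable = TRUE)
    tun <- tau_max(hs, identifiable = FALSE)
    expect_lte(tid$tau_max, tun$tau_max + 1e-10)
    s <- haplotype_system(hs$H, hs$pi, beta = tid$beta_star)
    expect_equal(population_captured_variance(s, "genotypic"),
                 haplotype_variance(s), tolerance = 1e-10)
  }
})

test_that("effect_path hits requested tau' and variance on random systems", {
  set.seed(52)
  for (rep in 1:3) {
    hs <- random_system(m = 2, k = 4, with_beta = FALSE)
    if (tau_max(hs)$tau_max < 0.05) next
    for (t in seq(0, 1, by = 0.2)) {
      b <- effect_path(hs, 0.006, t)
      s <- haplotype_system(hs$H, hs$pi, beta = b)
      expect_equal(haplotype_variance(s), 0.006, tolerance = 1e-10)
      expect_equal(nonadditivity(s)$tau_prime, t, tolerance = 1e-6)
    }
  }
})

test_that("captured variance declines with tau' and the genotypic ceiling
           dominates the additive design", {
  hs <- sys_le()
  grid <- seq(0, 1, by = 0.25)
  va <- vg <- vh <- numeric(length(grid))
  for (i in seq_along(grid)) {
    s <- haplotype_system(hs$H, hs$pi,
                          beta = effect_path(hs, 0.006, grid[i]))
    va[i] <- population_captured_variance(s, "additive")
    vg[i] <- population_captured_variance(s, "genotypic")
    vh[i] <- population_captured_variance(s, "haplotype_prob")
  }
  expect_equal(va[1], 0.006, tolerance = 1e-10)  # tau' = 0: fully additive
  expect_true(all(diff(va) < 1e-10))             # additive capture decays
  expect_lt(va[length(grid)], 0.9 * va[1])
  # genotype-saturated designs share a ceiling that dominates additive but
  # loses the pure-phase component at tau' > 0
  expect_equal(vg, vh, tolerance = 1e-8)
  expect_true(all(vg >= va - 1e-10))
  expect_true(all(vg <= 0.006 + 1e-10))
  expect_gt(vg[3] - va[3], 1e-4)
})

test_that("non-central F power behaves like a power function", {
  expect_equal(analytic_power_f(1000, 0, 2, 0.05), 0.05, tolerance = 1e-10)
  pw_n <- sapply(c(500, 2000, 8000), analytic_power_f, r2 = 0.005,
                 df1 = 2, alpha = 5e-5)
  expect_true(all(diff(pw_n) > 0))
  pw_r <- sapply(c(0.002, 0.006, 0.02), function(r)
    analytic_power_f(5000, r, 2, 5e-5))
  expect_true(all(diff(pw_r) > 0))
  expect_error(analytic_power_f(3, 0.1, 5, 0.05), "df2")
})

test_that("power_table covers the requested grid", {
  tab <- power_table(n = c(1000, 5000), r2 = c(0.002, 0.006), df1 = 2,
                     alpha = 5e-5)
  expect_equal(nrow(tab), 4L)
  expect_true(all(tab$power >= 0 & tab$power <= 1))
})
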