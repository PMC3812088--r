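test_that("Akaike weights follow the closed forms", {
  cmp <- aic_weights(list(a = list(d = 3, logCL = -1000),
                          b = list(d = 3, logCL = -1000)))
  expect_equal(cmp$weight, c(0.5, 0.5))
  expect_equal(sum(cmp$weight), 1)

  # dAIC = 2 gives a weight ratio of exp(-1)
  cmp2 <- aic_weights(list(a = list(d = 3, logCL = -1000),
                           b = list(d = 4, logCL = -1000)))
  expect_equal(cmp2$weight[2] / cmp2$weight[1], exp(-1))
  expect_equal(cmp2$AIC, c(2 * 3 + 2000, 2 * 4 + 2000))
  # the minimum-AIC model carries the largest weight
  expect_equal(which.max(cmp2$weight), which.min(cmp2$AIC))
})

test_that("Akaike weights are invariant to a constant logCL shift", {
  m <- list(a = list(d = 2, logCL = -500), b = list(d = 5, logCL = -490))
  shifted <- lapply(m, function(x) list(d = x$d, logCL = x$logCL + 1234.5))
  expect_equal(aic_weights(m)$weight, aic_weights(shifted)$weight)
})

test_that("parametric bootstrap produces ordered intervals around the estimate", {
  set.seed(51)
  obs <- simulate_sfs(const_deme(15, 8000), num_loci = 8000,
                      locus_length = 50, mu = 2.5e-8)
  cfg <- ecm_config(cycles = 3, runs = 2, z_start = 2000, z_end = 4000,
                    boot_runs = 2)
  fit <- sfs_fit(obs, one_param_space(15), config = cfg, seed = 13)
  bt <- bootstrap_ci(fit, B = 8, seed = 17)
  expect_equal(nrow(bt$ci), 1)
  expect_lt(bt$ci[1, 1], bt$ci[1, 2])
  expect_equal(bt$failed, 0)
  # the interval sits in the right neighbourhood
  expect_gt(bt$ci["N", 2], 0.5 * coef(fit)[["N"]])
  expect_lt(bt$ci["N", 1], 2.0 * coef(fit)[["N"]])
  # confint method returns the same shape
  ci <- confint(fit, B = 4, runs = 2)
  expect_equal(dim(ci), c(1L, 2L))
})

test_that("interval width shrinks with dataset size", {
  set.seed(52)
  cfg <- ecm_config(cycles = 3, runs = 2, z_start = 2000, z_end = 4000,
                    boot_runs = 2)
  w <- vapply(c(2000, 30000), function(nl) {
    obs <- simulate_sfs(const_deme(15, 8000), num_loci = nl,
                        locus_length = 50, mu = 2.5e-8)
    fit <- sfs_fit(obs, one_param_space(15), config = cfg, seed = 19)
    bt <- bootstrap_ci(fit, B = 8, seed = 23)
    diff(log(bt$ci[1, ]))
  }, 0)
  expect_lt(w[2], w[1])
})

test_that("multinomial and per-locus bootstrap data paths agree", {
  set.seed(53)
  obs <- simulate_sfs(const_deme(12, 6000), num_loci = 10000,
                      locus_length = 50, mu = 2.5e-8)
  cfg <- ecm_config(cycles = 3, runs = 2, z_start = 2000, z_end = 20000)
  fit <- sfs_fit(obs, one_param_space(12), config = cfg, seed = 29)
  a <- simulate(fit, nsim = 40, method = "multinomial")
  b <- simulate(fit, nsim = 40, method = "loci")
  Sa <- vapply(a, `[[`, 0, "S")
  Sb <- vapply(b, `[[`, 0, "S")
  # same expected number of SNPs within Monte Carlo error
  expect_lt(abs(mean(Sa) - mean(Sb)) / mean(Sb), 0.1)
  pa <- rowMeans(vapply(a, function(o) o$counts[2:12] / o$S, numeric(11)))
  pb <- rowMeans(vapply(b, function(o) o$counts[2:12] / o$S, numeric(11)))
  expect_lt(tvd(pa, pb), 0.03)
})

test_that("an observed spectrum proportional to the expectation gives G near zero", {
  set.seed(54)
  d <- const_deme(12, 6000)
  e <- expected_sfs(d, Z = 100000, mu = 2.5e-8)
  S <- 5000; L <- 500000
  counts <- numeric(length(e$probs))
  counts[2:12] <- round(S * e$probs[2:12] / sum(e$probs[2:12]))
  obs <- observed_sfs(counts, dims = 12, L = L)
  sat <- saturated_loglik(obs, use_monomorphic = FALSE)
  e2 <- expected_sfs(d, Z = 100000, mu = 2.5e-8)
  cl <- composite_loglik(obs, e2, use_monomorphic = FALSE)
  G <- 2 * (sat$logCL - cl$logCL)
  expect_gte(G, -1e-6)
  expect_lt(G, 8)  # chi-square-scale noise only, no systematic misfit
})

test_that("gof_test assembles the statistic and null distribution coherently", {
  set.seed(55)
  obs <- simulate_sfs(const_deme(10, 5000), num_loci = 4000,
                      locus_length = 50, mu = 2.5e-8)
  cfg <- ecm_config(cycles = 2, runs = 2, z_start = 2000, z_end = 4000,
                    boot_runs = 1)
  fit <- sfs_fit(obs, one_param_space(10), config = cfg, seed = 31)
  gt <- gof_test(fit, B = 6, rescore = 3, seed = 37)
  expect_gte(gt$p_value, 0)
  expect_lte(gt$p_value, 1)
  expect_length(gt$G_null, 6)
  expect_true(all(is.finite(gt$G_null)))
  expect_gte(gt$G_obs, 0)
})
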