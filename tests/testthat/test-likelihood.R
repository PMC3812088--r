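test_that("multinomial part matches hand computation", {
  o <- observed_sfs(c(0, 3, 1, 0), dims = 3)
  e <- fixture_exp_sfs(c(0, 0.75, 0.25, 0), dims = 3)
  cl <- composite_loglik(o, e, use_monomorphic = FALSE)
  expect_equal(cl$logCL, 3 * log(0.75) + log(0.25))
  expect_equal(cl$logCL, sum(cl$per_entry))

  sat <- saturated_loglik(o, use_monomorphic = FALSE)
  expect_equal(sat$logCL, 3 * log(0.75) + log(0.25))  # same frequencies
})

test_that("monomorphic terms add the binomial split over sites", {
  o <- observed_sfs(c(0, 3, 1, 0), dims = 3, L = 100)
  e <- fixture_exp_sfs(c(0, 0.75, 0.25, 0), dims = 3, p0 = 0.95)
  cl <- composite_loglik(o, e, use_monomorphic = TRUE)
  expect_equal(cl$mono, 96 * log(0.95) + 4 * log(0.05))
  expect_equal(cl$logCL, cl$mono + 3 * log(0.75) + log(0.25))
  # all-monomorphic limit: logCL = L log p0 needs S = 0, which the
  # saturated likelihood rejects but the composite one handles
  o0 <- observed_sfs(c(100, 0, 0, 0), dims = 3, L = 100)
  cl0 <- composite_loglik(o0, e, use_monomorphic = TRUE)
  expect_equal(cl0$logCL, 100 * log(0.95))
  expect_error(saturated_loglik(o0), "at least one polymorphic")
})

test_that("missing ingredients for the monomorphic mode are errors", {
  o <- observed_sfs(c(0, 3, 1, 0), dims = 3)  # no L
  e <- fixture_exp_sfs(c(0, 0.75, 0.25, 0), dims = 3)
  expect_error(composite_loglik(o, e, use_monomorphic = TRUE), "L")
  o2 <- observed_sfs(c(0, 3, 1, 0), dims = 3, L = 100)
  expect_error(composite_loglik(o2, e, use_monomorphic = TRUE), "p0")
})

test_that("zero-probability classes are floored or rejected", {
  o <- observed_sfs(c(0, 3, 1, 0), dims = 3)
  e <- fixture_exp_sfs(c(0, 1, 0, 0), dims = 3)
  expect_error(composite_loglik(o, e, use_monomorphic = FALSE, floor = 0),
               "zero expected")
  cl <- composite_loglik(o, e, use_monomorphic = FALSE, floor = 1e-12)
  expect_equal(cl$logCL, 3 * log(1) + log(1e-12))
  expect_length(cl$floored_entries, 1)
})

test_that("saturated likelihood dominates any model likelihood", {
  set.seed(33)
  for (i in 1:20) {
    x <- rmultinom(1, 500, c(0.4, 0.3, 0.2, 0.1))[, 1]
    o <- observed_sfs(c(0, x, 0), dims = 5)
    p <- runif(4); p <- p / sum(p)
    e <- fixture_exp_sfs(c(0, p, 0), dims = 5)
    expect_gte(saturated_loglik(o, use_monomorphic = FALSE)$logCL + 1e-8,
               composite_loglik(o, e, use_monomorphic = FALSE)$logCL)
  }
})

test_that("permuting entries of obs and exp together leaves logCL unchanged", {
  set.seed(34)
  x <- c(0, rpois(8, 20), 0)
  p <- c(0, runif(8), 0); p[2:9] <- p[2:9] / sum(p[2:9])
  o1 <- observed_sfs(x, dims = 9)
  e1 <- fixture_exp_sfs(p, dims = 9)
  # permute the interior entries consistently
  perm <- c(1, sample(2:9), 10)
  o2 <- observed_sfs(x[perm], dims = 9)
  e2 <- fixture_exp_sfs(p[perm], dims = 9)
  expect_equal(composite_loglik(o1, e1, use_monomorphic = FALSE)$logCL,
               composite_loglik(o2, e2, use_monomorphic = FALSE)$logCL)
})

test_that("collapsing never increases class count and conserves mass", {
  set.seed(35)
  x <- c(0, rpois(12, 3), 0)
  p <- c(0, runif(12), 0); p[2:13] <- p[2:13] / sum(p[2:13])
  o <- observed_sfs(x, dims = 13)
  e <- fixture_exp_sfs(p, dims = 13)
  prev <- Inf
  for (eps in c(0, 1, 2, 5, 10)) {
    cl <- collapse_entries(o, e, eps)
    expect_lte(length(cl$counts), prev)
    prev <- length(cl$counts)
    expect_equal(sum(cl$counts), o$S)
    expect_equal(sum(cl$probs), sum(p[2:13]))
  }
})

test_that("pairwise product equals the joint 2-D likelihood for two demes", {
  set.seed(36)
  d <- divergence_demes(n1 = 5, n2 = 5)
  e <- expected_sfs(d, Z = 3000)
  obs <- simulate_sfs(d, num_loci = 3000, locus_length = 50, mu = 2.5e-8)
  single <- composite_loglik(obs, e, use_monomorphic = FALSE)
  pw <- pairwise_loglik(obs, e)
  expect_equal(pw$logCL, single$logCL)
})

test_that("pairwise product over three demes adds the three pair terms", {
  set.seed(37)
  d <- demography(sample_sizes = c(4, 4, 4), sizes = 2000, events = list(
    hist_event(time = 500, source = 2, sink = 1, proportion = 1),
    hist_event(time = 900, source = 3, sink = 1, proportion = 1)))
  e <- expected_sfs(d, Z = 3000)
  obs <- simulate_sfs(d, num_loci = 3000, locus_length = 50, mu = 2.5e-8)
  pw <- pairwise_loglik(obs, e)
  pairs <- rbind(c(1, 2), c(1, 3), c(2, 3))
  by_hand <- sum(vapply(1:3, function(i)
    composite_loglik(marginal_pair(obs, pairs[i, ]),
                     marginal_pair(e, pairs[i, ]),
                     use_monomorphic = FALSE)$logCL, 0))
  expect_equal(pw$logCL, by_hand)
  expect_length(pw$per_entry, 3)
})

test_that("without monomorphic terms the likelihood is exactly multinomial", {
  # the no-monomorphic composite likelihood must equal the multinomial
  # log-likelihood (up to the data-only multinomial coefficient) computed
  # by dmultinom on the same class probabilities
  set.seed(38)
  d <- bottleneck_deme(n = 8)
  e <- expected_sfs(d, Z = 5000)
  obs <- simulate_sfs(d, num_loci = 4000, locus_length = 50, mu = 2.5e-8)
  idx <- 2:8
  x <- obs$counts[idx]
  p <- e$probs[idx] / sum(e$probs[idx])
  ref <- stats::dmultinom(x, prob = p, log = TRUE) -
    lgamma(obs$S + 1) + sum(lgamma(x + 1))
  cl <- composite_loglik(obs, e, use_monomorphic = FALSE)
  expect_equal(cl$logCL, ref, tolerance = 1e-10)
})
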