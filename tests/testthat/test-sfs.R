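test_that("observed SFS container tracks S, L and the absorbing mask", {
  o <- observed_sfs(c(0, 120, 55, 30, 0), dims = 4)
  expect_equal(o$S, 205)
  expect_equal(o$mask, c(1L, 5L))
  expect_error(observed_sfs(c(0, 10, 0), dims = 2, L = 5), "smaller")
  # known monomorphic count fills the all-ancestral cell
  o2 <- observed_sfs(c(0, 10, 5, 0), dims = 3, L = 1000)
  expect_equal(o2$counts[1], 985)
  # array input round-trips through the dense vector
  m <- matrix(1:12, nrow = 3)  # dims (2, 3)
  o3 <- observed_sfs(m, L = NA)
  expect_equal(as.array(o3), m)
})

test_that("a two-lineage sample has a single frequency class", {
  set.seed(4)
  e <- expected_sfs(demography(sample_sizes = 2, sizes = 1000), Z = 50)
  expect_equal(e$probs, c(0, 1, 0))  # exact for any Z
})

test_that("constant-size spectrum matches the 1/i closed form", {
  set.seed(14)
  e <- expected_sfs(const_deme(20, 10000), Z = 30000)
  expect_lt(max(abs(e$probs[2:20] - neutral_probs(20))), 0.01)
  expect_equal(sum(e$probs), 1)
})

test_that("probabilities sum to one exactly, with and without ascertainment", {
  set.seed(15)
  d <- divergence_demes(n1 = 6, n2 = 6)
  e <- expected_sfs(d, Z = 2000)
  expect_equal(sum(e$probs), 1, tolerance = 1e-12)
  ea <- expected_sfs(d, Z = 2000, ascertainment = ascertainment(1))
  expect_equal(sum(ea$probs), 1, tolerance = 1e-12)
})

test_that("p0 behaves like the Poisson zero class", {
  expect_equal(estimate_p0(c(100, 200, 300), mu = 0, L = 50), 1)
  # monotone decay to zero in mu * L
  T <- c(1000, 5000, 2000)
  p <- vapply(c(1e-6, 1e-5, 1e-4, 1e-3), function(m)
    estimate_p0(T, m, 50), 0)
  expect_true(all(diff(p) < 0))
  expect_lt(p[4], 1e-10)
  # n = 2, constant N: p0 = 1/(1 + 4 N mu L) by exponential TMRCA
  set.seed(16)
  N <- 5000; mu <- 2.5e-8; L <- 50
  e <- expected_sfs(demography(sample_sizes = 2, sizes = N), Z = 60000,
                    mu = mu, locus_length = L)
  expect_equal(e$p0, 1 / (1 + 4 * N * mu * L), tolerance = 0.005)
})

test_that("entry collapsing pools rare classes and conserves totals", {
  o <- observed_sfs(c(0, 10, 3, 1, 0, 0), dims = 5)
  e <- fixture_exp_sfs(c(0, 0.5, 0.3, 0.15, 0.05, 0), dims = 5)
  un <- collapse_entries(o, e, epsilon = 0)
  expect_false(un$pooled)
  expect_equal(un$counts, c(10, 3, 1, 0))

  cl <- collapse_entries(o, e, epsilon = 2)
  expect_true(cl$pooled)
  expect_equal(cl$counts, c(10, 3, 1))
  expect_equal(cl$probs, c(0.5, 0.3, 0.2))
  expect_equal(sum(cl$counts), sum(un$counts))
  expect_equal(sum(cl$probs), sum(un$probs))

  o2 <- observed_sfs(c(0, 1, 2, 0), dims = 3)
  expect_error(collapse_entries(o2, e, 1), "dims differ")
})

test_that("branch-ratio and mutation-dropping estimators agree (oracle)", {
  # The Eq-for-probabilities estimator vs empirical frequency-class
  # proportions of dropped mutations, under a non-equilibrium model.
  set.seed(23)
  d <- bottleneck_deme(n = 12)
  e <- expected_sfs(d, Z = 60000)
  obs <- simulate_sfs(d, num_loci = 20000, locus_length = 50, mu = 2.5e-8)
  idx <- 2:12
  emp <- obs$counts[idx] / obs$S
  expect_lt(tvd(emp, e$probs[idx]),
            tvd_bound(e$probs[idx], obs$S))
})

test_that("ascertained spectrum of a stationary deme is proportional to n - i", {
  # picking 2 lineages keeps a branch with i descendants with probability
  # 2 i (n-i) / (n (n-1)); combined with branch lengths 1/i this gives
  # class probabilities proportional to (n - i)
  set.seed(24)
  n <- 20
  e <- expected_sfs(const_deme(n, 10000), Z = 40000,
                    ascertainment = ascertainment(1))
  shape <- (n - (1:(n - 1))) / sum(n - (1:(n - 1)))
  expect_lt(max(abs(e$probs[2:n] - shape)), 0.01)
  # depleted in singletons relative to the unascertained 1/i spectrum
  expect_lt(e$probs[2], neutral_probs(n)[1])
})

test_that("subtree estimator matches the heterozygous-site filter (oracle)", {
  set.seed(25)
  d <- bottleneck_deme(n = 12)
  asc <- ascertainment(1)
  e <- expected_sfs(d, Z = 60000, ascertainment = asc)
  obs <- simulate_sfs(d, num_loci = 30000, locus_length = 50, mu = 2e-7,
                      ascertainment = asc)
  idx <- 2:12
  emp <- obs$counts[idx] / obs$S
  expect_lt(tvd(emp, e$probs[idx]), tvd_bound(e$probs[idx], obs$S))
})

test_that("when the whole sample is the two ascertained lineages nothing is excluded", {
  set.seed(26)
  d <- demography(sample_sizes = 2, sizes = 3000)
  e0 <- expected_sfs(d, Z = 4000)
  ea <- expected_sfs(d, Z = 4000, ascertainment = ascertainment(1))
  expect_equal(ea$probs, e0$probs)
  expect_equal(ea$mean_length, ea$mean_T)  # subtree is the whole tree
})

test_that("ascertain_subtree returns the paths joining the two chosen leaves", {
  set.seed(27)
  g <- simulate_genealogy(const_deme(10, 1000))
  sub <- ascertain_subtree(g, ascertainment(1))
  expect_length(sub$leaves, 2)
  expect_true(all(sub$leaves <= 10))
  expect_equal(sub$total_length, sum(sub$lengths))
  expect_lt(sub$total_length, total_tree_length(g))
  # every subtree branch has exactly one chosen leaf below it
  for (j in seq_along(sub$branches)) {
    below <- rowSums(sub$descent)[j]
    expect_true(below >= 1 && below <= 9)
  }
  g2 <- simulate_genealogy(demography(sample_sizes = c(1, 9),
                                      sizes = 1000,
                                      migration = matrix(c(0, 1e-3, 1e-3, 0),
                                                         2, 2)))
  expect_error(ascertain_subtree(g2, ascertainment(1)), "fewer than 2")
})

test_that("replicate spectrum estimates tighten as 1/sqrt(Z)", {
  set.seed(28)
  d <- bottleneck_deme(n = 10)
  spread <- vapply(c(500, 5000, 50000), function(Z) {
    reps <- vapply(1:12, function(i) expected_sfs(d, Z)$probs[2], 0)
    sd(reps)
  }, 0)
  # each 10x in Z shrinks the sd by about sqrt(10); allow generous slack
  expect_lt(spread[2], spread[1] * 0.6)
  expect_lt(spread[3], spread[2] * 0.6)
})
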