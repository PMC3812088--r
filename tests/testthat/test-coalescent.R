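test_that("pair and triple coalescence times match closed forms", {
  # E[TMRCA] = 2N for two lineages, so E[total length] = 4N;
  # for n = 3, E[T] = 4N (1 + 1/2) = 6N. Monte Carlo via the accumulated
  # mean tree length of the expectation engine.
  set.seed(3)
  N <- 5000
  e2 <- expected_sfs(demography(sample_sizes = 2, sizes = N), Z = 60000)
  expect_equal(e2$mean_T, 4 * N, tolerance = 0.02)
  e3 <- expected_sfs(demography(sample_sizes = 3, sizes = N), Z = 60000)
  expect_equal(e3$mean_T, 6 * N, tolerance = 0.02)
})

test_that("simulation refuses non-closable models", {
  iso <- demography(sample_sizes = c(5, 5), sizes = 1000)
  expect_error(simulate_genealogy(iso), "non-closable")
})

test_that("genealogies satisfy the structural tree invariants", {
  set.seed(9)
  d <- divergence_demes(n1 = 6, n2 = 4, T_DIV = 800)
  for (i in 1:20) {
    g <- simulate_genealogy(d)
    n <- g$n
    expect_equal(n, 10)
    # times non-decreasing from leaves to MRCA in coalescence order
    expect_true(all(diff(g$node_time[(n + 1):(2 * n - 1)]) >= 0))
    expect_true(all(g$node_time[1:n] == 0))
    # every non-root branch subtends between 1 and n-1 leaves
    sz <- rowSums(g$descent)[1:(2 * n - 2)]
    expect_true(all(sz >= 1 & sz <= n - 1))
    # parent descent vector is the sum of its children's
    for (v in seq_len(2 * n - 2))
      expect_true(all(g$descent[g$parent[v], ] >=
                        g$descent[v, ]))
    # total length is the sum of child-parent gaps
    gaps <- g$node_time[g$parent[1:(2 * n - 2)]] -
      g$node_time[1:(2 * n - 2)]
    expect_equal(total_tree_length(g), sum(gaps))
  }
})

test_that("two-leaf trees have total length twice the TMRCA", {
  set.seed(5)
  g <- simulate_genealogy(demography(sample_sizes = 2, sizes = 1000))
  expect_equal(total_tree_length(g), 2 * max(g$node_time))
})

test_that("the same seed reproduces a genealogy exactly", {
  d <- bottleneck_deme(n = 10)
  set.seed(123)
  g1 <- simulate_genealogy(d)
  set.seed(123)
  g2 <- simulate_genealogy(d)
  expect_identical(g1, g2)
})

test_that("pair coalescence times are exponential at rate 1/(2N)", {
  set.seed(31)
  N <- 2000
  tm <- replicate(1500, max(simulate_genealogy(
    demography(sample_sizes = 2, sizes = N))$node_time))
  ks <- suppressWarnings(stats::ks.test(tm, "pexp", 1 / (2 * N)))
  expect_gt(ks$p.value, 0.001)
})

test_that("exponential growth uses the exact time change", {
  # backward size N0 exp(-rt): for two lineages the TMRCA CDF is
  # 1 - exp(-(exp(rt) - 1) / (2 N0 r)); compare simulated times to it.
  set.seed(17)
  N0 <- 10000; r <- 0.001
  d <- demography(sample_sizes = 2, sizes = N0, growth = r)
  tm <- replicate(1500, max(simulate_genealogy(d)$node_time))
  cdf <- function(t) 1 - exp(-(exp(r * t) - 1) / (2 * N0 * r))
  ks <- suppressWarnings(stats::ks.test(tm, cdf))
  expect_gt(ks$p.value, 0.001)
})

test_that("mutation dropping is Poisson with the right mean and classes", {
  set.seed(21)
  d <- const_deme(10, 2000)
  g <- simulate_genealogy(d)
  expect_identical(nrow(drop_mutations(g, mu = 0, L = 50)), 0L)

  mu <- 2.5e-8; L <- 50
  nm <- vapply(1:3000, function(i) {
    g <- simulate_genealogy(d)
    nrow(drop_mutations(g, mu, L))
  }, 0L)
  # E[count] = mu * L * E[T], E[T] = 4N * H_9
  expected <- mu * L * 4 * 2000 * sum(1 / (1:9))
  expect_equal(mean(nm), expected, tolerance = 0.1)
})

test_that("relabelling lineages within a deme leaves descent statistics exchangeable", {
  # frequency-class totals from mutation dropping must not depend on which
  # lineages of a deme are 'first'; compare two disjoint halves of the
  # simulation stream
  set.seed(29)
  d <- const_deme(8, 1000)
  freq <- function(reps) {
    acc <- numeric(7)
    for (i in seq_len(reps)) {
      g <- simulate_genealogy(d)
      m <- drop_mutations(g, 1e-5, 50)
      if (nrow(m)) {
        tb <- tabulate(rowSums(m), nbins = 7)
        acc <- acc + tb
      }
    }
    acc / sum(acc)
  }
  f1 <- freq(1500)
  f2 <- freq(1500)
  expect_lt(tvd(f1, f2), 0.05)
})

test_that("newick export is readable and preserves total length", {
  set.seed(2)
  g <- simulate_genealogy(const_deme(6, 500))
  txt <- as_newick(g)
  expect_match(txt, ";$")
  skip_if_not_installed("ape")
  tr <- ape::read.tree(text = txt)
  expect_equal(sum(tr$edge.length), total_tree_length(g), tolerance = 1e-9)
  expect_equal(ape::Ntip(tr), 6)
})
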