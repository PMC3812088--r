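test_that("validation catches structural violations and accepts minimal models", {
  expect_length(validate_demography(const_deme(20, 10000)), 0)

  # two demes that can never exchange lineages cannot fully coalesce
  iso <- demography(sample_sizes = c(10, 10), sizes = 1000)
  expect_match(validate_demography(iso), "non-closable", all = FALSE)

  # a fusion event closes the same model
  ok <- demography(sample_sizes = c(10, 10), sizes = 1000, events = list(
    hist_event(time = 500, source = 2, sink = 1, proportion = 1)))
  expect_length(validate_demography(ok), 0)

  bad_prop <- demography(sample_sizes = c(10, 10), sizes = 1000,
                         events = list(hist_event(100, source = 2, sink = 1,
                                                  proportion = 1.2)))
  expect_match(validate_demography(bad_prop), "proportion out of range",
               all = FALSE)

  bad_size <- demography(sample_sizes = 10, sizes = -5)
  expect_match(validate_demography(bad_size), "positive", all = FALSE)
})

test_that("binding evaluates derived parameters and rounds integer kinds", {
  sp <- bottleneck_space()
  d <- bind_parameters(sp, c(N_CUR = 10000, N_BOT = 100, T_BOT = 1000))
  expect_s3_class(d, "demography")
  expect_equal(d$sizes, 10000)
  # bottleneck starts at 1000 and ends at 1000 + fixed 100-generation duration
  expect_equal(d$events$time, c(1000, 1100))
  expect_equal(d$events$new_size, c(100, 10000))

  # fractional sizes and times are rounded before building
  d2 <- bind_parameters(sp, c(N_CUR = 10000.4, N_BOT = 99.7, T_BOT = 999.9))
  expect_equal(d2$sizes, 10000)
  expect_equal(d2$events$new_size[1], 100)
  expect_equal(d2$events$time, c(1000, 1100))

  expect_error(bind_parameters(sp, c(N_CUR = -5, N_BOT = 100, T_BOT = 1000)),
               "N_CUR")
  expect_error(bind_parameters(sp, c(N_CUR = 1e7, N_BOT = 100, T_BOT = 1000)),
               "outside bounds")
})

test_that("a space with zero free parameters binds to the fixed demography", {
  sp <- parameter_space(
    param("N", "size", value = 5000),
    builder = function(th) demography(sample_sizes = 10, sizes = th$N))
  d <- bind_parameters(sp, numeric(0))
  expect_equal(d$sizes, 5000)
})

test_that("derived-parameter expressions are validated", {
  mk <- function(derived) parameter_space(
    param("A", "time", 10, 100), derived = derived,
    builder = function(th) demography(sample_sizes = 2, sizes = 100))
  expect_error(mk(list(B = "C + 1")), "unknown name")
  expect_error(mk(list(B = "C + 1", C = "B * 2")), "cyclic")
  expect_error(mk(list(B = "exp(A)")), "derived expressions")
  sp <- mk(list(B = "A + 100", C = "min(B, 150)"))
  expect_s3_class(sp, "parameter_space")
})

test_that("initial parameter draws respect scale and are reproducible", {
  sp <- parameter_space(
    param("FIXEDPT", "time", 10, 10),
    param("RATE", "rate", 1e-6, 1e-2),
    param("PROP", "proportion", 0, 1),
    builder = function(th) demography(sample_sizes = 2, sizes = 100))
  set.seed(42)
  th <- sample_initial_parameters(sp)
  expect_equal(th[["FIXEDPT"]], 10)  # degenerate interval
  expect_true(th[["RATE"]] >= 1e-6 && th[["RATE"]] <= 1e-2)
  expect_true(th[["PROP"]] >= 0 && th[["PROP"]] <= 1)

  set.seed(42)
  expect_identical(th, sample_initial_parameters(sp))

  # log-uniform draws on [1e-6, 1e-2] have median 1e-4
  set.seed(1)
  draws <- sample_initial_parameters(sp, n = 10000)[, "RATE"]
  expect_gt(median(draws), 1e-4 / 1.3)
  expect_lt(median(draws), 1e-4 * 1.3)
})

test_that("bind after sample always yields a valid demography and is pure", {
  sp <- bottleneck_space()
  set.seed(7)
  for (i in 1:25) {
    th <- sample_initial_parameters(sp)
    d <- bind_parameters(sp, th)
    expect_length(validate_demography(d), 0)
    expect_identical(d, bind_parameters(sp, th))
  }
})
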