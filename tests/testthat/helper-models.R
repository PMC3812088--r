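# Small model builders shared across tests.

const_deme <- function(n = 20, N = 10000) {
  demography(sample_sizes = n, sizes = N)
}

# Bottleneck at the Fig-1A-style values: current size 10000, size 100
# between generations 1000 and 1100, ancestral 10000 (all diploid).
bottleneck_deme <- function(n = 20, N_CUR = 10000, N_BOT = 100,
                            T_BOT = 1000, dur = 100, N_ANC = 10000) {
  demography(sample_sizes = n, sizes = N_CUR, events = list(
    hist_event(time = T_BOT, sink = 1, new_size = N_BOT),
    hist_event(time = T_BOT + dur, sink = 1, new_size = N_ANC)))
}

divergence_demes <- function(n1 = 20, n2 = 30, N1 = 5000, N2 = 500,
                             N_ANC = 5000, T_DIV = 1000) {
  demography(sample_sizes = c(n1, n2), sizes = c(N1, N2), events = list(
    hist_event(time = T_DIV, source = 2, sink = 1, proportion = 1,
               new_size = N_ANC)))
}

# Neutral constant-size expectation: p_i proportional to 1/i.
neutral_probs <- function(n) {
  p <- 1 / (1:(n - 1))
  p / sum(p)
}

one_param_space <- function(n = 20) {
  parameter_space(
    param("N", "size", 100, 1e6),
    builder = function(th) demography(sample_sizes = n, sizes = th$N))
}

bottleneck_space <- function(n = 20, N_ANC = 10000) {
  parameter_space(
    param("N_CUR", "size", 100, 1e6),
    param("N_BOT", "size", 1, 1e4),
    param("T_BOT", "time", 10, 1e5),
    param("N_ANC", "size", value = N_ANC),
    derived = list(T_END = "T_BOT + 100"),
    builder = function(th)
      demography(sample_sizes = n, sizes = th$N_CUR, events = list(
        hist_event(time = th$T_BOT, sink = 1, new_size = th$N_BOT),
        hist_event(time = th$T_END, sink = 1, new_size = th$N_ANC))))
}

# Wrap a probability vector as an expected-SFS object (deterministic fixture).
fixture_exp_sfs <- function(probs, dims, p0 = NA_real_) {
  structure(list(dims = as.integer(dims), probs = probs, p0 = p0, Z = 1L,
                 mean_T = NA_real_, mean_length = NA_real_,
                 ascertained = FALSE), class = "exp_sfs")
}

# Total-variation distance between two probability vectors.
tvd <- function(p, q) 0.5 * sum(abs(p - q))

# Monte-Carlo TVD acceptance bound: the 99.5th percentile of the TVD between
# the reference probabilities and a multinomial sample of size S from them.
tvd_bound <- function(p, S, reps = 400, q = 0.995) {
  sims <- vapply(seq_len(reps), function(i) {
    x <- as.numeric(rmultinom(1, S, p))
    tvd(x / S, p)
  }, 0)
  as.numeric(quantile(sims, q))
}
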