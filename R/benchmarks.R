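#' Simulate a pseudo-observed site frequency spectrum
#'
#' Generates an observed spectrum by direct simulation: `num_loci`
#' independent (unlinked, non-recombining) genealogies, each carrying
#' `Poisson(mu * locus_length * T)` infinite-sites mutations placed uniformly
#' along branches. With an [ascertainment()] scheme, only mutations falling
#' on branches through which exactly one of two randomly chosen lineages of
#' the ascertained deme descends -- the sites heterozygous between the two
#' chromosomes of the discovery individual -- are retained; this filters true
#' mutation placements directly and therefore serves as an independent check
#' of the subtree-based expected-SFS estimator. The monomorphic count is
#' recorded in the all-ancestral cell (unascertained case only; an
#' ascertained panel reports no monomorphic sites, so `L` is `NA`).
#'
#' @param d a [demography()] or a [scenario_preset()].
#' @param num_loci number of independent loci.
#' @param locus_length length of each locus, bp.
#' @param mu per-site per-generation mutation rate.
#' @param ascertainment optional [ascertainment()].
#' @param tmax simulation time cap.
#' @return an [observed_sfs()], with `L = num_loci * locus_length` (or `NA`
#'   under ascertainment).
#' @examples
#' d <- demography(sample_sizes = 10, sizes = 5000)
#' obs <- simulate_sfs(d, num_loci = 2000, locus_length = 50, mu = 2.5e-8)
#' @export
simulate_sfs <- function(d, num_loci = NULL, locus_length = NULL,
                         mu = NULL, ascertainment = NULL, tmax = 1e12) {
  if (inherits(d, "scenario_preset")) {
    p <- d
    return(simulate_sfs(p$demography, num_loci = num_loci %||% p$num_loci,
                        locus_length = locus_length %||% p$locus_length,
                        mu = mu %||% p$mu,
                        ascertainment = ascertainment %||% p$ascertainment,
                        tmax = tmax))
  }
  num_loci <- num_loci %||% 400000L
  locus_length <- locus_length %||% 50
  mu <- mu %||% 2.5e-8
  check_valid_demography(d)
  asc_deme <- if (is.null(ascertainment)) -1L else ascertainment$deme - 1L
  raw <- cpp_pseudo_sfs(as_cpp_model(d), as.integer(num_loci), mu,
                        locus_length, asc_deme, tmax)
  L <- if (is.null(ascertainment)) num_loci * locus_length else NA
  observed_sfs(raw$counts, dims = d$sample_sizes, L = L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benchmark scenario presets
#'
#' Fully specified simulation scenarios used to exercise parameter recovery,
#' each bundling a true demography, the matching estimation
#' [parameter_space()] (search ranges spanning four orders of magnitude on a
#' log10 scale), the data-generation settings and, where relevant, an
#' ascertainment scheme.
#'
#' `"bottleneck"`: one deme, n = 20 lineages; current size 10000 diploids,
#' bottleneck size 100 between generations 1000 and 1100, ancestral size
#' 10000 (fixed in estimation, as is the 100-generation duration). Free:
#' `N_CUR`, `N_BOT`, `T_BOT`.
#'
#' `"divergence_no_mig"`: two demes (n1 = 20, n2 = 30) of diploid sizes 5000
#' and 500 (2N = 10000 and 1000) that split from an ancestral population of
#' diploid size 5000 at `t_div` generations (default 1000, i.e. 0.1 in
#' units of 2N ancestral; 10 and 100000 are the other standard settings).
#' Free: `N1`, `N2`, `N_ANC`, `T_DIV`.
#'
#' `"im"`: two-population isolation-with-migration; `"three_pop_growth"`:
#' three-population divergence with growth and migration;
#' `"hierarchical_islands"`: two continent-island systems with ten sampled
#' islands; `"asc_divergence"`: two-population divergence observed through a
#' SNP panel ascertained in deme 1. The true parameter values of these last
#' four are plausible defaults chosen for this package's benchmarks and are
#' user-editable via the returned object.
#'
#' @param name one of `"bottleneck"`, `"divergence_no_mig"`, `"im"`,
#'   `"three_pop_growth"`, `"hierarchical_islands"`, `"asc_divergence"`.
#' @param t_div divergence time override for `"divergence_no_mig"`.
#' @return a `"scenario_preset"`: list with `name`, `demography` (at the true
#'   values), `true_theta`, `space`, `num_loci`, `locus_length`, `mu`,
#'   `ascertainment`.
#' @export
scenario_preset <- function(name = c("bottleneck", "divergence_no_mig", "im",
                                     "three_pop_growth",
                                     "hierarchical_islands",
                                     "asc_divergence"),
                            t_div = 1000) {
  name <- match.arg(name)
  preset <- switch(name,
    bottleneck = {
      space <- parameter_space(
        param("N_CUR", "size", 100, 1e6),
        param("N_BOT", "size", 1, 1e4),
        param("T_BOT", "time", 10, 1e5),
        param("N_ANC", "size", value = 10000),
        derived = list(T_END = "T_BOT + 100"),
        builder = function(th)
          demography(sample_sizes = 20, sizes = th$N_CUR, events = list(
            hist_event(time = th$T_BOT, sink = 1, new_size = th$N_BOT),
            hist_event(time = th$T_END, sink = 1, new_size = th$N_ANC))))
      list(true_theta = c(N_CUR = 10000, N_BOT = 100, T_BOT = 1000),
           space = space, num_loci = 400000L, locus_length = 50, mu = 2.5e-8,
           ascertainment = NULL)
    },
    divergence_no_mig = {
      space <- parameter_space(
        param("N1", "size", 50, 5e5),
        param("N2", "size", 5, 5e4),
        param("N_ANC", "size", 50, 5e5),
        param("T_DIV", "time", 10, 1e5),
        builder = function(th)
          demography(sample_sizes = c(20, 30), sizes = c(th$N1, th$N2),
                     events = list(
            hist_event(time = th$T_DIV, source = 2, sink = 1, proportion = 1,
                       new_size = th$N_ANC))))
      list(true_theta = c(N1 = 5000, N2 = 500, N_ANC = 5000, T_DIV = t_div),
           space = space, num_loci = 400000L, locus_length = 50, mu = 2.5e-8,
           ascertainment = NULL)
    },
    im = {
      space <- parameter_space(
        param("N1", "size", 100, 1e6),
        param("N2", "size", 100, 1e6),
        param("N_ANC", "size", 100, 1e6),
        param("T_DIV", "time", 10, 1e5),
        param("M12", "rate", 1e-6, 1e-2),
        param("M21", "rate", 1e-6, 1e-2),
        builder = function(th) {
          mig <- matrix(c(0, th$M12, th$M21, 0), 2, 2, byrow = TRUE)
          demography(sample_sizes = c(20, 30), sizes = c(th$N1, th$N2),
                     migration = mig, events = list(
            hist_event(time = th$T_DIV, source = 2, sink = 1, proportion = 1,
                       new_size = th$N_ANC)))
        })
      list(true_theta = c(N1 = 10000, N2 = 5000, N_ANC = 10000, T_DIV = 2000,
                          M12 = 1e-4, M21 = 5e-5),
           space = space, num_loci = 400000L, locus_length = 50, mu = 2.5e-8,
           ascertainment = NULL)
    },
    three_pop_growth = {
      # African-like deme 1; demes 2-3 split T2 ago, grow to a large known
      # current size, exchange migrants; all stem from deme 1 at T1.
      space <- parameter_space(
        param("N1", "size", 100, 1e6),
        param("N2_BOT", "size", 10, 1e5),
        param("N3_BOT", "size", 10, 1e5),
        param("T1", "time", 100, 1e5),
        param("T2", "time", 10, 1e4),
        param("M", "rate", 1e-6, 1e-2),
        param("N_CUR", "size", value = 1e6),
        builder = function(th) {
          r2 <- log(th$N_CUR / th$N2_BOT) / th$T2
          r3 <- log(th$N_CUR / th$N3_BOT) / th$T2
          mig <- matrix(0, 3, 3)
          mig[2, 3] <- mig[3, 2] <- th$M
          demography(sample_sizes = c(20, 20, 20),
                     sizes = c(th$N1, th$N_CUR, th$N_CUR),
                     growth = c(0, r2, r3), migration = mig, events = list(
            hist_event(time = th$T2, source = 3, sink = 2, proportion = 1,
                       new_size = th$N2_BOT, new_growth = 0),
            hist_event(time = th$T1, source = 2, sink = 1, proportion = 1)))
        })
      list(true_theta = c(N1 = 10000, N2_BOT = 2000, N3_BOT = 1000,
                          T1 = 3000, T2 = 1000, M = 1e-4),
           space = space, num_loci = 400000L, locus_length = 50, mu = 2.5e-8,
           ascertainment = NULL)
    },
    hierarchical_islands = {
      # Two continent-island systems: continents are demes 11 and 12
      # (unsampled); islands 1-5 attach to continent 11, islands 6-10 to
      # continent 12, which stems from island 5 at time T_CI2.
      nisl <- 10
      space <- parameter_space(
        c(lapply(seq_len(nisl), function(i)
            param(paste0("M", i), "rate", 1e-6, 1e-2)),
          list(param("T_CI1", "time", 100, 1e5),
               param("T_CI2", "time", 10, 1e4),
               param("N_A", "size", 100, 1e6),
               param("N_ISL", "size", value = 500),
               param("N_CONT", "size", value = 10000))),
        builder = function(th) {
          np <- nisl + 2
          mig <- matrix(0, np, np)
          for (i in seq_len(nisl)) {
            cont <- if (i <= 5) nisl + 1 else nisl + 2
            mig[i, cont] <- th[[paste0("M", i)]]  # backward: island -> continent
          }
          # tie-break order matters: islands empty into their continent
          # before that continent itself empties backward in time
          events <- list()
          for (i in 6:10)
            events <- c(events, list(hist_event(time = th$T_CI2, source = i,
                                                sink = nisl + 2,
                                                proportion = 1)))
          events <- c(events, list(
            hist_event(time = th$T_CI2, source = nisl + 2, sink = 5,
                       proportion = 1)))
          for (i in 1:5)
            events <- c(events, list(hist_event(time = th$T_CI1, source = i,
                                                sink = nisl + 1,
                                                proportion = 1)))
          events <- c(events, list(
            hist_event(time = th$T_CI1, source = nisl + 1, sink = 1,
                       proportion = 1, new_size = th$N_A)))
          demography(sample_sizes = c(rep(4L, nisl), 0L, 0L),
                     sizes = c(rep(th$N_ISL, nisl), th$N_CONT, th$N_CONT),
                     migration = mig, events = events)
        })
      list(true_theta = c(setNames(c(5e-4, 2e-4, 1e-4, 5e-5, 2e-5,
                                     5e-4, 2e-4, 1e-4, 5e-5, 2e-5),
                                   paste0("M", seq_len(nisl))),
                          T_CI1 = 5000, T_CI2 = 1000, N_A = 10000),
           space = space, num_loci = 400000L, locus_length = 50, mu = 2.5e-8,
           ascertainment = NULL)
    },
    asc_divergence = {
      space <- parameter_space(
        param("N1", "size", 100, 1e6),
        param("N2", "size", 100, 1e6),
        param("T_DIV", "time", 10, 1e5),
        param("N_ANC", "size", value = 10000),
        builder = function(th)
          demography(sample_sizes = c(20, 20), sizes = c(th$N1, th$N2),
                     events = list(
            hist_event(time = th$T_DIV, source = 2, sink = 1, proportion = 1,
                       new_size = th$N_ANC))))
      list(true_theta = c(N1 = 20000, N2 = 8000, T_DIV = 3000),
           space = space, num_loci = 400000L, locus_length = 50,
           mu = 2.5e-8, ascertainment = ascertainment(deme = 1))
    })
  preset$name <- name
  preset$demography <- bind_parameters(preset$space, preset$true_theta)
  structure(preset, class = "scenario_preset")
}

#' @export
print.scenario_preset <- function(x, ...) {
  cat("Scenario preset '", x$name, "': ", x$num_loci, " loci x ",
      x$locus_length, " bp, mu = ", x$mu,
      if (!is.null(x$ascertainment))
        paste0(", ascertained in deme ", x$ascertainment$deme), "\n", sep = "")
  cat("true parameters:",
      paste(sprintf("%s = %.5g", names(x$true_theta), x$true_theta),
            collapse = ", "), "\n")
  invisible(x)
}

#' Parameter-recovery benchmark
#'
#' Generates `replicates` independent pseudo-observed datasets under a
#' scenario preset, fits the preset's estimation space to each with
#' [sfs_fit()], and tabulates the estimates against the truth.
#'
#' @param preset a [scenario_preset()].
#' @param replicates number of independent datasets.
#' @param config an [ecm_config()].
#' @param num_loci,locus_length data-generation size override (the preset's
#'   full scale is often more than a test needs).
#' @param use_monomorphic passed to [sfs_fit()]; forced off under
#'   ascertainment.
#' @param seed optional master seed.
#' @param verbose progress.
#' @return a data frame with one row per replicate x parameter: `replicate`,
#'   `parameter`, `truth`, `estimate`, `rel_error`; the per-parameter
#'   medians and quartiles are attached as `attr(, "summary")`.
#' @export
recovery_benchmark <- function(preset, replicates = 10,
                               config = ecm_config(), num_loci = NULL,
                               locus_length = NULL, use_monomorphic = TRUE,
                               seed = NULL, verbose = FALSE) {
  stopifnot(inherits(preset, "scenario_preset"), replicates >= 1)
  if (is.null(seed)) seed <- sample.int(2147483629L, 1)
  num_loci <- num_loci %||% preset$num_loci
  locus_length <- locus_length %||% preset$locus_length
  if (!is.null(preset$ascertainment)) use_monomorphic <- FALSE
  rows <- list()
  for (r in seq_len(replicates)) {
    set.seed(derive_seed(seed, r, "bench-data"))
    obs <- simulate_sfs(preset$demography, num_loci = num_loci,
                        locus_length = locus_length, mu = preset$mu,
                        ascertainment = preset$ascertainment)
    fit <- sfs_fit(obs, preset$space, config = config, mu = preset$mu,
                   use_monomorphic = use_monomorphic,
                   ascertainment = preset$ascertainment,
                   seed = derive_seed(seed, r, "bench-fit"))
    est <- coef(fit)
    tru <- preset$true_theta[names(est)]
    rows[[r]] <- data.frame(replicate = r, parameter = names(est),
                            truth = as.numeric(tru),
                            estimate = as.numeric(est),
                            rel_error = (as.numeric(est) - as.numeric(tru)) /
                              as.numeric(tru))
    if (verbose)
      message(sprintf("replicate %d/%d: %s", r, replicates,
                      paste(sprintf("%s=%.4g", names(est), est),
                            collapse = " ")))
  }
  out <- do.call(rbind, rows)
  sm <- do.call(rbind, lapply(split(out, out$parameter), function(g)
    data.frame(parameter = g$parameter[1], truth = g$truth[1],
               median = median(g$estimate),
               q25 = quantile(g$estimate, 0.25),
               q75 = quantile(g$estimate, 0.75))))
  rownames(sm) <- NULL
  attr(out, "summary") <- sm
  out
}
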