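#' Optimization settings for the ECM composite-likelihood fit
#'
#' Tunables of the expectation/conditional-maximization search. The
#' simulation count used to estimate the expected SFS ramps linearly from
#' `z_start` in the first cycle to `z_end` in the last (visited parameter
#' vectors are re-scored at `z_end` when a run completes); larger `Z` reduces
#' the Monte Carlo noise of each likelihood evaluation at proportional cost.
#'
#' @param cycles maximum ECM cycles over the free parameters.
#' @param runs independent multi-start optimizations.
#' @param z_start,z_end simulation counts at the first and last cycle.
#' @param stop_tol relative parameter-change threshold: a run stops early
#'   when no free parameter moved by more than this fraction over a full
#'   cycle.
#' @param brent_tol absolute tolerance of each one-dimensional (Brent)
#'   maximization, on the parameter's search scale (log10 units for
#'   log-scaled parameters).
#' @param brent_maxiter cap on Brent iterations per one-dimensional search.
#' @param boot_runs multi-start runs used when re-fitting bootstrap
#'   replicates.
#' @return an `"ecm_config"` list.
#' @export
ecm_config <- function(cycles = 20, runs = 20, z_start = 50000,
                       z_end = 250000, stop_tol = 0.005, brent_tol = 0.01,
                       brent_maxiter = 20, boot_runs = 10) {
  stopifnot(cycles >= 1, runs >= 1, z_start >= 1, z_start <= z_end,
            stop_tol > 0, brent_tol > 0, brent_maxiter >= 1)
  structure(list(cycles = as.integer(cycles), runs = as.integer(runs),
                 z_start = as.integer(z_start), z_end = as.integer(z_end),
                 stop_tol = stop_tol, brent_tol = brent_tol,
                 brent_maxiter = as.integer(brent_maxiter),
                 boot_runs = as.integer(boot_runs)), class = "ecm_config")
}

#' One-dimensional maximization by Brent's method
#'
#' Maximizes a univariate function on a bounded interval with Brent's
#' combination of golden-section search and successive parabolic
#' interpolation (via [stats::optimize()]). `maxiter` bounds the work by
#' flooring the effective tolerance at `(upper - lower) * 0.618^maxiter`,
#' the golden-section convergence rate.
#'
#' @param f objective, called with a scalar.
#' @param lower,upper finite interval bounds.
#' @param tol absolute convergence tolerance on the argument.
#' @param maxiter iteration cap.
#' @return list with `maximum` (the argmax) and `objective` (its value).
#' @examples
#' brent_maximize(function(p) 7 * log(p) + 3 * log(1 - p), 1e-6, 1 - 1e-6)
#' @export
brent_maximize <- function(f, lower, upper, tol = 1e-6, maxiter = 100) {
  stopifnot(is.finite(lower), is.finite(upper), lower <= upper)
  if (lower == upper) return(list(maximum = lower, objective = f(lower)))
  eff_tol <- max(tol, (upper - lower) * 0.618^maxiter)
  r <- optimize(f, c(lower, upper), maximum = TRUE, tol = eff_tol)
  list(maximum = r$maximum, objective = r$objective)
}

# Objective factory: theta (named, natural scale) -> composite logCL, with a
# fresh batch of Z simulated genealogies per evaluation (no common random
# numbers; two evaluations at the same theta differ by Monte Carlo noise).
make_objective <- function(obs, space, mu, use_monomorphic, epsilon, floor,
                           ascertainment, pairwise, tmax) {
  force(obs); force(space)
  function(theta, Z) {
    d <- bind_parameters(space, theta)
    e <- expected_sfs(d, Z, ascertainment = ascertainment,
                      mu = if (use_monomorphic) mu else NULL, tmax = tmax)
    if (pairwise)
      pairwise_loglik(obs, e, epsilon = epsilon, floor = floor)$logCL
    else
      composite_loglik(obs, e, use_monomorphic = use_monomorphic,
                       epsilon = epsilon, floor = floor)$logCL
  }
}

#' Single ECM optimization run
#'
#' One expectation/conditional-maximization run from a given (or random)
#' starting point: in every cycle each free parameter is maximized in turn by
#' [brent_maximize()] over its search range (on its search scale), holding
#' the others at their latest values; every objective evaluation re-estimates
#' the expected SFS from a fresh batch of simulations whose size follows the
#' configured linear ramp. The run stops when no parameter moved by more than
#' `stop_tol` (relative) over a full cycle, or at the cycle cap; every visited
#' cycle's parameters are then re-scored once at `z_end`, and the best
#' re-scored vector is the run's estimate -- a guard against a late cycle
#' derailed by one unlucky noisy comparison inside a one-dimensional search.
#'
#' Most users call [sfs_fit()] (multi-start) instead.
#'
#' @param obs an [observed_sfs()].
#' @param space a [parameter_space()].
#' @param config an [ecm_config()].
#' @param mu per-site per-generation mutation rate (used for the monomorphic
#'   terms).
#' @param start optional named starting vector; random (see
#'   [sample_initial_parameters()]) when `NULL`.
#' @param use_monomorphic include the monomorphic-site terms in the
#'   likelihood; requires `obs$L`.
#' @param epsilon rare-entry collapsing threshold.
#' @param floor zero-probability floor inside the likelihood.
#' @param ascertainment optional [ascertainment()] scheme.
#' @param pairwise maximize the product of pairwise 2-D composite likelihoods
#'   instead of the full joint spectrum (for many-deme models).
#' @param tmax simulation hard time cap.
#' @param verbose print one line per cycle.
#' @return an `"ecm_run"` list: `theta`, `logCL` (final, re-scored at
#'   `z_end`), `trajectory` (per-cycle parameters and logCL), `cycles`,
#'   `converged`.
#' @export
ecm_fit <- function(obs, space, config = ecm_config(), mu = 2.5e-8,
                    start = NULL, use_monomorphic = TRUE, epsilon = 0,
                    floor = 1e-12, ascertainment = NULL, pairwise = FALSE,
                    tmax = 1e12, verbose = FALSE) {
  stopifnot(inherits(obs, "obs_sfs"), inherits(space, "parameter_space"),
            inherits(config, "ecm_config"))
  fp <- free_params(space)
  obj <- make_objective(obs, space, mu, use_monomorphic, epsilon, floor,
                        ascertainment, pairwise, tmax)
  if (!length(fp)) {
    ll <- obj(numeric(0), config$z_end)
    return(structure(list(theta = numeric(0), logCL = ll,
                          trajectory = data.frame(cycle = 0, logCL = ll),
                          cycles = 0L, converged = TRUE), class = "ecm_run"))
  }
  nm <- vapply(fp, `[[`, "", "name")
  theta <- if (is.null(start)) sample_initial_parameters(space) else start[nm]
  names(theta) <- nm
  zs <- if (config$cycles == 1) config$z_end else
    round(seq(config$z_start, config$z_end, length.out = config$cycles))
  traj <- vector("list", config$cycles)
  converged <- FALSE
  cyc <- 0L
  last_ll <- NA_real_
  for (cycle in seq_len(config$cycles)) {
    cyc <- cycle
    Z <- zs[cycle]
    old <- theta
    for (j in seq_along(fp)) {
      p <- fp[[j]]
      tr <- if (p$scale == "log10") log10 else identity
      inv <- if (p$scale == "log10") function(x) 10^x else identity
      f1 <- function(x) {
        th <- theta; th[j] <- inv(x)
        obj(th, Z)
      }
      r <- brent_maximize(f1, tr(p$lower), tr(p$upper),
                          tol = config$brent_tol,
                          maxiter = config$brent_maxiter)
      theta[j] <- inv(r$maximum)
      last_ll <- r$objective
    }
    traj[[cycle]] <- c(cycle = cycle, theta, logCL = last_ll, Z = Z)
    if (verbose)
      message(sprintf("cycle %2d  Z=%d  logCL=%.4f  %s", cycle, Z, last_ll,
                      paste(sprintf("%s=%.5g", nm, theta), collapse = " ")))
    rel <- abs(theta - old) / pmax(abs(old), .Machine$double.eps)
    if (max(rel) < config$stop_tol) { converged <- TRUE; break }
  }
  # Final selection: re-score every visited cycle's parameters at z_end and
  # keep the best. A single noisy Brent comparison can occasionally discard
  # the half-interval holding the optimum and derail a late cycle; taking
  # the best re-scored visited point instead of the last cycle's makes the
  # run robust to such excursions (the derailed cycles score far below the
  # good ones, well beyond the re-scoring noise).
  tdf <- as.data.frame(do.call(rbind, traj[seq_len(cyc)]))
  cand <- unique(tdf[, nm, drop = FALSE])
  resc <- vapply(seq_len(nrow(cand)), function(i) {
    th <- unlist(cand[i, , drop = FALSE])
    names(th) <- nm
    obj(th, config$z_end)
  }, 0)
  best <- which.max(resc)
  structure(list(theta = setNames(unlist(cand[best, , drop = FALSE]), nm),
                 logCL = resc[best], trajectory = tdf,
                 cycles = cyc, converged = converged), class = "ecm_run")
}

#' Fit a demographic model to an observed SFS
#'
#' The main estimation entry point: maximizes the simulation-based composite
#' likelihood of the observed (joint) site frequency spectrum over the free
#' parameters of a demographic model, by multi-start ECM cycles of
#' one-dimensional Brent maximizations (see [ecm_fit()]). Because the
#' likelihood surface is both noisy (it is estimated from a finite number of
#' coalescent simulations) and potentially multi-modal, `config$runs`
#' independent optimizations are launched from random starting points drawn
#' on the search scale, each on its own deterministic sub-stream of the
#' random seed; the run with the highest re-scored log-likelihood wins, ties
#' broken by run order.
#'
#' @inheritParams ecm_fit
#' @param runs overrides `config$runs`.
#' @param seed optional master seed keying the per-run sub-streams; taken
#'   from the current RNG state when `NULL`.
#' @return an object of class `"sfs_fit"` with methods [coef()], [print()],
#'   [summary()], [logLik()], [confint()] (parametric bootstrap),
#'   [simulate()] (pseudo-data at the estimate) and [plot()] (marginal
#'   observed vs fitted spectra). Fields include `theta` (the estimate),
#'   `logCL`, `runs` (every [ecm_fit()] trajectory), `best_run`, `expected`
#'   (the expected SFS at the estimate, `z_end` simulations) and the data
#'   and settings needed to reproduce the fit.
#' @examples
#' \donttest{
#' sp <- parameter_space(
#'   param("N", "size", 100, 1e6),
#'   builder = function(th) demography(sample_sizes = 20, sizes = th$N))
#' obs <- simulate_sfs(demography(sample_sizes = 20, sizes = 10000),
#'                     num_loci = 5000, locus_length = 50, mu = 2.5e-8)
#' fit <- sfs_fit(obs, sp, config = ecm_config(cycles = 5, runs = 2,
#'                                             z_start = 2000, z_end = 5000))
#' coef(fit)
#' }
#' @export
sfs_fit <- function(obs, space, config = ecm_config(), mu = 2.5e-8,
                    use_monomorphic = TRUE, epsilon = 0, floor = 1e-12,
                    ascertainment = NULL, pairwise = FALSE, runs = NULL,
                    seed = NULL, tmax = 1e12, verbose = FALSE) {
  if (!is.null(runs)) config$runs <- as.integer(runs)
  if (is.null(seed)) seed <- sample.int(2147483629L, 1)
  results <- vector("list", config$runs)
  for (r in seq_len(config$runs)) {
    set.seed(derive_seed(seed, r, "ecm-run"))
    results[[r]] <- tryCatch(
      ecm_fit(obs, space, config, mu = mu, use_monomorphic = use_monomorphic,
              epsilon = epsilon, floor = floor, ascertainment = ascertainment,
              pairwise = pairwise, tmax = tmax, verbose = verbose),
      error = function(e) e)
    if (verbose && !inherits(results[[r]], "error"))
      message(sprintf("run %d/%d: logCL = %.4f", r, config$runs,
                      results[[r]]$logCL))
  }
  ok <- !vapply(results, inherits, TRUE, "error")
  if (!any(ok))
    stop("all optimization runs failed; first error: ",
         conditionMessage(results[[1]]))
  lls <- vapply(results[ok], `[[`, 0, "logCL")
  best <- which(ok)[which.max(lls)]  # which.max: earliest index wins ties
  theta <- results[[best]]$theta
  set.seed(derive_seed(seed, 0L, "final-expected"))
  d_hat <- bind_parameters(space, theta)
  e_hat <- expected_sfs(d_hat, config$z_end, ascertainment = ascertainment,
                        mu = mu, tmax = tmax)
  structure(list(theta = theta, logCL = results[[best]]$logCL,
                 runs = results, best_run = best, expected = e_hat,
                 obs = obs, space = space, config = config, mu = mu,
                 use_monomorphic = use_monomorphic, epsilon = epsilon,
                 floor = floor, ascertainment = ascertainment,
                 pairwise = pairwise, seed = seed, tmax = tmax,
                 call = match.call()), class = "sfs_fit")
}

#' @rdname sfs_fit
#' @param ... passed on to [sfs_fit()].
#' @export
multi_start_fit <- function(obs, space, config = ecm_config(), ...) {
  sfs_fit(obs, space, config = config, ...)
}

#' Re-evaluate the composite likelihood at the fitted parameters
#'
#' Repeats the likelihood estimation `R` times at the fitted parameter values
#' (each with a fresh simulation batch of `z_end` genealogies) and returns
#' the maximum -- the noise-robust summary used for model comparison, where
#' an imprecisely estimated likelihood would distort AIC differences.
#'
#' @param fit an [sfs_fit()] result.
#' @param R number of re-evaluations.
#' @return list with `logCL` (the maximum), `all` (every re-evaluation).
#' @export
rescore_loglik <- function(fit, R = 100) {
  stopifnot(inherits(fit, "sfs_fit"), R >= 1)
  obj <- make_objective(fit$obs, fit$space, fit$mu, fit$use_monomorphic,
                        fit$epsilon, fit$floor, fit$ascertainment,
                        fit$pairwise, fit$tmax)
  all <- vapply(seq_len(R), function(i) obj(fit$theta, fit$config$z_end), 0)
  list(logCL = max(all), all = all)
}

#' @export
coef.sfs_fit <- function(object, ...) object$theta

#' @export
logLik.sfs_fit <- function(object, ...) {
  structure(object$logCL, df = length(object$theta), class = "logLik")
}

#' @export
print.sfs_fit <- function(x, ...) {
  cat("Composite-likelihood demographic fit\n")
  cat("  free parameters:", if (length(x$theta))
    paste(sprintf("%s = %.6g", names(x$theta), x$theta), collapse = ", ")
    else "(none)", "\n")
  cat(sprintf("  log composite likelihood: %.4f (run %d of %d, Z = %d)\n",
              x$logCL, x$best_run, length(x$runs), x$config$z_end))
  invisible(x)
}

#' @export
summary.sfs_fit <- function(object, ...) {
  ok <- !vapply(object$runs, inherits, TRUE, "error")
  lls <- vapply(object$runs[ok], `[[`, NA_real_, "logCL")
  cyc <- vapply(object$runs[ok], `[[`, NA_integer_, "cycles")
  out <- list(theta = object$theta, logCL = object$logCL,
              n_runs = length(object$runs), n_failed = sum(!ok),
              run_logCL = lls, run_cycles = cyc,
              S = object$obs$S, L = object$obs$L,
              use_monomorphic = object$use_monomorphic,
              epsilon = object$epsilon)
  class(out) <- "summary.sfs_fit"
  out
}

#' @export
print.summary.sfs_fit <- function(x, ...) {
  cat("Composite-likelihood demographic fit\n")
  cat(sprintf("  data: S = %s SNPs%s\n", format(x$S, big.mark = ","),
              if (!is.na(x$L)) paste0(", L = ", format(x$L, big.mark = ","),
                                      " bp") else " (no monomorphic count)"))
  cat("  estimates:\n")
  for (nm in names(x$theta))
    cat(sprintf("    %-10s %.6g\n", nm, x$theta[[nm]]))
  cat(sprintf("  best logCL %.4f over %d run(s) (%d failed)\n", x$logCL,
              x$n_runs, x$n_failed))
  if (length(x$run_logCL) > 1)
    cat(sprintf("  run logCL spread: [%.4f, %.4f]\n", min(x$run_logCL),
                max(x$run_logCL)))
  invisible(x)
}

#' @export
plot.sfs_fit <- function(x, demes = NULL, ...) {
  obs <- x$obs
  v <- length(obs$dims)
  if (is.null(demes)) demes <- seq_len(v)
  oldpar <- graphics::par(mfrow = c(1, length(demes)))
  on.exit(graphics::par(oldpar))
  oa <- sfs_vec_to_array(obs$counts, obs$dims)
  ea <- sfs_vec_to_array(x$expected$probs, obs$dims)
  for (k in demes) {
    om <- if (v == 1) oa else apply(oa, k, sum)
    em <- if (v == 1) ea else apply(ea, k, sum)
    om[c(1, length(om))] <- NA  # absorbing cells
    em <- em / sum(em[-c(1, length(em))], na.rm = TRUE) * obs$S
    graphics::plot(0:obs$dims[k], om, type = "h", lwd = 3, log = "y",
                   xlab = "derived allele count", ylab = "sites",
                   main = paste("deme", k), ...)
    graphics::points(0:obs$dims[k], em, col = 2, pch = 19)
  }
  invisible(x)
}

#' @export
residuals.sfs_fit <- function(object, ...) {
  obs <- object$obs
  idx <- setdiff(seq_along(obs$counts), obs$mask)
  p <- object$expected$probs[idx]
  p <- p / sum(p)
  expd <- obs$S * p
  (obs$counts[idx] - expd) / sqrt(pmax(expd, .Machine$double.eps))
}
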