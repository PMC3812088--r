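#' Simulate pseudo-observed spectra from a fitted model
#'
#' Draws replicate observed spectra at the fitted parameter values, the
#' generator behind the parametric bootstrap. Two paths exist:
#' `method = "multinomial"` (fast, the default) samples site counts from the
#' expected spectrum stored in the fit -- with the monomorphic terms in the
#' likelihood the number of SNPs is first drawn `Binomial(L, 1 - p0)`, and
#' with them excluded (SNP-panel mode) it is fixed at the observed `S`;
#' `method = "loci"` re-simulates independent loci tree by tree with
#' infinite-sites mutations (exact but much slower). The two agree in
#' distribution for unlinked sites.
#'
#' @param object an [sfs_fit()].
#' @param nsim number of replicate datasets.
#' @param seed optional seed.
#' @param method `"multinomial"` or `"loci"`.
#' @param num_loci,locus_length loci configuration for `method = "loci"`.
#' @param ... unused.
#' @return a list of [observed_sfs()] objects of length `nsim`.
#' @export
simulate.sfs_fit <- function(object, nsim = 1, seed = NULL,
                             method = c("multinomial", "loci"),
                             num_loci = NULL, locus_length = 50, ...) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  e <- object$expected
  obs <- object$obs
  out <- vector("list", nsim)
  if (method == "multinomial") {
    idx <- setdiff(seq_along(e$probs), obs$mask)
    p <- e$probs[idx]
    p <- p / sum(p)
    for (i in seq_len(nsim)) {
      S <- if (object$use_monomorphic)
        rbinom(1, obs$L, 1 - e$p0) else obs$S
      counts <- numeric(length(e$probs))
      counts[idx] <- as.numeric(rmultinom(1, S, p))
      out[[i]] <- observed_sfs(counts, dims = obs$dims, L = obs$L)
    }
  } else {
    d <- bind_parameters(object$space, object$theta)
    if (is.null(num_loci)) {
      if (is.na(obs$L)) stop("method 'loci' needs num_loci when obs$L is unknown")
      num_loci <- round(obs$L / locus_length)
    }
    for (i in seq_len(nsim))
      out[[i]] <- simulate_sfs(d, num_loci = num_loci,
                               locus_length = locus_length, mu = object$mu,
                               ascertainment = object$ascertainment)
  }
  out
}

#' Parametric-bootstrap confidence intervals
#'
#' Simulates `B` replicate datasets at the maximum composite-likelihood
#' estimates (see [simulate.sfs_fit()]), re-estimates the parameters on each
#' with a reduced number of multi-start runs, and reports percentile
#' intervals. Replicates whose estimation fails are logged and skipped, with
#' a minimum-success guard.
#'
#' @param fit an [sfs_fit()].
#' @param B bootstrap replicates.
#' @param runs multi-start runs per replicate (defaults to
#'   `fit$config$boot_runs`).
#' @param level confidence level.
#' @param config optional [ecm_config()] override for replicate fits.
#' @param method pseudo-data path, see [simulate.sfs_fit()].
#' @param min_success minimum fraction of replicates that must succeed.
#' @param seed optional master seed for the replicate sub-streams.
#' @param verbose print progress.
#' @param g_rescore,g_z protocol for the per-replicate G statistic (stored in
#'   `$G` and consumed by [gof_test()]): the replicate model likelihood is
#'   the maximum over `g_rescore` re-evaluations at `g_z` simulations, so
#'   the null G carries the same Monte-Carlo noise as the observed one.
#' @return an `"sfs_boot"` object: `theta` (replicate estimates, B x p),
#'   `ci` (2-column matrix), `B`, `failed`, `G` (per-replicate G statistics).
#' @export
bootstrap_ci <- function(fit, B = 100, runs = NULL, level = 0.95,
                         config = NULL, method = "multinomial",
                         min_success = 0.5, seed = NULL, verbose = FALSE,
                         g_rescore = 1, g_z = NULL) {
  stopifnot(inherits(fit, "sfs_fit"), B >= 1)
  if (is.null(config)) config <- fit$config
  config$runs <- as.integer(if (is.null(runs)) fit$config$boot_runs else runs)
  if (is.null(g_z)) g_z <- config$z_end
  if (is.null(seed)) seed <- sample.int(2147483629L, 1)
  est <- matrix(NA_real_, B, length(fit$theta),
                dimnames = list(NULL, names(fit$theta)))
  glist <- numeric(B)
  for (b in seq_len(B)) {
    set.seed(derive_seed(seed, b, "boot-data"))
    rep_obs <- simulate.sfs_fit(fit, nsim = 1, method = method)[[1]]
    r <- tryCatch(
      sfs_fit(rep_obs, fit$space, config = config, mu = fit$mu,
              use_monomorphic = fit$use_monomorphic, epsilon = fit$epsilon,
              floor = fit$floor, ascertainment = fit$ascertainment,
              pairwise = fit$pairwise, seed = derive_seed(seed, b, "boot-fit"),
              tmax = fit$tmax),
      error = function(e) e)
    if (inherits(r, "error")) {
      if (verbose) message("bootstrap replicate ", b, " failed: ",
                           conditionMessage(r))
      glist[b] <- NA_real_
      next
    }
    est[b, ] <- r$theta
    sat <- saturated_loglik(rep_obs, use_monomorphic = fit$use_monomorphic,
                            epsilon = fit$epsilon)
    # replicate G uses the same rescoring protocol (max over g_rescore
    # re-evaluations at g_z) as the observed statistic, so the null and the
    # observed values carry identical Monte-Carlo noise
    rep_ll <- if (g_rescore > 1 || g_z != config$z_end) {
      obj <- make_objective(rep_obs, fit$space, fit$mu, fit$use_monomorphic,
                            fit$epsilon, fit$floor, fit$ascertainment,
                            fit$pairwise, fit$tmax)
      max(vapply(seq_len(g_rescore), function(i) obj(r$theta, g_z), 0))
    } else r$logCL
    glist[b] <- 2 * (sat$logCL - rep_ll)
    if (verbose) message(sprintf("bootstrap %d/%d done", b, B))
  }
  ok <- if (ncol(est)) !is.na(est[, 1]) else !is.na(glist)
  if (mean(ok) < min_success)
    stop("only ", sum(ok), " of ", B, " bootstrap replicates succeeded")
  a <- (1 - level) / 2
  ci <- t(apply(est[ok, , drop = FALSE], 2, quantile, probs = c(a, 1 - a),
                na.rm = TRUE))
  colnames(ci) <- paste0(format(100 * c(a, 1 - a), trim = TRUE), " %")
  structure(list(theta = est, ci = ci, B = B, failed = sum(!ok),
                 G = glist, level = level), class = "sfs_boot")
}

#' @export
print.sfs_boot <- function(x, ...) {
  cat("Parametric bootstrap,", x$B, "replicates (", x$failed, "failed )\n")
  print(x$ci)
  invisible(x)
}

#' @export
confint.sfs_fit <- function(object, parm, level = 0.95, B = 100, ...) {
  bt <- bootstrap_ci(object, B = B, level = level, ...)
  ci <- bt$ci
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  attr(ci, "bootstrap") <- bt
  ci
}

#' Akaike weights for a set of fitted models
#'
#' Computes `AIC = 2 d - 2 logCL` for each model and the Akaike weight of
#' evidence `w_i = exp(-(AIC_i - AIC_min)/2)`, normalized to sum to one: the
#' relative likelihood of each model among those compared. All models must
#' have been fitted to the same observed data. Because the log composite
#' likelihood is simulation-estimated, supply the noise-robust value from
#' [rescore_loglik()] (the maximum over repeated re-evaluations at the
#' estimate) rather than a single noisy evaluation -- [compare_models()]
#' does this automatically.
#'
#' @param models a list; each element either an [sfs_fit()] or a list with
#'   elements `d` (free-parameter count) and `logCL`.
#' @return an `"sfs_aic"` data frame with columns `model`, `d`, `logCL`,
#'   `AIC`, `dAIC`, `weight`.
#' @examples
#' aic_weights(list(m1 = list(d = 2, logCL = -1000),
#'                  m2 = list(d = 3, logCL = -999)))
#' @export
aic_weights <- function(models) {
  stopifnot(length(models) >= 1)
  nm <- names(models)
  if (is.null(nm)) nm <- paste0("model", seq_along(models))
  d <- vapply(models, function(m)
    if (inherits(m, "sfs_fit")) length(m$theta) else m$d, 0)
  ll <- vapply(models, function(m)
    if (inherits(m, "sfs_fit")) m$logCL else m$logCL, 0)
  aic <- 2 * d - 2 * ll
  w <- exp(-(aic - min(aic)) / 2)
  w <- w / sum(w)
  structure(data.frame(model = nm, d = d, logCL = ll, AIC = aic,
                       dAIC = aic - min(aic), weight = w,
                       row.names = NULL), class = c("sfs_aic", "data.frame"))
}

#' @rdname aic_weights
#' @param ... named [sfs_fit()] objects fitted to the same data.
#' @param rescore number of likelihood re-evaluations per model used to form
#'   the noise-robust `logCL` (the maximum over re-evaluations).
#' @export
compare_models <- function(..., rescore = 100) {
  fits <- list(...)
  if (length(fits) == 1 && is.list(fits[[1]]) &&
      !inherits(fits[[1]], "sfs_fit")) fits <- fits[[1]]
  stopifnot(all(vapply(fits, inherits, TRUE, "sfs_fit")))
  models <- lapply(fits, function(f)
    list(d = length(f$theta), logCL = rescore_loglik(f, R = rescore)$logCL))
  names(models) <- names(fits)
  aic_weights(models)
}

#' Composite likelihood ratio goodness-of-fit test
#'
#' Tests whether the observed spectrum is compatible with the fitted model
#' using the G-type statistic `G = 2 (logCL_saturated - logCL_model)`, where
#' the saturated likelihood replaces the expected spectrum by the relative
#' observed one (see [saturated_loglik()]) and the model likelihood is
#' re-scored at the fitted parameters (maximum over `rescore`
#' re-evaluations). The null distribution of `G` is obtained by parametric
#' bootstrap: `B` datasets are simulated at the estimates, parameters are
#' re-estimated on each, and the replicate G statistics form the reference
#' distribution; the p-value is the fraction of null values at least as
#' large as the observed one.
#'
#' @param fit an [sfs_fit()].
#' @param B bootstrap replicates.
#' @param runs multi-start runs per replicate.
#' @param rescore re-evaluations of the model likelihood at the estimate.
#' @param config optional [ecm_config()] override for replicate fits.
#' @param seed optional master seed.
#' @param verbose print progress.
#' @return an `"sfs_gof"` object: `G_obs`, `G_null`, `p_value`, `B`.
#' @export
gof_test <- function(fit, B = 100, runs = NULL, rescore = 10, config = NULL,
                     seed = NULL, verbose = FALSE) {
  stopifnot(inherits(fit, "sfs_fit"), B >= 1)
  g_z <- if (is.null(config)) fit$config$z_end else config$z_end
  sat <- saturated_loglik(fit$obs, use_monomorphic = fit$use_monomorphic,
                          epsilon = fit$epsilon)
  obj <- make_objective(fit$obs, fit$space, fit$mu, fit$use_monomorphic,
                        fit$epsilon, fit$floor, fit$ascertainment,
                        fit$pairwise, fit$tmax)
  ll <- max(vapply(seq_len(rescore), function(i) obj(fit$theta, g_z), 0))
  G_obs <- 2 * (sat$logCL - ll)
  bt <- bootstrap_ci(fit, B = B, runs = runs, config = config, seed = seed,
                     verbose = verbose, g_rescore = rescore, g_z = g_z)
  G_null <- bt$G[!is.na(bt$G)]
  p <- mean(G_null >= G_obs)
  structure(list(G_obs = G_obs, G_null = G_null, p_value = p, B = B,
                 boot = bt), class = "sfs_gof")
}

#' @export
print.sfs_gof <- function(x, ...) {
  cat("Composite likelihood ratio goodness-of-fit test\n")
  cat(sprintf("  G observed = %.2f;  null: %d bootstrap replicates\n",
              x$G_obs, length(x$G_null)))
  cat(sprintf("  p-value = %.4f %s\n", x$p_value,
              if (x$p_value == 0) sprintf("(< %.4f)", 1 / length(x$G_null))
              else ""))
  invisible(x)
}
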