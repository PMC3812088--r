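#' Composite log-likelihood of an observed SFS
#'
#' Natural-log composite likelihood of the observed spectrum given an
#' expected spectrum: a binomial term for the split of the `L` surveyed sites
#' into `L - S` monomorphic and `S` polymorphic ones,
#' `(L - S) log(p0) + S log(1 - p0)`, plus a multinomial term over the
#' polymorphic classes, `sum_i X_i log(p_i)`, where the `p_i` are the
#' branch-length-ratio class probabilities conditional on one mutation.
#' With `use_monomorphic = FALSE` the binomial terms are dropped -- the mode
#' used for ascertained SNP panels, where only polymorphic sites are reported
#' and no molecular clock is available; the remaining term is then exactly a
#' multinomial log-likelihood over SFS classes.
#'
#' Entries are first collapsed at `epsilon` (see [collapse_entries()]);
#' classes observed with positive count but estimated probability zero are
#' then floored at `floor` (applied after normalization, inside the
#' likelihood only).
#'
#' @param obs an [observed_sfs()].
#' @param exp an [expected_sfs()] with matching dims; must carry `p0` when
#'   `use_monomorphic` is on.
#' @param use_monomorphic include the binomial monomorphic/polymorphic terms
#'   (requires `obs$L` and `exp$p0`).
#' @param epsilon collapsing threshold for rare entries.
#' @param floor value substituted for zero expected probabilities of observed
#'   classes; set to 0 to make such classes an error.
#' @param renormalize rescale the expected probabilities to sum to one over
#'   the retained polymorphic classes (the default; relevant for pairwise
#'   marginal spectra whose within-pair absorbing entries carry mass).
#' @return an object of class `"sfs_cl"`: `logCL`, `per_entry` (contribution
#'   of each retained class), `mono` (the binomial contribution),
#'   `used_monomorphic`, `floored_entries`, `S`, `L`.
#' @examples
#' o <- observed_sfs(c(0, 3, 1, 0), dims = 3)
#' e <- structure(list(dims = 3L, probs = c(0, 0.75, 0.25, 0), p0 = NA_real_,
#'                     Z = 1L, mean_T = 1, mean_length = 1,
#'                     ascertained = FALSE), class = "exp_sfs")
#' composite_loglik(o, e, use_monomorphic = FALSE)$logCL  # 3 log .75 + log .25
#' @export
composite_loglik <- function(obs, exp, use_monomorphic = TRUE, epsilon = 0,
                             floor = 1e-12, renormalize = TRUE) {
  cl <- collapse_entries(obs, exp, epsilon)
  x <- cl$counts
  p <- cl$probs
  if (renormalize && sum(p) > 0) p <- p / sum(p)
  floored <- which(x > 0 & p <= 0)
  if (length(floored)) {
    if (floor <= 0)
      stop(length(floored), " observed class(es) have zero expected ",
           "probability and flooring is disabled")
    p[floored] <- floor
  }
  per <- ifelse(x > 0, x * log(p), 0)
  mono <- 0
  if (use_monomorphic) {
    if (is.na(obs$L)) stop("use_monomorphic requires obs$L")
    if (is.na(exp$p0)) stop("use_monomorphic requires exp$p0 (supply mu ",
                            "to expected_sfs)")
    p0 <- exp$p0
    mono <- (obs$L - obs$S) * log(p0) + obs$S * log1p(-p0)
  }
  structure(list(logCL = mono + sum(per), per_entry = per, mono = mono,
                 used_monomorphic = isTRUE(use_monomorphic),
                 floored_entries = cl$kept[floored[floored <= length(cl$kept)]],
                 S = obs$S, L = obs$L), class = "sfs_cl")
}

#' @export
print.sfs_cl <- function(x, ...) {
  cat("Composite log-likelihood: ", format(x$logCL, digits = 10),
      " (", length(x$per_entry), " classes",
      if (x$used_monomorphic) ", with monomorphic terms", ")\n", sep = "")
  invisible(x)
}

#' Saturated composite log-likelihood
#'
#' The maximum composite log-likelihood achievable for the data: the expected
#' class probabilities are replaced by the relative observed frequencies
#' `X_i / S` (and `p0` by `(L - S) / L` when the monomorphic terms are used).
#' The difference to a model's log-likelihood is the basis of the G-type
#' goodness-of-fit statistic (see [gof_test()]).
#'
#' @inheritParams composite_loglik
#' @return an `"sfs_cl"` object.
#' @export
saturated_loglik <- function(obs, use_monomorphic = TRUE, epsilon = 0) {
  stopifnot(inherits(obs, "obs_sfs"))
  if (obs$S < 1) stop("saturated likelihood needs at least one polymorphic site")
  idx <- setdiff(seq_along(obs$counts), obs$mask)
  cl <- .collapse(obs$counts[idx], obs$counts[idx] / obs$S, idx, epsilon)
  per <- ifelse(cl$counts > 0, cl$counts * log(cl$probs), 0)
  mono <- 0
  if (use_monomorphic) {
    if (is.na(obs$L)) stop("use_monomorphic requires obs$L")
    p0 <- (obs$L - obs$S) / obs$L
    mono <- (obs$L - obs$S) * log(p0) + obs$S * log1p(-p0)
  }
  structure(list(logCL = mono + sum(per), per_entry = per, mono = mono,
                 used_monomorphic = isTRUE(use_monomorphic),
                 floored_entries = integer(0), S = obs$S, L = obs$L),
            class = "sfs_cl")
}

#' Marginal 2-D spectrum of a deme pair
#'
#' Sums a dense multidimensional spectrum over all demes other than the two
#' kept ones. Works on both observed and expected spectra; the within-pair
#' absorbing cells of an expected marginal keep the probability mass of
#' branches that are polymorphic in the full sample but invariant in the
#' pair, which the pairwise likelihood later drops and renormalizes away.
#'
#' @param x an `"obs_sfs"` or `"exp_sfs"`.
#' @param pair integer vector of two deme indices.
#' @return an object of the same class over `dims[pair]`.
#' @export
marginal_pair <- function(x, pair) {
  stopifnot(length(pair) == 2, all(pair >= 1), all(pair <= length(x$dims)))
  if (inherits(x, "obs_sfs")) {
    a <- sfs_vec_to_array(x$counts, x$dims)
    m <- apply(a, pair, sum)
    observed_sfs(sfs_array_to_vec(m, x$dims[pair]), dims = x$dims[pair],
                 L = x$L, infer_L = FALSE)
  } else if (inherits(x, "exp_sfs")) {
    a <- sfs_vec_to_array(x$probs, x$dims)
    m <- apply(a, pair, sum)
    structure(list(dims = x$dims[pair],
                   probs = sfs_array_to_vec(m, x$dims[pair]), p0 = x$p0,
                   Z = x$Z, mean_T = x$mean_T, mean_length = x$mean_length,
                   ascertained = x$ascertained), class = "exp_sfs")
  } else stop("x must be an observed or expected SFS")
}

#' Product of pairwise composite likelihoods
#'
#' For models with many populations the full `v`-dimensional spectrum becomes
#' unmanageable; the objective is then the sum over all `v(v-1)/2` deme pairs
#' of the 2-D composite log-likelihoods of their marginal spectra. The
#' monomorphic terms are always excluded in this mode (each pair would count
#' them again).
#'
#' @param obs a `v`-dimensional [observed_sfs()] (`v >= 2`), or a list of
#'   2-D observed marginals for every pair.
#' @param exp the matching [expected_sfs()] or list of expected marginals.
#' @param pairs optional 2-column matrix of deme pairs (rows), defaulting to
#'   all pairs; must index `obs`/`exp` lists row-wise when lists are given.
#' @inheritParams composite_loglik
#' @return an `"sfs_cl"` object whose `per_entry` holds one total per pair.
#' @export
pairwise_loglik <- function(obs, exp, pairs = NULL, epsilon = 0,
                            floor = 1e-12) {
  if (inherits(obs, "obs_sfs")) {
    v <- length(obs$dims)
    if (v < 2) stop("pairwise likelihood needs at least two demes")
    if (is.null(pairs)) pairs <- t(utils::combn(v, 2))
    obs <- lapply(seq_len(nrow(pairs)), function(i)
      marginal_pair(obs, pairs[i, ]))
    exp <- lapply(seq_len(nrow(pairs)), function(i)
      marginal_pair(exp, pairs[i, ]))
  }
  if (length(obs) != length(exp))
    stop("need one expected marginal per observed pair")
  contrib <- vapply(seq_along(obs), function(i)
    composite_loglik(obs[[i]], exp[[i]], use_monomorphic = FALSE,
                     epsilon = epsilon, floor = floor)$logCL, 0)
  structure(list(logCL = sum(contrib), per_entry = contrib, mono = 0,
                 used_monomorphic = FALSE, floored_entries = integer(0),
                 S = NA_real_, L = NA_real_), class = "sfs_cl")
}
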