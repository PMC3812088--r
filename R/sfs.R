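#' Observed site frequency spectrum
#'
#' Container for an observed (possibly joint, multidimensional) spectrum of
#' derived-allele counts. Internally the spectrum is stored as a dense vector
#' over all `prod(dims + 1)` entries of the composite index
#' `(i_1, ..., i_v)`, with the **last** deme's index varying fastest (the
#' order of the multidimensional text dialect). The two absorbing entries --
#' all-ancestral and all-derived in the whole sample -- are masked out of `S`
#' and of every likelihood; the all-ancestral cell may carry the monomorphic
#' site count when it is known.
#'
#' @param counts numeric vector of length `prod(dims + 1)` in dense order, or
#'   an array/matrix with `dim = dims + 1` indexed `[i_1+1, ..., i_v+1]`.
#' @param dims per-deme sample sizes `n_1..n_v`; inferred from an array's
#'   dimensions when omitted.
#' @param L total surveyed length in bp, or `NA` when the monomorphic count
#'   is unknown (e.g. SNP panels). When `L` is given and the all-ancestral
#'   cell is zero, it is filled with `L - S`; when `L` is missing but the
#'   all-ancestral cell is populated, `L` is inferred as its count plus `S`
#'   (disable with `infer_L = FALSE`).
#' @param infer_L infer `L` from a populated all-ancestral cell.
#' @return an object of class `"obs_sfs"` with fields `dims`, `counts`
#'   (dense), `S` (polymorphic sites), `L` and `mask` (absorbing entries).
#' @examples
#' obs <- observed_sfs(c(0, 120, 55, 30, 0), dims = 4)
#' obs$S
#' @export
observed_sfs <- function(counts, dims = NULL, L = NA, infer_L = TRUE) {
  if (is.array(counts) && is.null(dims)) dims <- dim(counts) - 1L
  if (is.null(dims)) stop("dims must be given when counts is a plain vector")
  dims <- as.integer(dims)
  nent <- prod(dims + 1L)
  if (is.array(counts) && length(dim(counts)) > 1) {
    counts <- as.vector(aperm(counts, rev(seq_along(dims))))  # last deme fastest
  }
  counts <- as.numeric(counts)
  if (length(counts) != nent)
    stop("counts has length ", length(counts), ", expected ", nent)
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("counts must be finite and non-negative")
  mask <- c(1L, nent)
  S <- sum(counts[-mask])
  if (is.na(L) && infer_L && counts[1] > 0)
    L <- counts[1] + S  # all-ancestral cell holds the monomorphic count
  if (!is.na(L)) {
    if (L < S) stop("L (", L, ") is smaller than the number of SNPs S (", S, ")")
    if (counts[1] == 0) counts[1] <- L - S
  }
  structure(list(dims = dims, counts = counts, S = S, L = as.numeric(L),
                 mask = mask), class = "obs_sfs")
}

#' @export
print.obs_sfs <- function(x, ...) {
  cat("Observed SFS: dims (", paste(x$dims, collapse = ", "), "), S = ",
      format(x$S, big.mark = ","), " SNPs",
      if (!is.na(x$L)) paste0(", L = ", format(x$L, big.mark = ","), " bp"),
      "\n", sep = "")
  invisible(x)
}

#' @export
as.array.obs_sfs <- function(x, ...) {
  sfs_vec_to_array(x$counts, x$dims)
}

# dense vector (last deme fastest) <-> R array (first index = deme 1)
sfs_vec_to_array <- function(v, dims) {
  if (length(dims) == 1) return(setNames(v, paste0("d0_", 0:dims)))
  a <- array(v, dim = rev(dims + 1L))
  aperm(a, rev(seq_along(dims)))
}

sfs_array_to_vec <- function(a, dims) {
  if (length(dims) == 1) return(as.numeric(a))
  as.vector(aperm(a, rev(seq_along(dims))))
}

#' Expected SFS by the branch-length-ratio estimator
#'
#' Estimates the probability that a polymorphic site falls in each entry of
#' the (joint) site frequency spectrum under a demographic model, from `Z`
#' simulated genealogies: the estimate for entry `i` is the summed length of
#' all branches whose descent vector equals `i`, across the `Z` trees,
#' divided by the summed total tree length. Numerator and denominator are
#' accumulated over the *same* genealogies, which implicitly weights each
#' simulation by the probability that a mutation occurs on its tree (an
#' unweighted per-tree average would over-weight shallow trees, a problem for
#' recently bottlenecked populations).
#'
#' With an [ascertainment()] scheme, both the compatible-branch sets and the
#' denominator are restricted to the subtree joining two random lineages of
#' the ascertained deme to their MRCA (see [ascertain_subtree()]), while
#' descent vectors still count the full sample: the result is the expected
#' *ascertained* spectrum.
#'
#' When `mu` is supplied the probability `p0` that a site carries no mutation
#' is estimated as the Monte-Carlo mean of the Poisson zero class,
#' `mean(exp(-mu * locus_length * T_k))` (over subtree lengths under
#' ascertainment).
#'
#' @param d a valid [demography()].
#' @param Z number of coalescent simulations (>= 1).
#' @param ascertainment optional [ascertainment()].
#' @param mu optional per-site per-generation mutation rate, enabling `p0`.
#' @param locus_length length in bp over which `p0` is expressed (default 1:
#'   per-site probability, the scale the composite likelihood uses).
#' @param tmax hard simulation time cap, generations.
#' @return an object of class `"exp_sfs"`: `dims`, `probs` (dense, absorbing
#'   entries 0, summing to 1 over the rest), `p0`, `Z`, `mean_T` (mean total
#'   tree length) and `mean_length` (mean of the accumulated denominator:
#'   equal to `mean_T` without ascertainment, the mean subtree length with).
#' @examples
#' d <- demography(sample_sizes = 10, sizes = 5000)
#' e <- expected_sfs(d, Z = 2000)
#' sum(e$probs)  # 1
#' @export
expected_sfs <- function(d, Z, ascertainment = NULL, mu = NULL,
                         locus_length = 1, tmax = 1e12) {
  check_valid_demography(d)
  if (Z < 1) stop("Z must be at least 1")
  asc_deme <- -1L
  if (!is.null(ascertainment)) {
    stopifnot(inherits(ascertainment, "ascertainment"))
    if (d$sample_sizes[ascertainment$deme] < ascertainment$chromosomes)
      stop("ascertained deme must have at least ", ascertainment$chromosomes,
           " sampled lineages")
    asc_deme <- ascertainment$deme - 1L
  }
  mu_eff <- if (is.null(mu)) -1 else mu * locus_length
  raw <- cpp_expected_sfs(as_cpp_model(d), as.integer(Z), asc_deme, mu_eff, tmax)
  probs <- raw$numer / raw$denom
  structure(list(dims = d$sample_sizes, probs = probs,
                 p0 = if (is.null(mu)) NA_real_ else raw$sum_exp / Z,
                 Z = as.integer(Z), mean_T = raw$sum_T / Z,
                 mean_length = raw$denom / Z,
                 ascertained = !is.null(ascertainment)),
            class = "exp_sfs")
}

#' @export
print.exp_sfs <- function(x, ...) {
  cat("Expected SFS (", if (x$ascertained) "ascertained, " else "",
      "Z = ", format(x$Z, big.mark = ","), "): dims (",
      paste(x$dims, collapse = ", "), "), mean tree length ",
      format(x$mean_T, digits = 6), " generations",
      if (!is.na(x$p0)) paste0(", p0 = ", format(x$p0, digits = 6)),
      "\n", sep = "")
  invisible(x)
}

#' Monte-Carlo estimate of the monomorphic probability
#'
#' Probability that a locus of length `L` carries no mutation, averaged over
#' genealogies: `mean(exp(-mu * L * T_k))`, the mean of the Poisson zero
#' class under tree-length variation (unbiased, unlike plugging the mean tree
#' length into the exponential).
#'
#' @param total_lengths numeric vector of total tree lengths (generations).
#' @param mu per-site per-generation mutation rate.
#' @param L locus length in bp.
#' @return scalar in `(0, 1]`.
#' @export
estimate_p0 <- function(total_lengths, mu, L = 1) {
  stopifnot(length(total_lengths) >= 1, mu >= 0, L >= 1)
  mean(exp(-mu * L * total_lengths))
}

#' Collapse rare SFS entries
#'
#' Pools every (non-absorbing) entry whose observed count is below a
#' threshold into a single class whose observed count and expected
#' probability are the sums over the pooled entries. Used to stabilize the
#' composite likelihood of high-dimensional spectra where most entries hold
#' counts too small for their expectations to be estimated precisely.
#'
#' @param obs an [observed_sfs()].
#' @param exp an [expected_sfs()] with matching dims.
#' @param epsilon pooling threshold on observed counts; entries with
#'   `X_i < epsilon` are pooled, `epsilon = 0` pools nothing.
#' @return list with `counts` and `probs` over the retained classes (the
#'   pooled class last, when present), `kept` (dense indices of unpooled
#'   entries) and `pooled` (logical: was a pooled class formed).
#' @examples
#' o <- observed_sfs(c(0, 10, 3, 1, 0, 0), dims = 5)
#' @export
collapse_entries <- function(obs, exp, epsilon) {
  stopifnot(inherits(obs, "obs_sfs"), inherits(exp, "exp_sfs"), epsilon >= 0)
  if (!identical(obs$dims, as.integer(exp$dims)))
    stop("observed and expected SFS dims differ: (",
         paste(obs$dims, collapse = ","), ") vs (",
         paste(exp$dims, collapse = ","), ")")
  idx <- setdiff(seq_along(obs$counts), obs$mask)
  x <- obs$counts[idx]
  p <- exp$probs[idx]
  .collapse(x, p, idx, epsilon)
}

.collapse <- function(x, p, idx, epsilon) {
  low <- x < epsilon
  if (epsilon > 0 && any(low)) {
    list(counts = c(x[!low], sum(x[low])), probs = c(p[!low], sum(p[low])),
         kept = idx[!low], pooled = TRUE)
  } else {
    list(counts = x, probs = p, kept = idx, pooled = FALSE)
  }
}
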