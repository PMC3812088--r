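#' Simulate a single-locus genealogy
#'
#' Draws one realization of the exact continuous-time structured coalescent
#' under a demographic model: within deme `k` at backward time `t` every
#' lineage pair coalesces at rate `1/(2 N_k(t))`, lineages migrate at the
#' backward matrix rates, and waiting times under exponential growth are
#' drawn by the exact time-change inversion of the integrated hazard (no
#' discretized stepping). Historical events move lineages and reset deme
#' parameters at their times; simultaneous events are processed in their
#' declaration order. Simulation ends at the grand MRCA of the sample.
#'
#' @param d a valid, closable [demography()].
#' @param tmax hard cap on simulated time, in generations; exceeding it (a
#'   symptom of a non-closable model that slipped past validation) is an
#'   error.
#' @return an object of class `"genealogy"`: a list with `parent` (1-based
#'   node parent indices, `NA` at the root), `node_time` (generations),
#'   `leaf_deme`, `branch_length` (to the parent; 0 at the root),
#'   `descent` (per-node matrix of sampled-leaf counts per deme -- the
#'   frequency class of a mutation on that branch), `n`, `dims`
#'   (per-deme sample sizes) and `total_length`. Leaves are nodes
#'   `1..n` at time 0; internal nodes follow in coalescence order, so a
#'   parent index always exceeds its children's.
#' @examples
#' d <- demography(sample_sizes = 4, sizes = 1000)
#' g <- simulate_genealogy(d)
#' total_tree_length(g)
#' @export
simulate_genealogy <- function(d, tmax = 1e12) {
  check_valid_demography(d)
  raw <- cpp_simulate_genealogy(as_cpp_model(d), tmax)
  structure(list(
    parent = ifelse(raw$parent < 0, NA_integer_, raw$parent + 1L),
    node_time = raw$node_time,
    leaf_deme = raw$leaf_deme + 1L,
    branch_length = raw$branch_length,
    descent = raw$descent,
    entry = raw$entry + 1L,   # dense SFS entry per branch (last deme fastest)
    n = length(raw$leaf_deme),
    dims = d$sample_sizes,
    total_length = sum(raw$branch_length)), class = "genealogy")
}

#' Total length of a genealogy
#'
#' Sum of all branch lengths in generations; the denominator of the
#' branch-length-ratio SFS estimator and the rate multiplier of the
#' infinite-sites mutation process.
#'
#' @param g a [simulate_genealogy()] result.
#' @return positive scalar, generations.
#' @export
total_tree_length <- function(g) {
  stopifnot(inherits(g, "genealogy"))
  sum(g$branch_length)
}

#' Drop infinite-sites mutations on a genealogy
#'
#' Places `Poisson(mu * L * T)` mutations uniformly along the branches of the
#' tree (each branch hit with probability proportional to its length) and
#' returns the sample frequency class of every mutation.
#'
#' @param g a genealogy.
#' @param mu per-site, per-generation mutation rate.
#' @param L locus length in base pairs.
#' @return matrix with one row per mutation and one column per deme: the
#'   per-deme counts of sampled lineages carrying the derived allele. Zero
#'   rows when no mutation occurred.
#' @export
drop_mutations <- function(g, mu, L = 1) {
  stopifnot(inherits(g, "genealogy"), mu >= 0, L >= 1)
  nb <- 2L * g$n - 2L
  len <- g$branch_length[seq_len(nb)]
  nmut <- rpois(1, mu * L * sum(len))
  if (nmut == 0)
    return(matrix(0L, 0, length(g$dims)))
  hit <- sample.int(nb, nmut, replace = TRUE, prob = len)
  g$descent[hit, , drop = FALSE]
}

#' Ascertainment scheme of a SNP panel
#'
#' Describes the discovery scheme in which SNPs are sites heterozygous in a
#' single individual of one population: two lineages (the individual's two
#' chromosomes) are drawn at random from the ascertained deme, and only
#' mutations on the subtree joining them to their most recent common ancestor
#' are observable.
#'
#' @param deme 1-based index of the ascertained population.
#' @param chromosomes number of ascertainment lineages; only the
#'   heterozygous-individual scheme (`2`) is supported.
#' @param included_in_sample whether the two lineages are part of the
#'   reported sample (they are, for the panels this models).
#' @return an `"ascertainment"` object.
#' @export
ascertainment <- function(deme, chromosomes = 2, included_in_sample = TRUE) {
  if (chromosomes != 2)
    stop("only the 2-chromosome (heterozygous individual) scheme is supported")
  structure(list(deme = as.integer(deme), chromosomes = 2L,
                 included_in_sample = isTRUE(included_in_sample)),
            class = "ascertainment")
}

#' Ascertainment subtree of a genealogy
#'
#' Implements the subtree construction for the heterozygous-individual
#' ascertainment scheme: choose two distinct lineages uniformly at random in
#' the ascertained deme, and take the union of the two paths from those
#' leaves to their MRCA. Only mutations on these branches are heterozygous
#' between the two chromosomes, hence observable on the panel. Each subtree
#' branch keeps its *full-sample* descent vector; the subtree total length is
#' the per-tree contribution to the denominator of the ascertained SFS
#' estimator.
#'
#' @param g a genealogy.
#' @param asc an [ascertainment()].
#' @return list with `branches` (node indices whose parent-branch lies in
#'   the subtree), `lengths`, `descent` (full-sample descent vectors, one row
#'   per subtree branch), `leaves` (the two chosen leaf indices) and
#'   `total_length`.
#' @export
ascertain_subtree <- function(g, asc) {
  stopifnot(inherits(g, "genealogy"), inherits(asc, "ascertainment"))
  if (sum(g$leaf_deme == asc$deme) < 2)
    stop("ascertained deme ", asc$deme, " has fewer than 2 sampled lineages")
  res <- cpp_ascertain_subtree(
    ifelse(is.na(g$parent), -1L, g$parent - 1L), g$node_time,
    g$leaf_deme - 1L, asc$deme - 1L)
  idx <- which(res$in_subtree)
  list(branches = idx, lengths = g$branch_length[idx],
       descent = g$descent[idx, , drop = FALSE],
       leaves = res$leaves + 1L,
       total_length = sum(g$branch_length[idx]))
}

#' Newick export of a genealogy
#'
#' Debug representation with branch lengths in generations; readable by any
#' phylogenetics package (e.g. `ape::read.tree`).
#'
#' @param g a genealogy.
#' @return a single Newick string.
#' @export
as_newick <- function(g) {
  stopifnot(inherits(g, "genealogy"))
  nnode <- 2L * g$n - 1L
  kids <- vector("list", nnode)
  for (v in seq_len(nnode - 1L)) {
    p <- g$parent[v]
    kids[[p]] <- c(kids[[p]], v)
  }
  rec <- function(v) {
    lab <- if (v <= g$n) paste0("t", v, "_d", g$leaf_deme[v])
           else paste0("(", paste(vapply(kids[[v]], rec, ""), collapse = ","), ")")
    if (v == nnode) lab else paste0(lab, ":", format(g$branch_length[v], digits = 12))
  }
  paste0(rec(nnode), ";")
}

#' @export
print.genealogy <- function(x, ...) {
  cat("Coalescent genealogy:", x$n, "leaves in", length(x$dims), "deme(s);",
      "TMRCA =", format(max(x$node_time), digits = 6), "generations;",
      "total length =", format(x$total_length, digits = 6), "\n")
  invisible(x)
}

#' @export
plot.genealogy <- function(x, ...) {
  if (!requireNamespace("ape", quietly = TRUE))
    stop("plotting a genealogy requires the 'ape' package")
  plot(ape::read.tree(text = as_newick(x)), ...)
}
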