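#' Define a multi-population demographic model
#'
#' A demography is the object genealogies are simulated under: a set of demes
#' with current effective sizes and exponential growth rates, a backward-time
#' migration matrix, and a time-ordered list of historical events (divergences,
#' admixture pulses, size changes) created with [hist_event()].
#'
#' Conventions:
#' * sizes are numbers of **diploid** individuals; a pair of lineages in a
#'   deme of size `N` coalesces at rate `1/(2N)` per generation;
#' * `migration[k, j]` is the backward per-lineage, per-generation rate at
#'   which a lineage currently in deme `k` moves to deme `j` going back in
#'   time;
#' * `growth` is the forward exponential growth rate per generation, so
#'   looking backward a deme's size is `N(t) = N(0) * exp(-r t)` until an
#'   event resets it;
#' * times are in generations before present.
#'
#' @param sample_sizes integer vector, sampled gene copies (haploid lineages)
#'   per deme. Length defines the number of demes.
#' @param sizes numeric vector of current diploid effective sizes, recycled.
#' @param growth numeric vector of forward growth rates per generation,
#'   recycled. Default 0 (constant size).
#' @param migration square migration matrix (backward convention, see above),
#'   or `NULL` for no migration. Alternatively `migration_matrices` may give
#'   several matrices between which events can switch; the first is active at
#'   present.
#' @param events list of [hist_event()] objects; sorted by time (stable for
#'   ties, which are then processed in list order).
#' @param migration_matrices optional list of migration matrices, switched by
#'   the `migration_id` field of events. Overrides `migration`.
#'
#' @return an object of class `"demography"`.
#' @seealso [validate_demography()], [simulate_genealogy()], [expected_sfs()]
#' @examples
#' # single constant-size deme, 20 sampled lineages
#' d <- demography(sample_sizes = 20, sizes = 10000)
#'
#' # bottleneck: size 100 between generations 1000 and 1100, ancestral 10000
#' db <- demography(sample_sizes = 20, sizes = 10000, events = list(
#'   hist_event(time = 1000, sink = 1, new_size = 100),
#'   hist_event(time = 1100, sink = 1, new_size = 10000)))
#' @export
demography <- function(sample_sizes, sizes, growth = 0, migration = NULL,
                       events = list(), migration_matrices = NULL) {
  npop <- length(sample_sizes)
  sample_sizes <- as.integer(sample_sizes)
  sizes <- rep_len(as.numeric(sizes), npop)
  growth <- rep_len(as.numeric(growth), npop)
  if (is.null(migration_matrices)) {
    if (is.null(migration)) migration <- matrix(0, npop, npop)
    migration_matrices <- list(as.matrix(migration))
  }
  migration_matrices <- lapply(migration_matrices, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    diag(m) <- 0
    m
  })
  if (inherits(events, "hist_event")) events <- list(events)
  ev <- do.call(rbind, lapply(events, as.data.frame.hist_event))
  if (is.null(ev)) {
    ev <- data.frame(time = numeric(0), source = numeric(0), sink = numeric(0),
                     proportion = numeric(0), new_size = numeric(0),
                     new_growth = numeric(0), migration_id = numeric(0))
  }
  ev <- ev[order(ev$time), , drop = FALSE]  # stable sort: ties keep list order
  rownames(ev) <- NULL
  structure(list(npop = npop, sample_sizes = sample_sizes, sizes = sizes,
                 growth = growth, migration = migration_matrices, events = ev),
            class = "demography")
}

#' Historical event of a demographic model
#'
#' Encodes, at a time in the past, any combination of: a mass movement of
#' lineages (backward in time) from a `source` deme to a `sink` deme with a
#' given `proportion` (1 = complete fusion, i.e. a population divergence seen
#' forward in time; values in (0,1) = admixture pulses), a new size and/or
#' growth rate for the sink deme, and a switch of the active migration matrix.
#'
#' @param time generations before present (>= 0).
#' @param source deme index (1-based) lineages move from, or `NA` for a pure
#'   size/growth/matrix change.
#' @param sink deme index affected; receives lineages and/or the new size and
#'   growth rate.
#' @param proportion fraction in `[0, 1]` of source lineages moved to sink.
#' @param new_size optional new diploid size of the sink deme.
#' @param new_growth optional new growth rate of the sink deme.
#' @param migration_id optional index into the demography's list of migration
#'   matrices to activate from this time backward.
#' @return an object of class `"hist_event"`.
#' @export
hist_event <- function(time, source = NA, sink = source, proportion = 1,
                       new_size = NA, new_growth = NA, migration_id = NA) {
  structure(list(time = as.numeric(time), source = as.numeric(source),
                 sink = as.numeric(sink), proportion = as.numeric(proportion),
                 new_size = as.numeric(new_size),
                 new_growth = as.numeric(new_growth),
                 migration_id = as.numeric(migration_id)),
            class = "hist_event")
}

as.data.frame.hist_event <- function(x, ...) {
  data.frame(time = x$time, source = x$source, sink = x$sink,
             proportion = x$proportion, new_size = x$new_size,
             new_growth = x$new_growth, migration_id = x$migration_id)
}

#' Validate a demographic model
#'
#' Checks a [demography()] for structural violations: non-positive sizes,
#' negative migration rates, out-of-range admixture proportions, invalid deme
#' indices, unsorted or negative event times, too few sampled lineages, and
#' non-closable models -- models in which, tracing lineage movements backward
#' through migration and events, the sampled demes can never all reach a
#' common deme and therefore can never fully coalesce.
#'
#' @param d a [demography()].
#' @return a character vector of human-readable violations; empty when valid.
#' @examples
#' d2 <- demography(sample_sizes = c(10, 10), sizes = 1000)  # no migration
#' validate_demography(d2)  # non-closable: the two demes can never meet
#' @export
validate_demography <- function(d) {
  stopifnot(inherits(d, "demography"))
  bad <- character(0)
  if (any(!is.finite(d$sizes)) || any(d$sizes <= 0))
    bad <- c(bad, "all deme sizes must be positive and finite")
  for (m in d$migration)
    if (any(m < 0) || nrow(m) != d$npop || ncol(m) != d$npop)
      bad <- c(bad, "migration matrices must be npop x npop with non-negative rates")
  if (sum(d$sample_sizes) < 2)
    bad <- c(bad, "total sample size must be at least 2")
  if (any(d$sample_sizes < 0))
    bad <- c(bad, "sample sizes must be non-negative")
  ev <- d$events
  if (nrow(ev)) {
    if (any(ev$time < 0)) bad <- c(bad, "event times must be >= 0")
    if (is.unsorted(ev$time)) bad <- c(bad, "events must be sorted by time")
    pr <- ev$proportion[!is.na(ev$source)]
    if (any(pr < 0 | pr > 1, na.rm = TRUE))
      bad <- c(bad, "event proportion out of range [0, 1]")
    idx <- c(ev$source[!is.na(ev$source)], ev$sink[!is.na(ev$sink)])
    if (any(idx < 1 | idx > d$npop))
      bad <- c(bad, "event deme index out of range")
    if (any(ev$new_size <= 0, na.rm = TRUE))
      bad <- c(bad, "event new_size must be positive")
    mid <- ev$migration_id[!is.na(ev$migration_id)]
    if (any(mid < 1 | mid > length(d$migration)))
      bad <- c(bad, "event migration_id out of range")
  }
  if (!length(bad) && !.closable(d))
    bad <- c(bad, "non-closable: sampled lineages can never reach a common deme")
  bad
}

# Reachability heuristic for closability: a directed edge k -> j exists if any
# migration matrix has m[k, j] > 0 or an event moves lineages k -> j with
# positive proportion. The model is closable when some deme is reachable from
# every sampled deme. (The simulator additionally guards at run time.)
.closable <- function(d) {
  npop <- d$npop
  adj <- matrix(FALSE, npop, npop)
  diag(adj) <- TRUE
  for (m in d$migration) adj <- adj | (m > 0)
  ev <- d$events
  for (i in seq_len(nrow(ev)))
    if (!is.na(ev$source[i]) && !is.na(ev$proportion[i]) && ev$proportion[i] > 0)
      adj[ev$source[i], ev$sink[i]] <- TRUE
  reach <- adj
  for (k in seq_len(npop)) reach <- reach | (reach %*% reach > 0)  # transitive closure
  sampled <- which(d$sample_sizes > 0)
  any(colSums(reach[sampled, , drop = FALSE]) == length(sampled))
}

#' @export
print.demography <- function(x, ...) {
  cat("Demographic model:", x$npop, "deme(s),",
      sum(x$sample_sizes), "sampled lineages\n")
  df <- data.frame(deme = seq_len(x$npop), size = x$sizes, growth = x$growth,
                   n = x$sample_sizes)
  print(df, row.names = FALSE)
  if (any(unlist(lapply(x$migration, function(m) any(m > 0)))))
    cat("migration matrices:", length(x$migration), "\n")
  if (nrow(x$events)) {
    cat("events:\n")
    print(x$events, row.names = FALSE)
  }
  v <- validate_demography(x)
  if (length(v)) cat("INVALID:", paste(v, collapse = "; "), "\n")
  invisible(x)
}

# Internal: translate to the 0-based flat representation the C++ engine takes.
as_cpp_model <- function(d) {
  ev <- d$events
  evm <- cbind(time = ev$time,
               source = ifelse(is.na(ev$source), -1, ev$source - 1),
               sink = ifelse(is.na(ev$sink), -1, ev$sink - 1),
               proportion = ifelse(is.na(ev$proportion), 0, ev$proportion),
               new_size = ev$new_size,
               new_growth = ev$new_growth,
               migration_id = ev$migration_id - 1)
  if (!nrow(evm)) evm <- matrix(numeric(0), 0, 7)
  list(npop = d$npop, sample_sizes = d$sample_sizes, sizes = d$sizes,
       growth = d$growth, migration = d$migration, events = evm)
}

check_valid_demography <- function(d) {
  v <- validate_demography(d)
  if (length(v))
    stop("invalid demography: ", paste(v, collapse = "; "), call. = FALSE)
  invisible(d)
}
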