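#' Read and write observed-SFS files
#'
#' Plain-text spectra in three dialects, chosen by dimensionality.
#'
#' 1-D: a first line `1 observations`, a header line `d0_0 ... d0_n`, and a
#' line of `n + 1` tab-separated counts.
#'
#' 2-D: `1 observations`, a header row of `d0_i` labels (deme 1 runs across
#' columns), then `n2 + 1` rows each starting with its `d1_j` label (deme 2
#' runs down rows).
#'
#' Multi-D (3 demes and more): `1 observations`, a dimensions line with the
#' `n_k + 1` extents, then the `prod(n_k + 1)` counts in lexicographic order
#' with the **last** deme's index varying fastest.
#'
#' A known monomorphic count sits in the all-ancestral cell. Writing then
#' reading a spectrum reproduces it exactly.
#'
#' @param path file path.
#' @param expected_dims optional per-deme sample sizes to validate against;
#'   a mismatch is an error naming both.
#' @param L optional total surveyed length in bp (when the file's
#'   all-ancestral cell does not already carry the monomorphic count).
#' @return [read_observed_sfs()]: an [observed_sfs()].
#' @export
read_observed_sfs <- function(path, expected_dims = NULL, L = NA) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines) || !grepl("^\\s*1\\s+observation", lines[1]))
    stop("line 1 of '", path, "': expected '1 observations' header")
  tok2 <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  if (all(grepl("^[0-9]+$", tok2))) {
    # multi-D: dims line then flat counts
    extents <- as.integer(tok2)
    dims <- extents - 1L
    counts <- as.numeric(unlist(strsplit(trimws(lines[-(1:2)]), "\\s+")))
    if (length(counts) != prod(extents))
      stop("line 3 of '", path, "': expected ", prod(extents),
           " counts, found ", length(counts))
  } else if (all(grepl("^d0_[0-9]+$", tok2))) {
    n0 <- length(tok2) - 1L
    body <- lines[-(1:2)]
    first <- strsplit(trimws(body[1]), "\\s+")[[1]]
    if (grepl("^d1_", first[1])) {
      # 2-D: rows are deme-2 classes
      rows <- lapply(body, function(l) strsplit(trimws(l), "\\s+")[[1]])
      n1 <- length(rows) - 1L
      dims <- c(n0, n1)
      counts <- numeric((n0 + 1L) * (n1 + 1L))
      for (j in seq_along(rows)) {
        r <- rows[[j]]
        if (!grepl("^d1_[0-9]+$", r[1]))
          stop("line ", j + 2, " of '", path, "': expected a d1_ row label")
        vals <- as.numeric(r[-1])
        if (length(vals) != n0 + 1L)
          stop("line ", j + 2, " of '", path, "': expected ", n0 + 1L,
               " counts, found ", length(vals))
        i0 <- 0:n0
        counts[i0 * (n1 + 1L) + (j - 1L) + 1L] <- vals
      }
    } else {
      dims <- n0
      counts <- as.numeric(first)
      if (length(counts) != n0 + 1L)
        stop("line 3 of '", path, "': expected ", n0 + 1L, " counts, found ",
             length(counts))
    }
  } else {
    stop("line 2 of '", path, "': expected d0_ labels or a dimensions line")
  }
  if (anyNA(counts)) stop("non-numeric count in '", path, "'")
  if (!is.null(expected_dims) &&
      !identical(as.integer(expected_dims), as.integer(dims)))
    stop("SFS dimensions in '", path, "' are (", paste(dims, collapse = ","),
         ") but the model expects (", paste(expected_dims, collapse = ","),
         ")")
  observed_sfs(counts, dims = dims, L = L)
}

#' @rdname read_observed_sfs
#' @param obs an [observed_sfs()] to write.
#' @export
write_observed_sfs <- function(obs, path) {
  stopifnot(inherits(obs, "obs_sfs"))
  v <- length(obs$dims)
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  if (v == 1) {
    n <- obs$dims
    lines <- c("1 observations",
               paste(paste0("d0_", 0:n), collapse = "\t"),
               paste(fmt(obs$counts), collapse = "\t"))
  } else if (v == 2) {
    n0 <- obs$dims[1]; n1 <- obs$dims[2]
    m <- sfs_vec_to_array(obs$counts, obs$dims)  # [i0+1, i1+1]
    lines <- c("1 observations",
               paste(paste0("d0_", 0:n0), collapse = "\t"),
               vapply(0:n1, function(j)
                 paste(c(paste0("d1_", j), fmt(m[, j + 1])), collapse = "\t"),
                 ""))
  } else {
    lines <- c("1 observations",
               paste(obs$dims + 1L, collapse = "\t"),
               paste(fmt(obs$counts), collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Model configuration files
# ---------------------------------------------------------------------------

#' Read a demographic-model configuration file
#'
#' Parses the package's structured-text model format into a [demography()]
#' (when every field is numeric) or a [parameter_space()] whose builder
#' substitutes parameter values into the template (when a `[parameters]`
#' section declares free or fixed parameters).
#'
#' The format has five sections, introduced by bracketed headers; `#` starts
#' a comment and blank lines are ignored. Times are in generations, sizes in
#' diploid individuals, rates per generation.
#'
#' `[populations]` -- one row per deme: `size growth sample_size`.
#'
#' `[migration]` -- one or more matrices, each introduced by a line
#' `matrix`, followed by `npop` rows of `npop` backward rates
#' (`m[from][to]`). The first matrix is active at present.
#'
#' `[events]` -- rows `time source sink proportion new_size new_growth
#' matrix_id`, with `.` for "unchanged"/not applicable.
#'
#' `[parameters]` -- rows `name kind lower upper scale free`, or
#' `name kind value fixed`; kinds are `size`, `time`, `rate`, `proportion`,
#' scales `log10` or `linear`.
#'
#' `[derived]` -- rows `name = expression` using `+ - * / min max` over
#' parameter names.
#'
#' Any `size`, `growth`, `time`, rate or proportion field in the first three
#' sections may be a parameter name instead of a number.
#'
#' @param path configuration file.
#' @return a [demography()] or [parameter_space()].
#' @export
read_model_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  keep <- nzchar(lines)
  lines <- lines[keep]
  lineno <- which(keep)
  sec <- ""
  secs <- list(populations = list(), migration = list(), events = list(),
               parameters = list(), derived = list())
  for (i in seq_along(lines)) {
    l <- lines[i]
    if (grepl("^\\[.*\\]$", l)) {
      sec <- gsub("\\[|\\]", "", l)
      if (!sec %in% names(secs))
        stop("line ", lineno[i], ": unknown section [", sec, "]")
      next
    }
    if (sec == "") stop("line ", lineno[i], ": content before any section")
    secs[[sec]] <- c(secs[[sec]], list(list(line = lineno[i], text = l)))
  }
  if (!length(secs$populations)) stop("config has no [populations] section")

  pops <- lapply(secs$populations, function(e) {
    f <- strsplit(e$text, "\\s+")[[1]]
    if (length(f) != 3)
      stop("line ", e$line, ": expected 'size growth sample_size'")
    f
  })
  npop <- length(pops)

  mats <- list(); cur <- NULL
  for (e in secs$migration) {
    if (identical(e$text, "matrix")) {
      if (!is.null(cur)) mats <- c(mats, list(cur))
      cur <- list()
    } else {
      if (is.null(cur)) stop("line ", e$line,
                             ": migration rows must follow a 'matrix' line")
      f <- strsplit(e$text, "\\s+")[[1]]
      if (length(f) != npop)
        stop("line ", e$line, ": migration row needs ", npop, " entries")
      cur <- c(cur, list(f))
    }
  }
  if (!is.null(cur)) mats <- c(mats, list(cur))
  for (m in mats) if (length(m) != npop)
    stop("each migration matrix needs ", npop, " rows")

  evs <- lapply(secs$events, function(e) {
    f <- strsplit(e$text, "\\s+")[[1]]
    if (length(f) != 7)
      stop("line ", e$line, ": expected 7 event fields ",
           "(time source sink proportion new_size new_growth matrix_id)")
    f
  })

  pars <- list()
  for (e in secs$parameters) {
    f <- strsplit(e$text, "\\s+")[[1]]
    if (length(f) == 6 && f[6] == "free") {
      pars <- c(pars, list(param(f[1], f[2], as.numeric(f[3]),
                                 as.numeric(f[4]), scale = f[5])))
    } else if (length(f) == 4 && f[4] == "fixed") {
      pars <- c(pars, list(param(f[1], f[2], value = as.numeric(f[3]))))
    } else {
      stop("line ", e$line, ": expected 'name kind lower upper scale free' ",
           "or 'name kind value fixed'",
           if (length(f) >= 4 && !f[length(f)] %in% c("free", "fixed"))
             " (free parameters need bounds)")
    }
  }
  derived <- list()
  for (e in secs$derived) {
    kv <- strsplit(e$text, "=")[[1]]
    if (length(kv) != 2) stop("line ", e$line, ": expected 'name = expression'")
    derived[[trimws(kv[1])]] <- trimws(kv[2])
  }

  resolve <- function(tok, th, what, integerish = FALSE) {
    if (tok == ".") return(NA_real_)
    v <- suppressWarnings(as.numeric(tok))
    if (!is.na(v)) return(v)
    if (!tok %in% names(th))
      stop("unknown parameter '", tok, "' used as ", what)
    th[[tok]]
  }
  build <- function(th) {
    sizes <- vapply(pops, function(p) resolve(p[1], th, "a deme size"), 0)
    growth <- vapply(pops, function(p) resolve(p[2], th, "a growth rate"), 0)
    samp <- vapply(pops, function(p) resolve(p[3], th, "a sample size"), 0)
    migm <- lapply(mats, function(m)
      do.call(rbind, lapply(m, function(r)
        vapply(r, resolve, 0, th = th, what = "a migration rate"))))
    events <- lapply(evs, function(f)
      hist_event(time = resolve(f[1], th, "an event time"),
                 source = resolve(f[2], th, "an event source"),
                 sink = resolve(f[3], th, "an event sink"),
                 proportion = resolve(f[4], th, "an event proportion"),
                 new_size = resolve(f[5], th, "an event size"),
                 new_growth = resolve(f[6], th, "an event growth"),
                 migration_id = resolve(f[7], th, "a matrix id")))
    demography(sample_sizes = samp, sizes = sizes, growth = growth,
               events = events,
               migration_matrices = if (length(migm)) migm else NULL)
  }
  if (!length(pars)) {
    d <- build(list())
    v <- validate_demography(d)
    if (length(v)) stop("invalid model in '", path, "': ",
                        paste(v, collapse = "; "))
    return(d)
  }
  parameter_space(pars, builder = build, derived = derived)
}
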