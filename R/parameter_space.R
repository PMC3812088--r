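#' Declare a model parameter
#'
#' Helper used inside [parameter_space()]. A parameter is either free (with
#' search bounds) or fixed at a value. The `kind` drives integer rounding at
#' binding time (sizes and times are rounded to whole numbers >= 1) and the
#' default search scale: sizes, times and rates are searched on a log10 scale
#' (search ranges in this kind of inference typically span several orders of
#' magnitude), proportions on a linear scale.
#'
#' @param name parameter name (used in derived expressions and the builder).
#' @param kind one of `"size"`, `"time"`, `"rate"`, `"proportion"`.
#' @param lower,upper search bounds for a free parameter.
#' @param value fixed value (makes the parameter fixed; bounds then unused).
#' @param scale `"log10"` or `"linear"`; default depends on `kind`.
#' @return a `"sfs_param"` object.
#' @export
param <- function(name, kind = c("size", "time", "rate", "proportion"),
                  lower = NA, upper = NA, value = NA, scale = NULL) {
  kind <- match.arg(kind)
  if (is.null(scale))
    scale <- if (kind == "proportion") "linear" else "log10"
  scale <- match.arg(scale, c("log10", "linear"))
  free <- is.na(value)
  if (free) {
    if (is.na(lower) || is.na(upper))
      stop("free parameter '", name, "' needs lower and upper bounds")
    if (!(lower < upper) && !(lower == upper))
      stop("bounds of '", name, "' must satisfy lower <= upper")
    if (scale == "log10" && lower <= 0)
      stop("log10-scaled parameter '", name, "' needs a positive lower bound")
    if (kind == "proportion" && (lower < 0 || upper > 1))
      stop("proportion '", name, "' must be bounded within [0, 1]")
  }
  structure(list(name = name, kind = kind, lower = as.numeric(lower),
                 upper = as.numeric(upper), value = as.numeric(value),
                 scale = scale, free = free), class = "sfs_param")
}

#' Parameter space of a demographic model
#'
#' Couples an ordered set of named parameters (free with search bounds, or
#' fixed), optional derived parameters defined by simple arithmetic
#' expressions, and a *builder* rule mapping a complete parameter vector to a
#' [demography()]. This is the object the optimizer searches over.
#'
#' Derived expressions may use the operators `+`, `-`, `*`, `/` and the
#' functions `min` and `max`, referring to parameter names defined earlier or
#' to other derived parameters (the dependency graph must be acyclic). This
#' is enough to encode, e.g., a bottleneck that ends a fixed number of
#' generations after it starts (`T_END = T_BOT + 100`).
#'
#' @param ... [param()] declarations, in the order the optimizer will cycle
#'   over them.
#' @param builder `function(th)` receiving the full named parameter list
#'   (free + fixed + derived, sizes and times already rounded) and returning
#'   a [demography()].
#' @param derived named list of derived-parameter expressions, as strings or
#'   unevaluated expressions.
#' @return an object of class `"parameter_space"`.
#' @examples
#' sp <- parameter_space(
#'   param("N_CUR", "size", 100, 1e6),
#'   param("N_BOT", "size", 1, 1e4),
#'   param("T_BOT", "time", 10, 1e5),
#'   param("N_ANC", "size", value = 10000),
#'   derived = list(T_END = "T_BOT + 100"),
#'   builder = function(th) {
#'     demography(sample_sizes = 20, sizes = th$N_CUR, events = list(
#'       hist_event(time = th$T_BOT, sink = 1, new_size = th$N_BOT),
#'       hist_event(time = th$T_END, sink = 1, new_size = th$N_ANC)))
#'   })
#' @export
parameter_space <- function(..., builder, derived = list()) {
  params <- list(...)
  if (length(params) == 1 && is.list(params[[1]]) &&
      !inherits(params[[1]], "sfs_param"))
    params <- params[[1]]
  stopifnot(all(vapply(params, inherits, TRUE, "sfs_param")),
            is.function(builder))
  nm <- vapply(params, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicated parameter names")
  derived <- lapply(derived, function(e)
    if (is.character(e)) parse(text = e)[[1]] else e)
  .check_derived(derived, nm)
  structure(list(params = params, names = nm, derived = derived,
                 builder = builder), class = "parameter_space")
}

# Restricted expression language for derived parameters and a topological
# order of their dependency graph; cycles and unknown symbols are errors.
.derived_ok_calls <- c("+", "-", "*", "/", "min", "max", "(")

.expr_names <- function(e) {
  if (is.name(e)) return(as.character(e))
  if (is.call(e)) {
    op <- as.character(e[[1]])
    if (!op %in% .derived_ok_calls)
      stop("derived expressions may only use +, -, *, /, min, max (got '",
           op, "')")
    return(unlist(lapply(as.list(e)[-1], .expr_names)))
  }
  if (is.numeric(e)) return(character(0))
  stop("unsupported token in derived expression")
}

.check_derived <- function(derived, param_names) {
  if (!length(derived)) return(character(0))
  dn <- names(derived)
  deps <- lapply(derived, .expr_names)
  for (i in seq_along(deps)) {
    unknown <- setdiff(deps[[i]], c(param_names, dn))
    if (length(unknown))
      stop("derived parameter '", dn[i], "' references unknown name(s): ",
           paste(unknown, collapse = ", "))
  }
  # Kahn's algorithm over derived-on-derived edges
  order <- character(0)
  pending <- dn
  repeat {
    ready <- pending[vapply(pending, function(d)
      !any(intersect(deps[[d]], dn) %in% pending), TRUE)]
    if (!length(ready)) {
      if (length(pending)) stop("cyclic derived-parameter definitions: ",
                                paste(pending, collapse = ", "))
      break
    }
    order <- c(order, ready)
    pending <- setdiff(pending, ready)
  }
  order
}

free_params <- function(space) {
  space$params[vapply(space$params, `[[`, TRUE, "free")]
}

#' Bind a parameter vector into a concrete demography
#'
#' Checks bounds, evaluates derived parameters, rounds integer-valued kinds
#' (sizes, times) to the nearest whole number (at least 1), and calls the
#' space's builder. Binding is pure: identical `theta` always yields an
#' identical demography, and the likelihood is evaluated on the rounded
#' values.
#'
#' @param space a [parameter_space()].
#' @param theta named numeric vector of the free parameters (extra names are
#'   ignored; missing free parameters are an error).
#' @return a [demography()].
#' @export
bind_parameters <- function(space, theta) {
  stopifnot(inherits(space, "parameter_space"))
  th <- list()
  for (p in space$params) {
    if (p$free) {
      if (!p$name %in% names(theta))
        stop("missing value for free parameter '", p$name, "'")
      v <- as.numeric(theta[[p$name]])
      if (!is.finite(v) || v < p$lower || v > p$upper)
        stop("parameter '", p$name, "' = ", v, " outside bounds [",
             p$lower, ", ", p$upper, "]")
    } else v <- p$value
    th[[p$name]] <- v
  }
  ord <- .check_derived(space$derived, space$names)
  for (d in ord)
    th[[d]] <- eval(space$derived[[d]], envir = th)
  kinds <- setNames(vapply(space$params, `[[`, "", "kind"),
                    space$names)
  for (nm in names(th)) {
    k <- if (nm %in% names(kinds)) kinds[[nm]] else "time"  # derived: times
    if (k %in% c("size", "time")) th[[nm]] <- max(1, round(th[[nm]]))
  }
  space$builder(th)
}

#' Draw random starting values for the free parameters
#'
#' Each free parameter is drawn independently and uniformly on its search
#' scale: uniform on `[lower, upper]` for linear-scale parameters, uniform on
#' `[log10(lower), log10(upper)]` (then exponentiated) for log10-scale ones.
#' Used to initialize independent optimization runs.
#'
#' @param space a [parameter_space()].
#' @param n number of draws.
#' @return for `n = 1` a named vector; otherwise an `n` x p matrix.
#' @export
sample_initial_parameters <- function(space, n = 1) {
  fp <- free_params(space)
  draw <- function() vapply(fp, function(p) {
    if (p$scale == "log10") 10^runif(1, log10(p$lower), log10(p$upper))
    else runif(1, p$lower, p$upper)
  }, 0)
  out <- t(vapply(seq_len(n), function(i) draw(), numeric(length(fp))))
  colnames(out) <- vapply(fp, `[[`, "", "name")
  if (n == 1) out[1, ] else out
}

#' @export
print.parameter_space <- function(x, ...) {
  df <- data.frame(name = x$names,
                   kind = vapply(x$params, `[[`, "", "kind"),
                   lower = vapply(x$params, `[[`, 0, "lower"),
                   upper = vapply(x$params, `[[`, 0, "upper"),
                   scale = vapply(x$params, `[[`, "", "scale"),
                   fixed = ifelse(vapply(x$params, `[[`, TRUE, "free"), "",
                                  vapply(x$params, `[[`, 0, "value")))
  cat("Parameter space (", sum(vapply(x$params, `[[`, TRUE, "free")),
      " free of ", length(x$params), "):\n", sep = "")
  print(df, row.names = FALSE)
  if (length(x$derived))
    cat("derived:", paste(names(x$derived), vapply(x$derived, deparse, ""),
                          sep = " = ", collapse = "; "), "\n")
  invisible(x)
}
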