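#' Piecewise-linear fuzzy set
#'
#' A fuzzy set is a named membership function defined by an ordered list of
#' `(x, mu)` breakpoints. Between breakpoints the membership degree is linearly
#' interpolated; beyond the first/last breakpoint it extends as a constant at
#' the boundary degree, so trapezoidal plateaus written as two points (e.g.
#' `(0,1),(60,1)`) behave as intended over the whole variable domain.
#'
#' @param name Short label for the linguistic term, e.g. `"low"`, `"normal"`.
#' @param points Two-column numeric matrix (or data.frame) of breakpoints;
#'   column 1 is the domain value `x` (strictly increasing), column 2 the
#'   membership degree `mu` in `[0, 1]`. At least two breakpoints.
#' @return An object of class `fuzzy_set`.
#' @examples
#' s <- fuzzy_set("normal", cbind(c(75, 105, 130), c(0, 1, 0)))
#' membership(s, 105)
#' @export
fuzzy_set <- function(name, points) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 2L || nrow(points) < 2L)
    stop("'points' must be a numeric matrix with 2 columns and >= 2 rows",
         call. = FALSE)
  if (anyNA(points) || any(!is.finite(points)))
    stop("fuzzy set breakpoints must be finite", call. = FALSE)
  if (any(diff(points[, 1L]) <= 0))
    stop("fuzzy set '", name, "': breakpoint x values must be strictly increasing",
         call. = FALSE)
  if (any(points[, 2L] < 0 | points[, 2L] > 1))
    stop("fuzzy set '", name, "': membership degrees must lie in [0, 1]",
         call. = FALSE)
  dimnames(points) <- list(NULL, c("x", "mu"))
  structure(list(name = name, points = points), class = "fuzzy_set")
}

#' @export
print.fuzzy_set <- function(x, ...) {
  pts <- paste0("(", x$points[, 1L], ", ", x$points[, 2L], ")",
                collapse = ", ")
  cat("<fuzzy_set> ", x$name, ": {", pts, "}\n", sep = "")
  invisible(x)
}

#' Evaluate a fuzzy set's membership function
#'
#' Linear interpolation between the bracketing breakpoints; constant extension
#' at the boundary degree outside the breakpoint range. A value falling exactly
#' on a breakpoint evaluates to that breakpoint's printed degree.
#'
#' @param set A [fuzzy_set()].
#' @param x Numeric vector of crisp values; must be finite.
#' @return Numeric vector of degrees in `[0, 1]`, one per element of `x`.
#' @export
membership <- function(set, x) {
  stopifnot(inherits(set, "fuzzy_set"))
  if (length(x) == 0L) return(numeric(0))
  if (anyNA(x) || any(!is.finite(x)))
    stop("membership() requires finite input values", call. = FALSE)
  stats::approx(set$points[, "x"], set$points[, "mu"], xout = x,
                method = "linear", rule = 2L)$y
}

#' Linguistic variable
#'
#' A named input or output quantity with units, a closed domain `[lo, hi]` and
#' a collection of fuzzy sets (its linguistic terms). Term names must be unique
#' within the variable.
#'
#' @param name Variable name, e.g. `"MBP"`.
#' @param units Measurement units (`"mmHg"`, `"%"`, or `"score"`).
#' @param domain Numeric length-2 vector `c(lo, hi)`, `lo < hi`.
#' @param sets List of [fuzzy_set()] objects.
#' @return An object of class `linguistic_variable`.
#' @export
linguistic_variable <- function(name, units, domain, sets) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(units), length(units) == 1L,
            is.numeric(domain), length(domain) == 2L, domain[1L] < domain[2L])
  if (!is.list(sets) || length(sets) == 0L ||
      !all(vapply(sets, inherits, logical(1), "fuzzy_set")))
    stop("'sets' must be a non-empty list of fuzzy_set objects", call. = FALSE)
  nm <- vapply(sets, `[[`, character(1), "name")
  if (anyDuplicated(nm))
    stop("variable '", name, "': duplicate term names", call. = FALSE)
  names(sets) <- nm
  structure(list(name = name, units = units,
                 domain = as.numeric(domain), sets = sets),
            class = "linguistic_variable")
}

#' @export
print.linguistic_variable <- function(x, ...) {
  cat("<linguistic_variable> ", x$name, " [", x$domain[1L], ", ",
      x$domain[2L], "] ", x$units, "\n", sep = "")
  for (s in x$sets) print(s)
  invisible(x)
}

#' Fuzzify a crisp value
#'
#' Maps a crisp measurement to its membership degree in every term of a
#' linguistic variable. Values outside the variable's domain are clamped to
#' the nearest bound (with a warning), so fuzzification is total: at least
#' one term always has a strictly positive degree. A domain boundary point
#' where every membership function vanishes exactly (e.g. a saturation
#' reading of exactly 100 % against a normal-term function whose last
#' breakpoint is `(100, 0)`) is pulled inward in 0.01 steps — the coverage
#' grid resolution — until a term covers it.
#'
#' @param variable A [linguistic_variable()].
#' @param x Single finite numeric value.
#' @return Named numeric vector, one degree in `[0, 1]` per term.
#' @examples
#' eng <- default_engine()
#' fuzzify(eng$variables$MBP, 126)
#' @export
fuzzify <- function(variable, x) {
  stopifnot(inherits(variable, "linguistic_variable"),
            is.numeric(x), length(x) == 1L)
  if (is.na(x) || !is.finite(x))
    stop("fuzzify() requires a finite input value", call. = FALSE)
  lo <- variable$domain[1L]; hi <- variable$domain[2L]
  if (x < lo || x > hi) {
    warning(sprintf("%s = %g outside domain [%g, %g]; clamped",
                    variable$name, x, lo, hi), call. = FALSE)
    x <- min(max(x, lo), hi)
  }
  deg <- vapply(variable$sets, membership, numeric(1), x = x)
  step <- if (x > (lo + hi) / 2) -0.01 else 0.01
  while (all(deg == 0) && x >= lo && x <= hi) {
    x <- x + step
    deg <- vapply(variable$sets, membership, numeric(1), x = x)
  }
  deg
}
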