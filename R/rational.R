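#' Exact rational numbers
#'
#' `rational()` creates vectors of arbitrary-precision rational numbers.
#' Values are stored in canonical lowest-terms form (positive denominator),
#' so `==` is decidable and exact. The usual arithmetic operators, integer
#' powers, comparisons, `sum()` and `prod()` are available, and values
#' render to doubles with [as.numeric()].
#'
#' Inputs may be integer-valued numerics, integers, strings like `"11/9"`
#' or `"-3"`, or existing rational vectors. Non-integral doubles are
#' rejected rather than approximated: exactness is the point of the class.
#'
#' @param x Integer-valued numeric, character (`"p"` or `"p/q"`), or
#'   rational vector.
#' @return An object of class `"rational"`.
#' @examples
#' rational("11/9") + rational(2)
#' rational(1) / rational(3) == rational("2/6")
#' as.numeric(rational("-355/113"))
#' @export
rational <- function(x) {
  if (is_rational(x)) return(x)
  if (is.character(x)) {
    return(new_rational(.rat_canonical(x)))
  }
  if (is.numeric(x)) {
    bad <- is.na(x) | x != floor(x) | abs(x) >= 2^53
    if (any(bad)) {
      stop("rational() accepts only integer-valued numerics; got ",
           paste(utils::head(x[bad], 3), collapse = ", "))
    }
    return(new_rational(sprintf("%.0f", x)))
  }
  stop("cannot coerce object of class '", class(x)[1], "' to rational")
}

new_rational <- function(x) structure(x, class = "rational")

#' Test for rational vectors
#' @param x An object.
#' @return `TRUE` if `x` is a rational vector.
#' @export
is_rational <- function(x) inherits(x, "rational")

as_rat_pair <- function(e1, e2) {
  list(rational(e1), rational(e2))
}

#' @export
Ops.rational <- function(e1, e2) {
  if (missing(e2)) {
    if (.Generic == "-") return(rational(0) - e1)
    if (.Generic == "+") return(e1)
    stop("unary '", .Generic, "' not defined for rationals")
  }
  if (.Generic == "^") {
    ex <- if (is_rational(e2)) as.numeric(e2) else e2
    if (any(ex != floor(ex))) stop("rational '^' needs an integer exponent")
    return(new_rational(.rat_pow(rational(e1), as.integer(ex))))
  }
  p <- as_rat_pair(e1, e2)
  op <- match(.Generic, c("+", "-", "*", "/"))
  if (!is.na(op)) {
    return(new_rational(.rat_arith(op, p[[1]], p[[2]])))
  }
  cmp <- .rat_cmp(p[[1]], p[[2]])
  switch(.Generic,
    "==" = cmp == 0L, "!=" = cmp != 0L,
    "<" = cmp < 0L, "<=" = cmp <= 0L,
    ">" = cmp > 0L, ">=" = cmp >= 0L,
    stop("'", .Generic, "' not defined for rationals"))
}

#' @export
Summary.rational <- function(..., na.rm = FALSE) {
  xs <- unclass(c(...))
  if (.Generic == "sum") {
    acc <- "0"
    for (v in xs) acc <- .rat_arith(1L, acc, v)
    return(new_rational(acc))
  }
  if (.Generic == "prod") {
    acc <- "1"
    for (v in xs) acc <- .rat_arith(3L, acc, v)
    return(new_rational(acc))
  }
  if (.Generic %in% c("min", "max")) {
    acc <- xs[1]
    for (v in xs[-1]) {
      cmp <- .rat_cmp(acc, v)
      if ((.Generic == "min" && cmp > 0) || (.Generic == "max" && cmp < 0)) acc <- v
    }
    return(new_rational(acc))
  }
  stop("'", .Generic, "' not defined for rationals")
}

#' @export
as.numeric.rational <- function(x, ...) .rat_to_double(unclass(x))

#' @export
as.double.rational <- function(x, ...) .rat_to_double(unclass(x))

#' @export
as.character.rational <- function(x, ...) as.character(unclass(x))

#' @export
format.rational <- function(x, ...) format(unclass(x), ...)

#' @export
print.rational <- function(x, ...) {
  cat("<exact rational>\n")
  print(unclass(x), quote = FALSE, ...)
  invisible(x)
}

#' @export
`[.rational` <- function(x, i) new_rational(unclass(x)[i])

#' @export
length.rational <- function(x) length(unclass(x))

#' @export
c.rational <- function(...) {
  new_rational(unlist(lapply(list(...), function(v) unclass(rational(v)))))
}

#' @export
abs.rational <- function(x) {
  neg <- .rat_cmp(unclass(x), "0") < 0
  out <- unclass(x)
  if (any(neg)) out[neg] <- .rat_arith(2L, "0", out[neg])
  new_rational(out)
}
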