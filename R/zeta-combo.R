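#' Exact constants over the basis {1, pi^2, pi^4, pi^6, zeta(3), pi^2 zeta(3)}
#'
#' Every finite large-sample limit of the moments, covariances, and ratio
#' approximations in this package lies in the rational span of the six
#' constants 1, \eqn{\pi^2}, \eqn{\pi^4}, \eqn{\pi^6}, \eqn{\zeta(3)}, and
#' \eqn{\pi^2\zeta(3)} (the even zeta values \eqn{\zeta(2)=\pi^2/6},
#' \eqn{\zeta(4)=\pi^4/90}, \eqn{\zeta(6)=\pi^6/945} are rational multiples
#' of powers of pi). `zeta_combo()` represents such a constant exactly by
#' its six rational coefficients; equality is coefficient-wise.
#'
#' @param one,pi2,pi4,pi6,zeta3,pi2zeta3 Coefficients; anything accepted by
#'   [rational()].
#' @return An object of class `"zeta_combo"`.
#' @examples
#' # pi^2/3 - 2, the limiting expectation of the basal-branch summary
#' as.numeric(zeta_combo(one = -2, pi2 = "1/3"))
#' @export
zeta_combo <- function(one = 0, pi2 = 0, pi4 = 0, pi6 = 0,
                       zeta3 = 0, pi2zeta3 = 0) {
  structure(list(coef = list(one = rational(one), pi2 = rational(pi2),
                             pi4 = rational(pi4), pi6 = rational(pi6),
                             zeta3 = rational(zeta3),
                             pi2zeta3 = rational(pi2zeta3))),
            class = "zeta_combo")
}

#' @export
is_zeta_combo <- function(x) inherits(x, "zeta_combo")

zc_names <- c("one", "pi2", "pi4", "pi6", "zeta3", "pi2zeta3")

as_zeta_combo <- function(x) {
  if (is_zeta_combo(x)) return(x)
  zeta_combo(one = rational(x))
}

#' @export
Ops.zeta_combo <- function(e1, e2) {
  if (missing(e2)) {
    if (.Generic == "-") return(as_zeta_combo(0) - e1)
    return(e1)
  }
  if (.Generic %in% c("+", "-")) {
    a <- as_zeta_combo(e1); b <- as_zeta_combo(e2)
    out <- zeta_combo()
    for (nm in zc_names) {
      out$coef[[nm]] <- if (.Generic == "+") a$coef[[nm]] + b$coef[[nm]]
                        else a$coef[[nm]] - b$coef[[nm]]
    }
    return(out)
  }
  if (.Generic == "*") {
    # scalar (rational) times combo only; basis products are not needed here
    if (is_zeta_combo(e1) && is_zeta_combo(e2)) {
      stop("products of two basis combinations are not supported")
    }
    combo <- if (is_zeta_combo(e1)) e1 else e2
    scl <- rational(if (is_zeta_combo(e1)) e2 else e1)
    out <- combo
    for (nm in zc_names) out$coef[[nm]] <- out$coef[[nm]] * scl
    return(out)
  }
  if (.Generic %in% c("==", "!=")) {
    a <- as_zeta_combo(e1); b <- as_zeta_combo(e2)
    eq <- all(vapply(zc_names, function(nm) a$coef[[nm]] == b$coef[[nm]],
                     logical(1)))
    return(if (.Generic == "==") eq else !eq)
  }
  stop("'", .Generic, "' not defined for zeta_combo objects")
}

#' @export
as.double.zeta_combo <- function(x, ...) as.numeric.zeta_combo(x)

#' @export
as.numeric.zeta_combo <- function(x, ...) {
  basis <- c(1, pi^2, pi^4, pi^6, 1.2020569031595942854, # zeta(3)
             pi^2 * 1.2020569031595942854)
  sum(vapply(seq_along(zc_names),
             function(i) as.numeric(x$coef[[zc_names[i]]]) * basis[i],
             numeric(1)))
}

#' @export
format.zeta_combo <- function(x, ...) {
  lab <- c("", "*pi^2", "*pi^4", "*pi^6", "*zeta(3)", "*pi^2*zeta(3)")
  parts <- character(0)
  for (i in seq_along(zc_names)) {
    co <- x$coef[[zc_names[i]]]
    if (co != rational(0)) {
      parts <- c(parts, paste0("(", as.character(co), ")", lab[i]))
    }
  }
  if (!length(parts)) parts <- "0"
  paste0(paste(parts, collapse = " + "), " = ",
         format(round(as.numeric(x), 5), nsmall = 5))
}

#' @export
print.zeta_combo <- function(x, ...) {
  cat("<exact constant> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Sentinel values for limits and undefined quantities
#'
#' `coal_divergent()` marks a limit that grows without bound (for example
#' the expectation of the total branch length); `coal_undefined()` marks a
#' quantity outside its validity domain (for example the basal-branch
#' summary with fewer than four leaves). The two are distinct on purpose:
#' callers must be able to tell "grows without bound" from "not defined".
#'
#' @return A sentinel object of class `"coal_sentinel"`.
#' @export
coal_divergent <- function() {
  structure(list(kind = "divergent"), class = "coal_sentinel")
}

#' @rdname coal_divergent
#' @export
coal_undefined <- function() {
  structure(list(kind = "undefined"), class = "coal_sentinel")
}

#' @rdname coal_divergent
#' @param x An object.
#' @export
is_divergent <- function(x) {
  inherits(x, "coal_sentinel") && x$kind == "divergent"
}

#' @rdname coal_divergent
#' @export
is_undefined <- function(x) {
  inherits(x, "coal_sentinel") && x$kind == "undefined"
}

#' @export
as.numeric.coal_sentinel <- function(x, ...) {
  if (x$kind == "divergent") Inf else NaN
}

#' @export
as.double.coal_sentinel <- function(x, ...) as.numeric.coal_sentinel(x)

#' @export
print.coal_sentinel <- function(x, ...) {
  cat("<", x$kind, ">\n", sep = "")
  invisible(x)
}

#' Render an exact scalar as a double
#'
#' Convenience dispatcher for the value types used throughout the package:
#' rationals, basis combinations, sentinels, and plain numerics all render
#' to a double (`Inf` for divergent limits, `NaN` for undefined values).
#'
#' @param x A rational, `zeta_combo`, sentinel, or numeric scalar.
#' @return A double.
#' @export
exact_value <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  as.numeric(x)
}
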