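#' Generalised harmonic sums
#'
#' `harmonic_sum(p, n)` computes \eqn{S_{p,n} = \sum_{k=1}^{n} k^{-p}}, the
#' building block of every closed-form moment in the package. With
#' `exact = TRUE` the result is an exact [rational()]; with `exact = FALSE`
#' it is a double computed through the polygamma function, which stays
#' accurate for very large `n` (e.g. `n = 1e7`) where exact arithmetic is
#' out of the question:
#' \eqn{S_{1,n} = \psi(n+1) + \gamma},
#' \eqn{S_{2,n} = \pi^2/6 - \psi'(n+1)},
#' \eqn{S_{3,n} = \zeta(3) + \psi''(n+1)/2}.
#'
#' @param p Integer order, `p >= 1`.
#' @param n Integer upper limit, `n >= 0` (the empty sum is 0).
#' @param exact Return an exact rational (default) or a double.
#' @return A [rational()] scalar or a double.
#' @examples
#' harmonic_sum(1, 3)                  # 11/6
#' harmonic_sum(2, 100, exact = FALSE) # close to pi^2/6
#' @export
harmonic_sum <- function(p, n, exact = TRUE) {
  check_count(p, "p", min = 1)
  check_count(n, "n", min = 0)
  if (exact) {
    return(new_rational(.rat_harmonic(as.integer(p), as.integer(n))))
  }
  if (n == 0) return(0)
  if (p == 1) return(digamma(n + 1) - digamma(1))
  if (p == 2) return(pi^2 / 6 - psigamma(n + 1, 1))
  if (p == 3) return(zeta3_const + psigamma(n + 1, 2) / 2)
  # general order: direct sum (converges fast; cap the number of terms)
  k <- seq_len(min(n, 1e7))
  s <- sum(k^(-p))
  if (n > 1e7) s <- s + (1e7^(1 - p)) / (p - 1)  # integral tail bound remainder
  s
}

zeta3_const <- 1.2020569031595942854

#' Limits of generalised harmonic sums
#'
#' Returns \eqn{\lim_{n\to\infty} S_{p,n} = \zeta(p)}. The limit diverges
#' for `p = 1`; for `p` in {2, 3, 4, 6} it is returned exactly over the
#' package's constant basis; for other orders a double approximation of
#' \eqn{\zeta(p)} is returned.
#'
#' @param p Integer order, `p >= 1`.
#' @return A [zeta_combo()], a divergent sentinel, or a double.
#' @examples
#' harmonic_limit(1)  # diverges
#' as.numeric(harmonic_limit(2))  # 1.64493...
#' @export
harmonic_limit <- function(p) {
  check_count(p, "p", min = 1)
  switch(as.character(p),
    "1" = coal_divergent(),
    "2" = zeta_combo(pi2 = "1/6"),
    "3" = zeta_combo(zeta3 = 1),
    "4" = zeta_combo(pi4 = "1/90"),
    "6" = zeta_combo(pi6 = "1/945"),
    {
      k <- seq_len(1e6)
      sum(k^(-p)) + (1e6^(1 - p)) / (p - 1)
    })
}

check_count <- function(x, name, min) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x != floor(x) || x < min) {
    stop("'", name, "' must be a single integer >= ", min, call. = FALSE)
  }
  invisible(x)
}
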