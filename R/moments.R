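#' Exact expectations and variances of coalescent tree summaries
#'
#' Closed-form first and second moments of the six tree summaries under the
#' standard constant-size coalescent, as functions of the sample size `n`.
#' Writing \eqn{S_{p,m} = \sum_{k=1}^m k^{-p}}:
#' \deqn{E[H_n] = 2(n-1)/n, \quad E[L_n] = 2S_{1,n-1}, \quad E[E_n] = 2,}
#' \deqn{E[I_n] = 2S_{1,n-1} - 2, \quad E[B_n] = 2S_{2,n-1} - 2 + 2/n,
#'       \quad E[T_k] = 2/(k(k-1)).}
#' Variances follow the corresponding published closed forms (for example
#' \eqn{Var[T_k] = 4/(k^2(k-1)^2)} and
#' \eqn{Var[H_n] = 8(S_{2,n} - 1) - 4((n-1)/n)^2}).
#'
#' With `exact = TRUE` (default) all values are exact rationals; with
#' `exact = FALSE` they are doubles, usable for very large `n`.
#'
#' @param stat A [tree_stat()] or a label such as `"H"` or `"T3"`.
#' @param n Sample size (number of leaves); must lie in the statistic's
#'   validity domain (see [stat_min_n()]).
#' @param exact Exact rational (default) or double arithmetic.
#' @return A [rational()] scalar, or a double if `exact = FALSE`.
#' @examples
#' stat_mean("B", 4)                      # 11/9
#' as.numeric(stat_variance("H", 10))
#' @export
stat_mean <- function(stat, n, exact = TRUE) {
  stat <- as_tree_stat(stat)
  n <- check_stat_n(stat, n)
  x <- moment_ctx(n, exact)
  switch(stat$kind,
    H = x$two * (x$nn - 1) / x$nn,
    L = x$two * x$S1,
    E = x$two,
    I = x$two * x$S1 - 2,
    B = x$two * x$S2 - 2 + x$two / x$nn,
    T = {
      kk <- x$lift(stat$k)
      x$two / (kk * (kk - 1))
    })
}

#' @rdname stat_mean
#' @export
stat_variance <- function(stat, n, exact = TRUE) {
  stat <- as_tree_stat(stat)
  n <- check_stat_n(stat, n)
  x <- moment_ctx(n, exact)
  nn <- x$nn
  switch(stat$kind,
    H = x$eight * x$Z2n - 8 - x$four * ((nn - 1) / nn)^2,
    L = x$four * x$S2,
    E = if (n == 2) x$lift(4)
        else x$eight * (nn * x$S1 - 2 * (nn - 1)) / ((nn - 1) * (nn - 2)),
    I = x$four * (x$two * (nn * x$S1 - 2 * (nn - 1)) / ((nn - 1) * (nn - 2)) -
                  x$two * x$S1 / (nn - 1) + x$S2),
    B = x$two * (3 * x$S2 * nn^2 - x$two * x$S2^2 * nn^2 - x$four * x$S2 * nn +
                 nn^2 + 3 * nn - 4) / nn^2,
    T = {
      kk <- x$lift(stat$k)
      x$four / (kk^2 * (kk - 1)^2)
    })
}

# Shared evaluation context: n, harmonic sums of order 1..3 at n-1, and
# S_{2,n}, lifted either to exact rationals or to doubles.
moment_ctx <- function(n, exact) {
  lift <- if (exact) function(v) rational(v) else function(v) as.numeric(v)
  list(
    nn = lift(n),
    S1 = harmonic_sum(1, n - 1, exact = exact),
    S2 = harmonic_sum(2, n - 1, exact = exact),
    S3 = harmonic_sum(3, n - 1, exact = exact),
    Z2n = harmonic_sum(2, n, exact = exact),
    two = lift(2), four = lift(4), eight = lift(8),
    lift = lift)
}

#' Large-sample limits of the tree-summary moments
#'
#' Exact \eqn{n \to \infty} limits of [stat_mean()] and [stat_variance()].
#' Finite limits are returned exactly: rationals where the limit is
#' rational (for example \eqn{E[T_k]}, which does not depend on `n`), and
#' [zeta_combo()] basis combinations otherwise (for example
#' \eqn{\lim Var[H_n] = 4\pi^2/3 - 12}). The expectations of the total and
#' internal branch lengths grow without bound and return the divergent
#' sentinel.
#'
#' @param stat A [tree_stat()] or label.
#' @return A [rational()], [zeta_combo()], or [coal_divergent()] sentinel.
#' @examples
#' as.numeric(stat_mean_limit("B"))      # pi^2/3 - 2 = 1.28987...
#' stat_mean_limit("L")                  # diverges
#' as.numeric(stat_variance_limit("H"))  # 4 pi^2/3 - 12 = 1.15947...
#' @export
stat_mean_limit <- function(stat) {
  stat <- as_tree_stat(stat)
  switch(stat$kind,
    H = rational(2),
    L = coal_divergent(),
    E = rational(2),
    I = coal_divergent(),
    B = zeta_combo(one = -2, pi2 = "1/3"),
    T = {
      k <- rational(stat$k)
      rational(2) / (k * (k - 1))
    })
}

#' @rdname stat_mean_limit
#' @export
stat_variance_limit <- function(stat) {
  stat <- as_tree_stat(stat)
  switch(stat$kind,
    H = zeta_combo(one = -12, pi2 = "4/3"),
    L = zeta_combo(pi2 = "2/3"),
    E = rational(0),
    I = zeta_combo(pi2 = "2/3"),
    B = zeta_combo(one = 2, pi2 = 1, pi4 = "-1/9"),
    T = {
      k <- rational(stat$k)
      rational(4) / (k^2 * (k - 1)^2)
    })
}
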