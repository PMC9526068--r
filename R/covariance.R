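#' Covariances of pairs of coalescent tree summaries
#'
#' Exact finite-`n` covariances for all pairs among the six tree summaries,
#' from the published compendium of pairwise covariances. Thirteen of the
#' fifteen pairs are exact; the covariances of the pairs (E, B) and (I, B)
#' are themselves approximations, and the result carries an `approximate`
#' flag that propagates to every downstream quantity consuming them.
#'
#' Pairs involving `E` or `I` require `n >= 3`; pairs involving `B` require
#' `n >= 4`. Two coalescence times with different levels, `(T(j), T(k))`
#' with `j != k`, are rejected: the compendium does not include them (they
#' are independent, but exposing that would extend the published table).
#' A pair of a statistic with itself returns its variance.
#'
#' @param x,y [tree_stat()] objects or labels (`"H"`, ..., `"T3"`).
#' @param n Sample size, inside the joint validity domain.
#' @param exact Exact rational (default) or double arithmetic.
#' @return An object of class `"coal_cov"`: a list with elements `value`
#'   (a [rational()] or double) and `approximate` (logical).
#' @examples
#' stat_covariance("H", "T2", 10)$value      # Var[T_2] = 1
#' stat_covariance("E", "B", 6)$approximate  # TRUE
#' @export
stat_covariance <- function(x, y, n, exact = TRUE) {
  x <- as_tree_stat(x); y <- as_tree_stat(y)
  n <- check_stat_n(x, n)
  n <- check_stat_n(y, n)
  if (identical(stat_label(x), stat_label(y))) {
    return(new_cov(stat_variance(x, n, exact = exact), FALSE))
  }
  if (x$kind == "T" && y$kind == "T") {
    stop("covariance of two coalescence times with different levels is ",
         "not part of the compendium")
  }
  key <- pair_key(x, y)
  k <- if (x$kind == "T") x$k else if (y$kind == "T") y$k else NULL
  ctx <- moment_ctx(n, exact)
  new_cov(cov_formula(key, ctx, k), key %in% c("E:B", "I:B"))
}

new_cov <- function(value, approximate) {
  structure(list(value = value, approximate = approximate),
            class = "coal_cov")
}

#' @export
print.coal_cov <- function(x, ...) {
  cat("<covariance", if (x$approximate) " (approximate)", "> ", sep = "")
  if (is_rational(x$value) || is_zeta_combo(x$value)) {
    cat(format(x$value), "\n")
  } else {
    print(x$value)
  }
  invisible(x)
}

# canonical unordered key, kinds sorted in fixed order with T last
pair_key <- function(x, y) {
  ord <- c(H = 1, L = 2, E = 3, I = 4, B = 5, T = 6)
  kinds <- c(x$kind, y$kind)[order(ord[c(x$kind, y$kind)])]
  paste(kinds, collapse = ":")
}

cov_formula <- function(key, x, k = NULL) {
  nn <- x$nn
  kk <- if (!is.null(k)) x$lift(k) else NULL
  switch(key,
    "H:T" = x$four / (kk^2 * (kk - 1)^2),
    "H:L" = x$four * x$S2 - 4 + x$four / nn,
    "H:E" = x$four / nn,
    "H:I" = x$four * x$S2 - 4,
    "H:B" = x$four * (x$S3 * nn^2 - 3 * x$S2 * nn^2 +
                      (4 * nn + 1) * (nn - 1)) / nn^2,
    "L:T" = x$four / (kk * (kk - 1)^2),
    "L:E" = x$four * x$S1 / (nn - 1),
    "L:I" = x$four * x$S2 - x$four * x$S1 / (nn - 1),
    "L:B" = x$four * (x$S3 * nn - x$S2 * nn + nn - 1) / nn,
    "E:T" = x$four / (kk * (kk - 1) * (nn - 1)),
    "E:I" = x$four * x$S1 / (nn - 1) -
            x$eight * x$S1 * nn / ((nn - 1) * (nn - 2)) +
            x$lift(16) / (nn - 2),
    "E:B" = x$four * (x$S2 * nn - nn + 1) / (nn * (nn - 1)),
    "I:T" = x$four * (nn - kk) / (kk * (kk - 1)^2 * (nn - 1)),
    "I:B" = x$four * (x$S3 * nn - x$S2 * nn + nn - x$S3 - 1) / (nn - 1),
    "B:T" = x$four / (kk^2 * (kk - 1)^3),
    stop("no covariance formula for pair ", key))
}

#' Large-sample limits of the pairwise covariances
#'
#' Exact \eqn{n \to \infty} limits of [stat_covariance()], over the
#' package's constant basis. For pairs with a coalescence time the limit
#' may depend on `k`; for (H, B) for example the limit is
#' \eqn{-2\pi^2 + 4\zeta(3) + 16 \approx 1.06902}.
#'
#' @inheritParams stat_covariance
#' @return A `"coal_cov"` whose `value` is a [rational()] or
#'   [zeta_combo()].
#' @examples
#' as.numeric(stat_covariance_limit("H", "B")$value)  # 1.06902...
#' @export
stat_covariance_limit <- function(x, y) {
  x <- as_tree_stat(x); y <- as_tree_stat(y)
  if (identical(stat_label(x), stat_label(y))) {
    return(new_cov(stat_variance_limit(x), FALSE))
  }
  if (x$kind == "T" && y$kind == "T") {
    stop("covariance of two coalescence times with different levels is ",
         "not part of the compendium")
  }
  key <- pair_key(x, y)
  k <- if (x$kind == "T") x$k else if (y$kind == "T") y$k else NULL
  kk <- if (!is.null(k)) rational(k) else NULL
  value <- switch(key,
    "H:T" = rational(4) / (kk^2 * (kk - 1)^2),
    "H:L" = zeta_combo(one = -4, pi2 = "2/3"),
    "H:E" = rational(0),
    "H:I" = zeta_combo(one = -4, pi2 = "2/3"),
    "H:B" = zeta_combo(one = 16, pi2 = -2, zeta3 = 4),
    "L:T" = rational(4) / (kk * (kk - 1)^2),
    "L:E" = rational(0),
    "L:I" = zeta_combo(pi2 = "2/3"),
    "L:B" = zeta_combo(one = 4, pi2 = "-2/3", zeta3 = 4),
    "E:T" = rational(0),
    "E:I" = rational(0),
    "E:B" = rational(0),
    "I:T" = rational(4) / (kk * (kk - 1)^2),
    "I:B" = zeta_combo(one = 4, pi2 = "-2/3", zeta3 = 4),
    "B:T" = rational(4) / (kk^2 * (kk - 1)^3),
    stop("no covariance formula for pair ", key))
  new_cov(value, key %in% c("E:B", "I:B"))
}
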