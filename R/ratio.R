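#' Ratios of coalescent tree summaries
#'
#' `ratio_pair()` identifies an ordered ratio `X/Y` of two distinct tree
#' summaries. Fifteen unordered pairs exist among {H, L, E, I, B, T(k)};
#' the canonical orientations carried by the published tables are H/T, H/L,
#' E/H, H/I, B/H, L/T, E/L, L/I, B/L, E/T, E/I, B/E, I/T, B/I, and B/T.
#' Reciprocals of these are accepted everywhere finite-`n` machinery is
#' involved (the delta method applies equally in either orientation), but
#' exact limits are tabulated only for the canonical orientations.
#'
#' @param numerator,denominator [tree_stat()] objects or labels.
#' @return An object of class `"ratio_pair"`.
#' @examples
#' ratio_pair("E", "H")
#' ratio_pair("L", tree_stat("T", 3))
#' @export
ratio_pair <- function(numerator, denominator) {
  num <- as_tree_stat(numerator)
  den <- as_tree_stat(denominator)
  if (identical(stat_label(num), stat_label(den))) {
    stop("numerator and denominator must be distinct statistics")
  }
  structure(list(num = num, den = den), class = "ratio_pair")
}

#' @export
print.ratio_pair <- function(x, ...) {
  cat("<ratio> ", stat_label(x$num), "/", stat_label(x$den),
      if (!ratio_is_canonical(x)) "  (reciprocal orientation)", "\n",
      sep = "")
  invisible(x)
}

canonical_orientations <- c(
  "H:T", "H:L", "E:H", "H:I", "B:H", "L:T", "E:L", "L:I", "B:L",
  "E:T", "E:I", "B:E", "I:T", "B:I", "B:T")

ratio_key <- function(pair) paste(pair$num$kind, pair$den$kind, sep = ":")

ratio_is_canonical <- function(pair) ratio_key(pair) %in% canonical_orientations

ratio_min_n <- function(pair) max(stat_min_n(pair$num), stat_min_n(pair$den))

check_pair_n <- function(pair, n) {
  n <- check_stat_n(pair$num, n)
  check_stat_n(pair$den, n)
}

#' Delta-method approximations for ratios of tree summaries
#'
#' Approximate expectation (second-order) and variance (first-order) of the
#' ratio of two tree summaries at sample size `n`, obtained by feeding the
#' exact moments ([stat_mean()], [stat_variance()]) and covariances
#' ([stat_covariance()]) through the generic delta-method formulas
#' ([taylor_mean_ratio()], [taylor_var_ratio()]). This composition is the
#' package's authoritative evaluation path; the transcribed closed forms
#' ([ratio_mean_closed()], [ratio_var_closed()]) agree with it exactly and
#' serve as an independent cross-check.
#'
#' The computation fails when the required moments do not exist at `n`
#' (e.g. any ratio involving B below `n = 4`) or when a mean in a
#' denominator position vanishes (e.g. `I` at `n = 2`).
#'
#' @param pair A [ratio_pair()].
#' @param n Sample size within the pair's joint validity domain.
#' @param exact Exact rational (default) or double arithmetic.
#' @return An object of class `"ratio_approx"`: list with `value`,
#'   `approximate` (whether an approximate covariance entered), `n`,
#'   `pair`, and `moment` (`"mean"` or `"variance"`).
#' @examples
#' ratio_mean_approx(ratio_pair("H", "L"), 2)$value         # exactly 1/2
#' as.numeric(ratio_var_approx(ratio_pair("E", "H"), 20)$value)
#' @export
ratio_mean_approx <- function(pair, n, exact = TRUE) {
  n <- check_pair_n(pair, n)
  cv <- stat_covariance(pair$num, pair$den, n, exact = exact)
  value <- taylor_mean_ratio(
    mean_x = stat_mean(pair$num, n, exact = exact),
    mean_y = stat_mean(pair$den, n, exact = exact),
    var_y = stat_variance(pair$den, n, exact = exact),
    cov_xy = cv$value)
  new_ratio_approx(value, cv$approximate, n, pair, "mean")
}

#' @rdname ratio_mean_approx
#' @export
ratio_var_approx <- function(pair, n, exact = TRUE) {
  n <- check_pair_n(pair, n)
  cv <- stat_covariance(pair$num, pair$den, n, exact = exact)
  value <- taylor_var_ratio(
    mean_x = stat_mean(pair$num, n, exact = exact),
    mean_y = stat_mean(pair$den, n, exact = exact),
    var_x = stat_variance(pair$num, n, exact = exact),
    var_y = stat_variance(pair$den, n, exact = exact),
    cov_xy = cv$value)
  new_ratio_approx(value, cv$approximate, n, pair, "variance")
}

new_ratio_approx <- function(value, approximate, n, pair, moment) {
  structure(list(value = value, approximate = approximate, n = n,
                 pair = pair, moment = moment),
            class = "ratio_approx")
}

#' @export
print.ratio_approx <- function(x, ...) {
  cat("<delta-method ", x$moment, "> ",
      stat_label(x$pair$num), "/", stat_label(x$pair$den),
      " at n = ", x$n,
      if (x$approximate) "  [uses approximate covariance]", "\n", sep = "")
  if (is_rational(x$value)) {
    cat("  ", as.character(x$value), " = ",
        format(round(as.numeric(x$value), 5), nsmall = 5), "\n", sep = "")
  } else {
    cat("  ", format(x$value), "\n", sep = "")
  }
  invisible(x)
}

#' Large-sample limits of the ratio approximations
#'
#' Exact \eqn{n \to \infty} limits of [ratio_mean_approx()] and
#' [ratio_var_approx()] for the canonical pair orientations, over the
#' package's constant basis. Ratios with the total or internal branch
#' length in the numerator and a coalescence time in the denominator grow
#' without bound and return the divergent sentinel. Notable finite values:
#' \eqn{\lim \tilde E[E_n/H_n] = \pi^2/3 - 2 \approx 1.28987} even though
#' both summaries have limiting expectation 2, and
#' \eqn{\lim \tilde E[B_n/H_n] = \pi^4/18 - \pi^2/6 - \zeta(3) - 2
#' \approx 0.56463}.
#'
#' @param pair A [ratio_pair()] in canonical orientation.
#' @return A [rational()], [zeta_combo()], or [coal_divergent()] sentinel,
#'   wrapped with the `approximate` flag as in [ratio_mean_approx()].
#' @examples
#' as.numeric(ratio_mean_limit(ratio_pair("E", "H"))$value)  # 1.28987...
#' ratio_mean_limit(ratio_pair("L", "T2"))                   # diverges
#' @export
ratio_mean_limit <- function(pair) {
  key <- require_canonical(pair)
  k <- t_level(pair)
  kk <- if (!is.null(k)) rational(k) else NULL
  value <- switch(key,
    "H:T" = 2 * kk^2 - 2 * kk - 1,
    "H:L" = rational(0),
    "E:H" = zeta_combo(one = -2, pi2 = "1/3"),
    "H:I" = rational(0),
    "B:H" = zeta_combo(one = -2, pi2 = "-1/6", pi4 = "1/18", zeta3 = -1),
    "L:T" = coal_divergent(),
    "E:L" = rational(0),
    "L:I" = rational(1),
    "B:L" = rational(0),
    "E:T" = 2 * kk * (kk - 1),
    "E:I" = rational(0),
    "B:E" = zeta_combo(one = -1, pi2 = "1/6"),
    "I:T" = coal_divergent(),
    "B:I" = rational(0),
    "B:T" = zeta_combo(one = rational(-2) * kk * (kk - 1) - 1 / (kk - 1),
                       pi2 = kk * (kk - 1) / 3))
  new_ratio_approx(value, key %in% c("B:E", "B:I"), Inf, pair, "mean")
}

#' @rdname ratio_mean_limit
#' @export
ratio_var_limit <- function(pair) {
  key <- require_canonical(pair)
  k <- t_level(pair)
  kk <- if (!is.null(k)) rational(k) else NULL
  value <- switch(key,
    "H:T" = zeta_combo(one = -2 * kk^2 * (kk - 1)^2 - 2 * kk * (kk - 1),
                       pi2 = kk^2 * (kk - 1)^2 / 3),
    "H:L" = rational(0),
    "E:H" = zeta_combo(one = -3, pi2 = "1/3"),
    "H:I" = rational(0),
    "B:H" = zeta_combo(one = "11/2", pi2 = "-3/4", pi4 = "-1/18",
                       pi6 = "1/108", zeta3 = 2, pi2zeta3 = "-1/3"),
    "L:T" = coal_divergent(),
    "E:L" = rational(0),
    "L:I" = rational(0),
    "B:L" = rational(0),
    "E:T" = kk^2 * (kk - 1)^2,
    "E:I" = rational(0),
    "B:E" = zeta_combo(one = "1/2", pi2 = "1/4", pi4 = "-1/36"),
    "I:T" = coal_divergent(),
    "B:I" = rational(0),
    "B:T" = zeta_combo(
      one = 3 * kk^2 * (kk - 1)^2 / 2 + 2 * kk,
      pi2 = rational(-1) * kk * (kk * (kk - 1)^2 + 4) / 12))
  new_ratio_approx(value, key %in% c("B:E", "B:I"), Inf, pair, "variance")
}

require_canonical <- function(pair) {
  if (!inherits(pair, "ratio_pair")) stop("expected a ratio_pair")
  key <- ratio_key(pair)
  if (!key %in% canonical_orientations) {
    stop("exact limits are tabulated for the canonical orientation ",
         "only; use the reciprocal pair (and transform if needed)")
  }
  key
}

t_level <- function(pair) {
  if (pair$num$kind == "T") pair$num$k
  else if (pair$den$kind == "T") pair$den$k
  else NULL
}
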