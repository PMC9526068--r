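#' Transcribed closed forms for the ratio approximations
#'
#' Pair-specific closed-form expressions for the delta-method expectation
#' and variance of each canonical ratio, as published in tabulated form.
#' These are algebraically identical to the generic composition computed by
#' [ratio_mean_approx()] and [ratio_var_approx()] -- the test suite checks
#' exact rational equality across the validity domain -- and exist as an
#' independently coded transcription guarding against transcription errors
#' in either path. The composition is the package's runtime path.
#'
#' All expressions are polynomials in `n`, `k`, and the harmonic sums
#' \eqn{S_{1,n-1}}, \eqn{S_{2,n-1}}, \eqn{S_{3,n-1}}, \eqn{S_{2,n}}.
#'
#' @param pair A [ratio_pair()] in canonical orientation (see
#'   [ratio_pair()] for the list).
#' @param n Sample size within the pair's joint validity domain.
#' @param exact Exact rational (default) or double arithmetic.
#' @return A [rational()] scalar (or double if `exact = FALSE`).
#' @examples
#' ratio_mean_closed(ratio_pair("H", "L"), 2)   # 1/2
#' @export
ratio_mean_closed <- function(pair, n, exact = TRUE) {
  key <- require_canonical(pair)
  n <- check_pair_n(pair, n)
  x <- moment_ctx(n, exact)
  nn <- x$nn; S1 <- x$S1; S2 <- x$S2; S3 <- x$S3; Z <- x$Z2n
  kk <- if (!is.null(t_level(pair))) x$lift(t_level(pair)) else NULL
  switch(key,
    "H:T" = ((2 * kk^2 - 2 * kk - 1) * nn - 2 * kk * (kk - 1)) / nn,
    "H:L" = (nn - 1) / (S1 * nn) - (S2 * nn - nn + 1) / (S1^2 * nn) +
            S2 * (nn - 1) / (S1^3 * nn),
    "E:H" = nn * (2 * Z * nn^2 - 2 * nn^2 - nn + 1) / (nn - 1)^3,
    "H:I" = (nn - 1) / ((S1 - 1) * nn) - (S2 - 1) / (S1 - 1)^2 +
            (S2 * (nn - 1) * (nn - 2) - 4 * nn + 4 * S1 + 4) /
              ((S1 - 1)^3 * nn * (nn - 2)),
    "B:H" = (S2 * nn - nn + 1) / (nn - 1) +
            (3 * S2 * nn^2 - S3 * nn^2 - 4 * nn^2 + 3 * nn + 1) / (nn - 1)^2 +
            (S2 * nn - nn + 1) * (2 * Z * nn^2 - 3 * nn^2 + 2 * nn - 1) /
              (nn - 1)^3,
    "L:T" = 2 * S1 * kk^2 - (2 * S1 + 1) * kk,
    "E:L" = ((S1^2 + S2) * nn - 2 * S1^2 - S2) / (S1^3 * (nn - 1)),
    "L:I" = ((S1^3 + S2) * (nn - 1) * (nn - 2) -
             S1^2 * (2 * nn^2 - 7 * nn + 2) + S1 * (nn^2 - 8 * nn + 8)) /
            ((S1 - 1)^3 * (nn - 1) * (nn - 2)),
    "B:L" = (S2 * nn - nn + 1) / (S1 * nn) +
            (S2 * nn - S3 * nn - nn + 1) / (S1^2 * nn) +
            S2 * (S2 * nn - nn + 1) / (S1^3 * nn),
    "E:T" = kk * (kk - 1) * (2 * nn - 3) / (nn - 1),
    "E:I" = (S1^2 * (nn^2 - 2 * nn + 4) - S1 * (2 * nn^2 - nn - 2) +
             (S2 + 1) * (nn - 1) * (nn - 2)) /
            ((S1 - 1)^3 * (nn - 1) * (nn - 2)),
    "B:E" = (nn^2 + 2 * S1 * nn - 8 * nn + 8) * (S2 * nn - nn + 1) /
            (nn * (nn - 1) * (nn - 2)),
    "I:T" = 2 * kk * (kk - 1) * (S1 - 1) - kk * (nn - kk) / (nn - 1),
    "B:I" = (S2 * nn - nn + 1) / ((S1 - 1) * nn) +
            (S2 * nn - nn + 1) *
              (S2 * (nn - 1) * (nn - 2) - 4 * nn + 4 * S1 + 4) /
              ((S1 - 1)^3 * nn * (nn - 1) * (nn - 2)) +
            (S2 * nn - (S3 + 1) * (nn - 1)) / ((S1 - 1)^2 * (nn - 1)),
    "B:T" = 2 * kk * (kk - 1) * (S2 * nn - nn + 1) / nn - 1 / (kk - 1))
}

#' @rdname ratio_mean_closed
#' @export
ratio_var_closed <- function(pair, n, exact = TRUE) {
  key <- require_canonical(pair)
  n <- check_pair_n(pair, n)
  x <- moment_ctx(n, exact)
  nn <- x$nn; S1 <- x$S1; S2 <- x$S2; S3 <- x$S3; Z <- x$Z2n
  kk <- if (!is.null(t_level(pair))) x$lift(t_level(pair)) else NULL
  switch(key,
    "H:T" = 2 * kk * (kk - 1) *
            (kk * (kk - 1) * Z * nn - (kk^2 - kk + 1) * nn + 1) / nn,
    "H:L" = ((nn - 1) / (S1 * nn))^2 *
            ((2 * (Z - 1) * nn^2 - (nn - 1)^2) / (nn - 1)^2 -
             2 * (S2 * nn - (nn - 1)) / (S1 * (nn - 1)) + S2 / S1^2),
    "E:H" = (2 * S1 * nn * (nn - 1) + 2 * Z * nn^2 * (nn - 2) -
             (nn^2 - 3) * (3 * nn - 2)) * nn^2 / ((nn - 1)^4 * (nn - 2)),
    "H:I" = (2 * Z * nn^2 - 3 * nn^2 + 2 * nn - 1) / ((S1 - 1)^2 * nn^2) +
            (((S2 * (nn - 2) - 4) * (nn - 1) + 4 * S1) * (nn - 1) /
               (nn^2 * (nn - 2)) -
             2 * (S1 - 1) * (S2 - 1) * (nn - 1) / nn) / (S1 - 1)^4,
    "B:H" = ((4 * S3 * nn^2 + 4 * Z * nn^2 + 11 * nn^2 - 5 * nn - 10) *
               (nn - 1)^2 -
             S2 * (4 * S3 * nn^2 + 8 * Z * nn^2 + 13 * nn^2 - 9 * nn - 12) *
               nn * (nn - 1) +
             4 * S2^2 * (Z * nn^2 + nn^2 - nn - 1) * nn^2) /
            (2 * (nn - 1)^4),
    "L:T" = kk^2 * (kk - 1)^2 * S1^2 *
            (S2 / S1^2 - 2 / ((kk - 1) * S1) + 1),
    "E:L" = (2 * S1^3 * nn - S1^2 * (6 * nn - 8) +
             S2 * (nn - 1) * (nn - 2)) / (S1^4 * (nn - 1) * (nn - 2)),
    "L:I" = (2 * S1^3 * nn - S1^2 * (6 * nn - 8) +
             S2 * (nn - 1) * (nn - 2)) /
            ((S1 - 1)^4 * (nn - 1) * (nn - 2)),
    "B:L" = (S1^2 * (S2 * (3 * nn - 4) * nn - 2 * S2^2 * nn^2 +
                     nn^2 + 3 * nn - 4) +
             4 * S1 * (S2 * nn - nn + 1) * (S2 * nn - S3 * nn - nn + 1) +
             2 * S2 * (S2 * nn - nn + 1)^2) / (2 * S1^4 * nn^2),
    "E:T" = kk^2 * (kk - 1)^2 * (nn^2 + 2 * S1 * nn - 9 * nn + 10) /
            ((nn - 1) * (nn - 2)),
    "E:I" = (2 * S1^3 * nn - S1^2 * (6 * nn - 8) +
             S2 * (nn - 1) * (nn - 2)) /
            ((S1 - 1)^4 * (nn - 1) * (nn - 2)),
    "B:E" = (4 * S1 * nn * (S2 * nn - nn + 1)^2 -
             2 * S2^2 * (nn^2 + 3 * nn - 6) * nn^2 +
             S2 * (3 * nn - 4) * (nn + 6) * nn * (nn - 1) +
             (nn^2 - 10 * nn + 8) * (nn - 1)^2) /
            (2 * nn^2 * (nn - 1) * (nn - 2)),
    "I:T" = kk^2 * (kk - 1) *
            ((kk - 1) * S1^2 * (nn - 1) * (nn - 2) -
             2 * S1 * (kk * nn^2 - 4 * kk * nn + nn + 2 * kk) +
             (kk - 1) * S2 * (nn - 1) * (nn - 2) +
             kk * nn^2 + nn^2 - 9 * kk * nn + 3 * nn + 10 * kk - 6) /
            ((nn - 1) * (nn - 2)),
    "B:I" = (S2 * (nn - 1) * (nn - 2) - 4 * nn + 4 * S1 + 4) *
              (S2 * nn - nn + 1)^2 /
              ((S1 - 1)^4 * nn^2 * (nn - 1) * (nn - 2)) +
            2 * (S2 * nn - (S3 + 1) * (nn - 1)) * (S2 * nn - nn + 1) /
              ((S1 - 1)^3 * nn * (nn - 1)) +
            (S2 * (3 * nn - 4) * nn - 2 * S2^2 * nn^2 +
             (nn + 4) * (nn - 1)) / (2 * (S1 - 1)^2 * nn^2),
    "B:T" = kk / 2 *
            ((kk * (kk - 1)^2 * (3 * nn + 2) + 4 * nn) * (nn - 1) / nn^2 -
             (kk + 1) * (kk^2 - 3 * kk + 4) * S2))
}
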