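#' Delta-method approximations for moments of a ratio
#'
#' Generic Taylor (delta-method) approximations for the expectation and
#' variance of a ratio of two random variables with known first and second
#' moments, expanded around the mean vector. The second-order expectation
#' approximation is
#' \deqn{E[X/Y] \approx \frac{E[X]}{E[Y]} - \frac{Cov[X,Y]}{E[Y]^2}
#'       + \frac{E[X]\,Var[Y]}{E[Y]^3},}
#' and the first-order variance approximation is
#' \deqn{Var[X/Y] \approx \left(\frac{E[X]}{E[Y]}\right)^2
#'       \left(\frac{Var[X]}{E[X]^2} - \frac{2\,Cov[X,Y]}{E[X]E[Y]}
#'       + \frac{Var[Y]}{E[Y]^2}\right).}
#'
#' Both functions are exact in the arithmetic of their inputs: given
#' [rational()] moments they return rationals, given doubles they return
#' doubles.
#'
#' @param mean_x,mean_y Means of numerator and denominator; `mean_y` (and
#'   for the variance also `mean_x`) must be nonzero.
#' @param var_x,var_y Variances (nonnegative).
#' @param cov_xy Covariance of numerator and denominator.
#' @return A scalar of the same arithmetic type as the inputs.
#' @examples
#' taylor_mean_ratio(rational(2), rational(2), rational(1), rational(0))  # 5/4
#' taylor_var_ratio(1, 2, 1, 4, 2)                                        # 0
#' @export
taylor_mean_ratio <- function(mean_x, mean_y, var_y, cov_xy) {
  check_nonzero(mean_y, "the denominator mean")
  mean_x / mean_y - cov_xy / mean_y^2 + mean_x * var_y / mean_y^3
}

#' @rdname taylor_mean_ratio
#' @export
taylor_var_ratio <- function(mean_x, mean_y, var_x, var_y, cov_xy) {
  check_nonzero(mean_x, "the numerator mean")
  check_nonzero(mean_y, "the denominator mean")
  (mean_x / mean_y)^2 *
    (var_x / mean_x^2 - 2 * cov_xy / (mean_x * mean_y) + var_y / mean_y^2)
}

check_nonzero <- function(v, what) {
  zero <- if (is_rational(v)) v == rational(0) else v == 0
  if (isTRUE(zero)) {
    stop(what, " is zero; the delta-method expansion is undefined",
         call. = FALSE)
  }
  invisible(v)
}
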