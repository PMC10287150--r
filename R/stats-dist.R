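#' Upper-tail chi-square probability
#'
#' `P(X >= x)` for a chi-square variable with `df` degrees of freedom, i.e.
#' the regularized upper incomplete gamma function `Q(df/2, x/2)`. Thin
#' wrapper over the base R implementation; kept as a named operation so the
#' rank tests depend on one audited tail function.
#'
#' @param x Non-negative quantile.
#' @param df Positive integer degrees of freedom.
#' @return Probability in \[0, 1\], monotone decreasing in `x`.
#' @examples
#' chi_square_upper_tail(2 * log(20), df = 2)  # exactly 0.05
#' @export
chi_square_upper_tail <- function(x, df) {
  if (length(df) != 1 || is.na(df) || df < 1 || df != floor(df)) {
    stop("df must be a positive integer")
  }
  if (any(x < 0)) stop("x must be non-negative")
  stats::pchisq(x, df = df, lower.tail = FALSE)
}

#' Two-sided standard-normal p-value
#'
#' `2 * (1 - Phi(|z|))`, computed on the complementary tail for accuracy.
#'
#' @param z Finite numeric.
#' @return Probability in \[0, 1\]; symmetric in `z`, equal to 1 at `z = 0`.
#' @examples
#' normal_two_sided_p(1.959964)
#' @export
normal_two_sided_p <- function(z) {
  if (any(!is.finite(z))) stop("z must be finite")
  pmin(1, 2 * stats::pnorm(abs(z), lower.tail = FALSE))
}
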