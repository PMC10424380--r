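#' Sigmoid BOLD response model
#'
#' The ratio-scale response curve \eqn{f(x) = d + a / (1 + e^{b (c - x)})}
#' with offset `d = 1`: a unit baseline that rises (or falls, for `a < 0`)
#' logistically to a plateau of `1 + a`. `a` is the increase value
#' (fractional amplitude), `b` the rate per scan, and `c` the midpoint
#' scan index at which exactly half the rise has occurred.
#'
#' The function is total: extreme exponents saturate to the asymptotes
#' (`d` for \eqn{x \to -\infty} with `b > 0`, `d + a` for
#' \eqn{x \to +\infty}) rather than producing non-finite output.
#'
#' @param x Scan index (vectorized, need not be integer).
#' @param a Increase value (dimensionless plateau rise).
#' @param b Rate per scan; positive for a response that rises over time.
#' @param c Midpoint scan index.
#' @param d Offset (lower asymptote); 1 on the ratio scale, 0 when the
#'   model is expressed in percent-change units.
#' @return Numeric vector of responses, same length as `x`.
#' @examples
#' sigmoid_response(38, a = 0.2, b = 1, c = 38)  # midpoint: 1 + a/2
#' sigmoid_response(1e6, a = 0.05, b = 1, c = 38) # upper asymptote 1.05
#' @export
sigmoid_response <- function(x, a, b, c, d = 1) {
  # exp() overflow yields Inf and a/(1+Inf) == 0, so saturation is exact
  d + a / (1 + exp(b * (c - x)))
}
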