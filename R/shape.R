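#' Classify the shape of a fitted heterogeneity response curve
#'
#' On the standardised 0-1 gradient a quadratic `b1*x + b2*x^2` is classified
#' from its coefficients and their p-values:
#' \itemize{
#'   \item quadratic term not significant (`p2 > alpha`): `flat` when the
#'     linear term is also non-significant, otherwise `linear_increasing` or
#'     `linear_decreasing` by the sign of `b1`;
#'   \item significant negative `b2`: the vertex `x* = -b1 / (2 b2)` decides —
#'     `hump` when it lies strictly inside (0, 1), `saturating` when it is at
#'     or beyond 1 (the curve rises and levels off within the observed range);
#'     a vertex at or below 0 leaves a curve that only declines over [0, 1]
#'     and is classified `linear_decreasing`;
#'   \item significant positive `b2`: `u_shaped`.
#' }
#' Boundary conventions: a vertex of exactly 1 is `saturating`; exactly 0 is
#' `linear_decreasing`.
#'
#' @param beta1,beta2 Linear and quadratic coefficients.
#' @param p1,p2 Their p-values.
#' @param alpha Significance level (default 0.05).
#' @return List with `value` (the shape class) and `vertex` (`-b1/(2 b2)`
#'   when the quadratic is significant, otherwise NA).
#' @export
#' @examples
#' classify_shape(2, -1, 0.001, 0.001)  # saturating, vertex 1
#' classify_shape(2, -2, 0.001, 0.001)  # hump, vertex 0.5
classify_shape <- function(beta1, beta2, p1, p2, alpha = 0.05) {
  stopifnot(is.finite(beta1), is.finite(p1), is.finite(p2))
  if (p2 <= alpha && (!is.finite(beta2) || beta2 == 0)) {
    hdr_config_error("significant quadratic term with beta2 = 0 is inconsistent")
  }
  if (p2 > alpha) {
    value <- if (p1 > alpha) "flat" else
      if (beta1 > 0) "linear_increasing" else "linear_decreasing"
    return(list(value = value, vertex = NA_real_))
  }
  vertex <- -beta1 / (2 * beta2)
  if (beta2 > 0) return(list(value = "u_shaped", vertex = vertex))
  value <- if (vertex >= 1) "saturating" else
    if (vertex > 0) "hump" else "linear_decreasing"
  list(value = value, vertex = vertex)
}
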