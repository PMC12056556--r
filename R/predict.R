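#' Predicted lnRR curve over the standardised gradient
#'
#' Fixed-effects prediction `b0 + b1 x + b2 x^2 (+ moderator terms)` on a
#' grid of standardised heterogeneity values, with pointwise 95% confidence
#' intervals from the delta method using the fixed-effect covariance matrix.
#' No extrapolation is allowed beyond the 0-1 range of the standardised
#' gradient.
#'
#' @param fit An `hdr_fit`.
#' @param x_grid Numeric vector in [0, 1].
#' @param moderator_profile Named list fixing moderator values; unnamed
#'   moderators default to the reference level (factors) or the estimation
#'   sample mean (numeric covariates).
#' @param level Confidence level (default 0.95).
#' @return Tibble with `x`, `fit`, `se`, `lower`, `upper`.
#' @export
predict_curve <- function(fit, x_grid, moderator_profile = list(),
                          level = 0.95) {
  if (any(x_grid < 0 | x_grid > 1)) {
    hdr_config_error("x_grid outside the standardised [0, 1] range")
  }
  frame <- fit$frame
  newdata <- tibble::tibble(x = as.numeric(x_grid), x2 = as.numeric(x_grid)^2)
  mods <- setdiff(names(frame), c("lnrr", "x", "x2", "study_id", "hdr_id"))
  for (m in mods) {
    v <- frame[[m]]
    val <- moderator_profile[[m]]
    if (is.factor(v)) {
      val <- val %||% levels(v)[1]
      newdata[[m]] <- factor(val, levels = levels(v))
    } else {
      newdata[[m]] <- as.numeric(val %||% mean(v, na.rm = TRUE))
    }
  }
  ff <- lme4::nobars(fit$formula)
  ff <- stats::delete.response(stats::terms(ff))
  X <- model.matrix(ff, data = newdata)
  beta <- lme4::fixef(fit$model)
  X <- X[, names(beta), drop = FALSE]
  V <- as.matrix(vcov(fit$model))
  pred <- as.numeric(X %*% beta)
  se <- sqrt(pmax(0, rowSums((X %*% V) * X)))
  z <- qnorm(1 - (1 - level) / 2)
  tibble::tibble(x = as.numeric(x_grid), fit = pred, se = se,
                 lower = pred - z * se, upper = pred + z * se)
}
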