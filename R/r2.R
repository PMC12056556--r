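#' Variance-partition R-squared from components
#'
#' Marginal R2 = varF / (varF + varR + varE); conditional
#' R2 = (varF + varR) / (varF + varR + varE), where varF is the variance of
#' the fixed-effect linear predictor, varR the total random-effect variance
#' and varE the residual variance.
#'
#' @param var_fixed,var_random,var_resid Non-negative variance components.
#' @return Named numeric vector `c(r2_marginal, r2_conditional)`.
#' @export
#' @examples
#' r2_from_components(1, 1, 2)  # 0.25, 0.50
r2_from_components <- function(var_fixed, var_random, var_resid) {
  total <- var_fixed + var_random + var_resid
  if (total == 0) {
    warn("all variance components are zero; R2 defined as 0")
    return(c(r2_marginal = 0, r2_conditional = 0))
  }
  c(r2_marginal = var_fixed / total,
    r2_conditional = (var_fixed + var_random) / total)
}

#' Marginal and conditional R-squared of an HDR mixed model
#'
#' Variance explained by the fixed effects alone (marginal) and by fixed plus
#' random effects (conditional). The fixed-effect variance is the sample
#' variance of the fixed-effect linear predictor over the estimation data.
#' The random-effect variance sums the study intercept variance, the study
#' slope contribution evaluated at the sample's gradient distribution
#' (tau1^2 * mean(x^2) plus twice the intercept-slope covariance times
#' mean(x)), and the HDR intercept variance.
#'
#' @param fit An `hdr_fit` or a fitted `lmerMod`.
#' @return Named numeric vector `c(r2_marginal, r2_conditional)`.
#' @export
r2_nakagawa <- function(fit) {
  model <- if (inherits(fit, "hdr_fit")) fit$model else fit
  X <- lme4::getME(model, "X")
  eta <- as.numeric(X %*% lme4::fixef(model))
  var_fixed <- if (length(eta) > 1) var(eta) else 0
  vc <- lme4::VarCorr(model)
  x <- X[, "x"]
  study <- vc$study_id
  var_study <- study["(Intercept)", "(Intercept)"] +
    2 * study["(Intercept)", "x"] * mean(x) +
    study["x", "x"] * mean(x^2)
  var_hdr <- vc$hdr_id["(Intercept)", "(Intercept)"]
  var_random <- max(0, var_study) + var_hdr
  r2_from_components(var_fixed, var_random, sigma(model)^2)
}
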