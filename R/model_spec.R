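#' Specification of an HDR mixed model
#'
#' Every model regresses the per-observation lnRR on the standardised
#' heterogeneity gradient as a fixed quadratic term (`x` and `x2`; the
#' quadratic is always carried with the linear term), with a study-level
#' random intercept and slope on `x` (correlated) and a plot/HDR-level random
#' intercept. Moderators enter as additional fixed main effects; candidate
#' interactions (including `x:het_cv`, the gradient-breadth covariate) are
#' subject to backward elimination by [prune_interactions()] — main effects
#' and the heterogeneity terms themselves are never pruned.
#'
#' @param moderators Character vector of moderator columns to include as main
#'   effects (e.g. `"organismal_group"`, `"latitude_c"`). `"het_cv"` is added
#'   automatically when a CV interaction is among the candidates.
#' @param interactions Character vector of candidate interaction terms in
#'   formula syntax, e.g. `c("x:het_cv", "latitude_c:season")`.
#' @param alpha Significance level for pruning, term tests and shape
#'   classification (default 0.05).
#' @param df_method `"satterthwaite"` (default) or `"residual"` for the
#'   denominator df of coefficient t-tests.
#' @param reml Use REML for the final fit (default TRUE). Pruning always uses
#'   ML so that nested fixed-effect models are comparable.
#' @return An object of class `hdr_model_spec`.
#' @export
hdr_model_spec <- function(moderators = character(),
                           interactions = character(),
                           alpha = 0.05,
                           df_method = c("satterthwaite", "residual"),
                           reml = TRUE) {
  df_method <- match.arg(df_method)
  if (alpha <= 0 || alpha >= 1) hdr_config_error("alpha must be in (0, 1)")
  mods <- unique(moderators)
  ## interaction terms imply their main effects
  for (term in interactions) {
    parts <- strsplit(term, ":", fixed = TRUE)[[1]]
    mods <- union(mods, setdiff(parts, c("x", "x2")))
  }
  structure(list(moderators = mods, interactions = unique(interactions),
                 alpha = alpha, df_method = df_method, reml = reml),
            class = "hdr_model_spec")
}

#' @export
print.hdr_model_spec <- function(x, ...) {
  cat("HDR model specification\n")
  cat("  fixed: lnrr ~ x + x2",
      if (length(x$moderators)) paste("+", paste(x$moderators, collapse = " + ")),
      "\n")
  if (length(x$interactions)) {
    cat("  candidate interactions:", paste(x$interactions, collapse = ", "), "\n")
  }
  cat("  random: (1 + x | study_id) + (1 | hdr_id)\n")
  cat(sprintf("  alpha = %g, df = %s, final fit = %s\n",
              x$alpha, x$df_method, if (x$reml) "REML" else "ML"))
  invisible(x)
}

model_formula <- function(spec, interactions = spec$interactions) {
  rhs <- c("x", "x2", spec$moderators, interactions,
           "(1 + x | study_id)", "(1 | hdr_id)")
  as.formula(paste("lnrr ~", paste(rhs, collapse = " + ")))
}

#' Build the model frame for an HDR model
#'
#' One row per observation with the response (`lnrr`), the standardised
#' gradient `x = het01` and its square `x2`, the gradient CV, grouping indices
#' and any requested moderators. Categorical moderators become factors with
#' alphabetically first reference level (treatment contrasts); the derived
#' covariates `latitude_c` (absolute latitude centred at the frame mean),
#' `sample_size_z` and `pub_year_z` (standardised) are computed on request.
#' Rows with missing values in requested moderators are removed listwise and
#' counted in the `design_log` attribute.
#'
#' @param groups Analysis-ready groups (from [prepare_hdr_data()]).
#' @param spec An [hdr_model_spec()].
#' @return A tibble (class `hdr_frame`) ready for [fit_hdr_model()].
#' @export
build_design <- function(groups, spec = hdr_model_spec()) {
  need <- c("lnrr", "het01", "hdr_id", "study_id")
  if (!all(need %in% names(groups))) {
    hdr_config_error("groups must carry lnrr and het01 (run prepare_hdr_data)")
  }
  frame <- tibble::tibble(
    lnrr = groups$lnrr,
    x = groups$het01,
    x2 = groups$het01^2,
    het_cv = groups$het_cv,
    study_id = factor(groups$study_id),
    hdr_id = factor(groups$hdr_id)
  )
  logs <- character()
  for (m in spec$moderators) {
    col <- switch(m,
      latitude_c = {
        lat <- groups$latitude_abs
        lat - mean(lat, na.rm = TRUE)
      },
      sample_size_z = scale_or_zero(groups$sample_size),
      pub_year_z = scale_or_zero(groups$pub_year),
      het_cv = groups$het_cv,
      {
        if (!m %in% names(groups)) {
          hdr_config_error(paste0("moderator column not found: ", m))
        }
        groups[[m]]
      })
    if (all(is.na(col))) {
      hdr_config_error(paste0("moderator entirely missing: ", m))
    }
    if (is.character(col)) col <- factor(col, levels = sort(unique(col[!is.na(col)])))
    frame[[m]] <- col
  }
  ok <- complete.cases(frame[, c("lnrr", "x", "x2", spec$moderators)])
  if (any(!ok)) {
    logs <- c(logs, sprintf("%d rows dropped listwise (missing moderators)",
                            sum(!ok)))
    frame <- frame[ok, , drop = FALSE]
  }
  frame <- droplevels(frame)
  structure(frame, class = c("hdr_frame", class(frame)), design_log = logs)
}

scale_or_zero <- function(x) {
  x <- as.numeric(x)
  s <- sd(x, na.rm = TRUE)
  if (is.na(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x, na.rm = TRUE)) / s
}
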