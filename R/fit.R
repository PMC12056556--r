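#' Fit an HDR quadratic mixed model
#'
#' Fits `lnrr ~ x + x2 + moderators (+ retained interactions) +
#' (1 + x | study_id) + (1 | hdr_id)` by REML (default), returning coefficient
#' Wald t-tests (Satterthwaite denominator df where available, residual df
#' otherwise — which one was used is recorded), variance components, marginal
#' and conditional R-squared, and the shape classification of the fitted
#' heterogeneity curve. Factor moderators left with a single level after
#' listwise deletion are dropped with a log entry rather than failing the fit.
#' Singular fits (a variance component estimated at zero) are retained with a
#' warning flag; optimiser non-convergence is retried with a second optimiser
#' and raised as an error (class `hdr_fit_error`) if it persists.
#'
#' @param frame Model frame from [build_design()].
#' @param spec An [hdr_model_spec()].
#' @param interactions Interaction terms to include; defaults to the spec's
#'   candidates (use [prune_interactions()] first to obtain the final set).
#' @return Object of class `hdr_fit`: list with `coefficients` (tibble),
#'   `varcomp`, `r2_marginal`, `r2_conditional`, `shape`, `n_obs`, `n_hdr`,
#'   `n_study`, `converged`, `singular`, `df_method_used`, `dropped_terms`,
#'   `spec`, and the underlying `lme4` fit in `$model`.
#' @export
fit_hdr_model <- function(frame, spec = hdr_model_spec(),
                          interactions = spec$interactions) {
  frame <- droplevels(frame)
  n_study <- length(unique(frame$study_id))
  n_hdr <- length(unique(frame$hdr_id))
  if (n_study < 2L) {
    abort("insufficient grouping levels: need >= 2 studies",
          class = c("hdr_fit_error", "hdr_data_error"))
  }
  if (n_hdr < 3L) {
    abort("insufficient grouping levels: need >= 3 HDR groups",
          class = c("hdr_fit_error", "hdr_data_error"))
  }

  deg <- drop_degenerate_terms(frame, spec, interactions)
  dropped_terms <- deg$dropped
  interactions <- deg$interactions
  form <- model_formula(deg$spec, interactions)

  fit <- fit_lmer(form, frame, reml = spec$reml)
  coefs <- coef_table(fit$model, spec$df_method)

  vc <- varcomp_table(fit$model)
  r2 <- r2_nakagawa(fit$model)
  shape <- shape_from_coefs(coefs, spec$alpha)

  structure(list(
    coefficients = coefs,
    varcomp = vc,
    r2_marginal = r2[["r2_marginal"]],
    r2_conditional = r2[["r2_conditional"]],
    shape = shape,
    n_obs = nrow(frame), n_hdr = n_hdr, n_study = n_study,
    converged = fit$converged, singular = fit$singular,
    messages = fit$messages,
    df_method_used = attr(coefs, "df_method_used"),
    dropped_terms = dropped_terms,
    interactions = interactions,
    spec = spec, formula = form,
    frame = frame, model = fit$model
  ), class = "hdr_fit")
}

## Drop moderators left degenerate (single level/value) in this frame, plus
## the interactions that reference them; used by both pruning and fitting.
drop_degenerate_terms <- function(frame, spec, interactions = spec$interactions) {
  dropped <- character()
  for (m in spec$moderators) {
    v <- frame[[m]]
    if ((is.factor(v) && nlevels(droplevels(v)) < 2L) ||
        (!is.factor(v) && length(unique(v[!is.na(v)])) < 2L)) {
      dropped <- c(dropped, m)
    }
  }
  mods <- setdiff(spec$moderators, dropped)
  keep_int <- vapply(interactions, function(term) {
    parts <- strsplit(term, ":", fixed = TRUE)[[1]]
    all(setdiff(parts, c("x", "x2")) %in% mods)
  }, logical(1))
  dropped <- c(dropped, interactions[!keep_int])
  spec$moderators <- mods
  spec$interactions <- interactions[keep_int]
  list(spec = spec, interactions = interactions[keep_int], dropped = dropped)
}

## lmer with a retry on convergence failure; singular fits are tolerated.
fit_lmer <- function(form, frame, reml = TRUE, check_derivs = TRUE) {
  msgs <- character()
  run <- function(optimizer) {
    withCallingHandlers(
      lmerTest::lmer(form, data = frame, REML = reml,
                     control = lme4::lmerControl(
                       optimizer = optimizer,
                       calc.derivs = check_derivs,
                       check.conv.singular = lme4::.makeCC(
                         action = "ignore", tol = 1e-4))),
      warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w))
        invokeRestart("muffleWarning")
      },
      message = function(m) {
        msgs <<- c(msgs, conditionMessage(m))
        invokeRestart("muffleMessage")
      })
  }
  ## the eigenvalue-ratio scaling check is a conditioning heuristic (fired
  ## e.g. by latitude in degrees next to the 0-1 gradient), not an optimizer
  ## failure; it is recorded but does not trigger restarts
  fatal <- function(model) {
    m <- unlist(model@optinfo$conv$lme4$messages %||% character())
    m[!grepl("Rescale variables|eigenvalue ratio", m)]
  }
  model <- run("nloptwrap")
  for (opt in c("bobyqa", "Nelder_Mead")) {
    if (!length(fatal(model))) break
    msgs <- c(msgs, paste("retrying with", opt))
    model <- run(opt)
  }
  if (length(fatal(model))) {
    abort(paste0("mixed model failed to converge after restarts: ",
                 paste(fatal(model), collapse = "; ")),
          class = c("hdr_fit_error", "hdr_data_error"))
  }
  msgs <- c(msgs, unlist(model@optinfo$conv$lme4$messages %||% character()))
  list(model = model, converged = TRUE,
       singular = lme4::isSingular(model, tol = 1e-4), messages = msgs)
}

## Coefficient table with Satterthwaite df when requested and available.
coef_table <- function(model, df_method = "satterthwaite") {
  used <- "residual"
  co <- NULL
  if (identical(df_method, "satterthwaite") &&
      methods::is(model, "lmerModLmerTest")) {
    co <- tryCatch(suppressWarnings(
      as.data.frame(summary(model)$coefficients)), error = function(e) NULL)
    if (!is.null(co) && "df" %in% names(co) && !anyNA(co$df)) {
      used <- "satterthwaite"
    } else co <- NULL
  }
  if (is.null(co)) {
    b <- lme4::fixef(model)
    se <- sqrt(diag(as.matrix(vcov(model))))
    df_res <- nobs(model) - length(b)
    tval <- b / se
    co <- data.frame(Estimate = b, `Std. Error` = se, df = df_res,
                     `t value` = tval,
                     `Pr(>|t|)` = 2 * pt(-abs(tval), df_res),
                     check.names = FALSE)
  }
  out <- tibble::tibble(
    term = rownames(co),
    estimate = co$Estimate,
    se = co$`Std. Error`,
    df = co$df,
    statistic = co$`t value`,
    p_value = co$`Pr(>|t|)`
  )
  attr(out, "df_method_used") <- used
  out
}

varcomp_table <- function(model) {
  vc <- lme4::VarCorr(model)
  study <- vc$study_id
  hdr <- vc$hdr_id
  tibble::tibble(
    component = c("study_intercept", "study_slope",
                  "study_intercept_slope_cov", "hdr_intercept", "residual"),
    variance = c(study["(Intercept)", "(Intercept)"],
                 study["x", "x"],
                 study["(Intercept)", "x"],
                 hdr["(Intercept)", "(Intercept)"],
                 sigma(model)^2)
  )
}

shape_from_coefs <- function(coefs, alpha) {
  ix <- match("x", coefs$term)
  ix2 <- match("x2", coefs$term)
  if (is.na(ix) || is.na(ix2)) return(list(value = NA_character_, vertex = NA_real_))
  classify_shape(coefs$estimate[ix], coefs$estimate[ix2],
                 coefs$p_value[ix], coefs$p_value[ix2], alpha)
}

#' @export
print.hdr_fit <- function(x, digits = 4, ...) {
  cat(sprintf("HDR mixed model: %d obs, %d HDR groups, %d studies\n",
              x$n_obs, x$n_hdr, x$n_study))
  cat(sprintf("  shape: %s%s | R2 marginal %.3f, conditional %.3f\n",
              x$shape$value,
              if (!is.na(x$shape$vertex))
                sprintf(" (vertex %.2f)", x$shape$vertex) else "",
              x$r2_marginal, x$r2_conditional))
  if (x$singular) cat("  note: singular fit (a variance component at zero)\n")
  cat(sprintf("  df method: %s\n", x$df_method_used))
  print(as.data.frame(x$coefficients), digits = digits)
  invisible(x)
}

#' @importFrom stats nobs sigma
#' @importFrom methods is
NULL
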