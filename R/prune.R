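#' Backward elimination of non-significant interactions
#'
#' Starting from the full set of candidate interaction terms, repeatedly
#' refits the model by maximum likelihood (so that nested fixed-effect models
#' are comparable), computes a drop-one likelihood-ratio p-value for each
#' remaining candidate, removes the candidate with the largest p-value above
#' `alpha`, and stops when every remaining candidate is significant. Main
#' effects and the heterogeneity terms `x` and `x2` are never removed. For a
#' single-df interaction such as `x:het_cv` the likelihood-ratio test agrees
#' asymptotically with the Wald test on its coefficient; the LRT form also
#' covers multi-column factor interactions.
#'
#' @param frame Model frame from [build_design()].
#' @param spec An [hdr_model_spec()] whose `interactions` are the candidates.
#' @return List: `spec` (a copy with `interactions` reduced to the retained
#'   set), `interactions` (retained terms), and `audit` — a tibble with one
#'   row per elimination step (`step`, `term`, `p_value`).
#' @export
prune_interactions <- function(frame, spec) {
  frame <- droplevels(frame)
  deg <- drop_degenerate_terms(frame, spec)
  spec <- deg$spec
  candidates <- spec$interactions
  ## interactions whose factors are degenerate in this frame can never be
  ## estimated; treat them as removed before testing
  estimable <- vapply(candidates, function(term) {
    parts <- setdiff(strsplit(term, ":", fixed = TRUE)[[1]], c("x", "x2"))
    all(vapply(parts, function(p) {
      v <- frame[[p]]
      if (is.factor(v)) nlevels(droplevels(v)) > 1L else
        length(unique(v[!is.na(v)])) > 1L
    }, logical(1)))
  }, logical(1))
  audit <- tibble::tibble(step = integer(), term = character(),
                          p_value = numeric())
  if (any(!estimable)) {
    audit <- dplyr::bind_rows(audit, tibble::tibble(
      step = 0L, term = candidates[!estimable], p_value = NA_real_))
  }
  retained <- candidates[estimable]
  spec_ml <- spec
  spec_ml$reml <- FALSE
  step <- 1L

  mods_for <- function(ints) {
    s <- spec_ml
    s$interactions <- ints
    s
  }
  ## deviance comparisons only: skip the post-fit derivative checks
  ml_loglik <- function(ints) {
    s <- mods_for(ints)
    fit <- fit_lmer(model_formula(s, ints), frame, reml = FALSE,
                    check_derivs = FALSE)
    as.numeric(logLik(fit$model))
  }

  while (length(retained)) {
    ll_full <- ml_loglik(retained)
    pvals <- vapply(retained, function(term) {
      ll_red <- ml_loglik(setdiff(retained, term))
      df <- term_df(frame, spec, retained, term)
      stat <- max(0, 2 * (ll_full - ll_red))
      pchisq(stat, df = df, lower.tail = FALSE)
    }, numeric(1))
    worst <- which.max(pvals)
    if (pvals[worst] <= spec$alpha) break
    audit <- dplyr::bind_rows(audit, tibble::tibble(
      step = step, term = retained[worst], p_value = pvals[worst]))
    retained <- retained[-worst]
    step <- step + 1L
  }
  out_spec <- spec
  out_spec$interactions <- retained
  list(spec = out_spec, interactions = retained, audit = audit)
}

## number of model-matrix columns an interaction term contributes
term_df <- function(frame, spec, interactions, term) {
  s <- spec
  s$interactions <- interactions
  ff <- lme4::nobars(model_formula(s, interactions))
  mm <- model.matrix(ff, data = frame)
  asg <- attr(mm, "assign")
  labs <- attr(stats::terms(ff), "term.labels")
  canon <- function(t) paste(sort(strsplit(t, ":", fixed = TRUE)[[1]]),
                             collapse = ":")
  pos <- which(vapply(labs, canon, character(1)) == canon(term))
  max(1L, sum(asg %in% pos))
}
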