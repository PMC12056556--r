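#' Model batteries across facets, organismal groups, processes and
#' environment
#'
#' Each suite fits one quadratic mixed model per stratum ("separately, never
#' pooled across strata"): [run_facet_suite()] one model per heterogeneity
#' facet on the aggregated micro- plus macroinvertebrate data for a single
#' response metric; [run_group_suite()] one model per organismal group with
#' community metrics pooled as the response and the four sparser facets
#' pooled into `other_pooled`; [run_process_suite()] one model per ecological
#' process; [run_environment_suite()] the facet or group battery refitted
#' with environmental moderators (substrate type, depth zone, season, centred
#' absolute latitude) plus the candidate interactions latitude x season and
#' x x substrate type, each included only where every participating factor
#' level is backed by at least two studies. Candidate interactions (always
#' including `x:het_cv`) are pruned by backward elimination before the final
#' REML fit. Strata with fewer than two studies are skipped with a reason.
#'
#' @param groups Analysis-ready groups from [prepare_hdr_data()].
#' @param response_metric For the facet suite: `"richness"` or `"abundance"`.
#' @param alpha Significance level passed to the model spec.
#' @param prune Logical; run backward elimination on candidate interactions
#'   (default TRUE).
#' @return An `hdr_suite`: list with `suite_name`, `fits` (named list of
#'   `hdr_fit`), `comparison` (long tibble: stratum, linear and quadratic term
#'   statistics, R2 pair, shape, counts), `pruning` (per-stratum audit
#'   trails) and `skipped` (tibble of skipped strata with reasons).
#' @name analysis_suites
NULL

run_suite <- function(groups, strata, strata_label, spec_for, suite_name,
                      prune = TRUE) {
  fits <- list()
  pruning <- list()
  skipped <- tibble::tibble(stratum = character(), reason = character())
  for (stratum in strata) {
    sub <- groups[groups[[strata_label]] == stratum, , drop = FALSE]
    sub <- restore_groups(sub, groups)
    if (nrow(sub) == 0L) {
      skipped <- dplyr::bind_rows(skipped, tibble::tibble(
        stratum = stratum, reason = "no data"))
      next
    }
    if (length(unique(sub$study_id)) < 2L) {
      skipped <- dplyr::bind_rows(skipped, tibble::tibble(
        stratum = stratum, reason = "fewer than 2 studies"))
      next
    }
    res <- tryCatch({
      spec <- spec_for(sub)
      frame <- build_design(sub, spec)
      ints <- spec$interactions
      if (prune && length(ints)) {
        pr <- prune_interactions(frame, spec)
        pruning[[stratum]] <- pr$audit
        ints <- pr$interactions
      }
      fit_hdr_model(frame, spec, interactions = ints)
    }, hdr_fit_error = function(e) e, hdr_config_error = function(e) e)
    if (inherits(res, "error")) {
      skipped <- dplyr::bind_rows(skipped, tibble::tibble(
        stratum = stratum, reason = conditionMessage(res)))
    } else {
      fits[[stratum]] <- res
    }
  }
  structure(list(suite_name = suite_name, fits = fits,
                 comparison = comparison_table_fits(fits),
                 pruning = pruning, skipped = skipped),
            class = "hdr_suite")
}

term_row <- function(fit, term) {
  i <- match(term, fit$coefficients$term)
  if (is.na(i)) {
    return(tibble::tibble(estimate = NA_real_, se = NA_real_, df = NA_real_,
                          statistic = NA_real_, p_value = NA_real_))
  }
  fit$coefficients[i, c("estimate", "se", "df", "statistic", "p_value")]
}

comparison_table_fits <- function(fits) {
  if (!length(fits)) {
    return(tibble::tibble(stratum = character()))
  }
  purrr::map_dfr(names(fits), function(s) {
    fit <- fits[[s]]
    xr <- term_row(fit, "x"); x2r <- term_row(fit, "x2")
    tibble::tibble(
      stratum = s,
      beta_x = xr$estimate, se_x = xr$se, df_x = xr$df, t_x = xr$statistic,
      p_x = xr$p_value,
      beta_x2 = x2r$estimate, se_x2 = x2r$se, df_x2 = x2r$df,
      t_x2 = x2r$statistic, p_x2 = x2r$p_value,
      r2_marginal = fit$r2_marginal, r2_conditional = fit$r2_conditional,
      shape = fit$shape$value, vertex = fit$shape$vertex,
      n_obs = fit$n_obs, n_hdr = fit$n_hdr, n_study = fit$n_study,
      singular = fit$singular
    )
  })
}

#' Comparison table of a suite or single fit
#'
#' @param x An `hdr_suite` or `hdr_fit`.
#' @return Long tibble with one row per stratum (a single fit is reported as
#'   stratum `"pooled"`).
#' @export
comparison_table <- function(x) {
  if (inherits(x, "hdr_suite")) return(x$comparison)
  if (inherits(x, "hdr_fit")) {
    tab <- comparison_table_fits(list(pooled = x))
    return(tab)
  }
  hdr_config_error("comparison_table expects an hdr_suite or hdr_fit")
}

#' @export
print.hdr_suite <- function(x, ...) {
  cat(sprintf("HDR suite '%s': %d stratum fit(s), %d skipped\n",
              x$suite_name, length(x$fits), nrow(x$skipped)))
  print(as.data.frame(x$comparison[, c("stratum", "beta_x", "p_x", "beta_x2",
                                       "p_x2", "r2_marginal",
                                       "r2_conditional", "shape")]),
        digits = 3)
  if (nrow(x$skipped)) {
    cat("skipped:\n")
    print(as.data.frame(x$skipped))
  }
  invisible(x)
}

#' @rdname analysis_suites
#' @export
run_facet_suite <- function(groups, response_metric = c("richness",
                                                        "abundance"),
                            alpha = 0.05, prune = TRUE) {
  response_metric <- match.arg(response_metric)
  sel <- groups$organismal_group %in% c("microinvertebrates",
                                        "macroinvertebrates") &
    groups$response_metric == response_metric
  sub <- restore_groups(groups[sel, , drop = FALSE], groups)
  spec_for <- function(stratum_data) {
    mods <- "organismal_group"
    if (response_metric == "abundance") mods <- c(mods, "n_species")
    hdr_model_spec(moderators = mods, interactions = "x:het_cv",
                   alpha = alpha)
  }
  run_suite(sub, hdr_levels()$facet, "facet", spec_for,
            paste0("facet_", response_metric), prune = prune)
}

#' Pool the four sparser facets into `other_pooled`
#'
#' Relabels substrate complexity, feature size, feature variation and feature
#' richness as one `other_pooled` level, leaving substrate 3D and 2D amount
#' untouched. Row counts are unchanged.
#'
#' @param groups Groups (or observations) with a `facet` column.
#' @return Input with an added `facet_pooled` column.
#' @export
pool_other_facets <- function(groups) {
  lv <- hdr_levels()
  groups$facet_pooled <- ifelse(groups$facet %in% lv$pooled_into_other,
                                "other_pooled", groups$facet)
  groups
}

#' @rdname analysis_suites
#' @export
run_group_suite <- function(groups, alpha = 0.05, prune = TRUE) {
  lv <- hdr_levels()
  sel <- groups$response_metric %in% lv$community_metrics
  sub <- restore_groups(groups[sel, , drop = FALSE], groups)
  sub <- pool_other_facets(sub)
  spec_for <- function(stratum_data) {
    hdr_model_spec(
      moderators = c("facet_pooled", "response_metric"),
      interactions = c("x:response_metric", "facet_pooled:response_metric",
                       "x:het_cv"),
      alpha = alpha)
  }
  run_suite(sub, lv$organismal_group, "organismal_group", spec_for,
            "organismal_groups", prune = prune)
}

#' @rdname analysis_suites
#' @export
run_process_suite <- function(groups, alpha = 0.05, prune = TRUE) {
  lv <- hdr_levels()
  sel <- groups$response_metric %in% lv$process_metrics
  sub <- restore_groups(groups[sel, , drop = FALSE], groups)
  spec_for <- function(stratum_data) {
    hdr_model_spec(moderators = c("facet", "organismal_group"),
                   interactions = "x:het_cv", alpha = alpha)
  }
  run_suite(sub, lv$process_metrics, "response_metric", spec_for,
            "processes", prune = prune)
}

## an interaction candidate is admissible when every level of each
## participating factor is backed by >= 2 studies
interaction_possible <- function(groups, term) {
  parts <- setdiff(strsplit(term, ":", fixed = TRUE)[[1]], c("x", "x2"))
  for (p in parts) {
    col <- switch(p, latitude_c = "latitude_abs", p)
    if (!col %in% names(groups)) return(FALSE)
    v <- groups[[col]]
    if (all(is.na(v))) return(FALSE)
    if (is.character(v) || is.factor(v)) {
      tab <- tapply(groups$study_id, v, function(s) length(unique(s)))
      if (any(tab < 2, na.rm = TRUE)) return(FALSE)
    }
  }
  TRUE
}

#' @rdname analysis_suites
#' @param which `"facet_models"` or `"group_models"`: which objective-1
#'   battery to refit with environmental moderators.
#' @export
run_environment_suite <- function(groups,
                                  which = c("facet_models", "group_models"),
                                  response_metric = "richness",
                                  alpha = 0.05, prune = TRUE) {
  which <- match.arg(which)
  lv <- hdr_levels()
  env_mods <- c("substrate_type", "depth_zone", "season", "latitude_c")
  if (which == "facet_models") {
    sel <- groups$organismal_group %in% c("microinvertebrates",
                                          "macroinvertebrates") &
      groups$response_metric == response_metric
    sub <- restore_groups(groups[sel, , drop = FALSE], groups)
    strata <- lv$facet
    strata_label <- "facet"
    base_mods <- "organismal_group"
    suite_name <- "environment_facets"
  } else {
    sel <- groups$response_metric %in% lv$community_metrics
    sub <- restore_groups(groups[sel, , drop = FALSE], groups)
    sub <- pool_other_facets(sub)
    strata <- lv$organismal_group
    strata_label <- "organismal_group"
    base_mods <- c("facet_pooled", "response_metric")
    suite_name <- "environment_groups"
  }
  spec_for <- function(stratum_data) {
    cands <- c("latitude_c:season", "x:substrate_type", "x:latitude_c",
               "x:het_cv")
    cands <- cands[vapply(cands, function(tt) {
      interaction_possible(stratum_data, tt)
    }, logical(1))]
    hdr_model_spec(moderators = c(base_mods, env_mods),
                   interactions = cands, alpha = alpha)
  }
  run_suite(sub, strata, strata_label, spec_for, suite_name, prune = prune)
}
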