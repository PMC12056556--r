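#' Published exclusion rules for sensitivity analysis
#'
#' Returns the standard set of pure observation/group filters used to probe
#' robustness: dropping large studies (per-study observation counts above a
#' quantile threshold), HDR groups with fewer than four data points, discrete
#' heterogeneity descriptors, multi-facet HDRs and studies that confound
#' heterogeneity with site, date or substrate (the latter two via
#' ingest-supplied design flags). Each rule is a pure filter; rules compose
#' and are idempotent.
#'
#' @param large_quantile Per-study observation-count quantile above which a
#'   study counts as large (default 0.95).
#' @param min_hdr_size Minimum HDR group size retained by `drop_small_hdrs`
#'   (default 4).
#' @return Named list of `hdr_exclusion_rule` objects (`name`, `description`,
#'   `threshold`, `keep` — a predicate returning a logical per observation).
#' @export
exclusion_rules <- function(large_quantile = 0.95, min_hdr_size = 4) {
  rule <- function(name, description, threshold, keep) {
    structure(list(name = name, description = description,
                   threshold = threshold, keep = keep),
              class = "hdr_exclusion_rule")
  }
  list(
    drop_large_studies = rule(
      "drop_large_studies",
      "drop studies with per-study observation counts above the quantile",
      large_quantile,
      function(groups) {
        n_by_study <- table(groups$study_id)
        cutoff <- quantile(as.numeric(n_by_study), large_quantile)
        !(groups$study_id %in% names(n_by_study)[n_by_study > cutoff])
      }),
    drop_small_hdrs = rule(
      "drop_small_hdrs", "drop HDR groups with fewer data points than the threshold",
      min_hdr_size,
      function(groups) {
        n_by_hdr <- table(groups$hdr_id)
        !(groups$hdr_id %in% names(n_by_hdr)[n_by_hdr < min_hdr_size])
      }),
    drop_discrete = rule(
      "drop_discrete", "drop discrete heterogeneity descriptors", NA,
      function(groups) !groups$is_discrete_het),
    drop_multifacet = rule(
      "drop_multifacet", "drop multi-facet HDRs (flagged at ingest)", NA,
      function(groups) !has_flag(groups$design_flags, "multi_facet")),
    drop_confounded = rule(
      "drop_confounded",
      "drop studies confounding heterogeneity with site/date/substrate", NA,
      function(groups) {
        !has_flag(groups$design_flags, "confounded_site_date_substrate")
      })
  )
}

#' Apply an exclusion rule to analysis-ready groups
#'
#' Filters observations by the rule predicate and removes groups left
#' degenerate (fewer than 2 distinct heterogeneity levels or fewer than 2
#' observations).
#'
#' @param groups Analysis-ready groups.
#' @param rule An `hdr_exclusion_rule`.
#' @return Filtered groups; attribute `excluded` holds before/after counts.
#' @export
apply_exclusion <- function(groups, rule) {
  before <- count_units(groups)
  keep <- rule$keep(groups)
  out <- restore_groups(groups[keep, , drop = FALSE], groups)
  ## re-check group viability after filtering
  ok_hdr <- vapply(split(seq_len(nrow(out)), out$hdr_id), function(i) {
    length(unique(out$het_raw[i])) >= 2L && length(i) >= 2L
  }, logical(1))
  out <- restore_groups(out[out$hdr_id %in% names(ok_hdr)[ok_hdr], ,
                            drop = FALSE], out)
  attr(out, "excluded") <- list(rule = rule$name, before = before,
                                after = count_units(out))
  out
}

count_units <- function(groups) {
  c(n_obs = nrow(groups),
    n_hdr = length(unique(groups$hdr_id)),
    n_study = length(unique(groups$study_id)))
}

#' Re-run an analysis under each exclusion rule
#'
#' Runs `runner` on the base data and once per rule on the filtered data, and
#' reports per-stratum deltas of the linear and quadratic heterogeneity terms
#' together with significance flips. Strata emptied by a rule are marked
#' not-estimable rather than failing.
#'
#' @param groups Analysis-ready groups.
#' @param runner Function `groups -> hdr_suite` or `groups -> hdr_fit` (e.g.
#'   `\(g) run_facet_suite(g, "richness")`, or a pooled single-model fit).
#' @param rules List of rules from [exclusion_rules()].
#' @param alpha Significance level used for flip detection.
#' @return List of class `hdr_sensitivity`: `base` (runner output), `runs`
#'   (per-rule outputs), `delta` (tibble: rule, stratum, delta_beta_x,
#'   delta_beta_x2, sig_flip_x, sig_flip_x2, estimable, counts before/after).
#' @export
run_exclusion_suite <- function(groups, runner, rules = exclusion_rules(),
                                alpha = 0.05) {
  base <- runner(groups)
  base_tab <- comparison_table(base)
  for (col in c("beta_x", "p_x", "beta_x2", "p_x2")) {
    if (!col %in% names(base_tab)) base_tab[[col]] <- numeric(0)
  }
  runs <- list()
  deltas <- list()
  for (rule in rules) {
    filtered <- apply_exclusion(groups, rule)
    counts <- attr(filtered, "excluded")
    run <- tryCatch(runner(filtered), error = function(e) NULL)
    runs[[rule$name]] <- run
    run_tab <- if (is.null(run)) tibble::tibble(stratum = character()) else
      comparison_table(run)
    for (col in c("beta_x", "p_x", "beta_x2", "p_x2")) {
      if (!col %in% names(run_tab)) run_tab[[col]] <- numeric(0)
    }
    d <- dplyr::left_join(base_tab[, c("stratum", "beta_x", "p_x",
                                       "beta_x2", "p_x2")],
                          run_tab[, c("stratum", "beta_x", "p_x",
                                      "beta_x2", "p_x2")],
                          by = "stratum", suffix = c("_base", "_rule"))
    deltas[[rule$name]] <- tibble::tibble(
      rule = rule$name,
      stratum = d$stratum,
      delta_beta_x = d$beta_x_rule - d$beta_x_base,
      delta_beta_x2 = d$beta_x2_rule - d$beta_x2_base,
      sig_flip_x = xor(d$p_x_base <= alpha, d$p_x_rule <= alpha),
      sig_flip_x2 = xor(d$p_x2_base <= alpha, d$p_x2_rule <= alpha),
      estimable = !is.na(d$beta_x_rule),
      n_obs_before = counts$before[["n_obs"]],
      n_obs_after = counts$after[["n_obs"]],
      n_hdr_after = counts$after[["n_hdr"]],
      n_study_after = counts$after[["n_study"]]
    )
  }
  structure(list(base = base, runs = runs,
                 delta = dplyr::bind_rows(deltas)),
            class = "hdr_sensitivity")
}

#' Publication-bias diagnostic
#'
#' Refits the model with standardised sample size and publication year as
#' additional fixed effects; their coefficients and p-values are the bias
#' diagnostic. A constant covariate (e.g. a single-year dataset) is dropped
#' with a log entry rather than failing.
#'
#' @param groups Analysis-ready groups.
#' @param spec Base model spec (default plain quadratic model).
#' @return List: `fit` (the augmented `hdr_fit`) and `bias_terms` (tibble of
#'   the two covariate rows of the coefficient table).
#' @export
publication_bias_check <- function(groups, spec = hdr_model_spec()) {
  spec$moderators <- union(spec$moderators, c("sample_size_z", "pub_year_z"))
  frame <- build_design(groups, spec)
  fit <- fit_hdr_model(frame, spec)
  bias <- fit$coefficients[fit$coefficients$term %in%
                             c("sample_size_z", "pub_year_z"), ]
  list(fit = fit, bias_terms = bias,
       dropped = intersect(fit$dropped_terms,
                           c("sample_size_z", "pub_year_z")))
}
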