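#' Simulation-based parameter recovery
#'
#' Repeatedly generates a dataset from `scenario` (varying the seed per
#' replicate), runs the full pipeline (grouping, standardisation, lnRR) and
#' fits the pooled quadratic mixed model, then summarises bias, RMSE and Wald
#' confidence-interval coverage for the linear and quadratic heterogeneity
#' terms against the generator truth.
#'
#' The scalar truth is taken from the scenario's common facet curve; if the
#' scenario mixes different curves, group multipliers or moderator slopes the
#' pooled truth is ill-defined and `true_beta` must be supplied explicitly.
#'
#' @param scenario An [simulation_scenario()].
#' @param n_reps Number of replicate datasets.
#' @param seed Base seed; replicate r uses `seed + r`.
#' @param true_beta Optional `c(b1, b2)` truth override.
#' @param level Confidence level for coverage (default 0.95).
#' @param df_method Denominator df for the Wald intervals (default
#'   Satterthwaite).
#' @return List of class `hdr_recovery`: `replicates` (tibble with per-rep
#'   estimates, SEs, df and coverage indicators), `summary` (bias, RMSE,
#'   coverage and significance rate per term) and `truth`.
#' @export
recover_parameters <- function(scenario, n_reps = 200, seed = 1,
                               true_beta = NULL, level = 0.95,
                               df_method = "satterthwaite") {
  truth <- true_beta %||% scenario_true_beta(scenario)
  spec <- hdr_model_spec(df_method = df_method)
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    sc <- scenario
    sc$seed <- as.integer(seed + r)
    obs <- simulate_hdr_dataset(sc)
    groups <- prepare_hdr_data(obs)
    frame <- build_design(groups, spec)
    fit <- fit_hdr_model(frame, spec)
    xr <- term_row(fit, "x"); x2r <- term_row(fit, "x2")
    q <- qt(1 - (1 - level) / 2, df = xr$df)
    q2 <- qt(1 - (1 - level) / 2, df = x2r$df)
    rows[[r]] <- tibble::tibble(
      rep = r,
      beta1_hat = xr$estimate, se1 = xr$se, df1 = xr$df, p1 = xr$p_value,
      beta2_hat = x2r$estimate, se2 = x2r$se, df2 = x2r$df, p2 = x2r$p_value,
      covered1 = abs(xr$estimate - truth[1]) <= q * xr$se,
      covered2 = abs(x2r$estimate - truth[2]) <= q2 * x2r$se,
      r2_marginal = fit$r2_marginal, r2_conditional = fit$r2_conditional,
      singular = fit$singular
    )
  }
  reps <- dplyr::bind_rows(rows)
  summary <- tibble::tibble(
    term = c("x", "x2"),
    truth = truth,
    bias = c(mean(reps$beta1_hat) - truth[1],
             mean(reps$beta2_hat) - truth[2]),
    rmse = c(sqrt(mean((reps$beta1_hat - truth[1])^2)),
             sqrt(mean((reps$beta2_hat - truth[2])^2))),
    coverage = c(mean(reps$covered1), mean(reps$covered2)),
    significant_rate = c(mean(reps$p1 <= 0.05), mean(reps$p2 <= 0.05))
  )
  structure(list(replicates = reps, summary = summary, truth = truth,
                 n_reps = n_reps, level = level),
            class = "hdr_recovery")
}

#' Pooled true curve coefficients of a scenario
#'
#' Valid only when every facet shares one curve, all group multipliers are 1
#' and all moderator effects are zero (the default scenario); otherwise the
#' pooled truth is ambiguous and an error is raised.
#'
#' @param scenario An [simulation_scenario()].
#' @return `c(b1, b2)`.
#' @export
scenario_true_beta <- function(scenario) {
  curves <- unique(lapply(scenario$facet_curves, function(c) round(c, 12)))
  me <- scenario$moderator_effects
  homogeneous <- length(curves) == 1L &&
    all(abs(unlist(scenario$group_multipliers) - 1) < 1e-12) &&
    me$latitude_slope_per_degree == 0 && me$lat_season_interaction == 0 &&
    all(unlist(me[c("depth_offsets", "substrate_offsets",
                    "season_offsets")]) == 0) &&
    scenario$confounded_fraction == 0 && scenario$process_fraction == 0
  if (!homogeneous) {
    hdr_config_error(paste0(
      "pooled truth is ambiguous for this scenario; ",
      "supply true_beta explicitly"))
  }
  curves[[1]]
}

#' @export
print.hdr_recovery <- function(x, ...) {
  cat(sprintf("Parameter recovery over %d replicates (CI level %.2f)\n",
              x$n_reps, x$level))
  print(as.data.frame(x$summary), digits = 4)
  invisible(x)
}
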