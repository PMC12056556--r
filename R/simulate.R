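#' Define a synthetic multi-study simulation scenario
#'
#' Parameterises the synthetic generator that emulates the statistical
#' structure the HDR analysis assumes: many studies, each holding several HDR
#' groups observed at a fixed number of heterogeneity levels with replicate
#' plots; true response curves quadratic on the standardised 0-1 gradient;
#' correlated study-level random intercepts and slopes; HDR(plot)-level
#' random intercepts; multiplicative lognormal noise (so lnRR is the natural
#' analysis scale); per-study affine raw heterogeneity units so the
#' standardisation pipeline is exercised; and optional discrete descriptors,
#' confounded studies and moderator-dependent slopes.
#'
#' The default scenario is the package's reference recovery condition:
#' 40 studies x 6 HDRs x 8 levels x 3 replicates, study intercept and slope
#' variances 0.04, HDR intercept variance 0.01, residual variance 0.09, a
#' common true curve (1.2, -0.6) for every facet, unit group multipliers and
#' no moderator effects, so the pooled linear and quadratic terms have the
#' scalar truths 1.2 and -0.6.
#'
#' @param seed Integer RNG seed; the same scenario and seed reproduce the
#'   dataset byte-for-byte.
#' @param n_studies,hdrs_per_study,levels_per_hdr,reps_per_level Design sizes.
#' @param facet_curves Named list facet -> c(b1, b2) true curves.
#' @param group_multipliers Named numeric, organismal group -> slope
#'   multiplier.
#' @param process_curves Named list process metric -> c(b1, b2); used for
#'   process studies (see `process_fraction`). Process slopes are not
#'   multiplied by group multipliers.
#' @param process_fraction Fraction of studies generated as ecological-process
#'   studies (responses drawn from `process_curves`).
#' @param response_metrics Community metrics cycled across HDRs of community
#'   studies.
#' @param moderator_effects List: `latitude_slope_per_degree`,
#'   `depth_offsets`, `substrate_offsets`, `season_offsets` (additive slope
#'   offsets), and `lat_season_interaction` (extra per-degree slope in
#'   winter).
#' @param variances List: `study_intercept` (tau0^2), `study_slope` (tau1^2),
#'   `intercept_slope_corr` (rho), `hdr_intercept` (omega^2), `residual`
#'   (sigma^2).
#' @param baseline_response_scale Positive multiplier for raw responses.
#' @param discrete_fraction Fraction of HDRs emitted as ordinal descriptors.
#' @param confounded_fraction Fraction of studies flagged
#'   `confounded_site_date_substrate`, whose fixed slopes are inflated by
#'   `confound_inflation`.
#' @param confound_inflation Slope inflation factor for confounded studies.
#' @param multifacet_fraction Fraction of studies flagged `multi_facet` (their
#'   HDRs alternate between two facets).
#' @param pub_bias_lnrr_per_decade Publication-bias plant: additive lnRR
#'   offset at all non-baseline heterogeneity levels per decade of
#'   publication year after 2000 (default 0).
#' @param raw_unit_transforms List `a_range`, `b_range`: per-study affine raw
#'   units `raw = a_s * x + b_s` with `a_s > 0`.
#' @return Object of class `hdr_scenario`.
#' @export
simulation_scenario <- function(
    seed = 1L,
    n_studies = 40L, hdrs_per_study = 6L,
    levels_per_hdr = 8L, reps_per_level = 3L,
    facet_curves = NULL,
    group_multipliers = NULL,
    process_curves = list(),
    process_fraction = 0,
    response_metrics = c("richness", "abundance"),
    moderator_effects = list(),
    variances = list(),
    baseline_response_scale = 10,
    discrete_fraction = 0.15,
    confounded_fraction = 0,
    confound_inflation = 2,
    multifacet_fraction = 0,
    pub_bias_lnrr_per_decade = 0,
    raw_unit_transforms = list(a_range = c(0.5, 20), b_range = c(1, 10))) {
  lv <- hdr_levels()
  if (is.null(facet_curves)) {
    facet_curves <- setNames(rep(list(c(1.2, -0.6)), length(lv$facet)),
                             lv$facet)
  }
  if (is.null(group_multipliers)) {
    group_multipliers <- setNames(rep(1, length(lv$organismal_group)),
                                  lv$organismal_group)
  }
  me_default <- list(
    latitude_slope_per_degree = 0,
    depth_offsets = setNames(rep(0, 4), lv$depth_zone),
    substrate_offsets = setNames(rep(0, 2), lv$substrate_type),
    season_offsets = setNames(rep(0, 4), lv$season),
    lat_season_interaction = 0
  )
  me <- modifyList(me_default, moderator_effects)
  v_default <- list(study_intercept = 0.04, study_slope = 0.04,
                    intercept_slope_corr = 0, hdr_intercept = 0.01,
                    residual = 0.09)
  v <- modifyList(v_default, variances)

  if (baseline_response_scale <= 0) {
    hdr_config_error("baseline_response_scale must be positive")
  }
  if (any(unlist(v[c("study_intercept", "study_slope", "hdr_intercept",
                     "residual")]) < 0)) {
    hdr_config_error("variances must be non-negative")
  }
  if (abs(v$intercept_slope_corr) > 1) {
    hdr_config_error("intercept_slope_corr must lie in [-1, 1]")
  }
  for (f in c(discrete_fraction, confounded_fraction, multifacet_fraction,
              process_fraction)) {
    if (f < 0 || f > 1) hdr_config_error("fractions must lie in [0, 1]")
  }
  bad_facet <- setdiff(names(facet_curves), lv$facet)
  if (length(bad_facet)) {
    hdr_config_error(paste0("unknown facet(s): ",
                            paste(bad_facet, collapse = ", ")))
  }

  structure(list(
    seed = as.integer(seed), n_studies = as.integer(n_studies),
    hdrs_per_study = as.integer(hdrs_per_study),
    levels_per_hdr = as.integer(levels_per_hdr),
    reps_per_level = as.integer(reps_per_level),
    facet_curves = facet_curves, group_multipliers = group_multipliers,
    process_curves = process_curves, process_fraction = process_fraction,
    response_metrics = response_metrics,
    moderator_effects = me, variances = v,
    baseline_response_scale = baseline_response_scale,
    discrete_fraction = discrete_fraction,
    confounded_fraction = confounded_fraction,
    confound_inflation = confound_inflation,
    multifacet_fraction = multifacet_fraction,
    pub_bias_lnrr_per_decade = pub_bias_lnrr_per_decade,
    raw_unit_transforms = raw_unit_transforms
  ), class = "hdr_scenario")
}

#' @export
print.hdr_scenario <- function(x, ...) {
  cat(sprintf(
    "HDR simulation scenario: %d studies x %d HDRs x %d levels x %d reps (seed %d)\n",
    x$n_studies, x$hdrs_per_study, x$levels_per_hdr, x$reps_per_level, x$seed))
  cat(sprintf(
    "  variances: tau0^2=%g tau1^2=%g rho=%g omega^2=%g sigma^2=%g\n",
    x$variances$study_intercept, x$variances$study_slope,
    x$variances$intercept_slope_corr, x$variances$hdr_intercept,
    x$variances$residual))
  invisible(x)
}

## fixed-effect slope offset implied by a study's environmental context
moderator_slope <- function(me, latitude, depth, season, substrate) {
  me$latitude_slope_per_degree * latitude +
    me$depth_offsets[[depth]] + me$substrate_offsets[[substrate]] +
    me$season_offsets[[season]] +
    me$lat_season_interaction * latitude * (season == "winter")
}

#' Generate a synthetic multi-study observation table
#'
#' Draws study-level random effects (u0, u1) from the bivariate study
#' distribution and an HDR-level intercept w for each group, places the
#' standardised gradient on an even grid over [0, 1] (the baseline x = 0 is
#' always present so the lnRR baseline is defined), and emits responses
#' `y = scale * exp(eta + e)` with
#' `eta = u0 + w + (b1 * m + u1 + moderator slope) * x + b2 * x^2` and
#' `e ~ N(0, sigma^2)`, so the lnRR pipeline recovers `eta` up to baseline
#' noise. Raw heterogeneity is reported in per-study affine units
#' `a_s * x + b_s`; a fraction of HDRs instead carry ordinal level labels.
#'
#' @param scenario An [simulation_scenario()].
#' @return An `hdr_observations` tibble with attribute `truth`: the scenario,
#'   a per-study parameter table (random effects, context, flags, affine
#'   units) and the per-HDR curve assignments.
#' @export
simulate_hdr_dataset <- function(scenario) {
  stopifnot(inherits(scenario, "hdr_scenario"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(scenario$seed)

  lv <- hdr_levels()
  v <- scenario$variances
  me <- scenario$moderator_effects
  ns <- scenario$n_studies
  facets <- names(scenario$facet_curves)
  groups <- names(scenario$group_multipliers)
  nf <- length(facets)

  ## correlated study intercept/slope via the Cholesky of the 2x2 covariance
  z1 <- rnorm(ns); z2 <- rnorm(ns)
  t0 <- sqrt(v$study_intercept); t1 <- sqrt(v$study_slope)
  rho <- v$intercept_slope_corr
  u0 <- t0 * z1
  u1 <- t1 * (rho * z1 + sqrt(1 - rho^2) * z2)

  n_conf <- round(scenario$confounded_fraction * ns)
  conf_ids <- if (n_conf > 0) sample(ns, n_conf) else integer()
  n_multi <- round(scenario$multifacet_fraction * ns)
  multi_ids <- if (n_multi > 0) sample(ns, n_multi) else integer()
  n_proc <- round(scenario$process_fraction * ns)
  proc_ids <- if (n_proc > 0 && length(scenario$process_curves)) {
    sample(ns, n_proc)
  } else integer()

  studies <- tibble::tibble(
    study_id = sprintf("S%03d", seq_len(ns)),
    u0 = u0, u1 = u1,
    facet = facets[(seq_len(ns) - 1L) %% nf + 1L],
    organismal_group = groups[(seq_len(ns) - 1L) %/% nf %% length(groups) + 1L],
    latitude_abs = round(runif(ns, 0, 60), 2),
    depth_zone = sample(lv$depth_zone, ns, replace = TRUE),
    season = sample(lv$season, ns, replace = TRUE),
    substrate_type = sample(lv$substrate_type, ns, replace = TRUE),
    pub_year = sample(1980:2020, ns, replace = TRUE),
    a_s = runif(ns, scenario$raw_unit_transforms$a_range[1],
                scenario$raw_unit_transforms$a_range[2]),
    b_s = runif(ns, scenario$raw_unit_transforms$b_range[1],
                scenario$raw_unit_transforms$b_range[2]),
    confounded = seq_len(ns) %in% conf_ids,
    multi_facet = seq_len(ns) %in% multi_ids,
    is_process = seq_len(ns) %in% proc_ids
  )

  x_grid <- seq(0, 1, length.out = scenario$levels_per_hdr)
  nrep <- scenario$reps_per_level
  nh <- scenario$hdrs_per_study
  NH <- ns * nh

  ## HDR-level draws and assignments (study index varies slowest)
  h_study <- rep(seq_len(ns), each = nh)
  h_index <- rep(seq_len(nh), times = ns)
  w <- rnorm(NH, 0, sqrt(v$hdr_intercept))
  discrete <- runif(NH) < scenario$discrete_fraction
  n_species <- pmax(1L, stats::rpois(NH, 12))

  h_facet <- studies$facet[h_study]
  alt <- studies$multi_facet[h_study] & h_index %% 2 == 0
  h_facet[alt] <- facets[match(h_facet[alt], facets) %% nf + 1L]
  is_proc <- studies$is_process[h_study]
  h_metric <- scenario$response_metrics[
    (h_index - 1L) %% length(scenario$response_metrics) + 1L]
  if (any(is_proc)) {
    pm <- names(scenario$process_curves)
    h_metric[is_proc] <- pm[(h_index[is_proc] - 1L) %% length(pm) + 1L]
  }
  curve_mat <- vapply(seq_len(NH), function(k) {
    if (is_proc[k]) scenario$process_curves[[h_metric[k]]] else
      scenario$facet_curves[[h_facet[k]]]
  }, numeric(2))
  mult <- ifelse(is_proc, 1,
                 unlist(scenario$group_multipliers)[
                   studies$organismal_group[h_study]])
  mod_slope <- vapply(seq_len(ns), function(s) {
    moderator_slope(me, studies$latitude_abs[s], studies$depth_zone[s],
                    studies$season[s], studies$substrate_type[s])
  }, numeric(1))
  slope_fixed <- curve_mat[1, ] * mult + mod_slope[h_study]
  slope_fixed <- ifelse(studies$confounded[h_study],
                        slope_fixed * scenario$confound_inflation,
                        slope_fixed)

  ## observation-level expansion: HDR varies slowest, then level, then rep
  per_hdr <- length(x_grid) * nrep
  o_hdr <- rep(seq_len(NH), each = per_hdr)
  o_level <- rep(rep(seq_along(x_grid), each = nrep), times = NH)
  o_rep <- rep(rep(seq_len(nrep), times = length(x_grid)), times = NH)
  x <- x_grid[o_level]
  eps <- rnorm(length(x), 0, sqrt(v$residual))
  o_study <- h_study[o_hdr]
  eta <- studies$u0[o_study] + w[o_hdr] +
    (slope_fixed[o_hdr] + studies$u1[o_study]) * x +
    curve_mat[2, o_hdr] * x^2 +
    scenario$pub_bias_lnrr_per_decade *
      ((studies$pub_year[o_study] - 2000) / 10) * (x > 0)
  y <- scenario$baseline_response_scale * exp(eta + eps)
  het_raw <- ifelse(discrete[o_hdr],
                    sprintf("lvl%02d", o_level),
                    sprintf("%.17g", studies$a_s[o_study] * x +
                              studies$b_s[o_study]))
  flag_str <- vapply(seq_len(ns), function(s) {
    paste(c(
      if (studies$confounded[s]) "confounded_site_date_substrate",
      if (studies$multi_facet[s]) "multi_facet"), collapse = ";")
  }, character(1))

  obs <- tibble::tibble(
    study_id = studies$study_id[o_study],
    plot_id = sprintf("%s_H%02d_L%02d_R%d", studies$study_id[o_study],
                      h_index[o_hdr], o_level, o_rep),
    site = sprintf("site%02d", h_index[o_hdr]),
    date = "2020-06-15",
    substrate_context = "ctx1",
    het_raw = het_raw,
    het_metric = ifelse(discrete[o_hdr], "ordinal_levels", "rugosity_index"),
    facet = h_facet[o_hdr],
    response_value = y,
    response_metric = h_metric[o_hdr],
    organismal_group = studies$organismal_group[o_study],
    latitude_abs = studies$latitude_abs[o_study],
    depth_zone = studies$depth_zone[o_study],
    season = studies$season[o_study],
    substrate_type = studies$substrate_type[o_study],
    n_species = n_species[o_hdr],
    sample_size = nrep,
    pub_year = studies$pub_year[o_study],
    is_discrete_het = discrete[o_hdr],
    design_flags = flag_str[o_study]
  )
  obs <- as_hdr_observations(obs)
  attr(obs, "truth") <- list(
    scenario = scenario,
    studies = studies,
    hdrs = tibble::tibble(
      study_id = studies$study_id[h_study], hdr_index = h_index,
      facet = h_facet, response_metric = h_metric, discrete = discrete,
      w = w, beta1 = curve_mat[1, ], beta2 = curve_mat[2, ],
      slope_fixed = slope_fixed)
  )
  obs
}

#' Truth attached to a simulated dataset
#'
#' @param obs Output of [simulate_hdr_dataset()].
#' @return The truth sidecar list (`scenario`, `studies`, `hdrs`).
#' @export
simulation_truth <- function(obs) {
  tr <- attr(obs, "truth")
  if (is.null(tr)) hdr_config_error("no truth sidecar attached")
  tr
}

#' Noise-free expected lnRR under a scenario
#'
#' The fixed-effect value of the true linear predictor at standardised
#' heterogeneity `x` for a facet and moderator profile — the oracle used by
#' the recovery tests. At the reference profile (no group multiplier deviation
#' and no moderator offsets) the curve is `b1 * x + b2 * x^2`, anchored at 0
#' for x = 0.
#'
#' @param scenario An [simulation_scenario()].
#' @param facet Facet name (must exist in `scenario$facet_curves`).
#' @param x Numeric in [0, 1].
#' @param moderator_profile Optional list with `organismal_group`, `latitude`,
#'   `depth_zone`, `season`, `substrate_type`.
#' @return Expected lnRR at `x`.
#' @export
#' @examples
#' sc <- simulation_scenario()
#' true_curve(sc, "substrate_3d_amount", x = 1)  # 0.6
true_curve <- function(scenario, facet, x, moderator_profile = list()) {
  if (any(x < 0 | x > 1)) hdr_config_error("x outside [0, 1]")
  curve <- scenario$facet_curves[[facet]]
  if (is.null(curve)) hdr_config_error(paste0("unknown facet: ", facet))
  mult <- if (!is.null(moderator_profile$organismal_group)) {
    scenario$group_multipliers[[moderator_profile$organismal_group]]
  } else 1
  me <- scenario$moderator_effects
  mod <- moderator_slope(
    me,
    moderator_profile$latitude %||% 0,
    moderator_profile$depth_zone %||% "shallow_subtidal",
    moderator_profile$season %||% "spring",
    moderator_profile$substrate_type %||% "rock")
  ## reference profile contributes zero offset under the default scenario
  (curve[1] * mult + mod) * x + curve[2] * x^2
}

#' Canned scenarios used throughout the tests and vignette
#'
#' \describe{
#'   \item{scenario_noise_free()}{All random-effect variances zero and
#'     residual variance 1e-16; group multipliers 1; for exactness checks.}
#'   \item{scenario_null()}{True curves all (0, 0); for type-I error and null
#'     pruning checks.}
#'   \item{scenario_facet_contrast()}{Heterogeneous facet curves (substrate 3D
#'     amount strongest, feature richness null) and trait-ordered group
#'     multipliers; for suite ordering checks.}
#'   \item{scenario_confounded()}{Default scenario with a fraction of studies
#'     confounded and their slopes inflated.}
#'   \item{scenario_environment()}{Moderator-dependent slopes: steeper at low
#'     latitude, stronger on biogenic substrate and in the intertidal.}
#'   \item{scenario_process()}{All studies measure ecological processes:
#'     grazing declining and non-linear, recruitment increasing, predation and
#'     body size null.}
#' }
#'
#' @param seed RNG seed.
#' @param ... Overrides passed to [simulation_scenario()].
#' @return An `hdr_scenario`.
#' @name canned_scenarios
NULL

canned <- function(defaults, seed, ...) {
  args <- modifyList(defaults, list(seed = seed, ...))
  do.call(simulation_scenario, args)
}

#' @rdname canned_scenarios
#' @export
scenario_noise_free <- function(seed = 1L, ...) {
  canned(list(
    variances = list(study_intercept = 0, study_slope = 0,
                     intercept_slope_corr = 0, hdr_intercept = 0,
                     residual = 1e-16),
    discrete_fraction = 0), seed, ...)
}

#' @rdname canned_scenarios
#' @export
scenario_null <- function(seed = 1L, ...) {
  lv <- hdr_levels()
  canned(list(
    facet_curves = setNames(rep(list(c(0, 0)), length(lv$facet)), lv$facet)),
    seed, ...)
}

#' @rdname canned_scenarios
#' @export
scenario_facet_contrast <- function(seed = 1L, ...) {
  canned(list(
    facet_curves = list(
      substrate_3d_amount = c(1.2, -0.6),
      substrate_2d_amount = c(0.6, -0.2),
      substrate_complexity = c(0.6, -0.15),
      feature_size = c(0.6, -0.2),
      feature_variation = c(0.45, -0.1),
      feature_richness = c(0, 0)),
    group_multipliers = c(
      microalgae = 1.0, macroalgae = 0.6, microinvertebrates = 1.4,
      macroinvertebrates = 0.6, large_macroinvertebrates = 0.7, fish = 1.2)),
    seed, ...)
}

#' @rdname canned_scenarios
#' @export
scenario_confounded <- function(seed = 1L, ...) {
  canned(list(confounded_fraction = 0.3, confound_inflation = 2), seed, ...)
}

#' @rdname canned_scenarios
#' @export
scenario_environment <- function(seed = 1L, ...) {
  canned(list(
    moderator_effects = list(
      latitude_slope_per_degree = -0.012,
      substrate_offsets = c(biogenic = 0.3, rock = 0),
      depth_offsets = c(high_intertidal = 0.25, low_intertidal = 0.15,
                        shallow_subtidal = 0, deep_subtidal = 0))),
    seed, ...)
}

#' @rdname canned_scenarios
#' @export
scenario_process <- function(seed = 1L, ...) {
  canned(list(
    process_curves = list(
      grazing = c(-0.8, 0.5), predation = c(0, 0),
      recruitment = c(0.6, -0.2), body_size = c(0, 0)),
    process_fraction = 1), seed, ...)
}
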