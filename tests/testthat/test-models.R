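test_that("build_design lays out the quadratic frame with grouping indices", {
  g <- small_groups(seed = 31, n_studies = 3, hdrs_per_study = 1,
                    levels_per_hdr = 4, reps_per_level = 1)
  frame <- build_design(g, hdr_model_spec())
  expect_named(frame, c("lnrr", "x", "x2", "het_cv", "study_id", "hdr_id"))
  expect_equal(nrow(frame), nrow(g))
  expect_equal(frame$x2, frame$x^2)
})

test_that("build_design deletes listwise on missing moderators, with a log", {
  g <- small_groups(seed = 32, n_studies = 4)
  g$depth_zone[c(1, 5)] <- NA
  spec <- hdr_model_spec(moderators = "depth_zone")
  frame <- build_design(g, spec)
  expect_equal(nrow(frame), nrow(g) - 2)
  expect_match(attr(frame, "design_log"), "2 rows dropped")
  g$depth_zone <- NA_character_
  expect_error(build_design(g, spec), class = "hdr_config_error")
})

test_that("categorical moderators use alphabetical treatment contrasts", {
  g <- small_groups(seed = 33, n_studies = 8)
  frame <- build_design(g, hdr_model_spec(moderators = "organismal_group"))
  expect_true(is.factor(frame$organismal_group))
  expect_equal(levels(frame$organismal_group),
               sort(levels(frame$organismal_group)))
})

test_that("fitting requires at least 2 studies and 3 HDR groups", {
  g <- small_groups(seed = 34, n_studies = 6)
  one_study <- filter_groups(g, g$study_id == g$study_id[1])
  expect_error(fit_hdr_model(build_design(one_study, hdr_model_spec())),
               "2 studies", class = "hdr_fit_error")
})

test_that("noise-free data are recovered exactly and flagged singular", {
  sc <- scenario_noise_free(seed = 35, n_studies = 6, hdrs_per_study = 2,
                            levels_per_hdr = 5, reps_per_level = 2)
  g <- prepare_hdr_data(simulate_hdr_dataset(sc))
  fit <- fit_hdr_model(build_design(g, hdr_model_spec()),
                       hdr_model_spec(df_method = "residual"))
  co <- fit$coefficients
  expect_equal(co$estimate[co$term == "x"], 1.2, tolerance = 1e-6)
  expect_equal(co$estimate[co$term == "x2"], -0.6, tolerance = 1e-6)
  expect_true(fit$singular)
  expect_equal(fit$df_method_used, "residual")
})

test_that("Satterthwaite df are used and recorded when available", {
  g <- small_groups(seed = 36)
  fit <- fit_hdr_model(build_design(g, hdr_model_spec()), hdr_model_spec())
  expect_equal(fit$df_method_used, "satterthwaite")
  expect_true(all(fit$coefficients$df > 0))
  ## variance components present and non-negative where they are variances
  vc <- fit$varcomp
  expect_setequal(vc$component,
                  c("study_intercept", "study_slope",
                    "study_intercept_slope_cov", "hdr_intercept", "residual"))
  vars <- vc$variance[vc$component != "study_intercept_slope_cov"]
  expect_true(all(vars >= 0))
})

test_that("interaction pruning removes null terms and keeps real ones", {
  ## het_cv genuinely moderates nothing here: x:het_cv should go
  g <- small_groups(seed = 37, n_studies = 12, hdrs_per_study = 3)
  spec <- hdr_model_spec(interactions = "x:het_cv")
  frame <- build_design(g, spec)
  pr <- prune_interactions(frame, spec)
  expect_equal(pr$interactions, character(0))
  expect_equal(nrow(pr$audit), 1)
  expect_gt(pr$audit$p_value, 0.05)

  ## plant a strong group-dependent slope: x:organismal_group must survive
  sc <- simulation_scenario(
    seed = 38, n_studies = 12, hdrs_per_study = 3, levels_per_hdr = 5,
    reps_per_level = 3,
    group_multipliers = c(microinvertebrates = 2, macroalgae = 0.2))
  g2 <- prepare_hdr_data(simulate_hdr_dataset(sc))
  spec2 <- hdr_model_spec(interactions = c("x:organismal_group", "x:het_cv"))
  frame2 <- build_design(g2, spec2)
  pr2 <- prune_interactions(frame2, spec2)
  expect_true("x:organismal_group" %in% pr2$interactions)
  expect_false("x:het_cv" %in% pr2$interactions)
  ## eliminations recorded largest-p-first, one per step
  expect_equal(pr2$audit$term[pr2$audit$step > 0], "x:het_cv")
})

test_that("R2 variance partition follows the component formula", {
  expect_equal(unname(r2_from_components(1, 1, 2)), c(0.25, 0.5))
  ## no random variance: marginal equals conditional
  r <- r2_from_components(2, 0, 1)
  expect_equal(r[["r2_marginal"]], r[["r2_conditional"]])
  expect_warning(r0 <- r2_from_components(0, 0, 0), "zero")
  expect_equal(unname(r0), c(0, 0))
})

test_that("model R2 is bounded and ordered on real fits", {
  g <- small_groups(seed = 39)
  fit <- fit_hdr_model(build_design(g, hdr_model_spec()), hdr_model_spec())
  expect_gte(fit$r2_marginal, 0)
  expect_lte(fit$r2_conditional, 1)
  expect_lte(fit$r2_marginal, fit$r2_conditional)
})

test_that("predicted curves follow the fitted quadratic with delta-method CIs", {
  sc <- scenario_noise_free(seed = 40, n_studies = 6, hdrs_per_study = 2,
                            levels_per_hdr = 5, reps_per_level = 2,
                            facet_curves = setNames(
                              rep(list(c(2, -2)), 6), hdr_levels()$facet))
  g <- prepare_hdr_data(simulate_hdr_dataset(sc))
  fit <- fit_hdr_model(build_design(g, hdr_model_spec()),
                       hdr_model_spec(df_method = "residual"))
  pc <- predict_curve(fit, c(0, 0.5, 1))
  ## vertex of (2, -2) sits at 0.5 with value 0.5
  expect_equal(pc$fit[2], 0.5, tolerance = 1e-5)
  expect_equal(pc$fit[3], 0, tolerance = 1e-5)
  ## noise-free: CI width collapses
  expect_lt(max(pc$upper - pc$lower), 1e-5)
  expect_error(predict_curve(fit, 1.2), class = "hdr_config_error")
})

test_that("pairwise contrasts are Holm-adjusted with letter groupings", {
  sc <- simulation_scenario(
    seed = 41, n_studies = 18, hdrs_per_study = 3, levels_per_hdr = 5,
    reps_per_level = 3,
    group_multipliers = c(microinvertebrates = 3, macroalgae = 1,
                          fish = 1))
  g <- prepare_hdr_data(simulate_hdr_dataset(sc))
  spec <- hdr_model_spec(moderators = "organismal_group",
                         interactions = "x:organismal_group")
  fit <- fit_hdr_model(build_design(g, spec), spec)
  pc <- pairwise_contrasts(fit, "organismal_group")
  ## k(k-1)/2 contrasts for 3 levels
  expect_equal(nrow(pc$contrasts), 3)
  expect_length(pc$letters, 3)
  ## the shifted level separates from the two others
  sep <- grepl("microinvertebrates", pc$contrasts$contrast)
  expect_true(all(pc$contrasts$p_value[sep] < 0.05))
  expect_false(pc$letters[["microinvertebrates"]] %in%
                 pc$letters[c("macroalgae", "fish")])
  expect_error(pairwise_contrasts(fit, "het_cv"), class = "hdr_config_error")
})
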