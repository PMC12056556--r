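test_that("drop_small_hdrs removes groups below the size threshold", {
  ## groups of sizes 3, 4, 5
  obs <- as_hdr_observations(dplyr::bind_rows(
    make_obs(3, site = "sA", plot_id = paste0("a", 1:3),
             het_raw = c("1", "2", "3")),
    make_obs(4, site = "sB", plot_id = paste0("b", 1:4),
             het_raw = c("1", "2", "3", "4")),
    make_obs(5, site = "sC", plot_id = paste0("c", 1:5),
             het_raw = c("1", "2", "3", "4", "5"))
  ))
  g <- add_lnrr(standardize_hdr(build_hdr_groups(obs)))
  rule <- exclusion_rules(min_hdr_size = 4)$drop_small_hdrs
  out <- apply_exclusion(g, rule)
  expect_equal(length(unique(out$hdr_id)), 2)
  expect_equal(attr(out, "excluded")$before[["n_hdr"]], 3)
  expect_equal(attr(out, "excluded")$after[["n_hdr"]], 2)
})

test_that("rules on absent features are no-ops with zero delta", {
  g <- small_groups(seed = 61, n_studies = 10, discrete_fraction = 0)
  runner <- function(gr) {
    fit_hdr_model(build_design(gr, hdr_model_spec()),
                  hdr_model_spec(df_method = "residual"))
  }
  sens <- run_exclusion_suite(
    g, runner, rules = exclusion_rules()["drop_discrete"])
  expect_equal(sens$delta$delta_beta_x, 0, tolerance = 1e-12)
  expect_equal(sens$delta$n_obs_before, sens$delta$n_obs_after)
  expect_false(sens$delta$sig_flip_x)
})

test_that("filters are idempotent and compose order-independently", {
  g <- small_groups(seed = 62, n_studies = 12, discrete_fraction = 0.3,
                    confounded_fraction = 0.25)
  rules <- exclusion_rules()
  once <- apply_exclusion(g, rules$drop_discrete)
  twice <- apply_exclusion(once, rules$drop_discrete)
  expect_equal(strip_attrs(twice), strip_attrs(once))
  ab <- apply_exclusion(apply_exclusion(g, rules$drop_discrete),
                        rules$drop_confounded)
  ba <- apply_exclusion(apply_exclusion(g, rules$drop_confounded),
                        rules$drop_discrete)
  expect_equal(strip_attrs(dplyr::arrange(tibble::as_tibble(ab), plot_id)),
               strip_attrs(dplyr::arrange(tibble::as_tibble(ba), plot_id)))
})

test_that("dropping planted confounded studies lowers the pooled slope", {
  sc <- scenario_confounded(seed = 63, n_studies = 24, hdrs_per_study = 3,
                            levels_per_hdr = 5, reps_per_level = 3)
  g <- prepare_hdr_data(simulate_hdr_dataset(sc))
  runner <- function(gr) {
    fit_hdr_model(build_design(gr, hdr_model_spec()),
                  hdr_model_spec(df_method = "residual"))
  }
  sens <- run_exclusion_suite(g, runner,
                              rules = exclusion_rules()["drop_confounded"])
  expect_lt(sens$delta$delta_beta_x, 0)
  expect_lt(sens$delta$n_obs_after, sens$delta$n_obs_before)
})

test_that("a rule that empties the data marks strata not-estimable", {
  g <- small_groups(seed = 64, n_studies = 6, discrete_fraction = 1)
  runner <- function(gr) {
    fit_hdr_model(build_design(gr, hdr_model_spec()),
                  hdr_model_spec(df_method = "residual"))
  }
  sens <- run_exclusion_suite(g, runner,
                              rules = exclusion_rules()["drop_discrete"])
  expect_false(sens$delta$estimable)
})

test_that("large-study exclusion uses the per-study observation quantile", {
  g <- small_groups(seed = 65, n_studies = 10)
  ## inflate one study by duplicating its rows under new HDR ids
  big <- filter_groups(g, g$study_id == "S001")
  extra <- dplyr::bind_rows(lapply(1:6, function(k) {
    b <- tibble::as_tibble(big)
    b$hdr_id <- paste0(b$hdr_id, "_dup", k)
    b$plot_id <- paste0(b$plot_id, "_dup", k)
    b
  }))
  g2 <- filter_groups(dplyr::bind_rows(tibble::as_tibble(g), extra),
                      rep(TRUE, nrow(g) + nrow(extra)))
  rule <- exclusion_rules(large_quantile = 0.95)$drop_large_studies
  out <- apply_exclusion(g2, rule)
  expect_false("S001" %in% out$study_id)
  expect_true(all(setdiff(unique(g2$study_id), "S001") %in% out$study_id))
})

test_that("publication-bias covariates are reported, or dropped if constant", {
  sc <- simulation_scenario(seed = 66, n_studies = 24, hdrs_per_study = 3,
                            levels_per_hdr = 5, reps_per_level = 3,
                            pub_bias_lnrr_per_decade = 0.4)
  g <- prepare_hdr_data(simulate_hdr_dataset(sc))
  pb <- publication_bias_check(g)
  yr <- pb$bias_terms[pb$bias_terms$term == "pub_year_z", ]
  expect_gt(yr$estimate, 0)
  expect_lt(yr$p_value, 0.05)

  ## single-year dataset: pub_year dropped, not fatal
  g$pub_year <- 2005
  pb2 <- publication_bias_check(g)
  expect_true("pub_year_z" %in% pb2$dropped)
})
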