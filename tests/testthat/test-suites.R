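## Shared simulated dataset for the suite tests: heterogeneous facet curves,
## invertebrate-focused groups so each facet stratum holds enough studies.
suite_groups <- local({
  sc <- scenario_facet_contrast(
    seed = 51, n_studies = 36, hdrs_per_study = 4, levels_per_hdr = 6,
    reps_per_level = 3,
    group_multipliers = c(microinvertebrates = 1.4, macroinvertebrates = 0.6))
  prepare_hdr_data(simulate_hdr_dataset(sc))
})

test_that("the facet suite fits one model per facet and ranks 3D amount first", {
  suite <- run_facet_suite(suite_groups, "richness")
  expect_s3_class(suite, "hdr_suite")
  expect_equal(nrow(suite$comparison), 6)
  tab <- suite$comparison
  ## substrate 3D amount was generated with the steepest curve
  expect_equal(tab$stratum[which.max(tab$beta_x)], "substrate_3d_amount")
  ## feature richness was generated null
  expect_gt(tab$p_x[tab$stratum == "feature_richness"], 0.05)
  expect_true(all(tab$r2_marginal <= tab$r2_conditional))
})

test_that("an empty facet stratum is skipped with a reason", {
  g <- filter_groups(suite_groups, suite_groups$facet != "feature_size")
  suite <- run_facet_suite(g, "richness")
  expect_true("feature_size" %in% suite$skipped$stratum)
  expect_match(suite$skipped$reason[suite$skipped$stratum == "feature_size"],
               "no data")
  expect_false("feature_size" %in% names(suite$fits))
})

test_that("facet pooling relabels the four sparse facets losslessly", {
  pooled <- pool_other_facets(suite_groups)
  expect_equal(nrow(pooled), nrow(suite_groups))
  expect_setequal(unique(pooled$facet_pooled),
                  c("substrate_3d_amount", "substrate_2d_amount",
                    "other_pooled"))
  lv <- hdr_levels()
  expect_true(all(pooled$facet_pooled[pooled$facet %in%
                                        lv$pooled_into_other] ==
                    "other_pooled"))
})

test_that("the organismal-group suite pools community metrics per group", {
  suite <- run_group_suite(suite_groups)
  expect_setequal(names(suite$fits), c("microinvertebrates",
                                       "macroinvertebrates"))
  fit <- suite$fits$microinvertebrates
  ## pooled facet factor is in the design
  expect_true("facet_pooled" %in% names(fit$frame))
  ## steeper generated slope for microinvertebrates
  tab <- suite$comparison
  expect_gt(tab$beta_x[tab$stratum == "microinvertebrates"],
            tab$beta_x[tab$stratum == "macroinvertebrates"])
})

test_that("a group with a single response metric drops the metric term", {
  g <- filter_groups(suite_groups, suite_groups$response_metric == "richness")
  suite <- run_group_suite(g)
  fit <- suite$fits$microinvertebrates
  expect_true("response_metric" %in% fit$dropped_terms)
  expect_false(any(grepl("response_metric",
                         fit$coefficients$term)))
})

test_that("the process suite recovers the planted process directions", {
  sc <- scenario_process(seed = 52, n_studies = 30, hdrs_per_study = 4,
                         levels_per_hdr = 6, reps_per_level = 3)
  g <- prepare_hdr_data(simulate_hdr_dataset(sc))
  suite <- run_process_suite(g)
  tab <- suite$comparison
  ## grazing declines non-linearly; recruitment rises; predation is null
  expect_lt(tab$beta_x[tab$stratum == "grazing"], 0)
  expect_gt(tab$beta_x2[tab$stratum == "grazing"], 0)
  expect_lt(tab$p_x[tab$stratum == "recruitment"], 0.05)
  expect_gt(tab$beta_x[tab$stratum == "recruitment"], 0)
  expect_gt(tab$p_x[tab$stratum == "predation"], 0.05)
})

test_that("a missing process is reported as a skipped stratum", {
  sc <- scenario_process(seed = 53, n_studies = 12, hdrs_per_study = 3,
                         levels_per_hdr = 5, reps_per_level = 3)
  obs <- simulate_hdr_dataset(sc)
  g <- prepare_hdr_data(obs)
  g2 <- filter_groups(g, g$response_metric != "body_size")
  suite <- run_process_suite(g2)
  expect_true("body_size" %in% suite$skipped$stratum)
})

test_that("environment suite recovers planted moderator structure", {
  sc <- scenario_environment(
    seed = 54, n_studies = 40, hdrs_per_study = 4, levels_per_hdr = 6,
    reps_per_level = 3,
    group_multipliers = c(microinvertebrates = 1.2, macroinvertebrates = 0.8))
  g <- prepare_hdr_data(simulate_hdr_dataset(sc))
  suite <- run_environment_suite(g, "group_models")
  expect_gte(length(suite$fits), 1)
  fit <- suite$fits$microinvertebrates
  ## latitude moderates the slope negatively in the generator
  if ("x:latitude_c" %in% fit$interactions) {
    i <- grep("x:latitude_c", fit$coefficients$term)
    expect_lt(fit$coefficients$estimate[i], 0)
  }
  ## environmental moderators entered the design
  expect_true(all(c("substrate_type", "depth_zone", "season", "latitude_c")
                  %in% names(fit$frame)))
})

test_that("a single-level environmental moderator is dropped, not fatal", {
  g <- suite_groups
  g$depth_zone <- "low_intertidal"
  suite <- run_environment_suite(g, "facet_models")
  fit <- suite$fits[[1]]
  expect_true("depth_zone" %in% fit$dropped_terms)
})

test_that("suites are deterministic and strata are independent", {
  s1 <- run_facet_suite(suite_groups, "richness")
  s2 <- run_facet_suite(suite_groups, "richness")
  expect_identical(comparison_table(s1), comparison_table(s2))
  ## perturbing one stratum leaves the others untouched
  g2 <- suite_groups
  sel <- g2$facet == "feature_size"
  g2$lnrr[sel] <- g2$lnrr[sel] + 0.5 * g2$het01[sel]
  s3 <- run_facet_suite(g2, "richness")
  t1 <- comparison_table(s1)
  t3 <- comparison_table(s3)
  other <- t1$stratum != "feature_size"
  expect_equal(as.data.frame(t3[other, ]), as.data.frame(t1[other, ]))
})
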