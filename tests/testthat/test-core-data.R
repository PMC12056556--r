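test_that("a well-formed CSV yields one observation per row", {
  obs_in <- make_obs(12, het_raw = as.character(rep(1:4, 3)))
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(obs_in, path)
  obs <- read_hdr_dataset(path)
  expect_s3_class(obs, "hdr_observations")
  expect_equal(nrow(obs), 12)
  rep <- validation_report(obs)
  expect_equal(rep$n_read, 12)
  expect_equal(nrow(rep$rejected), 0)
})

test_that("a missing required column is a configuration error naming it", {
  obs_in <- make_obs(3)
  obs_in$response_value <- NULL
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(obs_in, path)
  expect_error(read_hdr_dataset(path), "response_value",
               class = "hdr_config_error")
})

test_that("an empty file is a data error", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(make_obs(1)[0, ], path)
  expect_error(read_hdr_dataset(path), class = "hdr_data_error")
})

test_that("invalid rows are rejected with row numbers and reasons", {
  obs_in <- make_obs(5, het_raw = as.character(1:5))
  obs_in$response_value[2] <- -1
  obs_in$latitude_abs[4] <- 120
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(obs_in, path)
  obs <- read_hdr_dataset(path)
  rep <- validation_report(obs)
  expect_equal(nrow(obs), 3)
  expect_setequal(rep$rejected$row, c(2, 4))
  expect_match(rep$rejected$reason[rep$rejected$row == 2], "negative")
  expect_match(rep$rejected$reason[rep$rejected$row == 4], "latitude")
})

test_that("schema remapping resolves alternative column headers", {
  obs_in <- make_obs(3)
  names(obs_in)[names(obs_in) == "response_value"] <- "Response"
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(obs_in, path)
  expect_error(read_hdr_dataset(path), class = "hdr_config_error")
  obs <- read_hdr_dataset(path, hdr_schema(response_value = "Response"))
  expect_equal(nrow(obs), 3)
  expect_error(hdr_schema(not_a_field = "x"), class = "hdr_config_error")
})

test_that("grouping keys on study context: 2 sites x 2 dates give 4 groups", {
  obs <- as_hdr_observations(dplyr::bind_rows(lapply(1:4, function(i) {
    make_obs(4, site = paste0("site", (i - 1) %/% 2 + 1),
             date = paste0("2020-0", (i - 1) %% 2 + 1, "-01"),
             plot_id = paste0("P", i, "_", 1:4),
             het_raw = as.character(1:4))
  })))
  g <- build_hdr_groups(obs)
  expect_equal(length(unique(g$hdr_id)), 4)
  expect_true(all(g$collapse_level == 0))
})

test_that("the extension rule merges across sites, then dates, then substrates", {
  ## 2 obs at each of two sites: below min_replicates, so site collapses
  obs <- as_hdr_observations(dplyr::bind_rows(
    make_obs(2, site = "siteA", plot_id = c("P1", "P2"),
             het_raw = c("1", "2")),
    make_obs(2, site = "siteB", plot_id = c("P3", "P4"),
             het_raw = c("3", "4"))
  ))
  g <- build_hdr_groups(obs)
  expect_equal(length(unique(g$hdr_id)), 1)
  expect_equal(nrow(g), 4)
  expect_true(all(g$collapse_level == 1))

  ## 1 obs per site x date cell: needs site and date collapsed
  obs2 <- as_hdr_observations(dplyr::bind_rows(lapply(1:4, function(i) {
    make_obs(1, site = paste0("s", i %% 2), date = paste0("2020-0", i, "-01"),
             plot_id = paste0("Q", i), het_raw = as.character(i))
  })))
  g2 <- build_hdr_groups(obs2)
  expect_equal(length(unique(g2$hdr_id)), 1)
  expect_equal(unique(g2$collapse_level), 2)
})

test_that("groups below min_replicates after full collapse are unusable", {
  obs <- as_hdr_observations(make_obs(2, het_raw = c("1", "2")))
  g <- build_hdr_groups(obs, min_replicates = 3)
  expect_equal(nrow(g), 0)
  expect_match(grouping_report(g)$dropped$reason, "insufficient replicates")
})

test_that("single-heterogeneity-level groups are dropped with a reason", {
  obs <- as_hdr_observations(make_obs(4, het_raw = rep("7", 4)))
  g <- build_hdr_groups(obs)
  expect_equal(nrow(g), 0)
  expect_match(grouping_report(g)$dropped$reason, "single level")
})

test_that("grouping partitions retained observations and is order-invariant", {
  obs <- simulate_hdr_dataset(simulation_scenario(
    seed = 21, n_studies = 6, hdrs_per_study = 3, levels_per_hdr = 4,
    reps_per_level = 3))
  g <- build_hdr_groups(obs)
  ## partition: every retained obs in exactly one group; counts add up
  expect_equal(nrow(g) + sum(grouping_report(g)$dropped$n), nrow(obs))
  expect_false(any(duplicated(g$plot_id)))
  ## permuting input rows yields the identical grouping
  set.seed(99)
  perm <- obs[sample(nrow(obs)), ]
  attr(perm, "class") <- class(obs)
  g2 <- build_hdr_groups(perm)
  expect_equal(as.data.frame(g2), as.data.frame(g))
})
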