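#' Run commands: simulate, fit, recover
#'
#' Programmatic equivalents of the command-line entry points (a thin optparse
#' wrapper lives at `inst/scripts/hdr_cli.R`; see
#' `system.file("scripts", "hdr_cli.R", package = "hdrsynth")`). Every run
#' writes a manifest (config hash, input checksums, package version) so
#' deterministic outputs can be reproduced bit-for-bit from the archived
#' config, inputs and seed.
#'
#' `simulate_run()` writes the synthetic dataset CSV and its truth sidecar;
#' `fit_run()` ingests a dataset, runs the pipeline and the requested suites
#' (optionally under sensitivity exclusion rules) and writes one comparison
#' CSV per suite plus a combined long table and a run log; `recover_run()`
#' writes the parameter-recovery report and a PASS/FAIL verdict against the
#' configured tolerances.
#'
#' @param scenario An [simulation_scenario()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths of the written files.
#' @name run_commands
NULL

write_manifest <- function(out_dir, config, inputs = character()) {
  manifest <- list(
    package = "hdrsynth",
    version = as.character(packageVersion("hdrsynth")),
    config_hash = rlang::hash(config),
    inputs = as.list(tools::md5sum(inputs))
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  path
}

#' @rdname run_commands
#' @export
simulate_run <- function(scenario, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    abort(paste0("cannot create output directory: ", out_dir),
          class = "hdr_io_error")
  }
  obs <- simulate_hdr_dataset(scenario)
  data_path <- file.path(out_dir, "dataset.csv")
  readr::write_csv(tibble::as_tibble(obs), data_path)
  truth <- simulation_truth(obs)
  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(list(
    scenario = unclass(truth$scenario),
    studies = truth$studies,
    hdrs = truth$hdrs
  ), truth_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- write_manifest(out_dir, unclass(scenario), data_path)
  message(sprintf("simulate: wrote %d observations to %s", nrow(obs),
                  data_path))
  invisible(c(dataset = data_path, truth = truth_path, manifest = manifest))
}

#' @rdname run_commands
#' @param config A run configuration list (or path to a YAML file) with
#'   entries `input` (dataset CSV), optional `schema` (named overrides for
#'   [hdr_schema()]), `suites` (character vector among `facet_richness`,
#'   `facet_abundance`, `organismal_groups`, `processes`,
#'   `environment_facets`, `environment_groups`), `alpha`,
#'   `min_replicates`, and `exclusions` (names of [exclusion_rules()] to run
#'   as sensitivity re-runs).
#' @export
fit_run <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  if (is.null(config$input)) hdr_config_error("config$input is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  alpha <- config$alpha %||% 0.05
  log_lines <- character()
  logit <- function(...) log_lines <<- c(log_lines, sprintf(...))

  schema <- do.call(hdr_schema, as.list(config$schema %||% list()))
  obs <- read_hdr_dataset(config$input, schema)
  rep <- validation_report(obs)
  logit("ingest: %d rows read, %d valid, %d rejected", rep$n_read, rep$n_ok,
        nrow(rep$rejected))
  write_validation_report(obs, out_dir)

  groups <- prepare_hdr_data(obs, min_replicates = config$min_replicates %||% 3)
  logit("pipeline: %d observations in %d HDR groups across %d studies",
        nrow(groups), length(unique(groups$hdr_id)),
        length(unique(groups$study_id)))
  for (l in c(attr(groups, "log"), attr(groups, "standardize_log"),
              attr(groups, "lnrr_log"))) {
    logit("pipeline: %s", l)
  }

  suite_names <- config$suites %||% c("facet_richness", "organismal_groups")
  runners <- list(
    facet_richness = function(g) run_facet_suite(g, "richness", alpha = alpha),
    facet_abundance = function(g) run_facet_suite(g, "abundance",
                                                  alpha = alpha),
    organismal_groups = function(g) run_group_suite(g, alpha = alpha),
    processes = function(g) run_process_suite(g, alpha = alpha),
    environment_facets = function(g) {
      run_environment_suite(g, "facet_models", alpha = alpha)
    },
    environment_groups = function(g) {
      run_environment_suite(g, "group_models", alpha = alpha)
    }
  )
  bad <- setdiff(suite_names, names(runners))
  if (length(bad)) {
    hdr_config_error(paste0("unknown suite(s): ", paste(bad, collapse = ", ")))
  }

  results <- list()
  combined <- list()
  for (sn in suite_names) {
    res <- runners[[sn]](groups)
    results[[sn]] <- res
    tab <- comparison_table(res)
    readr::write_csv(tab, file.path(out_dir, paste0("suite_", sn, ".csv")))
    if (nrow(tab)) combined[[sn]] <- dplyr::mutate(tab, suite = sn,
                                                   .before = 1)
    logit("suite %s: %d fits, %d skipped", sn, length(res$fits),
          nrow(res$skipped))
    for (k in seq_len(nrow(res$skipped))) {
      logit("suite %s: stratum %s skipped (%s)", sn, res$skipped$stratum[k],
            res$skipped$reason[k])
    }
  }
  readr::write_csv(dplyr::bind_rows(combined),
                   file.path(out_dir, "suites_combined.csv"))

  if (length(config$exclusions)) {
    rules <- exclusion_rules()[unlist(config$exclusions)]
    if (any(vapply(rules, is.null, logical(1)))) {
      hdr_config_error("unknown exclusion rule in config$exclusions")
    }
    sens <- run_exclusion_suite(groups, runners[[suite_names[1]]],
                                rules = rules, alpha = alpha)
    readr::write_csv(sens$delta, file.path(out_dir, "sensitivity_delta.csv"))
    logit("sensitivity: %d rules re-run against suite %s", length(rules),
          suite_names[1])
    results$sensitivity <- sens
  }

  writeLines(log_lines, file.path(out_dir, "run.log"))
  write_manifest(out_dir, config, config$input)
  invisible(results)
}

#' @rdname run_commands
#' @param n_reps,seed Replication control for the recovery study.
#' @param tolerances List with `max_abs_bias` and `coverage_range` for the
#'   PASS/FAIL verdict.
#' @export
recover_run <- function(scenario, out_dir, n_reps = 200, seed = 1,
                        tolerances = list(max_abs_bias = 0.05,
                                          coverage_range = c(0.90, 0.98))) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rec <- recover_parameters(scenario, n_reps = n_reps, seed = seed)
  readr::write_csv(rec$replicates, file.path(out_dir,
                                             "recovery_replicates.csv"))
  readr::write_csv(rec$summary, file.path(out_dir, "recovery_summary.csv"))
  b1 <- rec$summary[rec$summary$term == "x", ]
  pass <- abs(b1$bias) <= tolerances$max_abs_bias &&
    b1$coverage >= tolerances$coverage_range[1] &&
    b1$coverage <= tolerances$coverage_range[2]
  verdict <- if (pass) "PASS" else "FAIL"
  writeLines(c(
    sprintf("bias(beta1) = %.5f (|tolerance| %.3f)", b1$bias,
            tolerances$max_abs_bias),
    sprintf("coverage(beta1) = %.3f (range %.2f-%.2f)", b1$coverage,
            tolerances$coverage_range[1], tolerances$coverage_range[2]),
    verdict
  ), file.path(out_dir, "recovery_verdict.txt"))
  write_manifest(out_dir, list(scenario = unclass(scenario), n_reps = n_reps,
                               seed = seed, tolerances = tolerances))
  invisible(structure(list(recovery = rec, pass = pass), class = "hdr_recover_run"))
}

#' Read a YAML run configuration
#'
#' @param path YAML file.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    hdr_config_error(paste0("config file does not exist: ", path))
  }
  cfg <- tryCatch(yaml::read_yaml(path), error = function(e) {
    hdr_config_error(paste0("malformed config file ", path, ": ",
                            conditionMessage(e)))
  })
  if (!is.list(cfg)) hdr_config_error("config must be a YAML mapping")
  cfg
}
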