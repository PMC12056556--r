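## Fixture builders shared across test files. Everything is generated in
## code; no data files.

## A minimal valid observation row; override any field via ...
make_obs <- function(n = 1, ...) {
  base <- tibble::tibble(
    study_id = "S1", plot_id = paste0("P", seq_len(n)), site = "siteA",
    date = "2020-01-01", substrate_context = "ctx1",
    het_raw = as.character(seq_len(n)), het_metric = "rugosity",
    facet = "substrate_3d_amount", response_value = 1,
    response_metric = "richness", organismal_group = "microinvertebrates",
    latitude_abs = 45, depth_zone = "low_intertidal", season = "summer",
    substrate_type = "rock", n_species = 5, sample_size = 3,
    pub_year = 2010, is_discrete_het = FALSE, design_flags = ""
  )
  overrides <- list(...)
  for (nm in names(overrides)) base[[nm]] <- overrides[[nm]]
  base
}

## A small analysis-ready groups table built through the real pipeline
small_groups <- function(seed = 1, n_studies = 8, hdrs_per_study = 2,
                         levels_per_hdr = 5, reps_per_level = 3, ...) {
  sc <- simulation_scenario(seed = seed, n_studies = n_studies,
                            hdrs_per_study = hdrs_per_study,
                            levels_per_hdr = levels_per_hdr,
                            reps_per_level = reps_per_level, ...)
  prepare_hdr_data(simulate_hdr_dataset(sc))
}

## Subset a groups tibble while keeping its class/attributes
filter_groups <- function(groups, keep) {
  out <- groups[keep, , drop = FALSE]
  attr(out, "class") <- class(groups)
  out
}

expect_tibble_equal <- function(a, b, tol = 1e-12) {
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = tol)
}

## column content only, ignoring bookkeeping attributes
strip_attrs <- function(d) {
  out <- as.data.frame(d)
  for (a in setdiff(names(attributes(out)), c("names", "row.names", "class"))) {
    attr(out, a) <- NULL
  }
  rownames(out) <- NULL
  out
}
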