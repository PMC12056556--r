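#' Default column schema for observation tables
#'
#' Maps the canonical observation fields used throughout the package to the
#' column names of an input CSV. Override entries to adapt to a file whose
#' headers differ, e.g. `hdr_schema(study_id = "StudyID")`.
#'
#' @param ... Named overrides, `canonical_field = "file_column"`.
#' @return A named character vector (canonical field -> file column).
#' @export
#' @examples
#' hdr_schema(study_id = "Study", response_value = "Response")
hdr_schema <- function(...) {
  schema <- c(
    study_id = "study_id", plot_id = "plot_id", site = "site", date = "date",
    substrate_context = "substrate_context", het_raw = "het_raw",
    het_metric = "het_metric", facet = "facet",
    response_value = "response_value", response_metric = "response_metric",
    organismal_group = "organismal_group", latitude_abs = "latitude_abs",
    depth_zone = "depth_zone", season = "season",
    substrate_type = "substrate_type", n_species = "n_species",
    sample_size = "sample_size", pub_year = "pub_year",
    is_discrete_het = "is_discrete_het", design_flags = "design_flags"
  )
  overrides <- c(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(schema))
    if (length(bad)) {
      hdr_config_error(paste0("Unknown schema field(s): ",
                              paste(bad, collapse = ", ")))
    }
    schema[names(overrides)] <- overrides
  }
  schema
}

## Fields that must be present and non-missing in every row; the remainder
## are optional (environmental context may be incomplete, see build_design).
.required_fields <- c("study_id", "plot_id", "site", "date",
                      "substrate_context", "het_raw", "facet",
                      "response_value", "response_metric", "organismal_group")
.optional_fields <- c("het_metric", "latitude_abs", "depth_zone", "season",
                      "substrate_type", "n_species", "sample_size",
                      "pub_year", "is_discrete_het", "design_flags")

#' Read and validate an observation table
#'
#' Reads a CSV of per-observation study data, renames columns to the canonical
#' field names via `schema`, coerces types, and validates each row against the
#' field invariants (non-negative responses, latitude within 0-90, categorical
#' fields within their controlled vocabularies, numeric heterogeneity unless
#' the row is flagged discrete). Rows failing validation are removed and
#' reported, with row numbers, in the attached validation report.
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @param schema Column mapping from [hdr_schema()].
#' @return A tibble of validated observations (class `hdr_observations`) with
#'   a `report` attribute: `list(n_read, n_ok, rejected)` where `rejected` is a
#'   tibble of `row`/`reason` pairs. Retrieve it with [validation_report()].
#' @export
read_hdr_dataset <- function(path, schema = hdr_schema()) {
  if (!file.exists(path)) {
    hdr_config_error(paste0("Input file does not exist: ", path))
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (nrow(raw) == 0L) hdr_data_error("Input file contains no data rows.")

  required_cols <- schema[.required_fields]
  missing_cols <- required_cols[!required_cols %in% names(raw)]
  if (length(missing_cols)) {
    hdr_config_error(paste0(
      "Required column(s) missing from ", path, ": ",
      paste(missing_cols, collapse = ", ")))
  }
  present <- schema[schema %in% names(raw)]
  obs <- raw[, unname(present), drop = FALSE]
  names(obs) <- names(present)
  for (f in setdiff(c(.required_fields, .optional_fields), names(obs))) {
    obs[[f]] <- NA_character_
  }
  as_hdr_observations(obs, n_read = nrow(raw))
}

#' Validate a raw observation table already in memory
#'
#' Applies the same coercion and row-level validation as [read_hdr_dataset()]
#' to a data frame using canonical column names.
#'
#' @param obs Data frame with canonical columns (character or typed).
#' @param n_read Number of input rows, for the report.
#' @return Validated `hdr_observations` tibble.
#' @export
as_hdr_observations <- function(obs, n_read = nrow(obs)) {
  obs <- tibble::as_tibble(obs)
  lv <- hdr_levels()
  n <- nrow(obs)
  reasons <- vector("list", n)
  add_reason <- function(bad, why) {
    idx <- which(bad)
    for (i in idx) reasons[[i]] <<- c(reasons[[i]], why)
  }
  num <- function(x) suppressWarnings(as.numeric(as.character(x)))

  obs$response_value <- num(obs$response_value)
  add_reason(is.na(obs$response_value), "response_value not numeric")
  add_reason(!is.na(obs$response_value) & obs$response_value < 0,
             "response_value negative")

  obs$is_discrete_het <- tolower(as.character(obs$is_discrete_het)) %in%
    c("true", "t", "1", "yes")
  obs$het_raw <- as.character(obs$het_raw)
  het_num <- num(obs$het_raw)
  add_reason(!obs$is_discrete_het & is.na(het_num),
             "het_raw not numeric for continuous heterogeneity")
  add_reason(is.na(obs$het_raw) | obs$het_raw == "", "het_raw missing")

  check_enum <- function(field, levels, required = FALSE) {
    x <- as.character(obs[[field]])
    bad <- !is.na(x) & !(x %in% levels)
    add_reason(bad, paste0(field, " outside vocabulary"))
    if (required) add_reason(is.na(x), paste0(field, " missing"))
    x[bad] <- NA_character_
    obs[[field]] <<- x
  }
  check_enum("facet", lv$facet, required = TRUE)
  check_enum("response_metric", lv$response_metric, required = TRUE)
  check_enum("organismal_group", lv$organismal_group, required = TRUE)
  check_enum("depth_zone", lv$depth_zone)
  check_enum("season", lv$season)
  check_enum("substrate_type", lv$substrate_type)

  obs$latitude_abs <- num(obs$latitude_abs)
  add_reason(!is.na(obs$latitude_abs) &
               (obs$latitude_abs < 0 | obs$latitude_abs > 90),
             "latitude_abs outside [0, 90]")

  for (f in c("n_species", "sample_size", "pub_year")) obs[[f]] <- num(obs[[f]])
  add_reason(!is.na(obs$n_species) &
               (obs$n_species < 1 | obs$n_species %% 1 != 0),
             "n_species not a positive integer")
  for (f in c("study_id", "plot_id", "site", "date", "substrate_context")) {
    obs[[f]] <- as.character(obs[[f]])
    add_reason(is.na(obs[[f]]) | obs[[f]] == "", paste0(f, " missing"))
  }
  obs$het_metric <- as.character(obs$het_metric)
  obs$design_flags <- as.character(obs$design_flags)
  obs$design_flags[is.na(obs$design_flags)] <- ""

  bad_rows <- which(!vapply(reasons, is.null, logical(1)))
  rejected <- tibble::tibble(
    row = bad_rows,
    reason = vapply(reasons[bad_rows], paste, character(1), collapse = "; ")
  )
  keep <- obs[setdiff(seq_len(n), bad_rows), , drop = FALSE]
  structure(keep,
            class = c("hdr_observations", class(keep)),
            report = list(n_read = n_read, n_ok = nrow(keep),
                          rejected = rejected))
}

#' Retrieve the validation report attached to an observation table
#'
#' @param obs An `hdr_observations` tibble from [read_hdr_dataset()].
#' @return `list(n_read, n_ok, rejected)`.
#' @export
validation_report <- function(obs) {
  attr(obs, "report") %||%
    list(n_read = nrow(obs), n_ok = nrow(obs),
         rejected = tibble::tibble(row = integer(), reason = character()))
}

#' Write a validation report to disk
#'
#' Writes the plain-text log and the machine-readable CSV of rejected rows.
#'
#' @param obs Validated observations.
#' @param dir Output directory (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
write_validation_report <- function(obs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rep <- validation_report(obs)
  log_path <- file.path(dir, "validation.log")
  csv_path <- file.path(dir, "rejected_rows.csv")
  writeLines(c(
    sprintf("rows read: %d", rep$n_read),
    sprintf("rows valid: %d", rep$n_ok),
    sprintf("rows rejected: %d", nrow(rep$rejected))
  ), log_path)
  readr::write_csv(rep$rejected, csv_path)
  invisible(c(log = log_path, rejected = csv_path))
}
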