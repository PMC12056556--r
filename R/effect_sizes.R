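#' Per-observation log response ratio against the lowest-heterogeneity
#' baseline
#'
#' The effect size of observation i in an HDR group is
#' `lnRR_i = ln(y_i / mean(min(y)))`, where `mean(min(y))` is the mean
#' response over all observations at the group's lowest standardised
#' heterogeneity level. For discrete descriptors the baseline is the treatment
#' with the lowest heterogeneity; when several raw levels tie at the minimum
#' after mapping, all tied observations form the baseline set.
#'
#' @param response_value Non-negative responses, one per observation.
#' @param het01 Standardised heterogeneity in [0, 1], same length.
#' @return A list of class `hdr_effect_sizes`: `lnrr` (NA where the
#'   observation had response 0 and was excluded), `baseline_mean`,
#'   `baseline_level` (the het01 value of the baseline), and `n_zero_excluded`.
#' @export
#' @examples
#' compute_lnrr(c(2, 4, 8), c(0, 0.5, 1))
compute_lnrr <- function(response_value, het01) {
  response_value <- as.numeric(response_value)
  het01 <- as.numeric(het01)
  if (length(response_value) != length(het01)) {
    hdr_config_error("response_value and het01 lengths differ")
  }
  if (any(response_value < 0, na.rm = TRUE)) {
    hdr_data_error("negative response values are invalid")
  }
  base_lev <- min(het01)
  at_base <- het01 == base_lev
  baseline_mean <- mean(response_value[at_base])
  if (baseline_mean == 0) {
    abort("baseline undefined: mean response at lowest heterogeneity is zero",
          class = c("hdr_baseline_error", "hdr_data_error"))
  }
  lnrr <- ifelse(response_value == 0, NA_real_,
                 log(response_value / baseline_mean))
  structure(list(lnrr = lnrr, baseline_mean = baseline_mean,
                 baseline_level = base_lev,
                 n_zero_excluded = sum(response_value == 0)),
            class = "hdr_effect_sizes")
}

#' Attach lnRR effect sizes to every HDR group
#'
#' Applies [compute_lnrr()] within each group of a standardised `hdr_groups`
#' table. Observations with response 0 are excluded (no offset constant is
#' invented) and counted in the log; groups whose baseline mean is zero are
#' dropped and logged.
#'
#' @param groups Standardised groups from [standardize_hdr()].
#' @return Groups with columns `lnrr` and `baseline_mean`; zero-response rows
#'   removed; attribute `lnrr_log` records exclusions and drops.
#' @export
add_lnrr <- function(groups) {
  if (!"het01" %in% names(groups)) {
    hdr_config_error("groups must be standardised first (het01 missing)")
  }
  logs <- character()
  groups$lnrr <- NA_real_
  groups$baseline_mean <- NA_real_
  keep <- rep(TRUE, nrow(groups))
  for (g in unique(groups$hdr_id)) {
    i <- which(groups$hdr_id == g)
    es <- tryCatch(compute_lnrr(groups$response_value[i], groups$het01[i]),
                   hdr_baseline_error = function(e) NULL)
    if (is.null(es)) {
      keep[i] <- FALSE
      logs <- c(logs, sprintf("group %s dropped: zero baseline mean", g))
      next
    }
    groups$lnrr[i] <- es$lnrr
    groups$baseline_mean[i] <- es$baseline_mean
    if (es$n_zero_excluded > 0) {
      keep[i][is.na(es$lnrr)] <- FALSE
      logs <- c(logs, sprintf("group %s: %d zero-response obs excluded",
                              g, es$n_zero_excluded))
    }
  }
  out <- restore_groups(groups[keep, , drop = FALSE], groups)
  attr(out, "lnrr_log") <- logs
  out
}

#' Run the full data-preparation pipeline
#'
#' Convenience wrapper: [build_hdr_groups()] then [standardize_hdr()] then
#' [add_lnrr()].
#'
#' @param obs Validated observations.
#' @param min_replicates Passed to [build_hdr_groups()].
#' @param discrete_orderings Passed to [standardize_hdr()].
#' @return Analysis-ready `hdr_groups` with `het01`, `het_cv`, `lnrr`.
#' @export
prepare_hdr_data <- function(obs, min_replicates = 3,
                             discrete_orderings = list()) {
  groups <- build_hdr_groups(obs, min_replicates = min_replicates)
  groups <- standardize_hdr(groups, discrete_orderings = discrete_orderings)
  add_lnrr(groups)
}

#' Export effect sizes as a tidy table
#'
#' @param groups Groups carrying `lnrr`.
#' @param path Optional CSV path; when supplied the table is written there.
#' @return Tibble with `hdr_id`, observation index, `het01`, `lnrr`.
#' @export
export_lnrr <- function(groups, path = NULL) {
  out <- tibble::tibble(
    hdr_id = groups$hdr_id,
    obs = stats::ave(seq_len(nrow(groups)), groups$hdr_id,
                     FUN = seq_along),
    het01 = groups$het01,
    lnrr = groups$lnrr
  )
  if (!is.null(path)) readr::write_csv(out, path)
  out
}
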