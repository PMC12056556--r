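#' Standardise a continuous heterogeneity gradient to [0, 1]
#'
#' z-transforms the raw values ((x - mean) / sd, sample sd) and then maps the
#' z-scores onto the 0-1 range by min-max scaling. Because z-scoring is an
#' affine map, the composition is identical to plain min-max normalisation;
#' the two-step form mirrors the published transformation and the identity is
#' asserted in the test suite.
#'
#' @param het_raw Numeric vector with at least two distinct values.
#' @return Numeric vector in [0, 1] with min 0 and max 1.
#' @export
#' @examples
#' transform_continuous(c(10, 20, 30))
transform_continuous <- function(het_raw) {
  het_raw <- as.numeric(het_raw)
  if (anyNA(het_raw)) hdr_data_error("het_raw contains missing values")
  if (length(unique(het_raw)) < 2L) {
    hdr_degenerate_error("degenerate gradient: zero variance in het_raw")
  }
  z <- (het_raw - mean(het_raw)) / sd(het_raw)
  (z - min(z)) / (max(z) - min(z))
}

#' Map ordered discrete heterogeneity levels to [0, 1]
#'
#' Level i of k (in the author-supplied ordering) maps to (i - 1) / (k - 1),
#' so a two-level descriptor becomes {0, 1} and a three-level descriptor
#' {0, 0.5, 1}. All observations at a level receive the same value.
#'
#' @param levels Character vector of observed level labels.
#' @param ordering Ordered unique labels, lowest heterogeneity first. Defaults
#'   to the sorted unique labels; supply explicitly whenever alphabetical
#'   order is not the ordinal order.
#' @return Numeric vector in [0, 1].
#' @export
#' @examples
#' transform_discrete(c("absent", "present", "present"),
#'                    ordering = c("absent", "present"))
transform_discrete <- function(levels, ordering = NULL) {
  levels <- as.character(levels)
  if (is.null(ordering)) ordering <- sort(unique(levels))
  ordering <- unique(as.character(ordering))
  if (length(ordering) < 2L) {
    hdr_degenerate_error("degenerate gradient: fewer than 2 discrete levels")
  }
  idx <- match(levels, ordering)
  if (anyNA(idx)) {
    hdr_config_error(paste0(
      "Unknown discrete level(s): ",
      paste(unique(levels[is.na(idx)]), collapse = ", ")))
  }
  (idx - 1) / (length(ordering) - 1)
}

#' Coefficient of variation of the raw heterogeneity values
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean, computed
#' on the raw values in their original units. Used as a covariate capturing
#' the breadth of the heterogeneity gradient relative to its magnitude.
#'
#' @param het_raw Numeric vector with positive mean.
#' @return Non-negative scalar.
#' @export
#' @examples
#' compute_cv(c(10, 20, 30))  # 0.5
compute_cv <- function(het_raw) {
  het_raw <- as.numeric(het_raw)
  if (anyNA(het_raw)) hdr_data_error("het_raw contains missing values")
  m <- mean(het_raw)
  if (m <= 0) {
    abort("undefined CV: mean of het_raw is not positive",
          class = c("hdr_cv_error", "hdr_data_error"))
  }
  sd(het_raw) / m
}

#' Standardise heterogeneity within every HDR group
#'
#' Adds to each group the 0-1 standardised gradient (`het01`) and the
#' raw-unit coefficient of variation (`het_cv`). Continuous gradients use
#' [transform_continuous()] and compute the CV on the raw units; discrete
#' descriptors use [transform_discrete()] and, lacking raw units, compute the
#' CV on the mapped 0-1 values with `het_cv_on_mapped = TRUE`. Groups whose
#' gradient degenerates (zero variance) are dropped and logged; groups whose
#' raw mean is non-positive keep `het_cv = NA` and are logged.
#'
#' @param groups An `hdr_groups` tibble from [build_hdr_groups()].
#' @param discrete_orderings Optional named list: `hdr_id` (or study_id) ->
#'   character vector giving the ordinal ordering of that unit's discrete
#'   levels. Defaults to sorted labels.
#' @return The groups with `het01`, `het_cv`, `het_cv_on_mapped` columns;
#'   attribute `standardize_log` records drops and missing CVs.
#' @export
standardize_hdr <- function(groups, discrete_orderings = list()) {
  logs <- character()
  groups$het01 <- NA_real_
  groups$het_cv <- NA_real_
  groups$het_cv_on_mapped <- FALSE
  keep <- rep(TRUE, nrow(groups))
  for (g in unique(groups$hdr_id)) {
    i <- which(groups$hdr_id == g)
    discrete <- any(groups$is_discrete_het[i])
    res <- tryCatch({
      if (discrete) {
        ordering <- discrete_orderings[[g]] %||%
          discrete_orderings[[groups$study_id[i][1]]]
        h01 <- transform_discrete(groups$het_raw[i], ordering)
        cv <- compute_cv(h01)
        list(het01 = h01, cv = cv, mapped = TRUE)
      } else {
        raw <- as.numeric(groups$het_raw[i])
        h01 <- transform_continuous(raw)
        cv <- tryCatch(compute_cv(raw), hdr_cv_error = function(e) {
          logs <<- c(logs, sprintf("group %s: CV undefined (mean <= 0)", g))
          NA_real_
        })
        list(het01 = h01, cv = cv, mapped = FALSE)
      }
    }, hdr_degenerate_error = function(e) {
      logs <<- c(logs, sprintf("group %s dropped: %s", g, conditionMessage(e)))
      NULL
    })
    if (is.null(res)) {
      keep[i] <- FALSE
    } else {
      groups$het01[i] <- res$het01
      groups$het_cv[i] <- res$cv
      groups$het_cv_on_mapped[i] <- res$mapped
    }
  }
  out <- restore_groups(groups[keep, , drop = FALSE], groups)
  attr(out, "standardize_log") <- logs
  out
}
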