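#' Aggregate observations into HDR groups
#'
#' An HDR group is the within-study unit over which a heterogeneity gradient
#' is standardised and the lnRR baseline is computed. Observations are grouped
#' by study, heterogeneity facet, response metric, organismal group, and the
#' site/date/substrate context in which they were collected. When that full
#' key leaves any cell of a study stratum below `min_replicates`, the grouping
#' is extended: site is collapsed first, then date, then substrate context,
#' until every cell reaches `min_replicates` or the stratum is flagged
#' unusable. Groups whose observations span fewer than two distinct
#' heterogeneity levels cannot define a gradient and are dropped.
#'
#' @param obs Validated observations ([read_hdr_dataset()] /
#'   [as_hdr_observations()]).
#' @param min_replicates Minimum observations per group before the extension
#'   rule fires (default 3).
#' @return A tibble of class `hdr_groups`: the retained observations with an
#'   `hdr_id` column and a `collapse_level` column (0 = full key, 1 = site
#'   collapsed, 2 = site+date, 3 = site+date+substrate). Attribute `dropped`
#'   is a tibble of dropped units with reasons; attribute `log` a character
#'   vector.
#' @export
build_hdr_groups <- function(obs, min_replicates = 3) {
  if (min_replicates < 1) hdr_config_error("min_replicates must be >= 1")
  obs <- tibble::as_tibble(obs)
  stratum_key <- c("study_id", "facet", "response_metric", "organismal_group")
  group_keys <- list(
    c("site", "date", "substrate_context"),  # level 0: full key
    c("date", "substrate_context"),          # level 1: site collapsed
    "substrate_context",                     # level 2: + date collapsed
    character(0)                             # level 3: study stratum pooled
  )

  ## deterministic regardless of input row order
  ord <- do.call(order, c(obs[c(stratum_key, "site", "date",
                                "substrate_context", "het_raw", "plot_id")],
                          list(method = "radix")))
  obs <- obs[ord, , drop = FALSE]

  stratum_id <- do.call(paste, c(obs[stratum_key], sep = "|"))
  pieces <- split(seq_len(nrow(obs)), stratum_id)

  dropped <- list()
  logs <- character()
  out <- vector("list", length(pieces))
  for (k in seq_along(pieces)) {
    idx <- pieces[[k]]
    sub <- obs[idx, , drop = FALSE]
    lvl <- NA_integer_
    for (L in seq_along(group_keys)) {
      keys <- group_keys[[L]]
      gid <- if (length(keys)) do.call(paste, c(sub[keys], sep = "|")) else
        rep("all", nrow(sub))
      if (min(table(gid)) >= min_replicates) { lvl <- L - 1L; break }
    }
    if (is.na(lvl)) {
      dropped[[length(dropped) + 1L]] <- tibble::tibble(
        unit = names(pieces)[k], n = nrow(sub),
        reason = "insufficient replicates after full collapse")
      logs <- c(logs, sprintf(
        "stratum %s unusable: %d obs < min_replicates after collapsing",
        names(pieces)[k], nrow(sub)))
      next
    }
    keys <- group_keys[[lvl + 1L]]
    gid <- if (length(keys)) do.call(paste, c(sub[keys], sep = "|")) else
      rep("all", nrow(sub))
    sub$hdr_id <- paste(names(pieces)[k], gid, sep = "|")
    sub$collapse_level <- lvl
    if (lvl > 0L) {
      logs <- c(logs, sprintf("stratum %s: grouping extended (level %d)",
                              names(pieces)[k], lvl))
    }
    ## a gradient needs >= 2 distinct heterogeneity levels
    for (g in unique(sub$hdr_id)) {
      lev <- unique(sub$het_raw[sub$hdr_id == g])
      if (length(lev) < 2L) {
        dropped[[length(dropped) + 1L]] <- tibble::tibble(
          unit = g, n = sum(sub$hdr_id == g), reason = "single level")
        logs <- c(logs, sprintf("group %s dropped: single level", g))
        sub <- sub[sub$hdr_id != g, , drop = FALSE]
      }
    }
    out[[k]] <- sub
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) {
    res <- obs[0, , drop = FALSE]
    res$hdr_id <- character()
    res$collapse_level <- integer()
  }
  res <- res[order(res$hdr_id, res$het_raw, res$plot_id, method = "radix"), ]
  dropped <- if (length(dropped)) dplyr::bind_rows(dropped) else
    tibble::tibble(unit = character(), n = integer(), reason = character())
  structure(res, class = c("hdr_groups", class(tibble::tibble())),
            dropped = dropped, log = logs)
}

#' Dropped units and log from a grouping
#'
#' @param groups An `hdr_groups` tibble.
#' @return `list(dropped, log)`.
#' @export
grouping_report <- function(groups) {
  list(dropped = attr(groups, "dropped"), log = attr(groups, "log"))
}

## keep hdr_groups attributes through dplyr-style subsetting used internally
restore_groups <- function(new, old) {
  structure(tibble::as_tibble(new),
            class = class(old),
            dropped = attr(old, "dropped"),
            log = attr(old, "log"))
}
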