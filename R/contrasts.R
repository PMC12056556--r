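#' Pairwise contrasts of a factor moderator
#'
#' All pairwise Wald contrasts of the factor's level effects evaluated at the
#' mean of the standardised gradient (and the means of other covariates),
#' with Holm-adjusted p-values, plus a compact letter display in which levels
#' sharing a letter are not significantly different.
#'
#' @param fit An `hdr_fit` whose model contains `factor`.
#' @param factor Name of a factor moderator in the fitted model.
#' @param alpha Significance level for the letter display (default 0.05).
#' @return List with `contrasts` (tibble: `contrast`, `estimate`, `se`,
#'   `statistic`, `p_value` Holm-adjusted) and `letters` (named character
#'   vector, one entry per level). A single-level factor yields empty tables.
#' @export
pairwise_contrasts <- function(fit, factor, alpha = 0.05) {
  frame <- fit$frame
  if (!factor %in% names(frame) || !is.factor(frame[[factor]])) {
    hdr_config_error(paste0("not a factor moderator in this model: ", factor))
  }
  levs <- levels(droplevels(frame[[factor]]))
  if (length(levs) < 2L) {
    return(list(contrasts = tibble::tibble(
      contrast = character(), estimate = numeric(), se = numeric(),
      statistic = numeric(), p_value = numeric()),
      letters = setNames(rep("a", length(levs)), levs)))
  }
  mx <- mean(frame$x)
  emm <- emmeans::emmeans(
    fit$model, specs = factor,
    at = list(x = mx, x2 = mx^2),
    lmer.df = "asymptotic",
    data = frame)
  prs <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                         adjust = "holm"))
  stat_col <- intersect(c("z.ratio", "t.ratio"), names(prs))[1]
  contrasts <- tibble::tibble(
    contrast = as.character(prs$contrast),
    estimate = prs$estimate,
    se = prs$SE,
    statistic = prs[[stat_col]],
    p_value = prs$p.value
  )
  means <- as.data.frame(emm)
  letters <- letter_display(levs, means$emmean[match(levs, means[[1]])],
                            contrasts, alpha)
  list(contrasts = contrasts, letters = letters)
}

## Compact letter display: order levels by estimated mean and assign letters
## to maximal runs of mutually non-significant levels.
letter_display <- function(levs, means, contrasts, alpha) {
  ord <- order(means)
  levs_o <- levs[ord]
  k <- length(levs_o)
  sig <- matrix(FALSE, k, k, dimnames = list(levs_o, levs_o))
  for (r in seq_len(nrow(contrasts))) {
    parts <- strsplit(contrasts$contrast[r], " - ", fixed = TRUE)[[1]]
    parts <- gsub("^\\(|\\)$", "", parts)
    if (all(parts %in% levs_o)) {
      s <- contrasts$p_value[r] <= alpha
      sig[parts[1], parts[2]] <- s
      sig[parts[2], parts[1]] <- s
    }
  }
  groups <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && !any(sig[i:(j + 1), i:(j + 1)])) j <- j + 1
    grp <- levs_o[i:j]
    contained <- any(vapply(groups, function(g) all(grp %in% g), logical(1)))
    if (!contained) groups[[length(groups) + 1L]] <- grp
  }
  out <- setNames(rep("", k), levs_o)
  for (gi in seq_along(groups)) {
    for (l in groups[[gi]]) out[l] <- paste0(out[l], letters[gi])
  }
  out[levs]
  out[match(levs, names(out))]
}
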