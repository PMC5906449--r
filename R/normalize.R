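#' Impute below-detection values as half the column minimum
#'
#' Censored (below detection) metabolite values are stored as `NA`.
#' Before clustering or PCA they are imputed as half the smallest
#' observed value of their column — the usual left-censoring convention —
#' so whole lines are not discarded because a single metabolite (larval
#' glucose, typically) fell below the assay floor.
#'
#' @param panel a [metabolite_panel()] (or compatible data frame).
#' @return the panel with `NA` metabolite entries replaced.
#' @export
impute_below_detection <- function(panel) {
  for (m in panel_metabolites(panel)) {
    v <- panel[[m]]
    if (anyNA(v)) {
      obs <- v[!is.na(v)]
      if (!length(obs))
        stop_config("metabolite '", m, "' has no observed values to impute from")
      v[is.na(v)] <- min(obs) / 2
      panel[[m]] <- v
    }
  }
  panel
}

#' Column-wise z-score normalisation
#'
#' Centres and scales each metabolite column to mean 0 and sample SD 1
#' over its non-missing entries; missing entries are preserved. This is
#' the normalisation used before k-means metabotyping and PCA.
#'
#' @param panel a [metabolite_panel()] or compatible data frame.
#' @return the panel with normalised metabolite columns.
#' @export
zscore_normalize <- function(panel) {
  for (m in panel_metabolites(panel)) {
    v <- panel[[m]]
    obs <- v[!is.na(v)]
    if (length(obs) < 2 || sd(obs) == 0)
      stop_config("zero-variance or near-empty metabolite column: ", m)
    panel[[m]] <- (v - mean(obs)) / sd(obs)
  }
  panel
}

#' Percent-of-maximum normalisation across lines
#'
#' Averages replicates into line means, then expresses every line mean as
#' a percent of the maximum line mean within its metabolite x stage x sex
#' (x diet) group, so the highest line maps to exactly 100. This puts
#' metabolites with very different absolute scales on a common footing
#' before diet-shift comparisons.
#'
#' @param panel a [metabolite_panel()].
#' @param basis optional data frame of reference maxima (columns `stage`,
#'   `sex`, `metabolite`, `max`) to normalise against — used to put a
#'   shifted panel on the same basis as its baseline. Defaults to the
#'   panel's own maxima.
#' @param by_diet logical; when `TRUE` (default) maxima are taken within
#'   diet as well.
#' @return list with `panel` (line-mean data frame with percent values)
#'   and `basis` (the maxima used).
#' @export
percent_normalize <- function(panel, basis = NULL, by_diet = TRUE) {
  lm_df <- line_means(panel)
  mets <- setdiff(names(lm_df), c("line", "stage", "sex", "diet"))
  keys <- if (by_diet) c("stage", "sex", "diet") else c("stage", "sex")
  if (is.null(basis)) {
    basis <- do.call(rbind, lapply(mets, function(m) {
      agg <- stats::aggregate(lm_df[[m]],
                              by = lm_df[keys],
                              FUN = function(v) suppressWarnings(
                                max(v, na.rm = TRUE)))
      agg$metabolite <- m
      names(agg)[names(agg) == "x"] <- "max"
      agg
    }))
    basis$max[!is.finite(basis$max)] <- NA_real_
  }
  for (m in mets) {
    b <- basis[basis$metabolite == m, , drop = FALSE]
    key_panel <- do.call(paste, c(lm_df[keys], sep = "\r"))
    key_basis <- do.call(paste, c(b[keys], sep = "\r"))
    mx <- b$max[match(key_panel, key_basis)]
    if (any(!is.na(lm_df[[m]]) & (is.na(mx) | mx <= 0)))
      stop_config("group maximum missing or non-positive for metabolite '",
                  m, "'")
    lm_df[[m]] <- 100 * lm_df[[m]] / mx
  }
  list(panel = lm_df, basis = basis)
}
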