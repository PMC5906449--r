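#' Metabolite panel container
#'
#' A metabolite panel is a data frame with one row per biological sample.
#' The metadata columns are `sample_id`, `line`, `stage` (`"larva"` or
#' `"adult"`), `sex` (`"female"`, `"male"` or `"mixed"`), `diet` (`"SD"`,
#' `"LSD"` or `"HSD"`) and `replicate`; every remaining column is a
#' metabolite with non-negative per-animal amounts (`NA` marks
#' below-detection or missing values). Larvae are collected before sexing,
#' so larval rows must carry `sex = "mixed"`.
#'
#' @param x data frame holding the metadata and metabolite columns;
#'   `sample_id` is derived from the metadata when absent.
#' @return `x` validated, with class `"metabolite_panel"` prepended.
#' @export
#' @examples
#' metabolite_panel(data.frame(
#'   line = "L1", stage = "adult", sex = "female", diet = "SD",
#'   replicate = 1, TAG = 12.5, glucose = 3.1))
metabolite_panel <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  need <- c("line", "stage", "sex", "diet", "replicate")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop_config("panel lacks metadata column(s): ", paste(miss, collapse = ", "))
  if (!"sample_id" %in% names(x))
    x$sample_id <- with(x, paste(line, stage, sex, diet, replicate, sep = "."))
  assert_that(all(x$stage %in% c("larva", "adult")),
              "stage must be 'larva' or 'adult'")
  assert_that(all(x$sex %in% c("female", "male", "mixed")),
              "sex must be 'female', 'male' or 'mixed'")
  assert_that(all(x$diet %in% c("SD", "LSD", "HSD")),
              "diet must be 'SD', 'LSD' or 'HSD'")
  assert_that(all(x$sex[x$stage == "larva"] == "mixed"),
              "larval samples must have sex = 'mixed'")
  assert_that(!anyDuplicated(x$sample_id),
              "(line, stage, sex, diet, replicate) must be unique")
  mets <- panel_metabolites(x)
  assert_that(length(mets) >= 1, "panel has no metabolite columns")
  for (m in mets) {
    assert_that(is.numeric(x[[m]]), paste0("metabolite '", m, "' not numeric"))
    assert_that(all(x[[m]] >= 0, na.rm = TRUE),
                paste0("metabolite '", m, "' has negative amounts"))
  }
  x <- x[, c("sample_id", need, mets)]
  class(x) <- unique(c("metabolite_panel", class(x)))
  x
}

panel_meta_cols <- c("sample_id", "line", "stage", "sex", "diet", "replicate")

#' Names of the metabolite columns of a panel
#' @param panel a metabolite panel (or plain data frame with the same layout).
#' @return character vector of metabolite column names.
#' @export
panel_metabolites <- function(panel) {
  setdiff(names(panel), panel_meta_cols)
}

#' Average replicates into line means
#'
#' Collapses a panel to one row per (line, stage, sex, diet), averaging the
#' replicate measurements of every metabolite with `NA` removal. Line means
#' are the unit of analysis for percent normalisation, correlation matrices
#' and diet-shift responses.
#'
#' @param panel a metabolite panel.
#' @return a data frame with `line`, `stage`, `sex`, `diet` and one mean
#'   column per metabolite (`NaN` becomes `NA` when all replicates are
#'   missing).
#' @export
line_means <- function(panel) {
  mets <- panel_metabolites(panel)
  key <- interaction(panel$line, panel$stage, panel$sex, panel$diet, drop = TRUE)
  idx <- split(seq_len(nrow(panel)), key)
  out <- do.call(rbind, lapply(idx, function(i) {
    row <- panel[i[1], c("line", "stage", "sex", "diet"), drop = FALSE]
    for (m in mets) {
      v <- mean(panel[[m]][i], na.rm = TRUE)
      row[[m]] <- if (is.nan(v)) NA_real_ else v
    }
    row
  }))
  rownames(out) <- NULL
  out
}

#' Read / write a metabolite panel as TSV
#'
#' The on-disk dialect is plain tab-separated text with a header row; any
#' leading `#` lines are treated as comments.
#'
#' @param path file path.
#' @return `read_panel_tsv` returns a validated [metabolite_panel()].
#' @export
read_panel_tsv <- function(path) {
  metabolite_panel(read.delim(path, comment.char = "#",
                              stringsAsFactors = FALSE))
}

#' @rdname read_panel_tsv
#' @param panel panel to write.
#' @param comment optional character vector written as leading `#` lines
#'   (used by the pipeline writers to record normalisation mode and seed).
#' @export
write_panel_tsv <- function(panel, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comment)) writeLines(paste0("# ", comment), con)
  write.table(panel, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
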