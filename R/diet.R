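#' Percent change of metabolite line means after a diet shift
#'
#' For each (line, stage, sex, metabolite) cell, the response to the
#' shift is `(shifted - baseline) / baseline * 100`, computed on line
#' means (replicates averaged first). Positive values are increases,
#' negative values decreases. Cells whose baseline is missing or zero are
#' emitted as missing. Because the response is a ratio, it is invariant
#' to any positive rescaling applied consistently to both arms — in
#' particular it is the same whether computed on raw amounts or on
#' percent-normalised values sharing one normalisation basis.
#'
#' @param lsd_panel baseline [metabolite_panel()] (one diet arm).
#' @param shifted_panel shifted panel (one diet arm).
#' @return long data frame: `line`, `stage`, `sex`, `metabolite`,
#'   `baseline_diet`, `shifted_diet`, `baseline`, `shifted`,
#'   `percent_change`.
#' @export
diet_response <- function(lsd_panel, shifted_panel) {
  base_diet <- unique(lsd_panel$diet)
  shift_diet <- unique(shifted_panel$diet)
  assert_that(length(base_diet) == 1 && length(shift_diet) == 1,
              "each panel must hold a single diet arm")
  b <- line_means(lsd_panel)
  s <- line_means(shifted_panel)
  mets_b <- setdiff(names(b), c("line", "stage", "sex", "diet"))
  mets_s <- setdiff(names(s), c("line", "stage", "sex", "diet"))
  assert_that(identical(sort(mets_b), sort(mets_s)),
              "panels measure different metabolites")
  kb <- paste(b$line, b$stage, b$sex, sep = "\r")
  ks <- paste(s$line, s$stage, s$sex, sep = "\r")
  un_b <- setdiff(kb, ks)
  un_s <- setdiff(ks, kb)
  if (length(un_b) || length(un_s))
    stop_config("unmatched (line, stage, sex) cells: ",
                paste(gsub("\r", "/", c(un_b, un_s)), collapse = ", "))
  s <- s[match(kb, ks), , drop = FALSE]
  out <- do.call(rbind, lapply(mets_b, function(m) {
    baseline <- b[[m]]
    shifted <- s[[m]]
    pc <- ifelse(is.na(baseline) | baseline == 0, NA_real_,
                 (shifted - baseline) / baseline * 100)
    data.frame(line = b$line, stage = b$stage, sex = b$sex, metabolite = m,
               baseline_diet = base_diet, shifted_diet = shift_diet,
               baseline = baseline, shifted = shifted, percent_change = pc,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
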