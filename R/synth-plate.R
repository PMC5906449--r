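#' Generate raw plate readings for a panel (inverse of quantification)
#'
#' Builds the plate a quantification run would start from: standard wells
#' spanning the observed concentration range plus one sample well per
#' panel row, with readings on the line
#' `reading = slope * well_concentration + intercept` plus optional
#' multiplicative read noise. The well concentration of a sample is
#' `amount * n_animals / (volume * dilution)`, so passing the readings
#' through [fit_standard_curve()] and [quantify()] recovers the panel
#' amounts exactly at zero noise. Sample wells whose concentration falls
#' outside the simulated linear range (above the top standard) are
#' flagged.
#'
#' @param panel a [metabolite_panel()] holding the assayed metabolite.
#' @param assay an [assay_spec()]; `assay$metabolite` selects the panel
#'   column.
#' @param seed integer seed for the read noise.
#' @param slope,intercept true standard-curve parameters of the simulated
#'   plate (slope must be positive).
#' @param read_noise_sd relative (multiplicative) noise SD on every
#'   reading; 0 for a noise-free plate.
#' @param n_standards number of standard levels including the blank.
#' @param linear_range_max top standard concentration; defaults to 110%
#'   of the largest sample well concentration.
#' @return data frame of class `"plate_read_set"` with columns `well`,
#'   `sample_id`, `role` (`"standard"` or `"sample"`), `standard_conc`,
#'   `reading`, `out_of_range`.
#' @export
gen_plate_reads <- function(panel, assay, seed = 1, slope = 0.5,
                            intercept = 0.05, read_noise_sd = 0,
                            n_standards = 6, linear_range_max = NULL) {
  stopifnot(inherits(assay, "assay_spec"))
  assert_that(slope > 0, "standard slope must be positive")
  m <- assay$metabolite
  if (!m %in% panel_metabolites(panel))
    stop_config("panel has no metabolite column '", m, "'")
  amount <- panel[[m]]
  well_conc <- amount * assay$n_animals / (assay$volume * assay$dilution)
  cmax <- linear_range_max %||%
    (1.1 * max(well_conc, na.rm = TRUE))
  if (!is.finite(cmax) || cmax <= 0) cmax <- 1
  std_conc <- seq(0, cmax, length.out = n_standards)
  with_seed(seed, {
    noise <- function(n) exp(rnorm(n, 0, read_noise_sd))
    std_read <- (slope * std_conc + intercept) * noise(length(std_conc))
    smp_read <- (slope * well_conc + intercept) * noise(length(well_conc))
  })
  out <- rbind(
    data.frame(well = paste0("STD", seq_along(std_conc)),
               sample_id = NA_character_, role = "standard",
               standard_conc = std_conc, reading = std_read,
               out_of_range = FALSE, stringsAsFactors = FALSE),
    data.frame(well = paste0("W", seq_along(well_conc)),
               sample_id = panel$sample_id, role = "sample",
               standard_conc = NA_real_, reading = smp_read,
               out_of_range = !is.na(well_conc) & well_conc > cmax,
               stringsAsFactors = FALSE))
  attr(out, "assay") <- assay
  attr(out, "truth") <- list(slope = slope, intercept = intercept,
                             read_noise_sd = read_noise_sd)
  class(out) <- c("plate_read_set", class(out))
  out
}

#' Quantify a generated or imported plate read set
#'
#' Convenience wrapper: fits the standard curve from the standard wells
#' and quantifies the sample wells with the plate's assay spec.
#'
#' @param reads a `"plate_read_set"` data frame (columns as produced by
#'   [gen_plate_reads()]).
#' @param assay an [assay_spec()]; defaults to the one attached to the
#'   read set.
#' @return as [quantify()].
#' @export
quantify_plate <- function(reads, assay = attr(reads, "assay")) {
  stds <- reads[reads$role == "standard",
                c("standard_conc", "reading")]
  names(stds) <- c("concentration", "reading")
  cal <- fit_standard_curve(stds)
  smp <- reads[reads$role == "sample", ]
  quantify(smp$reading, cal, assay, sample_id = smp$sample_id)
}
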