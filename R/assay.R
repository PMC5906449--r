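#' Specification of a colorimetric / fluorometric plate assay
#'
#' Captures everything needed to turn a well reading into a per-animal
#' amount: the dilution applied to the homogenate, the number of animals
#' pooled per sample (e.g. five late third-instar larvae or eight six-day
#' old adults), and the homogenisation volume. Dilutions differ by assay,
#' stage and sex — for example glycogen uses 1:2 for larvae, 1:3 for
#' males and 1:6 (basal) or 1:10 (diet-shift) for females — so each
#' combination gets its own spec.
#'
#' @param name assay name (conventionally the metabolite it measures).
#' @param dilution unitless dilution factor, >= 1.
#' @param n_animals animals pooled per sample, > 0.
#' @param volume homogenisation volume in the same units as the amounts
#'   (e.g. 0.4 for 400 uL when amounts are per-mL concentrations).
#' @param read_mode `"absorbance"` or `"fluorescence"`.
#' @param metabolite metabolite column the assay quantifies; defaults to
#'   `name`.
#' @return list of class `"assay_spec"`.
#' @export
assay_spec <- function(name, dilution = 1, n_animals, volume = 1,
                       read_mode = c("absorbance", "fluorescence"),
                       metabolite = name) {
  read_mode <- match.arg(read_mode)
  assert_that(dilution >= 1, "dilution must be >= 1")
  assert_that(n_animals > 0 && n_animals == round(n_animals),
              "n_animals must be a positive integer")
  assert_that(volume > 0, "volume must be positive")
  structure(list(name = name, dilution = dilution, n_animals = n_animals,
                 volume = volume, read_mode = read_mode,
                 metabolite = metabolite),
            class = "assay_spec")
}

#' Fit a linear standard curve
#'
#' Ordinary least-squares fit of `reading = slope * concentration +
#' intercept` over the standard wells. The intercept is fitted rather
#' than forced through the origin so the blank wells absorb plate
#' background.
#'
#' @param standards data frame with columns `concentration` and
#'   `reading`; at least two distinct concentrations (a blank plus one
#'   level suffices).
#' @return list of class `"calibration"` with `slope`, `intercept`,
#'   `r_squared`, `n`.
#' @export
fit_standard_curve <- function(standards) {
  assert_that(all(c("concentration", "reading") %in% names(standards)),
              "standards needs 'concentration' and 'reading' columns")
  standards <- standards[complete.cases(standards[, c("concentration",
                                                      "reading")]), ]
  if (length(unique(standards$concentration)) < 2)
    stop_config("degenerate standard design: need >= 2 distinct concentrations")
  fit <- lm(reading ~ concentration, data = standards)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((standards$reading - mean(standards$reading))^2)
  structure(list(slope = unname(fit$coefficients["concentration"]),
                 intercept = unname(fit$coefficients["(Intercept)"]),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
                 n = nrow(standards)),
            class = "calibration")
}

#' Convert well readings to per-animal metabolite amounts
#'
#' Inverts the standard curve and undoes dilution and pooling:
#' `concentration = (reading - intercept) / slope * dilution`, then
#' `amount per animal = concentration * volume / n_animals`. Readings
#' below the blank beyond `blank_tol` are flagged below-detection and the
#' amount is set missing rather than negative; concentrations within
#' `-blank_tol..0` are clamped to zero (blank noise).
#'
#' @param reading numeric vector of well readings.
#' @param cal a [fit_standard_curve()] calibration with nonzero slope.
#' @param spec an [assay_spec()].
#' @param sample_id optional ids for the readings.
#' @param blank_tol tolerance (concentration units) for negative computed
#'   concentrations before flagging below-detection.
#' @return data frame with `sample_id`, `metabolite`, `amount` (per
#'   animal, `NA` when below detection) and `below_detection`.
#' @export
quantify <- function(reading, cal, spec, sample_id = NULL, blank_tol = 0) {
  stopifnot(inherits(cal, "calibration"), inherits(spec, "assay_spec"))
  if (cal$slope == 0) stop_config("calibration slope is zero")
  conc <- (reading - cal$intercept) / cal$slope * spec$dilution
  below <- !is.na(conc) & conc < -blank_tol * spec$dilution
  conc[!below & !is.na(conc) & conc < 0] <- 0
  amount <- conc * spec$volume / spec$n_animals
  amount[below] <- NA_real_
  data.frame(sample_id = sample_id %||% paste0("w", seq_along(reading)),
             metabolite = spec$metabolite, amount = amount,
             below_detection = below, stringsAsFactors = FALSE)
}

#' Citrate synthase activity from the DTNB kinetic read
#'
#' Citrate synthase releases CoA-SH, which reduces DTNB to TNB2-; the
#' absorbance gain at 412 nm per minute converts to enzyme activity as
#'
#' `U/mL = (dA412_per_min * V_reaction * dil) / (epsilon * L * V_enz)`
#'
#' with the reaction volume, sample volume, path length and TNB2-
#' attenuation coefficient as parameters. The defaults correspond to a
#' 96-well kinetic assay: 0.22 mL reaction, 0.02 mL sample, ~0.63 cm
#' liquid column, epsilon 13.6 mM^-1 cm^-1. Activity is a proxy for
#' mitochondrial aerobic capacity.
#'
#' @param dA412_per_min change in absorbance at 412 nm per minute.
#' @param V_reaction total reaction volume in mL.
#' @param V_enz sample (enzyme) volume in mL.
#' @param dil sample dilution factor.
#' @param epsilon attenuation coefficient of TNB2- in mM^-1 cm^-1.
#' @param L optical path length in cm.
#' @return activity in U/mL.
#' @export
citrate_synthase_activity <- function(dA412_per_min, V_reaction = 0.22,
                                      V_enz = 0.02, dil = 1,
                                      epsilon = 13.6, L = 0.63) {
  if (epsilon <= 0 || L <= 0 || V_enz <= 0)
    stop_config("epsilon, L and V_enz must be positive")
  (dA412_per_min * V_reaction * dil) / (epsilon * L * V_enz)
}

#' Glycogen from paired glucose-oxidase readings
#'
#' The glucose-oxidase (GO) protocol measures free glucose in an
#' undigested aliquot and total glucose after amyloglucosidase digestion;
#' glycogen is the difference of the two quantified amounts. Negative
#' differences (measurement noise) are floored at zero and flagged.
#'
#' @param total_reading,free_reading well readings for the digested and
#'   undigested aliquots, from the same calibration.
#' @inheritParams quantify
#' @return data frame with `sample_id`, `metabolite` (`"glycogen"`),
#'   `amount`, `below_detection`, `floored`.
#' @export
glycogen_from_go <- function(total_reading, free_reading, cal, spec,
                             sample_id = NULL) {
  tot <- quantify(total_reading, cal, spec, sample_id = sample_id)
  fre <- quantify(free_reading, cal, spec, sample_id = sample_id)
  amount <- tot$amount - fre$amount
  floored <- !is.na(amount) & amount < 0
  if (any(floored))
    warning("free glucose exceeded total in ", sum(floored),
            " sample(s); glycogen floored at 0")
  amount[floored] <- 0
  data.frame(sample_id = tot$sample_id, metabolite = "glycogen",
             amount = amount,
             below_detection = tot$below_detection | fre$below_detection,
             floored = floored, stringsAsFactors = FALSE)
}
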