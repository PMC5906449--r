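# One "SD unit" of effect size expressed on the log scale: noise_sd = 1
# corresponds to a ~20% replicate coefficient of variation, typical of
# plate assays. All dimensionless effect sizes (cluster_separation,
# stage_sex_effect) are multiples of noise_sd in this unit.
.log_scale_unit <- 0.2

# Baseline log-scale per-animal amounts (adult male reference stratum).
# Values are plausible microgram-per-animal scales for the six standard
# metabolites; unknown metabolite names fall back to exp(1).
.base_log_amount <- c(TAG = log(20), protein = log(30), glycerol = log(2),
                      lactate = log(1.5), glycogen = log(15), glucose = log(3))

# Unit direction of the stage/sex mean offsets, scaled by
# stage_sex_effect * noise_sd. Larvae store less glycogen/TAG and little
# measurable glucose; females carry larger energy stores than males.
.stratum_pattern <- function(metabolites, stage, sex) {
  p <- setNames(numeric(length(metabolites)), metabolites)
  pick <- function(v) {
    keep <- intersect(names(v), metabolites)
    p[keep] <<- v[keep]
  }
  if (stage == "larva") {
    pick(c(TAG = -1, protein = 0.5, glycogen = -1.5, glucose = -2))
  } else if (sex == "female") {
    pick(c(TAG = 1, protein = 0.5, glycogen = 1, glucose = 0.5))
  }
  p
}

# k cluster centroids in metabolite space, mutually orthogonal directions
# each of norm `radius`, so every centroid pair is radius*sqrt(2) apart.
# Directions are drawn inside the orthogonal complement of `avoid` (the
# stage/sex offset subspace) whenever it has room, so the within-stratum
# cohort structure never projects onto the axes separating the strata.
.cluster_centroids <- function(k, metabolites, radius, avoid = NULL) {
  d <- length(metabolites)
  if (radius == 0 || k == 1)
    return(matrix(0, k, d, dimnames = list(NULL, metabolites)))
  n_avoid <- 0L
  base <- NULL
  if (!is.null(avoid)) {
    avoid <- avoid[, colSums(avoid^2) > 0, drop = FALSE]
    if (ncol(avoid)) {
      qa <- qr(avoid)
      n_avoid <- qa$rank
      base <- qr.Q(qa)[, seq_len(n_avoid), drop = FALSE]
    }
  }
  raw <- matrix(rnorm(d * k), d, k)
  if (k <= d - n_avoid) {
    q <- qr.Q(qr(cbind(base, raw)))[, n_avoid + seq_len(k), drop = FALSE]
  } else if (k <= d) {
    q <- qr.Q(qr(raw))[, seq_len(k), drop = FALSE]
  } else {
    q <- apply(raw, 2, function(v) v / sqrt(sum(v^2)))
  }
  cent <- t(q) * radius
  dimnames(cent) <- list(NULL, metabolites)
  cent
}

#' Generate a synthetic metabolite panel with planted structure
#'
#' Emits per-animal metabolite amounts for every line in three strata —
#' late third-instar larvae (mixed sex) and adult females and males — with
#' `config$n_replicates` replicates each. Amounts are generated on the log
#' scale and exponentiated, which keeps them positive and right-skewed
#' like real assay data. Planted structure, all recorded in the returned
#' truth object:
#'
#' * stage/sex mean offsets large enough that the three strata separate,
#'   with larval lactate means a configurable multiple (default 20-fold)
#'   of adult means;
#' * `k_metabotypes` line cohorts per stratum, with orthogonal centroid
#'   offsets of norm `cluster_separation * noise_sd`;
#' * virago lines, whose adult-female samples are drawn from the male
#'   distribution (male stratum offset and male metabotype effect);
#' * optional censoring: amounts below `detection_floor` are stored as
#'   missing (below detection).
#'
#' @param config a [synth_config()].
#' @param diet diet label for the emitted samples (default `"SD"`).
#' @return list with `panel` (a [metabolite_panel()]) and `truth` (list
#'   with `metabotype` labels per line x stage x sex, `virago_lines`, and
#'   the stratum/cluster offsets used).
#' @export
gen_metabolite_panel <- function(config, diet = "SD") {
  stopifnot(inherits(config, "synth_config"))
  mets <- config$metabolites
  strata <- data.frame(stage = c("larva", "adult", "adult"),
                       sex = c("mixed", "female", "male"),
                       stringsAsFactors = FALSE)
  sigma_log <- .log_scale_unit * config$noise_sd
  radius <- config$cluster_separation * sigma_log
  lact_off <- if ("lactate" %in% mets) log(config$lactate_fold) else NULL
  offsets <- lapply(seq_len(nrow(strata)), function(s) {
    off <- .stratum_pattern(mets, strata$stage[s], strata$sex[s]) *
      config$stage_sex_effect * sigma_log
    if (strata$stage[s] == "larva" && !is.null(lact_off))
      off["lactate"] <- off["lactate"] + lact_off
    off
  })
  avoid <- do.call(cbind, offsets)
  labels <- list()
  centroids <- list()
  with_seed(substream_seed(config$seed, 1L), {
    for (s in seq_len(nrow(strata))) {
      labels[[s]] <- sample(rep_len(seq_len(config$k_metabotypes),
                                    config$n_lines))
      centroids[[s]] <- .cluster_centroids(config$k_metabotypes, mets,
                                           radius, avoid = avoid)
    }
  })
  base <- ifelse(mets %in% names(.base_log_amount),
                 .base_log_amount[mets], 1)
  names(base) <- mets

  male_idx <- which(strata$stage == "adult" & strata$sex == "male")
  rows <- list()
  with_seed(substream_seed(config$seed, 2L), {
    for (s in seq_len(nrow(strata))) {
      st <- strata$stage[s]; sx <- strata$sex[s]
      off <- offsets[[s]]
      off_male <- offsets[[male_idx]]
      for (li in seq_len(config$n_lines)) {
        line <- config$line_ids[li]
        virago <- sx == "female" && line %in% config$virago_lines
        if (virago) {
          mu <- base + off_male + centroids[[male_idx]][labels[[male_idx]][li], ]
        } else {
          mu <- base + off + centroids[[s]][labels[[s]][li], ]
        }
        for (r in seq_len(config$n_replicates)) {
          val <- exp(mu + rnorm(length(mets), 0, sigma_log))
          val[val < config$detection_floor] <- NA_real_
          row <- data.frame(line = line, stage = st, sex = sx, diet = diet,
                            replicate = r, stringsAsFactors = FALSE)
          row[mets] <- as.list(val)
          rows[[length(rows) + 1L]] <- row
        }
      }
    }
  })
  panel <- metabolite_panel(do.call(rbind, rows))
  lab_df <- do.call(rbind, lapply(seq_len(nrow(strata)), function(s) {
    data.frame(line = config$line_ids, stage = strata$stage[s],
               sex = strata$sex[s], cluster = labels[[s]],
               stringsAsFactors = FALSE)
  }))
  truth <- list(metabotype = lab_df, virago_lines = config$virago_lines,
                cluster_centroids = centroids, diet = diet)
  list(panel = panel, truth = truth)
}

#' Generate diet-shift copies of a low-sugar-diet baseline panel
#'
#' Takes a panel of samples reared on the low sugar diet (LSD) and emits
#' SD (standard diet) and HSD (high sugar diet) copies with planted
#' per-line, per-sex multiplicative effects on each metabolite. Default
#' effect spectra follow the biology the shift emulates: glucose,
#' glycogen and TAG multipliers are positive on average (energy stores
#' rise with dietary sugar), glycerol multipliers straddle 1 (both
#' increases and decreases occur), and protein multipliers are close
#' to 1. Forced multipliers in `config$shift_effects` override the random
#' draws cell by cell. Every multiplier is recorded in the truth object,
#' so downstream percent-change estimates can be compared with the
#' planted `(multiplier - 1) * 100`.
#'
#' @param panel LSD baseline [metabolite_panel()].
#' @param config a [synth_config()]; uses `shift_effects`,
#'   `shift_noise_sd` and the seed.
#' @return list with `panel` (baseline plus SD and HSD rows) and `truth`
#'   (data frame `line`, `sex`, `metabolite`, `diet`, `multiplier`).
#' @export
gen_diet_shift <- function(panel, config) {
  stopifnot(inherits(config, "synth_config"))
  if (!all(panel$diet == "LSD"))
    stop_config("baseline panel must contain LSD samples only")
  mets <- panel_metabolites(panel)
  cells <- unique(panel[, c("line", "sex")])
  spectra <- function(m) {
    if (m %in% c("glucose", "glycogen", "TAG")) c(0.30, 0.25)
    else if (m == "glycerol") c(0.00, 0.30)
    else if (m == "protein")  c(0.00, 0.03)
    else c(0.05, 0.20)
  }
  grid <- expand.grid(i = seq_len(nrow(cells)), metabolite = mets,
                      diet = c("SD", "HSD"), stringsAsFactors = FALSE)
  truth <- data.frame(line = cells$line[grid$i], sex = cells$sex[grid$i],
                      metabolite = grid$metabolite, diet = grid$diet,
                      stringsAsFactors = FALSE)
  with_seed(substream_seed(config$seed, 3L), {
    truth$multiplier <- vapply(seq_len(nrow(truth)), function(j) {
      sp <- spectra(truth$metabolite[j])
      rlnorm(1, sp[1], sp[2])
    }, numeric(1))
  })
  forced <- config$shift_effects
  if (!is.null(forced)) {
    for (j in seq_len(nrow(forced))) {
      hit <- truth$line == forced$line[j] & truth$sex == forced$sex[j] &
        truth$metabolite == forced$metabolite[j] & truth$diet == forced$diet[j]
      if (!any(hit))
        stop_config("shift_effects row ", j, " matches no panel cell")
      truth$multiplier[hit] <- forced$multiplier[j]
    }
  }
  shifted <- list()
  with_seed(substream_seed(config$seed, 4L), {
    for (arm in c("SD", "HSD")) {
      copy <- as.data.frame(panel)
      copy$diet <- arm
      for (j in seq_len(nrow(copy))) {
        for (m in mets) {
          mult <- truth$multiplier[truth$line == copy$line[j] &
                                     truth$sex == copy$sex[j] &
                                     truth$metabolite == m &
                                     truth$diet == arm]
          eps <- exp(rnorm(1, 0, config$shift_noise_sd))
          copy[[m]][j] <- copy[[m]][j] * mult * eps
        }
      }
      copy$sample_id <- NULL
      shifted[[arm]] <- copy
    }
  })
  base_df <- as.data.frame(panel)
  base_df$sample_id <- NULL
  out <- rbind(base_df, shifted$SD, shifted$HSD)
  list(panel = metabolite_panel(out), truth = truth)
}
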