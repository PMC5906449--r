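#' Configuration for the synthetic-data generators
#'
#' Bundles every knob of the synthetic study: panel layout, planted
#' metabotype/virago structure, genotype matrix geometry, taxon table
#' composition and planted metabolite-microbe links. The defaults emulate
#' the study design the generators are meant to mirror: 35 inbred lines,
#' six metabolites measured in late third-instar larvae (mixed sex) and
#' six-day-old adults of both sexes, three metabotypes per stage/sex
#' stratum, four virago lines, larval lactate about 20-fold above adult
#' levels, and a gut community dominated by Acetobacter and Lactobacillus
#' species with one Wolbachia-infected line.
#'
#' @param n_lines number of inbred lines.
#' @param line_ids optional character ids for the lines; defaults to
#'   `"L1" ... "Ln"`.
#' @param metabolites metabolite names of the panel columns.
#' @param k_metabotypes number of planted metabotype clusters per
#'   stage/sex stratum.
#' @param virago_lines line ids whose adult females are drawn from the
#'   male distribution.
#' @param cluster_separation between-metabotype effect size, in units of
#'   the within-cluster standard deviation `noise_sd`.
#' @param stage_sex_effect effect size separating the larva / female /
#'   male strata, in units of `noise_sd`. The default (12) clearly
#'   exceeds the default metabotype separation, so the coarse
#'   larva/female/male structure dominates a combined clustering or
#'   principal-component projection while metabotypes are resolved
#'   within a stratum — mirroring real panels, where stage and sex move
#'   energy stores by far more than line-to-line variation does.
#' @param noise_sd within-cluster replicate noise, dimensionless: one
#'   unit corresponds to about a 20% replicate coefficient of variation
#'   on the natural scale (0.2 log units).
#' @param lactate_fold multiple by which larval lactate means exceed the
#'   adult means (default 20).
#' @param detection_floor per-animal amount below which a value is
#'   censored to `NA` (below detection); `0` disables censoring.
#' @param n_replicates replicates per line x stage x sex cell.
#' @param n_sites number of biallelic genotype sites.
#' @param maf_spectrum length-2 numeric: shape parameters of the Beta
#'   distribution the alternative-allele frequency of each site is drawn
#'   from (truncated to (0.02, 0.98)).
#' @param n_unique_alt,n_unique_ref planted counts of group-unique
#'   alternative / reference alleles.
#' @param unique_group line ids forming the group that carries the
#'   planted unique alleles.
#' @param genotype_missing_rate fraction of calls set to missing.
#' @param taxa named character vector mapping taxon (species) name to
#'   genus; default community has Acetobacter and Lactobacillus species,
#'   two minor genera and Wolbachia.
#' @param wolbachia_line line id whose samples carry a large Wolbachia
#'   fraction (`NULL` for none).
#' @param sequencing_depth reads per microbiome sample.
#' @param planted_links list of `list(metabolite=, taxon=, rho=)` entries;
#'   `taxon` may name a species or a genus (the link then modulates every
#'   member species). `rho` is the target Spearman correlation with the
#'   metabolite across samples.
#' @param shift_effects optional data frame of forced diet-shift
#'   multipliers with columns `line`, `sex`, `metabolite`, `diet`,
#'   `multiplier`; cells not listed get random multipliers.
#' @param shift_noise_sd log-scale noise added to the shifted replicate
#'   values.
#' @param seed master integer seed.
#' @return a validated list of class `"synth_config"`.
#' @export
synth_config <- function(n_lines = 35,
                         line_ids = NULL,
                         metabolites = c("TAG", "protein", "glycerol",
                                         "lactate", "glycogen", "glucose"),
                         k_metabotypes = 3,
                         virago_lines = character(),
                         cluster_separation = 5,
                         stage_sex_effect = 12,
                         noise_sd = 1,
                         lactate_fold = 20,
                         detection_floor = 0,
                         n_replicates = 3,
                         n_sites = 1000,
                         maf_spectrum = c(0.8, 1.6),
                         n_unique_alt = 0,
                         n_unique_ref = 0,
                         unique_group = character(),
                         genotype_missing_rate = 0,
                         taxa = default_taxonomy(),
                         wolbachia_line = NULL,
                         sequencing_depth = 50000,
                         planted_links = list(),
                         shift_effects = NULL,
                         shift_noise_sd = 0.02,
                         seed = 1) {
  if (is.null(line_ids)) line_ids <- paste0("L", seq_len(n_lines))
  assert_that(length(line_ids) == n_lines, "line_ids length must equal n_lines")
  assert_that(n_lines >= 1 && k_metabotypes >= 1 && n_replicates >= 1,
              "counts must be >= 1")
  assert_that(k_metabotypes <= n_lines, "k_metabotypes cannot exceed n_lines")
  bad <- setdiff(virago_lines, line_ids)
  if (length(bad))
    stop_config("virago line(s) not in line set: ", paste(bad, collapse = ", "))
  assert_that(noise_sd >= 0 && cluster_separation >= 0 && stage_sex_effect >= 0,
              "effect sizes and noise_sd must be non-negative")
  assert_that(n_sites >= 1, "n_sites must be >= 1")
  assert_that(n_unique_alt >= 0 && n_unique_ref >= 0 &&
                n_unique_alt + n_unique_ref <= n_sites,
              "n_unique_alt + n_unique_ref must not exceed n_sites")
  if ((n_unique_alt > 0 || n_unique_ref > 0) && length(unique_group) == 0)
    stop_config("planted unique alleles require a non-empty unique_group")
  bad <- setdiff(unique_group, line_ids)
  if (length(bad))
    stop_config("unique_group line(s) not in line set: ",
                paste(bad, collapse = ", "))
  assert_that(genotype_missing_rate >= 0 && genotype_missing_rate < 1,
              "genotype_missing_rate must be in [0, 1)")
  assert_that(!is.null(names(taxa)) && all(nzchar(names(taxa))),
              "taxa must be a named vector taxon -> genus")
  if (!is.null(wolbachia_line)) {
    assert_that(wolbachia_line %in% line_ids, "wolbachia_line not in line set")
    assert_that("Wolbachia" %in% taxa,
                "wolbachia_line set but no Wolbachia genus in taxa")
  }
  for (pl in planted_links) {
    assert_that(all(c("metabolite", "taxon", "rho") %in% names(pl)),
                "planted link needs metabolite, taxon, rho")
    if (!pl$metabolite %in% metabolites)
      stop_config("planted link names unknown metabolite: ", pl$metabolite)
    if (!(pl$taxon %in% names(taxa) || pl$taxon %in% taxa))
      stop_config("planted link names unknown taxon/genus: ", pl$taxon)
    assert_that(pl$rho >= -1 && pl$rho <= 1,
                "planted correlation target must be in [-1, 1]")
  }
  assert_that(sequencing_depth >= 1, "sequencing_depth must be >= 1")
  cfg <- list(n_lines = n_lines, line_ids = line_ids, metabolites = metabolites,
              k_metabotypes = k_metabotypes, virago_lines = virago_lines,
              cluster_separation = cluster_separation,
              stage_sex_effect = stage_sex_effect, noise_sd = noise_sd,
              lactate_fold = lactate_fold, detection_floor = detection_floor,
              n_replicates = n_replicates, n_sites = n_sites,
              maf_spectrum = maf_spectrum, n_unique_alt = n_unique_alt,
              n_unique_ref = n_unique_ref, unique_group = unique_group,
              genotype_missing_rate = genotype_missing_rate, taxa = taxa,
              wolbachia_line = wolbachia_line,
              sequencing_depth = sequencing_depth,
              planted_links = planted_links, shift_effects = shift_effects,
              shift_noise_sd = shift_noise_sd, seed = as.integer(seed))
  class(cfg) <- "synth_config"
  cfg
}

#' Default line ids for the synthetic study
#'
#' Thirty-five DGRP-style line numbers, including the lines that recur in
#' the analyses this package emulates (the virago lines 324, 380, 732 and
#' 786, the fecundity controls 362 and 714, the diet-shift examples 705
#' and 427, and the microbiome lines 301, 303, 315 and 859).
#'
#' @return character vector of 35 line ids.
#' @export
default_line_ids <- function() {
  as.character(c(301, 303, 315, 324, 335, 357, 362, 380, 391, 427,
                 705, 707, 714, 732, 737, 738, 757, 765, 786, 790,
                 796, 799, 801, 804, 805, 808, 810, 812, 818, 820,
                 821, 822, 832, 837, 859))
}

#' Default synthetic gut community taxonomy
#'
#' Species-to-genus map for the synthetic abundance tables: the community
#' is dominated by Acetobacter and Lactobacillus, as in laboratory-reared
#' Drosophila, with two minor genera and the intracellular endosymbiont
#' Wolbachia (not a gut resident; present only in infected lines).
#'
#' @return named character vector, names = species, values = genus.
#' @export
default_taxonomy <- function() {
  c("Acetobacter pomorum"        = "Acetobacter",
    "Acetobacter tropicalis"     = "Acetobacter",
    "Acetobacter pasteurianus"   = "Acetobacter",
    "Lactobacillus plantarum"    = "Lactobacillus",
    "Lactobacillus brevis"       = "Lactobacillus",
    "Lactobacillus fructivorans" = "Lactobacillus",
    "Lactobacillus homohiochii"  = "Lactobacillus",
    "Gluconobacter morbifer"     = "Gluconobacter",
    "Enterococcus faecalis"      = "Enterococcus",
    "Wolbachia pipientis"        = "Wolbachia")
}
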