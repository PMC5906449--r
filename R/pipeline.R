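.write_manifest <- function(out_dir, analysis, params) {
  # no timestamp: two runs with the same config must be byte-identical
  manifest <- list(analysis = analysis, params = params,
                   package = "metabotyper",
                   version = as.character(utils::packageVersion("metabotyper")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  manifest
}

.corr_long_write <- function(res, path) {
  write.table(correlation_long(res), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
}

#' Run the basal profiling analysis
#'
#' End-to-end basal-condition analysis of a metabolite panel: imputation
#' and z-score normalisation, per-stratum (larva / female / male)
#' Spearman correlation matrices on line means, combined k-means
#' metabotyping, PCA, and virago calling. All outputs are written as TSV
#' plus a JSON run manifest recording the seed and parameters.
#'
#' @param panel a [metabolite_panel()] (single diet arm).
#' @param out_dir output directory (created if needed).
#' @param k number of metabotype clusters for the combined panel
#'   (default 3: the larva / female / male structure).
#' @param n_init,seed k-means restarts and seed.
#' @param alpha significance level for the correlation filter.
#' @return (invisibly) list with `normalized`, `correlations` (per
#'   stratum), `clusters`, `pca`, `viragos`, `manifest`.
#' @export
run_basal <- function(panel, out_dir, k = 3, n_init = 50, seed = 1,
                      alpha = 0.05) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  norm <- zscore_normalize(impute_below_detection(panel))
  write_panel_tsv(norm, file.path(out_dir, "panel_normalized.tsv"),
                  comment = c("normalization: column z-score after half-min imputation",
                              paste("seed:", seed)))
  lm_df <- line_means(panel)
  strata <- unique(lm_df[, c("stage", "sex")])
  corrs <- list()
  for (i in seq_len(nrow(strata))) {
    sub <- lm_df[lm_df$stage == strata$stage[i] & lm_df$sex == strata$sex[i], ]
    mets <- setdiff(names(sub), c("line", "stage", "sex", "diet"))
    res <- filter_significant(spearman_matrix(sub[mets]), alpha)
    tag <- paste0(strata$stage[i], "_", strata$sex[i])
    corrs[[tag]] <- res
    .corr_long_write(res, file.path(out_dir,
                                    paste0("correlations_", tag, ".tsv")))
  }
  clusters <- kmeans_metabotypes(norm, k = k, n_init = n_init, seed = seed)
  write.table(data.frame(sample_id = names(clusters$cluster),
                         cluster = clusters$cluster),
              file.path(out_dir, "metabotype_clusters.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  pc <- panel_pca(norm)
  write.table(data.frame(sample_id = rownames(pc$scores),
                         pc$scores[, 1:min(3, ncol(pc$scores))]),
              file.path(out_dir, "pca_scores.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  vir <- call_viragos(panel, seed = seed)
  write.table(vir, file.path(out_dir, "virago_calls.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest <- .write_manifest(out_dir, "basal",
                              list(k = k, n_init = n_init, seed = seed,
                                   alpha = alpha))
  invisible(list(normalized = norm, correlations = corrs,
                 clusters = clusters, pca = pc, viragos = vir,
                 manifest = manifest))
}

#' Run the diet-shift analysis
#'
#' Percent-normalises the low-sugar-diet baseline (the normalisation
#' basis is reused for the shifted arms) and computes per-cell percent
#' responses for the LSD-to-SD and LSD-to-HSD shifts.
#'
#' @param lsd_panel,sd_panel,hsd_panel panels for the three arms; `NULL`
#'   arms raise an error naming the missing arm.
#' @param out_dir output directory.
#' @return (invisibly) list with `normalized_lsd`, `response_sd`,
#'   `response_hsd`, `manifest`.
#' @export
run_diet_shift <- function(lsd_panel, sd_panel, hsd_panel, out_dir) {
  arms <- list(LSD = lsd_panel, SD = sd_panel, HSD = hsd_panel)
  for (a in names(arms))
    if (is.null(arms[[a]])) stop_config("missing diet arm: ", a)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pn <- percent_normalize(lsd_panel, by_diet = FALSE)
  write.table(pn$panel, file.path(out_dir, "lsd_percent_normalized.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  resp <- list()
  for (a in c("SD", "HSD")) {
    r <- diet_response(lsd_panel, arms[[a]])
    resp[[a]] <- r
    write.table(r, file.path(out_dir, paste0("diet_response_LSD_to_", a,
                                             ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- .write_manifest(out_dir, "diet_shift",
                              list(normalization = "percent-of-max on LSD basis"))
  invisible(list(normalized_lsd = pn, response_sd = resp$SD,
                 response_hsd = resp$HSD, manifest = manifest))
}

#' Run the metabolite-microbiome correlation analysis
#'
#' The gut-correlation pipeline: exclude configured lines and taxa
#' (defaults: no line, the Wolbachia genus), apply the top-95% taxon
#' filter, log10-transform metabolite amounts and taxon relative
#' abundances, and compute significance-filtered Spearman correlation
#' matrices between metabolites and taxa at species and at genus level.
#'
#' @param tab an [abundance_table()].
#' @param panel a [metabolite_panel()] with samples matching
#'   `tab$meta$sample_id`.
#' @param out_dir output directory.
#' @param exclude_lines line ids dropped before correlation (e.g. a
#'   Wolbachia-infected line).
#' @param exclude_taxa taxa / genera dropped (default `"Wolbachia"`).
#' @param alpha correlation significance level.
#' @param pseudocount pseudocount of the log transform.
#' @return (invisibly) list with `species` and `genus` correlation
#'   results, `filter` (the retained-taxon report), `manifest`.
#' @export
run_microbiome <- function(tab, panel, out_dir,
                           exclude_lines = character(),
                           exclude_taxa = "Wolbachia",
                           alpha = 0.05, pseudocount = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tab <- exclude_from_table(tab, lines = exclude_lines, taxa = exclude_taxa)
  keep <- panel$sample_id %in% tab$meta$sample_id
  if (!any(keep)) stop_config("no panel sample matches the abundance table")
  panel <- panel[keep, , drop = FALSE]
  panel <- panel[match(tab$meta$sample_id, panel$sample_id), , drop = FALSE]
  filt <- top95_filter(tab)
  write.table(data.frame(taxon = filt$retained),
              file.path(out_dir, "retained_taxa.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  mets <- panel_metabolites(panel)
  correlate <- function(t2) {
    prop <- relative_abundance(t2)
    joined <- cbind(log_transform(as.data.frame(panel)[mets],
                                  pseudocount = pseudocount),
                    log_transform(as.data.frame(prop), pseudocount = 1e-6))
    filter_significant(spearman_matrix(joined), alpha)
  }
  species_tab <- abundance_table(tab$counts[, filt$retained, drop = FALSE],
                                 tab$meta, tab$taxonomy[filt$retained])
  res_sp <- correlate(species_tab)
  .corr_long_write(res_sp, file.path(out_dir, "correlations_species.tsv"))
  res_ge <- correlate(genus_rollup(species_tab))
  .corr_long_write(res_ge, file.path(out_dir, "correlations_genus.tsv"))
  manifest <- .write_manifest(out_dir, "microbiome",
                              list(exclude_lines = exclude_lines,
                                   exclude_taxa = exclude_taxa,
                                   alpha = alpha, pseudocount = pseudocount,
                                   top_filter = 0.95))
  invisible(list(species = res_sp, genus = res_ge, filter = filt,
                 manifest = manifest))
}
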