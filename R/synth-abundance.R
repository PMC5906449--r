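# Baseline log weights of the default community: Acetobacter and
# Lactobacillus species dominate, minor genera trail, Wolbachia is absent
# unless a line is infected.
.base_log_weight <- function(taxa) {
  genus <- unname(taxa)
  w <- ifelse(genus %in% c("Acetobacter", "Lactobacillus"), log(100),
              ifelse(genus == "Wolbachia", -Inf, log(5)))
  setNames(w + seq(0.4, -0.4, length.out = length(taxa)), names(taxa))
}

#' Generate a synthetic taxon abundance table with planted links
#'
#' Emits one 16S count profile per panel sample. Composition is built on
#' the log scale: a community baseline dominated by Acetobacter and
#' Lactobacillus species, a line-specific offset per taxon (so samples
#' cluster by line rather than by diet), and per-sample noise; counts are
#' multinomial draws at `config$sequencing_depth`, so every row sums to
#' exactly the stated depth. Samples of `config$wolbachia_line` receive a
#' Wolbachia weight equal to the rest of the community (about half the
#' reads); all other samples have structurally zero Wolbachia counts.
#'
#' Planted metabolite-taxon links use a Gaussian copula: the metabolite's
#' normal scores are mixed with an independent Gaussian noise vector, and
#' the mixing angle is calibrated against the *closed* relative abundance
#' of the linked taxon on the realised sample — so both the Spearman
#' sampling error at these sample sizes and the attenuation introduced by
#' compositional closure are absorbed into the calibration. The linked
#' taxon's — or every member species of a linked genus's — log weight
#' varies only through that latent variable. With `n >= 24` samples the
#' achieved Spearman correlation of the emitted relative abundances lies
#' within about 0.15 of the target (residual counting error only).
#'
#' @param config a [synth_config()].
#' @param panel a [metabolite_panel()]; one abundance sample is emitted
#'   per panel row.
#' @param line_comp_sd SD of the line-specific log-weight offsets.
#' @param sample_noise_sd SD of the per-sample log-weight noise.
#' @param link_sd log-weight amplitude of the planted-link latent
#'   variable.
#' @return list with `tab` (an [abundance_table()]) and `truth` (list
#'   with `links` data frame — metabolite, taxon, target rho, latent rho
#'   — and `wolbachia_line`).
#' @export
gen_abundance_table <- function(config, panel, line_comp_sd = 0.8,
                                sample_noise_sd = 0.3, link_sd = 2) {
  stopifnot(inherits(config, "synth_config"))
  assert_that(nrow(panel) >= 1, "panel is empty")
  taxa <- config$taxa
  spp <- names(taxa)
  ns <- nrow(panel)
  base <- .base_log_weight(taxa)
  linked_spp <- character()
  link_rows <- list()
  latent <- matrix(0, ns, length(spp), dimnames = list(NULL, spp))
  with_seed(substream_seed(config$seed, 7L), {
    link_z <- list()
    for (pl in config$planted_links) {
      members <- if (pl$taxon %in% spp) pl$taxon else spp[taxa == pl$taxon]
      v <- panel[[pl$metabolite]]
      rk <- rank(v, na.last = "keep")
      z_m <- qnorm((rk - 0.5) / sum(!is.na(v)))
      z_m[is.na(z_m)] <- 0
      link_z[[length(link_z) + 1L]] <- list(pl = pl, members = members,
                                            v = v, z_m = z_m,
                                            eps = rnorm(ns))
      linked_spp <- union(linked_spp, members)
    }
    line_off <- matrix(rnorm(config$n_lines * length(spp), 0, line_comp_sd),
                       config$n_lines, length(spp),
                       dimnames = list(config$line_ids, spp))
    logw <- matrix(base, ns, length(spp), byrow = TRUE,
                   dimnames = list(panel$sample_id, spp))
    free <- setdiff(spp, linked_spp)
    li <- match(panel$line, config$line_ids)
    logw[, free] <- logw[, free] + line_off[li, free, drop = FALSE] +
      matrix(rnorm(ns * length(free), 0, sample_noise_sd), ns)
    # initialise linked species at the naive latent mix, then calibrate
    # each link's mixing angle against the *closed* relative abundance of
    # its taxon, so compositional attenuation is absorbed
    for (lk in link_z) {
      rho0 <- 2 * sin(pi * lk$pl$rho / 6)
      z0 <- rho0 * lk$z_m + sqrt(max(0, 1 - rho0^2)) * lk$eps
      logw[, lk$members] <- rep(base[lk$members], each = ns) + link_sd * z0
      latent[, lk$members] <- z0
    }
    for (lk in link_z) {
      others <- setdiff(spp, lk$members)
      denom <- rowSums(exp(logw[, others, drop = FALSE]))
      ok <- !is.na(lk$v)
      member_base <- matrix(base[lk$members], ns, length(lk$members),
                            byrow = TRUE)
      prop_of <- function(theta) {
        z <- cos(theta) * lk$z_m + sin(theta) * lk$eps
        wm <- rowSums(exp(member_base + link_sd * z))
        wm / (wm + denom)
      }
      obj <- function(theta)
        (cor(prop_of(theta)[ok], lk$v[ok], method = "spearman") -
           lk$pl$rho)^2
      theta <- stats::optimize(obj, c(0, pi))$minimum
      z_t <- cos(theta) * lk$z_m + sin(theta) * lk$eps
      logw[, lk$members] <- member_base + link_sd * z_t
      latent[, lk$members] <- z_t
      link_rows[[length(link_rows) + 1L]] <-
        data.frame(metabolite = lk$pl$metabolite, taxon = lk$pl$taxon,
                   rho_target = lk$pl$rho, rho_latent = cos(theta),
                   stringsAsFactors = FALSE)
    }
    w <- exp(logw)
    if (!is.null(config$wolbachia_line)) {
      wolb <- spp[taxa == "Wolbachia"]
      infected <- panel$line == config$wolbachia_line
      w[infected, wolb] <- rowSums(w[infected, setdiff(spp, wolb),
                                     drop = FALSE]) / length(wolb)
    }
    counts <- t(vapply(seq_len(ns), function(i)
      as.integer(rmultinom(1, config$sequencing_depth, w[i, ])),
      integer(length(spp))))
  })
  dimnames(counts) <- list(panel$sample_id, spp)
  meta <- as.data.frame(panel)[, intersect(panel_meta_cols, names(panel))]
  tab <- abundance_table(counts, meta, taxa)
  truth <- list(links = if (length(link_rows)) do.call(rbind, link_rows)
                else NULL,
                wolbachia_line = config$wolbachia_line)
  list(tab = tab, truth = truth)
}
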