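#' Association result table container
#'
#' One record per (variant, trait) association as exported by a GWAS
#' run: variant id, 1-based coordinates, trait name, p-value, gene
#' symbol (`NA` or `""` when the variant has no clear-cut gene
#' association) and a condition tag distinguishing the basal and
#' diet-shift experiments.
#'
#' @param x data frame with columns `variant_id`, `chrom`, `pos`,
#'   `trait`, `pval`, `gene` (optional, default none) and `condition`
#'   (optional, default `"basal"`).
#' @return `x` validated with class `"association_table"` prepended.
#' @export
association_table <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  need <- c("variant_id", "chrom", "pos", "trait", "pval")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop_config("association table lacks column(s): ",
                paste(miss, collapse = ", "))
  if (!"gene" %in% names(x)) x$gene <- rep(NA_character_, nrow(x))
  if (!"condition" %in% names(x)) x$condition <- rep("basal", nrow(x))
  assert_that(all(x$pval > 0 & x$pval <= 1), "p-values must be in (0, 1]")
  key <- paste(x$variant_id, x$trait, x$condition)
  assert_that(!anyDuplicated(key),
              "variant ids must be unique within (trait, condition)")
  class(x) <- unique(c("association_table", class(x)))
  x
}

#' Keep associations below a p-value threshold
#'
#' Strict inequality (`pval < threshold`), preserving row order;
#' idempotent.
#'
#' @param x an [association_table()].
#' @param alpha p-value threshold in (0, 1); the conventional GWAS
#'   cut-off is `1e-5`.
#' @param ... unused.
#' @return the filtered [association_table()].
#' @export
filter_significant.association_table <- function(x, alpha = 1e-5, ...) {
  assert_that(alpha > 0 && alpha <= 1, "threshold must be in (0, 1]")
  out <- x[x$pval < alpha, , drop = FALSE]
  rownames(out) <- NULL
  association_table(out)
}

.has_gene <- function(gene) !is.na(gene) & nzchar(gene)

#' Count unique SNPs per trait, split by gene association
#'
#' For each trait the unique variant ids are counted and partitioned into
#' gene-associated (non-empty gene symbol) and unclear. A variant
#' annotated with a gene in any of its records counts as gene-associated.
#'
#' @param x a filtered [association_table()].
#' @return data frame `trait`, `total`, `gene_associated`, `unclear`;
#'   `total = gene_associated + unclear` for every trait.
#' @export
classify_and_count <- function(x) {
  traits <- unique(x$trait)
  out <- do.call(rbind, lapply(traits, function(tr) {
    sub <- x[x$trait == tr, ]
    with_gene <- tapply(.has_gene(sub$gene), sub$variant_id, any)
    data.frame(trait = tr, total = length(with_gene),
               gene_associated = sum(with_gene),
               unclear = sum(!with_gene), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Overlap of basal and diet-shift association tables
#'
#' Set intersections of the unique variant ids and of the unique
#' non-empty gene symbols (case-sensitive), plus per-condition unique
#' totals. Both tables should be filtered at the same threshold first.
#'
#' @param basal,shift [association_table()]s for the two conditions.
#' @return list with `shared_variants`, `shared_genes` (character
#'   vectors) and `counts` (named vector: n_basal_variants,
#'   n_shift_variants, n_basal_genes, n_shift_genes, n_shared_variants,
#'   n_shared_genes).
#' @export
overlap_associations <- function(basal, shift) {
  vb <- unique(basal$variant_id)
  vs <- unique(shift$variant_id)
  gb <- unique(basal$gene[.has_gene(basal$gene)])
  gs <- unique(shift$gene[.has_gene(shift$gene)])
  sv <- intersect(vb, vs)
  sg <- intersect(gb, gs)
  list(shared_variants = sv, shared_genes = sg,
       counts = c(n_basal_variants = length(vb),
                  n_shift_variants = length(vs),
                  n_basal_genes = length(gb),
                  n_shift_genes = length(gs),
                  n_shared_variants = length(sv),
                  n_shared_genes = length(sg)))
}

#' Prepare Manhattan-plot coordinates
#'
#' Assigns each variant a cumulative genome x-coordinate (chromosomes
#' laid end to end in the order of `chrom_lengths`) and `-log10(p)`,
#' with horizontal threshold lines at the stated significance levels
#' (defaults 1e-5 and 1e-7).
#'
#' @param x an [association_table()].
#' @param chrom_lengths named numeric vector of chromosome lengths in the
#'   desired plotting order.
#' @param thresholds p-value threshold lines.
#' @return list with `points` (data frame `variant_id`, `chrom`, `pos`,
#'   `coord`, `neg_log10_p`, `trait`) and `threshold_lines` (data frame
#'   `pval`, `neg_log10_p`).
#' @export
manhattan_prep <- function(x, chrom_lengths, thresholds = c(1e-5, 1e-7)) {
  assert_that(!is.null(names(chrom_lengths)), "chrom_lengths must be named")
  bad <- setdiff(unique(x$chrom), names(chrom_lengths))
  if (length(bad))
    stop_config("chromosome(s) without length: ", paste(bad, collapse = ", "))
  offset <- c(0, cumsum(as.numeric(chrom_lengths)))[seq_along(chrom_lengths)]
  names(offset) <- names(chrom_lengths)
  over <- x$pos > chrom_lengths[x$chrom]
  if (any(over))
    stop_config("position exceeds chromosome length for variant(s): ",
                paste(head(x$variant_id[over], 5), collapse = ", "))
  pts <- data.frame(variant_id = x$variant_id, chrom = x$chrom, pos = x$pos,
                    coord = offset[x$chrom] + x$pos,
                    neg_log10_p = -log10(x$pval), trait = x$trait,
                    stringsAsFactors = FALSE)
  list(points = pts,
       threshold_lines = data.frame(pval = thresholds,
                                    neg_log10_p = -log10(thresholds)))
}

#' Naive single-marker association scan
#'
#' A deliberately simple stand-in for a full mixed-model GWAS, intended
#' for synthetic end-to-end tests: at every biallelic site with at least
#' `min_minor_lines` lines carrying the minor allele, the trait line
#' means are regressed on allele dosage (0/1) and the two-sided p-value
#' of the slope is reported. No relatedness, inversion or symbiont
#' covariates are modelled, so results carry no claim of equivalence to
#' a production association tool.
#'
#' @param G a [genotype_matrix()].
#' @param trait_line_means named numeric vector of line means (names =
#'   line ids matching `G`).
#' @param trait trait label for the output records.
#' @param min_minor_lines minimum number of minor-allele carriers
#'   (default 4); sites failing the threshold are omitted.
#' @param condition condition tag for the output.
#' @return an [association_table()] (possibly empty, with a warning when
#'   no site is polymorphic enough).
#' @export
naive_association_scan <- function(G, trait_line_means, trait = "trait",
                                   min_minor_lines = 4,
                                   condition = "basal") {
  assert_that(min_minor_lines >= 2, "min_minor_lines must be >= 2")
  missing_lines <- setdiff(G$lines, names(trait_line_means))
  if (length(missing_lines))
    stop_config("trait means missing for line(s): ",
                paste(head(missing_lines, 5), collapse = ", "))
  y <- trait_line_means[G$lines]
  rows <- lapply(seq_len(ncol(G$calls)), function(j) {
    g <- G$calls[, j]
    ok <- !is.na(g) & !is.na(y)
    n_alt <- sum(g[ok] == 1L)
    n_ref <- sum(g[ok] == 0L)
    if (min(n_alt, n_ref) < min_minor_lines) return(NULL)
    fit <- summary(lm(y[ok] ~ g[ok]))
    pv <- fit$coefficients["g[ok]", "Pr(>|t|)"]
    data.frame(variant_id = G$sites$site_id[j], chrom = G$sites$chrom[j],
               pos = G$sites$pos[j], trait = trait, pval = pv,
               gene = NA_character_, condition = condition,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    warning("no site passed the minor-allele carrier threshold")
    return(association_table(data.frame(variant_id = character(),
                                        chrom = character(), pos = integer(),
                                        trait = character(), pval = numeric(),
                                        gene = character(),
                                        condition = character())))
  }
  association_table(do.call(rbind, rows))
}

#' Read an association TSV with flexible column names
#'
#' Supplementary-sheet exports name their columns differently; supply a
#' mapping from the required names to the file's names where they differ.
#'
#' @param path TSV path.
#' @param column_map named character vector mapping required names
#'   (`variant_id`, `chrom`, `pos`, `trait`, `pval`, `gene`,
#'   `condition`) to the file's column names.
#' @return an [association_table()].
#' @export
read_association_tsv <- function(path, column_map = character()) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  for (std in names(column_map)) {
    src <- column_map[[std]]
    if (!src %in% names(df))
      stop_config("mapped column '", src, "' not found in ", path)
    names(df)[names(df) == src] <- std
  }
  association_table(df)
}
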