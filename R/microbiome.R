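#' Taxon abundance table container
#'
#' Samples x taxa count matrix with per-sample metadata and a taxonomy
#' map assigning every taxon (species-level OTU) to a genus.
#'
#' @param counts non-negative integer matrix, rows = samples (rownames =
#'   sample ids), columns = taxa.
#' @param meta data frame with one row per sample: `sample_id`, `line`,
#'   `stage`, `sex`, `diet`, `replicate`.
#' @param taxonomy named character vector taxon -> genus covering every
#'   column of `counts`.
#' @return object of class `"abundance_table"`: list with `counts`,
#'   `meta`, `taxonomy`.
#' @export
abundance_table <- function(counts, meta, taxonomy) {
  counts <- as.matrix(counts)
  assert_that(all(counts >= 0), "counts must be non-negative")
  assert_that(!is.null(rownames(counts)) && !anyDuplicated(rownames(counts)),
              "counts needs unique sample ids as rownames")
  assert_that(!is.null(colnames(counts)), "counts needs taxon names")
  miss <- setdiff(colnames(counts), names(taxonomy))
  if (length(miss))
    stop_config("taxa missing from taxonomy: ", paste(miss, collapse = ", "))
  assert_that(identical(as.character(meta$sample_id), rownames(counts)),
              "meta$sample_id must match counts rownames in order")
  structure(list(counts = counts, meta = as.data.frame(meta),
                 taxonomy = taxonomy[colnames(counts)]),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("<abundance_table> ", nrow(x$counts), " samples x ", ncol(x$counts),
      " taxa (", length(unique(x$taxonomy)), " genera)\n", sep = "")
  invisible(x)
}

#' Per-sample relative abundance
#'
#' @param tab an [abundance_table()].
#' @return matrix of proportions; every row sums to 1.
#' @export
relative_abundance <- function(tab) {
  depth <- rowSums(tab$counts)
  zero <- depth == 0
  if (any(zero))
    stop_config("zero-depth sample(s): ",
                paste(rownames(tab$counts)[zero], collapse = ", "))
  sweep(tab$counts, 1, depth, `/`)
}

#' Retain taxa in the top 95% of at least one sample
#'
#' Within each sample, taxa are sorted by decreasing relative abundance
#' and the minimal prefix whose cumulative proportion reaches `cum`
#' (default 0.95) forms that sample's top set. A taxon is retained
#' globally iff it belongs to the top set of at least one sample — the
#' "among the top 95% most abundant in at least one sample" rule used
#' before hierarchical clustering and correlation analysis.
#'
#' @param tab an [abundance_table()].
#' @param cum cumulative-proportion cutoff.
#' @return object of class `"taxon_filter_result"`: list with `retained`
#'   (taxon names), `per_sample_top` (list of each sample's top set) and
#'   `retained_mass` (per-sample fraction of reads kept).
#' @export
top95_filter <- function(tab, cum = 0.95) {
  prop <- relative_abundance(tab)
  per_sample <- lapply(seq_len(nrow(prop)), function(i) {
    v <- sort(prop[i, ], decreasing = TRUE)
    k <- which(cumsum(v) >= cum - 1e-12)[1]
    names(v)[seq_len(k)]
  })
  names(per_sample) <- rownames(prop)
  retained <- colnames(prop)[colnames(prop) %in% unique(unlist(per_sample))]
  mass <- rowSums(prop[, retained, drop = FALSE])
  structure(list(retained = retained, per_sample_top = per_sample,
                 retained_mass = mass, cum = cum),
            class = "taxon_filter_result")
}

#' Aggregate species counts to genus level
#'
#' Sums counts within genus; metadata are preserved and the rolled-up
#' taxonomy maps each genus to itself. Total counts per sample are
#' conserved, so rollup and relative-abundance computation commute.
#'
#' @param tab an [abundance_table()].
#' @return a genus-level [abundance_table()].
#' @export
genus_rollup <- function(tab) {
  genus <- tab$taxonomy[colnames(tab$counts)]
  out <- t(rowsum(t(tab$counts), group = genus))
  abundance_table(out, tab$meta,
                  setNames(colnames(out), colnames(out)))
}

#' Exclude samples and/or taxa from an abundance table
#'
#' Removes named taxa, explicit sample ids, and all samples of listed
#' lines (the usual rule: drop the Wolbachia-infected line and the
#' Wolbachia taxon before gut-microbiome correlation). Remaining counts
#' are untouched.
#'
#' @param tab an [abundance_table()].
#' @param lines line ids whose samples are removed.
#' @param samples sample ids removed.
#' @param taxa taxon names removed.
#' @return an [abundance_table()].
#' @export
exclude_from_table <- function(tab, lines = character(),
                               samples = character(), taxa = character()) {
  drop_s <- tab$meta$sample_id %in% samples | tab$meta$line %in% lines
  if (all(drop_s)) stop_config("exclusions would remove every sample")
  keep_t <- !(colnames(tab$counts) %in% taxa |
                tab$taxonomy[colnames(tab$counts)] %in% taxa)
  assert_that(any(keep_t), "exclusions would remove every taxon")
  abundance_table(tab$counts[!drop_s, keep_t, drop = FALSE],
                  tab$meta[!drop_s, , drop = FALSE],
                  tab$taxonomy[keep_t])
}

#' Hierarchical clustering of samples by community composition
#'
#' Agglomerative clustering of the per-sample relative-abundance profiles
#' under a vegan dissimilarity (Bray-Curtis by default, the standard for
#' compositional 16S data) and a stats::hclust linkage (average by
#' default). Samples are ordered by id before clustering so ties break
#' deterministically.
#'
#' @param tab an [abundance_table()].
#' @param metric dissimilarity passed to [vegan::vegdist()].
#' @param linkage linkage method passed to [stats::hclust()].
#' @return list with `hclust` (the merge tree), `order` (sample ids in
#'   dendrogram order) and `dist` (the dissimilarity matrix).
#' @export
hcluster_samples <- function(tab, metric = "bray", linkage = "average") {
  assert_that(nrow(tab$counts) >= 2, "need at least 2 samples")
  prop <- relative_abundance(tab)
  prop <- prop[order(rownames(prop)), , drop = FALSE]
  d <- vegan::vegdist(prop, method = metric)
  hc <- hclust(d, method = linkage)
  list(hclust = hc, order = rownames(prop)[hc$order], dist = d)
}

#' Log10 transform with pseudocount
#'
#' `x -> log10(x + pseudocount)` applied to a numeric matrix or data
#' frame of non-negative values; the pseudocount is recorded as an
#' attribute. A monotone transform, so rank correlations are unchanged.
#'
#' @param x numeric matrix / data frame with values >= 0.
#' @param pseudocount added before the log (default 1).
#' @return transformed object with attribute `"pseudocount"`.
#' @export
log_transform <- function(x, pseudocount = 1) {
  num <- if (is.data.frame(x)) vapply(x, is.numeric, logical(1)) else
    rep(TRUE, ncol(as.matrix(x)))
  vals <- if (is.data.frame(x)) unlist(x[num]) else x
  assert_that(all(vals >= 0, na.rm = TRUE), "negative input to log_transform")
  if (is.data.frame(x)) {
    x[num] <- lapply(x[num], function(v) log10(v + pseudocount))
  } else {
    x <- log10(x + pseudocount)
  }
  attr(x, "pseudocount") <- pseudocount
  x
}

#' Read / write an abundance table as TSV
#'
#' Two files: a samples x taxa count TSV whose first columns are the
#' sample metadata, and a sidecar taxonomy TSV (`taxon`, `genus`).
#'
#' @param counts_path,taxonomy_path file paths.
#' @return `read_abundance_tsv` returns an [abundance_table()].
#' @export
read_abundance_tsv <- function(counts_path, taxonomy_path) {
  df <- read.delim(counts_path, comment.char = "#", check.names = FALSE,
                   stringsAsFactors = FALSE)
  tax <- read.delim(taxonomy_path, comment.char = "#",
                    stringsAsFactors = FALSE)
  meta_cols <- intersect(panel_meta_cols, names(df))
  counts <- as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE])
  rownames(counts) <- df$sample_id
  abundance_table(counts, df[, meta_cols, drop = FALSE],
                  setNames(tax$genus, tax$taxon))
}

#' Read an abundance table from a BIOM file
#'
#' Interoperability reader for the BIOM format used by 16S pipelines.
#' Genus assignments are taken from the BIOM observation metadata when
#' present, otherwise each taxon maps to itself. Sample metadata columns
#' absent from the file are filled with `NA`.
#'
#' @param path path to a BIOM file.
#' @return an [abundance_table()].
#' @export
read_abundance_biom <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("reading BIOM files requires the 'biomformat' package")
  b <- biomformat::read_biom(path)
  counts <- t(as.matrix(biomformat::biom_data(b)))   # samples x taxa
  om <- biomformat::observation_metadata(b)
  genus <- if (!is.null(om) && "genus" %in% colnames(om))
    setNames(as.character(om[colnames(counts), "genus"]), colnames(counts))
  else setNames(colnames(counts), colnames(counts))
  sm <- biomformat::sample_metadata(b)
  meta <- data.frame(sample_id = rownames(counts), stringsAsFactors = FALSE)
  for (col in c("line", "stage", "sex", "diet", "replicate"))
    meta[[col]] <- if (!is.null(sm) && col %in% colnames(sm))
      sm[rownames(counts), col] else NA
  abundance_table(counts, meta, genus)
}

#' @rdname read_abundance_tsv
#' @param tab table to write.
#' @export
write_abundance_tsv <- function(tab, counts_path, taxonomy_path) {
  df <- cbind(tab$meta, as.data.frame(tab$counts, check.names = FALSE))
  write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(taxon = names(tab$taxonomy),
                         genus = unname(tab$taxonomy)),
              taxonomy_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(counts_path)
}
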