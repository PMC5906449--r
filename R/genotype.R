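#' Biallelic genotype matrix for inbred lines
#'
#' Holds per-line calls at biallelic sites. Because the lines are inbred
#' and effectively homozygous, each call is a single allele state:
#' `0` = reference, `1` = alternative, `NA` = missing. Heterozygous or
#' multi-allelic calls in input files are treated as missing.
#'
#' @param calls integer/numeric matrix, rows = lines, columns = sites,
#'   values in \{0, 1, NA\}. Row names are line ids, column names site ids.
#' @param sites optional data frame with columns `site_id`, `chrom`,
#'   `pos` (1-based, VCF convention); defaults are derived from the
#'   column names.
#' @return object of class `"genotype_matrix"`: list with `calls`,
#'   `lines`, `sites`.
#' @export
genotype_matrix <- function(calls, sites = NULL) {
  calls <- as.matrix(calls)
  assert_that(!is.null(rownames(calls)), "calls must have line ids as rownames")
  assert_that(!is.null(colnames(calls)), "calls must have site ids as colnames")
  assert_that(all(calls %in% c(0, 1) | is.na(calls)),
              "calls must be 0 (ref), 1 (alt) or NA (missing)")
  assert_that(!anyDuplicated(rownames(calls)), "line ids must be unique")
  assert_that(!anyDuplicated(colnames(calls)), "site ids must be unique")
  assert_that(all(colSums(!is.na(calls)) >= 1),
              "every site needs at least one non-missing call")
  mode(calls) <- "integer"
  if (is.null(sites)) {
    sites <- data.frame(site_id = colnames(calls), chrom = "chr1",
                        pos = seq_len(ncol(calls)), stringsAsFactors = FALSE)
  }
  assert_that(all(c("site_id", "chrom", "pos") %in% names(sites)),
              "sites needs site_id, chrom, pos")
  assert_that(identical(as.character(sites$site_id), colnames(calls)),
              "sites$site_id must match calls colnames in order")
  structure(list(calls = calls, lines = rownames(calls), sites = sites),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", length(x$lines), " lines x ",
      nrow(x$sites), " sites; ",
      sum(is.na(x$calls)), " missing calls\n", sep = "")
  invisible(x)
}

#' Read / write a genotype matrix as a line x site TSV
#'
#' The TSV layout has one row per line: a `line` column followed by one
#' column per site, with values `ref`, `alt` or `NA`/empty. This is the
#' dialect the synthetic generator writes.
#'
#' @param path file path.
#' @return `read_genotype_tsv` returns a [genotype_matrix()].
#' @export
read_genotype_tsv <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                   check.names = FALSE)
  assert_that("line" %in% names(df), "genotype TSV needs a 'line' column")
  lines <- df$line
  df$line <- NULL
  calls <- t(vapply(seq_len(nrow(df)), function(i) {
    v <- as.character(unlist(df[i, ]))
    ifelse(v == "ref", 0L, ifelse(v == "alt", 1L, NA_integer_))
  }, integer(ncol(df))))
  dimnames(calls) <- list(lines, names(df))
  genotype_matrix(calls)
}

#' @rdname read_genotype_tsv
#' @param G genotype matrix to write.
#' @export
write_genotype_tsv <- function(G, path) {
  lab <- matrix(c("ref", "alt")[G$calls + 1L], nrow(G$calls),
                dimnames = dimnames(G$calls))
  df <- data.frame(line = G$lines, lab, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genotype matrix from a VCF file
#'
#' Keeps biallelic SNP records only. Homozygous-reference genotypes map to
#' `ref`, homozygous-alternative to `alt`; heterozygous, multi-allelic and
#' uncalled genotypes become missing (the lines are inbred, so residual
#' heterozygosity is treated as no-call). Coordinates stay 1-based as in
#' the VCF.
#'
#' @param path path to a VCF (plain or bgzipped).
#' @return a [genotype_matrix()] with one row per sample column.
#' @export
read_genotype_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  biallelic <- !grepl(",", fix[, "ALT"]) & nchar(fix[, "REF"]) == 1 &
    nchar(fix[, "ALT"]) == 1
  gt <- vcfR::extract.gt(v, element = "GT")[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]
  code <- function(g) {
    g <- sub("\\|", "/", g)
    ifelse(g %in% c("0/0", "0"), 0L, ifelse(g %in% c("1/1", "1"), 1L,
                                            NA_integer_))
  }
  calls <- t(apply(gt, 2, code))
  site_id <- ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                    paste0(fix[, "CHROM"], ":", fix[, "POS"]), fix[, "ID"])
  colnames(calls) <- site_id
  sites <- data.frame(site_id = site_id, chrom = fix[, "CHROM"],
                      pos = as.integer(fix[, "POS"]), stringsAsFactors = FALSE)
  keep <- colSums(!is.na(calls)) >= 1
  genotype_matrix(calls[, keep, drop = FALSE], sites[keep, , drop = FALSE])
}
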