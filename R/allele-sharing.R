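#' Percent of alleles of one class shared by a pair of lines
#'
#' For two inbred lines the shared-allele percent for a class (reference
#' or alternative) is
#' `100 * (# sites where both lines carry that allele) /
#'        (# sites where both lines have a non-missing call)`.
#' With no missing calls the reference and alternative percents of a pair
#' sum to 100 only when the two call vectors are identical; in general
#' they sum to 100 minus the percent of discordant sites.
#'
#' @param G a [genotype_matrix()].
#' @param line_a,line_b line ids.
#' @param allele_class `"alt"` or `"ref"`.
#' @return percent in `[0, 100]`.
#' @export
pairwise_sharing <- function(G, line_a, line_b, allele_class = c("alt", "ref")) {
  allele_class <- match.arg(allele_class)
  for (l in c(line_a, line_b))
    if (!l %in% G$lines) stop_config("line not in genotype matrix: ", l)
  a <- G$calls[line_a, ]
  b <- G$calls[line_b, ]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) stop_config("no jointly callable sites for pair ",
                            line_a, " / ", line_b)
  cls <- if (allele_class == "alt") 1L else 0L
  100 * sum(a[ok] == cls & b[ok] == cls) / sum(ok)
}

#' Distribution of pairwise shared-allele percents across all line pairs
#'
#' Computes [pairwise_sharing()] for every pair of lines and summarises
#' the values as a histogram; the mode is reported as the midpoint of the
#' most populated bin (ties broken towards the lower bin). This is the
#' empirical null against which the within-group sharing of a candidate
#' line group (for example the virago lines) is compared.
#'
#' @param G a [genotype_matrix()].
#' @param allele_class `"alt"` or `"ref"`.
#' @param bin_width histogram bin width in percentage points.
#' @return object of class `"sharing_distribution"`: list with `pairs`
#'   (data frame `line_a`, `line_b`, `percent`), `allele_class`,
#'   `bin_width` and `mode`.
#' @export
sharing_distribution <- function(G, allele_class = c("alt", "ref"),
                                 bin_width = 0.5) {
  allele_class <- match.arg(allele_class)
  assert_that(length(G$lines) >= 3, "need at least 3 lines")
  prs <- combn(G$lines, 2)
  pct <- apply(prs, 2, function(p)
    pairwise_sharing(G, p[1], p[2], allele_class))
  brk <- seq(0, 100 + bin_width, by = bin_width)
  bin <- findInterval(pct, brk, rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = length(brk) - 1L)
  top <- which.max(counts)                         # which.max -> lowest tie
  structure(list(pairs = data.frame(line_a = prs[1, ], line_b = prs[2, ],
                                    percent = pct, stringsAsFactors = FALSE),
                 allele_class = allele_class, bin_width = bin_width,
                 mode = brk[top] + bin_width / 2),
            class = "sharing_distribution")
}

#' Mean within-group shared-allele percent
#'
#' The single summary value for a group of lines: the mean of
#' [pairwise_sharing()] over all pairs within the group. Compared against
#' the mode of the all-pairs [sharing_distribution()] to judge whether
#' the group is unusually (dis)similar.
#'
#' @inheritParams pairwise_sharing
#' @param group character vector of at least two line ids.
#' @return percent in `[0, 100]`.
#' @export
group_sharing <- function(G, group, allele_class = c("alt", "ref")) {
  allele_class <- match.arg(allele_class)
  assert_that(length(group) >= 2, "group must have >= 2 lines")
  missing_lines <- setdiff(group, G$lines)
  if (length(missing_lines))
    stop_config("group line(s) absent from matrix: ",
                paste(missing_lines, collapse = ", "))
  prs <- combn(group, 2)
  mean(apply(prs, 2, function(p)
    pairwise_sharing(G, p[1], p[2], allele_class)))
}

#' Detect alleles unique to a group of lines
#'
#' A site is group-unique for an allele class when every group member has
#' a non-missing call of that class and every non-group line with a
#' non-missing call carries the other class. Both class lists are
#' returned; they are disjoint by construction.
#'
#' @inheritParams pairwise_sharing
#' @param group non-empty proper subset of the matrix lines.
#' @return object of class `"group_allele_report"`: list with `group`,
#'   `unique_ref_sites`, `unique_alt_sites` (site ids) and
#'   `missing_policy`.
#' @export
unique_alleles <- function(G, group) {
  assert_that(length(group) >= 1, "group must be non-empty")
  missing_lines <- setdiff(group, G$lines)
  if (length(missing_lines))
    stop_config("group line(s) absent from matrix: ",
                paste(missing_lines, collapse = ", "))
  if (length(group) >= length(G$lines))
    stop_config("group must be a proper subset of the lines")
  gi <- match(group, G$lines)
  grp <- G$calls[gi, , drop = FALSE]
  oth <- G$calls[-gi, , drop = FALSE]
  pick <- function(cls) {
    grp_all <- colSums(grp == cls) == length(gi)       # NA calls fail this
    grp_all[is.na(grp_all)] <- FALSE
    oth_none <- colSums(oth == cls, na.rm = TRUE) == 0
    colnames(G$calls)[which(grp_all & oth_none)]
  }
  structure(list(group = group,
                 unique_ref_sites = pick(0L),
                 unique_alt_sites = pick(1L),
                 missing_policy = "group calls must be non-missing; non-group missing calls are ignored"),
            class = "group_allele_report")
}

#' @export
print.group_allele_report <- function(x, ...) {
  cat("<group_allele_report> group of ", length(x$group), ": ",
      length(x$unique_ref_sites), " unique ref, ",
      length(x$unique_alt_sites), " unique alt sites\n", sep = "")
  invisible(x)
}

#' Write a sharing distribution as TSV plus JSON summary
#'
#' @param dist a [sharing_distribution()].
#' @param group_value optional within-group value to record alongside the
#'   mode.
#' @param path_tsv,path_json output paths.
#' @export
write_sharing <- function(dist, path_tsv, path_json, group_value = NULL) {
  write.table(dist$pairs, path_tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(list(allele_class = dist$allele_class,
                            bin_width = dist$bin_width, mode = dist$mode,
                            group_value = group_value),
                       path_json, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path_tsv)
}
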