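#' Generate a synthetic biallelic genotype matrix with planted unique alleles
#'
#' Sites are independent: each gets an alternative-allele frequency drawn
#' from a Beta distribution (`config$maf_spectrum`, clipped to
#' (0.02, 0.98)) and per-line calls are Bernoulli draws at that frequency
#' — an inbred-panel model with no linkage structure. On top of this
#' background the generator plants exactly `n_unique_alt` sites at which
#' every member of `config$unique_group` carries the alternative allele
#' while every other line carries the reference, and `n_unique_ref` sites
#' with the classes swapped. After the optional missing-call mask is
#' applied, background sites that have become group-unique by chance are
#' repaired (one non-group line is set to the group's allele), so that at
#' any missing rate the planted alternative/reference lists are exactly
#' the group-unique sites discoverable by a scan over non-missing calls —
#' except where a group member's own call was masked, which is the
#' realistic failure mode recovery tests measure.
#'
#' @param config a [synth_config()].
#' @return list with `G` (a [genotype_matrix()]) and `truth` (list with
#'   `unique_alt_sites`, `unique_ref_sites`, `group`, `alt_freq`).
#' @export
gen_genotype_matrix <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_lines
  m <- config$n_sites
  group <- config$unique_group
  gi <- match(group, config$line_ids)
  chroms <- c("2L", "2R", "3L", "3R", "X")
  sites <- data.frame(site_id = sprintf("s%05d", seq_len(m)),
                      chrom = chroms[((seq_len(m) - 1) %% length(chroms)) + 1],
                      pos = ((seq_len(m) - 1) %/% length(chroms)) * 1000 + 1,
                      stringsAsFactors = FALSE)
  with_seed(substream_seed(config$seed, 5L), {
    f <- stats::rbeta(m, config$maf_spectrum[1], config$maf_spectrum[2])
    f <- pmin(pmax(f, 0.02), 0.98)
    calls <- vapply(seq_len(m), function(j) rbinom(n, 1L, f[j]), integer(n))
    planted <- sample(m, config$n_unique_alt + config$n_unique_ref)
    alt_sites <- sort(planted[seq_len(config$n_unique_alt)])
    ref_sites <- sort(setdiff(planted, alt_sites))
    if (length(gi)) {
      calls[gi, alt_sites] <- 1L
      calls[-gi, alt_sites] <- 0L
      calls[gi, ref_sites] <- 0L
      calls[-gi, ref_sites] <- 1L
    }
  })
  with_seed(substream_seed(config$seed, 6L), {
    if (config$genotype_missing_rate > 0) {
      mask <- matrix(runif(n * m) < config$genotype_missing_rate, n, m)
      calls[mask] <- NA_integer_
      # keep the container invariant: each site retains >= 1 call
      dead <- which(colSums(!is.na(calls)) == 0)
      for (j in dead) calls[sample(n, 1), j] <- rbinom(1, 1L, f[j])
    }
    # repair background sites that are group-unique by chance
    if (length(gi) && length(gi) < n) {
      background <- setdiff(seq_len(m), c(alt_sites, ref_sites))
      for (cls in c(1L, 0L)) {
        grp_all <- colSums(calls[gi, background, drop = FALSE] == cls) ==
          length(gi)
        oth <- calls[-gi, background, drop = FALSE]
        oth_none <- colSums(oth == cls, na.rm = TRUE) == 0
        accidental <- background[which(grp_all & oth_none)]
        for (j in accidental) {
          fix_line <- setdiff(seq_len(n), gi)[1]
          calls[fix_line, j] <- cls
        }
      }
    }
  })
  dimnames(calls) <- list(config$line_ids, sites$site_id)
  truth <- list(unique_alt_sites = sites$site_id[alt_sites],
                unique_ref_sites = sites$site_id[ref_sites],
                group = group, alt_freq = f)
  list(G = genotype_matrix(calls, sites), truth = truth)
}
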