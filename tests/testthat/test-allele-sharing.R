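toy_matrix <- function(calls, lines = NULL) {
  lines <- lines %||% paste0("L", seq_len(nrow(calls)))
  dimnames(calls) <- list(lines, sprintf("s%02d", seq_len(ncol(calls))))
  genotype_matrix(calls)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("pairwise sharing matches hand-counted fractions", {
  # 10 sites: A alt at 1..3, B alt at {3,4}; both-alt = 1, both-ref = 6
  calls <- rbind(A = c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0),
                 B = c(0, 0, 1, 1, 0, 0, 0, 0, 0, 0),
                 C = rep(0, 10))
  G <- toy_matrix(calls, c("A", "B", "C"))
  expect_equal(pairwise_sharing(G, "A", "B", "alt"), 10)
  expect_equal(pairwise_sharing(G, "A", "B", "ref"), 60)

  # identical call vectors without missing: ref% + alt% = 100
  expect_equal(pairwise_sharing(G, "C", "C", "ref") +
                 pairwise_sharing(G, "C", "C", "alt"), 100)
  expect_error(pairwise_sharing(G, "A", "Z", "alt"), "not in genotype")
})

test_that("sharing distribution enumerates all pairs with a modal bin", {
  calls <- rbind(c(1, 1, 0, 0), c(1, 1, 0, 0), c(1, 1, 0, 0))
  G <- toy_matrix(calls)
  d <- sharing_distribution(G, "alt", bin_width = 0.5)
  expect_equal(nrow(d$pairs), 3)
  expect_true(all(d$pairs$percent == 50))
  expect_equal(d$mode, 50.25)  # midpoint of the bin holding 50

  # 4-line toy matrix: 6 pair values equal brute-force enumeration
  set.seed(4)
  calls4 <- matrix(rbinom(4 * 12, 1, 0.4), 4, 12)
  G4 <- toy_matrix(calls4)
  d4 <- sharing_distribution(G4, "ref")
  expect_equal(nrow(d4$pairs), choose(4, 2))
  for (i in seq_len(nrow(d4$pairs)))
    expect_equal(d4$pairs$percent[i],
                 brute_sharing(G4, d4$pairs$line_a[i], d4$pairs$line_b[i],
                               "ref"))
})

test_that("group sharing is the mean over within-group pairs", {
  set.seed(9)
  calls <- matrix(rbinom(5 * 20, 1, 0.5), 5, 20)
  G <- toy_matrix(calls)
  expect_equal(group_sharing(G, c("L1", "L2"), "alt"),
               pairwise_sharing(G, "L1", "L2", "alt"))
  hand <- mean(c(brute_sharing(G, "L1", "L2", "alt"),
                 brute_sharing(G, "L1", "L3", "alt"),
                 brute_sharing(G, "L2", "L3", "alt")))
  expect_equal(group_sharing(G, c("L1", "L2", "L3"), "alt"), hand)
  expect_error(group_sharing(G, c("L1", "LX"), "alt"), "absent")
})

test_that("group-unique allele detection matches planted toys", {
  # identical lines: nothing is unique
  G0 <- toy_matrix(matrix(rep(c(1, 0), each = 4), 4, 2))
  r0 <- unique_alleles(G0, c("L1", "L2"))
  expect_length(r0$unique_alt_sites, 0)
  expect_length(r0$unique_ref_sites, 0)

  # 4 x 10 toy with 2 planted group-unique alt sites (s01, s07)
  calls <- matrix(0L, 4, 10)
  calls[1:2, c(1, 7)] <- 1L
  calls[3, 4] <- 1L; calls[4, c(4, 9)] <- 1L
  G <- toy_matrix(calls)
  rep_ <- unique_alleles(G, c("L1", "L2"))
  expect_equal(rep_$unique_alt_sites, c("s01", "s07"))
  # report is invariant to the order of non-group lines
  G2 <- toy_matrix(calls[c(1, 2, 4, 3), ], c("L1", "L2", "L4", "L3"))
  expect_equal(unique_alleles(G2, c("L1", "L2"))$unique_alt_sites,
               c("s01", "s07"))
  expect_error(unique_alleles(G, paste0("L", 1:4)), "proper subset")
})

test_that("all sharing ops equal the brute-force oracle on random matrices", {
  for (s in 1:5) {
    set.seed(s)
    n <- sample(4:6, 1)
    calls <- matrix(rbinom(n * 50, 1, runif(1, 0.2, 0.8)), n, 50)
    calls[runif(n * 50) < 0.1] <- NA      # ~10% missing calls
    ok <- colSums(!is.na(calls)) >= 1
    G <- toy_matrix(calls[, ok, drop = FALSE])
    for (cls in c("ref", "alt")) {
      expect_equal(pairwise_sharing(G, "L1", "L2", cls),
                   brute_sharing(G, "L1", "L2", cls))
      grp <- c("L1", "L3")
      rep_ <- unique_alleles(G, grp)
      want <- if (cls == "alt") rep_$unique_alt_sites else
        rep_$unique_ref_sites
      expect_equal(want, brute_unique(G, grp, cls))
    }
  }
})

test_that("planted unique-allele recovery degrades monotonically with missingness", {
  recovered <- vapply(c(0, 0.15, 0.35), function(miss) {
    cfg <- synth_config(n_lines = 12, n_sites = 300, n_unique_alt = 30,
                        n_unique_ref = 8, unique_group = c("L1", "L2"),
                        genotype_missing_rate = miss, seed = 21)
    gg <- gen_genotype_matrix(cfg)
    rep_ <- unique_alleles(gg$G, c("L1", "L2"))
    expect_true(all(rep_$unique_alt_sites %in% gg$truth$unique_alt_sites))
    expect_true(all(rep_$unique_ref_sites %in% gg$truth$unique_ref_sites))
    length(rep_$unique_alt_sites) + length(rep_$unique_ref_sites)
  }, numeric(1))
  expect_equal(recovered[1], 38)          # exact at missing rate 0
  expect_true(all(diff(recovered) <= 0))  # graceful degradation
})

test_that("VCF genotypes load with inbred-line call coding", {
  vcf <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "L1", "L2", "L3", sep = "\t"),
           paste("2L", "100", "snp1", "A", "T", ".", ".", ".", "GT",
                 "0/0", "1/1", "0/1", sep = "\t"),     # het -> missing
           paste("2L", "200", ".", "G", "C", ".", ".", ".", "GT",
                 "1/1", "1/1", "./.", sep = "\t"),
           paste("3R", "50", "multi", "G", "C,T", ".", ".", ".", "GT",
                 "1/1", "0/0", "0/0", sep = "\t"))     # multi-allelic: dropped
  f <- tempfile(fileext = ".vcf")
  writeLines(vcf, f)
  G <- read_genotype_vcf(f)
  expect_equal(G$lines, c("L1", "L2", "L3"))
  expect_equal(ncol(G$calls), 2)
  expect_equal(unname(G$calls[, "snp1"]), c(0L, 1L, NA))
  expect_equal(unname(G$calls[, "2L:200"]), c(1L, 1L, NA))
  expect_equal(G$sites$pos, c(100L, 200L))
})

test_that("genotype TSV round-trips and sharing summary writes JSON", {
  set.seed(2)
  calls <- matrix(rbinom(4 * 15, 1, 0.5), 4, 15)
  calls[1, 3] <- NA
  G <- toy_matrix(calls)
  f <- tempfile(fileext = ".tsv")
  write_genotype_tsv(G, f)
  G2 <- read_genotype_tsv(f)
  expect_equal(G2$calls, G$calls)
  d <- sharing_distribution(G, "alt")
  js <- tempfile(fileext = ".json")
  write_sharing(d, tempfile(fileext = ".tsv"), js,
                group_value = group_sharing(G, c("L1", "L2"), "alt"))
  got <- jsonlite::read_json(js)
  expect_equal(got$mode, d$mode)
})
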