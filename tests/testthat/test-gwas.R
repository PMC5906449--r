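toy_assoc <- function(pvals, genes = NA, traits = "t",
                      condition = "basal", prefix = "v") {
  n <- length(pvals)
  if (n == 0)
    return(association_table(data.frame(
      variant_id = character(0), chrom = character(0), pos = integer(0),
      trait = character(0), pval = numeric(0), stringsAsFactors = FALSE)))
  association_table(data.frame(
    variant_id = paste0(prefix, seq_len(n)), chrom = "2L",
    pos = seq_len(n) * 100, trait = rep_len(traits, n), pval = pvals,
    gene = rep_len(genes, n), condition = condition,
    stringsAsFactors = FALSE))
}

test_that("significance filtering is strict and idempotent", {
  t0 <- toy_assoc(numeric(0))
  expect_equal(nrow(filter_significant(t0, 1e-5)), 0)

  tab <- toy_assoc(c(1e-6, 2e-5, 1e-4))
  kept <- filter_significant(tab, 1e-5)
  expect_equal(kept$variant_id, "v1")
  expect_equal(filter_significant(kept, 1e-5), kept)   # idempotent
  expect_equal(nrow(filter_significant(tab, 1)), 3)    # threshold 1: identity
  # boundary is excluded: p exactly at the threshold is dropped
  expect_equal(nrow(filter_significant(toy_assoc(1e-5), 1e-5)), 0)
})

test_that("per-trait counts partition into gene-associated and unclear", {
  tab <- toy_assoc(rep(1e-6, 5), genes = c("g1", "g2", "g3", NA, ""))
  cc <- classify_and_count(tab)
  expect_equal(cc$total, 5)
  expect_equal(cc$gene_associated, 3)
  expect_equal(cc$unclear, 2)
  expect_equal(cc$total, cc$gene_associated + cc$unclear)

  all_gene <- toy_assoc(rep(1e-6, 4), genes = "gX")
  expect_equal(classify_and_count(all_gene)$unclear, 0)
})

test_that("condition overlap intersects variants and gene symbols", {
  b <- toy_assoc(rep(1e-6, 5), genes = c("gA", "gB", "gC", NA, "gD"),
                 prefix = "s")
  s <- toy_assoc(rep(1e-6, 4), genes = c("gB", "gC", "gE", "gA"),
                 condition = "diet_shift", prefix = "x")
  s$variant_id[1:2] <- c("s1", "s2")   # two shared variants
  s <- association_table(as.data.frame(s))
  ov <- overlap_associations(b, s)
  expect_setequal(ov$shared_variants, c("s1", "s2"))
  expect_setequal(ov$shared_genes, c("gA", "gB", "gC"))
  expect_equal(unname(ov$counts["n_shared_variants"]), 2)
  expect_equal(unname(ov$counts["n_shared_genes"]), 3)
  # shared sets are symmetric
  vo <- overlap_associations(s, b)
  expect_setequal(vo$shared_variants, ov$shared_variants)
  expect_setequal(vo$shared_genes, ov$shared_genes)
  # disjoint tables
  ov0 <- overlap_associations(toy_assoc(1e-6, prefix = "a"),
                              toy_assoc(1e-6, prefix = "b"))
  expect_length(ov0$shared_variants, 0)
})

test_that("manhattan preparation lays chromosomes end to end", {
  tab <- association_table(data.frame(
    variant_id = c("a", "b"), chrom = c("c1", "c2"), pos = c(30, 10),
    trait = "t", pval = c(1e-6, 1e-3)))
  mp <- manhattan_prep(tab, c(c1 = 100, c2 = 50))
  expect_equal(mp$points$coord, c(30, 110))
  expect_equal(mp$points$neg_log10_p, c(6, 3))
  expect_equal(mp$threshold_lines$neg_log10_p, c(5, 7))
  single <- manhattan_prep(tab[tab$chrom == "c1", ], c(c1 = 100))
  expect_equal(single$points$coord, single$points$pos)
  bad <- association_table(data.frame(variant_id = "z", chrom = "c1",
                                      pos = 200, trait = "t", pval = 0.5))
  expect_error(manhattan_prep(bad, c(c1 = 100)), "exceeds")
})

test_that("the naive scan finds a planted additive effect and respects permutation", {
  cfg <- synth_config(n_lines = 35, n_sites = 150, seed = 12)
  G <- gen_genotype_matrix(cfg)$G
  set.seed(12)
  y <- setNames(rnorm(35), G$lines)
  # plant a 2-SD additive effect at the first common site
  mafs <- colMeans(G$calls == 1)
  site <- which(mafs > 0.3 & mafs < 0.7)[1]
  y <- y + 2 * G$calls[, site]
  tab <- naive_association_scan(G, y, trait = "tag")
  expect_equal(tab$variant_id[which.min(tab$pval)],
               colnames(G$calls)[site])
  # permutation control: shuffled traits lose the association
  set.seed(1)
  worse <- replicate(25, {
    yp <- setNames(sample(y), names(y))
    min(naive_association_scan(G, yp, trait = "tag")$pval)
  })
  expect_gt(mean(worse > tab$pval[which.min(tab$pval)]), 0.95)
})

test_that("association TSV reader honours a column mapping", {
  f <- tempfile(fileext = ".tsv")
  write.table(data.frame(SNP = "v1", CHR = "2L", BP = 100, PHENO = "tag",
                         P = 1e-6, GENE = "gA"),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  tab <- read_association_tsv(f, column_map = c(
    variant_id = "SNP", chrom = "CHR", pos = "BP", trait = "PHENO",
    pval = "P", gene = "GENE"))
  expect_s3_class(tab, "association_table")
  expect_equal(tab$pval, 1e-6)
})
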