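toy_tab <- function(counts, genera = NULL) {
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("S", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("t", seq_len(ncol(counts)))
  meta <- data.frame(sample_id = rownames(counts),
                     line = paste0("L", seq_len(nrow(counts))),
                     stage = "adult", sex = "female", diet = "SD",
                     replicate = 1, stringsAsFactors = FALSE)
  genera <- genera %||% setNames(colnames(counts), colnames(counts))
  abundance_table(counts, meta, genera)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("relative abundance closes each sample to 1", {
  tab <- toy_tab(matrix(c(50, 30, 20), 1))
  expect_equal(unname(relative_abundance(tab)[1, ]), c(0.5, 0.3, 0.2))
  set.seed(3)
  tab2 <- toy_tab(matrix(rpois(60, 40), 6, 10))
  expect_equal(unname(rowSums(relative_abundance(tab2))), rep(1, 6),
               tolerance = 1e-12)
  tab0 <- toy_tab(rbind(c(1, 2), c(0, 0)))
  expect_error(relative_abundance(tab0), "S2")
})

test_that("top-95% filter keeps the minimal cumulative prefix per sample", {
  tab <- toy_tab(matrix(c(50, 30, 16, 4), 1))
  res <- top95_filter(tab)
  expect_equal(res$retained, c("t1", "t2", "t3"))   # cumsum .5, .8, .96

  # a taxon rare everywhere but dominant once is retained globally
  counts <- rbind(c(96, 2, 2), c(4, 48, 48), c(96, 2, 2))
  res2 <- top95_filter(toy_tab(counts))
  expect_true("t1" %in% res2$retained)

  # equality with independent enumeration on random tables
  for (s in 1:5) {
    set.seed(s)
    counts <- matrix(rpois(8 * 12, exp(runif(96, 0, 5))), 8, 12)
    counts[counts == 0] <- 1
    tab3 <- toy_tab(counts)
    expect_setequal(top95_filter(tab3)$retained,
                    brute_top95(relative_abundance(tab3)))
  }

  # monotone: adding reads to a retained taxon never drops it
  tab4 <- toy_tab(rbind(c(60, 30, 10), c(10, 80, 10)))
  before <- top95_filter(tab4)$retained
  boosted <- tab4$counts; boosted[, before[1]] <- boosted[, before[1]] + 100
  after <- top95_filter(toy_tab(boosted))$retained
  expect_true(before[1] %in% after)
})

test_that("genus rollup sums member species and commutes with closure", {
  counts <- matrix(c(10, 15, 7, 20, 5, 8), 2, 3, byrow = FALSE)
  genera <- c(t1 = "Lactobacillus", t2 = "Lactobacillus", t3 = "Acetobacter")
  colnames(counts) <- names(genera)
  tab <- toy_tab(counts, genera)
  rolled <- genus_rollup(tab)
  expect_equal(unname(rolled$counts[, "Lactobacillus"]),
               unname(counts[, 1] + counts[, 2]))
  expect_equal(unname(rolled$counts[, "Acetobacter"]), unname(counts[, 3]))
  expect_equal(rowSums(rolled$counts), rowSums(tab$counts))  # conservation
  # rollup then closure == closure then column aggregation
  a <- relative_abundance(rolled)
  b <- relative_abundance(tab)
  expect_equal(unname(a[, "Lactobacillus"]), unname(b[, 1] + b[, 2]),
               tolerance = 1e-12)
})

test_that("exclusions drop the named lines and taxa and nothing else", {
  counts <- matrix(rpois(4 * 3, 50), 4, 3)
  genera <- c(t1 = "Acetobacter", t2 = "Lactobacillus", t3 = "Wolbachia")
  colnames(counts) <- names(genera)
  tab <- toy_tab(counts, genera)
  expect_equal(exclude_from_table(tab)$counts, tab$counts)
  no_w <- exclude_from_table(tab, taxa = "Wolbachia")
  expect_false("t3" %in% colnames(no_w$counts))
  no_l2 <- exclude_from_table(tab, lines = "L2")
  expect_equal(nrow(no_l2$counts), 3)
  expect_false("L2" %in% no_l2$meta$line)
  expect_error(exclude_from_table(tab, lines = paste0("L", 1:4)),
               "every sample")
})

test_that("hierarchical clustering reproduces hand-computed Bray-Curtis heights", {
  # three samples; A and B identical -> merge at height 0
  counts <- rbind(A = c(50, 50, 0), B = c(50, 50, 0), C = c(0, 20, 80))
  tab <- toy_tab(counts)
  hc <- hcluster_samples(tab)
  expect_equal(min(hc$hclust$height), 0)
  # Bray-Curtis(A, C) on proportions: 1 - 2*sum(min)/2 = 0.8
  d <- as.matrix(hc$dist)
  expect_equal(d["A", "C"], 0.8, tolerance = 1e-12)
  # average linkage: C joins {A,B} at mean(d(AC), d(BC)) = 0.8
  expect_equal(max(hc$hclust$height), 0.8, tolerance = 1e-12)
})

test_that("samples cluster by line rather than by diet on synthetic data", {
  cfg <- synth_config(n_lines = 4, n_replicates = 2, seed = 17)
  lsd <- gen_metabolite_panel(cfg, diet = "LSD")$panel
  shifted <- gen_diet_shift(lsd, cfg)$panel
  adults <- shifted[shifted$stage == "adult" & shifted$sex == "female", ]
  tab <- gen_abundance_table(cfg, adults)$tab
  hc <- hcluster_samples(tab)
  k4 <- cutree(hc$hclust, k = 4)
  lines <- tab$meta$line[match(names(k4), tab$meta$sample_id)]
  expect_gte(adjusted_rand(k4, lines), 0.9)
  diets <- tab$meta$diet[match(names(k4), tab$meta$sample_id)]
  expect_lt(adjusted_rand(k4, diets), 0.3)
})

test_that("log transform is exact and rank-preserving", {
  expect_equal(log_transform(0, pseudocount = 1), 0, ignore_attr = TRUE)
  expect_equal(log_transform(99, pseudocount = 1), 2, ignore_attr = TRUE)
  expect_error(log_transform(-3), "negative")
  set.seed(6)
  x <- rexp(15); y <- rexp(15)
  r0 <- spearman_matrix(data.frame(x, y))$r["x", "y"]
  r1 <- spearman_matrix(data.frame(x = as.numeric(log_transform(x)),
                                   y = y))$r["x", "y"]
  expect_equal(r1, r0, tolerance = 1e-12)
})

test_that("BIOM files load into abundance tables", {
  counts <- matrix(c(12, 0, 5, 30, 2, 9), 2, 3,
                   dimnames = list(c("S1", "S2"), c("t1", "t2", "t3")))
  f <- tempfile(fileext = ".biom")
  biomformat::write_biom(biomformat::make_biom(t(counts)), f)
  tab <- read_abundance_biom(f)
  expect_equal(tab$counts[c("S1", "S2"), c("t1", "t2", "t3")], counts)
  expect_equal(unname(tab$taxonomy["t2"]), "t2")
})

test_that("abundance TSV writers round-trip", {
  cfg <- synth_config(n_lines = 3, seed = 5)
  p <- gen_metabolite_panel(cfg)$panel
  tab <- gen_abundance_table(cfg, p)$tab
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  write_abundance_tsv(tab, f1, f2)
  tab2 <- read_abundance_tsv(f1, f2)
  expect_equal(tab2$counts, tab$counts)
  expect_equal(tab2$taxonomy, tab$taxonomy)
})
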