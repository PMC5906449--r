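tiny_panel <- function(x, metabolite = "TAG") {
  x <- x - min(x) + 1   # amounts must be non-negative; k-means geometry
  metabolite_panel(data.frame(line = paste0("L", seq_along(x)),
                              stage = "adult", sex = "male", diet = "SD",
                              replicate = 1,
                              setNames(data.frame(x), metabolite)))
}

test_that("k-means separates well-separated clouds and matches brute force", {
  set.seed(7)
  x <- c(rnorm(10, 20), rnorm(10, 30))
  p <- tiny_panel(x)
  cl <- kmeans_metabotypes(p, k = 2, seed = 1)
  expect_equal(length(unique(cl$cluster[1:10])), 1)
  expect_equal(length(unique(cl$cluster[11:20])), 1)
  expect_true(cl$cluster[1] != cl$cluster[20])

  # 6 points in 1D: WSS equals the exhaustive minimum over 2-partitions
  pts <- c(0.1, 0.4, 0.35, 2.2, 2.9, 2.5)
  cl6 <- kmeans_metabotypes(tiny_panel(pts), k = 2, n_init = 50, seed = 3)
  expect_equal(cl6$wss, brute_kmeans2_wss(pts), tolerance = 1e-12)

  expect_identical(kmeans_metabotypes(p, 2, seed = 9)$cluster,
                   kmeans_metabotypes(p, 2, seed = 9)$cluster)
  expect_error(kmeans_metabotypes(tiny_panel(c(1, 1, 1)), k = 2),
               "distinct")
})

test_that("PCA matches an independent eigen-decomposition", {
  # perfectly collinear columns: PC1 carries all variance
  df <- metabolite_panel(data.frame(line = paste0("L", 1:5), stage = "adult",
                                    sex = "male", diet = "SD", replicate = 1,
                                    a = 1:5, b = 2 * (1:5)))
  pc <- panel_pca(df)
  expect_equal(pc$var_explained[1], 1, tolerance = 1e-12)

  set.seed(11)
  x <- matrix(rnorm(30, mean = 10), 10, 3)
  p3 <- metabolite_panel(data.frame(line = paste0("L", 1:10),
                                    stage = "adult", sex = "male",
                                    diet = "SD", replicate = 1,
                                    a = x[, 1], b = x[, 2], c = x[, 3]))
  pc3 <- panel_pca(p3)
  ev <- eigen(stats::cov(x), symmetric = TRUE)$values
  expect_equal(pc3$var_explained, ev / sum(ev), tolerance = 1e-12)
  # orthonormal loadings, non-increasing variance fractions
  expect_equal(crossprod(pc3$loadings), diag(3), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(diff(pc3$var_explained) <= 1e-12))
  # sign convention: dominant loading of each component is positive
  for (j in 1:3) {
    l <- pc3$loadings[, j]
    expect_gt(l[which.max(abs(l))], 0)
  }
})

test_that("virago calling recovers planted lines exactly", {
  cfg <- synth_config(n_lines = 20, virago_lines = c("L3", "L9"), seed = 2)
  p <- gen_metabolite_panel(cfg)$panel
  v <- call_viragos(p, seed = 1)
  expect_setequal(v$line[v$virago], c("L3", "L9"))

  cfg0 <- synth_config(n_lines = 20, seed = 4)
  v0 <- call_viragos(gen_metabolite_panel(cfg0)$panel, seed = 1)
  expect_equal(sum(v0$virago), 0)

  # four planted viragos among 35 lines
  cfg4 <- synth_config(n_lines = 35,
                       virago_lines = c("L5", "L12", "L24", "L31"), seed = 1)
  v4 <- call_viragos(gen_metabolite_panel(cfg4)$panel, seed = 1)
  expect_setequal(v4$line[v4$virago], c("L5", "L12", "L24", "L31"))
  expect_error(call_viragos(p[p$sex == "female", ]), "both sexes")
})

test_that("diet response is the percent change of line means", {
  mk <- function(val, diet) metabolite_panel(
    data.frame(line = "L1", stage = "adult", sex = "male", diet = diet,
               replicate = seq_along(val), TAG = val))
  expect_equal(diet_response(mk(40, "LSD"), mk(78, "HSD"))$percent_change, 95)
  same <- diet_response(mk(c(10, 20), "LSD"), mk(c(20, 10), "SD"))
  expect_equal(same$percent_change, 0)

  # zero / missing baselines propagate as missing
  b <- metabolite_panel(data.frame(line = c("L1", "L2"), stage = "adult",
                                   sex = "male", diet = "LSD", replicate = 1,
                                   TAG = c(0, NA)))
  s <- metabolite_panel(data.frame(line = c("L1", "L2"), stage = "adult",
                                   sex = "male", diet = "SD", replicate = 1,
                                   TAG = c(5, 5)))
  expect_true(all(is.na(diet_response(b, s)$percent_change)))

  # unmatched cells are reported
  s2 <- metabolite_panel(data.frame(line = "L3", stage = "adult",
                                    sex = "male", diet = "SD", replicate = 1,
                                    TAG = 5))
  expect_error(diet_response(b, s2), "unmatched.*L3")
})
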