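test_that("config validation rejects inconsistent setups", {
  expect_error(synth_config(n_lines = 5, virago_lines = "L9"), "virago")
  expect_error(synth_config(n_sites = 10, n_unique_alt = 8, n_unique_ref = 5,
                            unique_group = "L1"), "exceed")
  expect_error(synth_config(n_unique_alt = 3), "unique_group")
  expect_error(synth_config(planted_links = list(
    list(metabolite = "caffeine", taxon = "Acetobacter", rho = 0.5))),
    "unknown metabolite")
  expect_error(synth_config(planted_links = list(
    list(metabolite = "TAG", taxon = "Klebsiella", rho = 0.5))),
    "unknown taxon")
  expect_error(synth_config(planted_links = list(
    list(metabolite = "TAG", taxon = "Acetobacter", rho = 1.5))),
    "\\[-1, 1\\]")
})

test_that("zero noise collapses each metabotype stratum to a point", {
  cfg <- synth_config(n_lines = 9, k_metabotypes = 3, noise_sd = 0,
                      cluster_separation = 5, seed = 3)
  g <- gen_metabolite_panel(cfg)
  truth <- g$truth$metabotype
  p <- g$panel
  key <- merge(p, truth, by = c("line", "stage", "sex"))
  for (m in panel_metabolites(p)) {
    spread <- tapply(key[[m]], paste(key$cluster, key$stage, key$sex),
                     function(v) diff(range(v)))
    expect_true(all(spread < 1e-9))
  }
})

test_that("virago females are drawn from the male distribution", {
  cfg <- synth_config(n_lines = 6, virago_lines = "L3", noise_sd = 0, seed = 1)
  p <- gen_metabolite_panel(cfg)$panel
  fem <- p[p$line == "L3" & p$sex == "female", panel_metabolites(p)]
  mal <- p[p$line == "L3" & p$sex == "male", panel_metabolites(p)]
  expect_equal(unlist(fem[1, ]), unlist(mal[1, ]), tolerance = 1e-12)
})

test_that("generators are deterministic given the seed", {
  cfg <- synth_config(n_lines = 8, virago_lines = "L2", n_sites = 120,
                      n_unique_alt = 5, n_unique_ref = 2,
                      unique_group = c("L1", "L2"), seed = 99)
  a <- gen_metabolite_panel(cfg)
  b <- gen_metabolite_panel(cfg)
  expect_identical(a, b)
  ga <- gen_genotype_matrix(cfg)
  gb <- gen_genotype_matrix(cfg)
  expect_identical(ga, gb)
  ta <- gen_abundance_table(cfg, a$panel)
  tb <- gen_abundance_table(cfg, b$panel)
  expect_identical(ta, tb)
})

test_that("abundance rows sum to the sequencing depth and Wolbachia is line-restricted", {
  cfg <- synth_config(n_lines = 5, wolbachia_line = "L4",
                      sequencing_depth = 20000, seed = 6)
  panel <- gen_metabolite_panel(cfg)$panel
  tab <- gen_abundance_table(cfg, panel)$tab
  expect_true(all(rowSums(tab$counts) == 20000))
  wolb <- tab$counts[, "Wolbachia pipientis"]
  infected <- tab$meta$line == "L4"
  expect_true(all(wolb[!infected] == 0))
  prop <- relative_abundance(tab)
  expect_true(all(prop[infected, "Wolbachia pipientis"] > 0.3))
})

test_that("planted rank correlations are achieved within tolerance", {
  cfg <- synth_config(n_lines = 10, seed = 3,
                      planted_links = list(
                        list(metabolite = "glycerol", taxon = "Acetobacter",
                             rho = -0.5),
                        list(metabolite = "TAG",
                             taxon = "Lactobacillus plantarum", rho = 0.6)))
  panel <- gen_metabolite_panel(cfg)$panel
  adults <- panel[panel$stage == "adult", ]
  tab <- gen_abundance_table(cfg, adults)$tab
  genus <- relative_abundance(genus_rollup(tab))
  spp <- relative_abundance(tab)
  r_gen <- cor(adults$glycerol, genus[, "Acetobacter"], method = "spearman")
  r_spp <- cor(adults$TAG, spp[, "Lactobacillus plantarum"],
               method = "spearman")
  expect_lt(abs(r_gen - (-0.5)), 0.15)
  expect_lt(abs(r_spp - 0.6), 0.15)
})

test_that("diet-shift multipliers are recovered exactly at zero shift noise", {
  forced <- data.frame(line = "L5", sex = "male", metabolite = "TAG",
                       diet = "HSD", multiplier = 1.95)
  cfg <- synth_config(n_lines = 6, seed = 11, shift_effects = forced,
                      shift_noise_sd = 0)
  lsd <- gen_metabolite_panel(cfg, diet = "LSD")$panel
  ds <- gen_diet_shift(lsd, cfg)
  for (arm in c("SD", "HSD")) {
    resp <- diet_response(lsd, ds$panel[ds$panel$diet == arm, ])
    tr <- ds$truth[ds$truth$diet == arm, ]
    merged <- merge(resp, tr, by = c("line", "sex", "metabolite"))
    expect_equal(merged$percent_change, (merged$multiplier - 1) * 100,
                 tolerance = 1e-9)
  }
  hsd <- ds$panel[ds$panel$diet == "HSD", ]
  r <- diet_response(lsd, hsd)
  expect_equal(r$percent_change[r$line == "L5" & r$sex == "male" &
                                  r$metabolite == "TAG"], 95,
               tolerance = 1e-9)
})

test_that("panel TSV writer round-trips", {
  cfg <- synth_config(n_lines = 3, seed = 1)
  p <- gen_metabolite_panel(cfg)$panel
  f <- tempfile(fileext = ".tsv")
  write_panel_tsv(p, f, comment = "normalization: none")
  q <- read_panel_tsv(f)
  expect_equal(as.data.frame(q), as.data.frame(p), tolerance = 1e-12)
})
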