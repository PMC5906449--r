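#' Generate paired synthetic GWAS output tables with planted counts
#'
#' Builds basal-condition and diet-shift-condition association tables
#' whose *recomputable* summary statistics are planted exactly: the
#' number of unique significant SNPs per condition, the number of SNPs
#' shared between conditions, the sizes of the per-condition unique gene
#' sets and of their intersection, and a per-trait SNP count for one
#' designated trait (by default 71 significant SNPs for larval glycerol
#' and none for larval lactate). Non-significant decoy records with
#' p-values above the threshold are interleaved so the significance
#' filter has real work to do.
#'
#' @param seed integer seed.
#' @param n_basal,n_shift unique significant SNPs per condition.
#' @param n_shared_variants SNPs significant under both conditions.
#' @param n_basal_genes,n_shift_genes unique gene symbols per condition.
#' @param n_shared_genes gene symbols appearing in both conditions.
#' @param focal_trait,focal_trait_n a basal trait with a planted SNP
#'   count.
#' @param empty_trait trait listed with zero significant SNPs.
#' @param n_decoys non-significant records added per condition.
#' @param threshold significance threshold the planted counts refer to.
#' @return list with `basal`, `shift` (unfiltered [association_table()]s
#'   including decoys) and `truth` (the planted counts).
#' @export
gen_association_tables <- function(seed = 1,
                                   n_basal = 565, n_shift = 878,
                                   n_shared_variants = 6,
                                   n_basal_genes = 256, n_shift_genes = 377,
                                   n_shared_genes = 32,
                                   focal_trait = "glycerol_larva",
                                   focal_trait_n = 71,
                                   empty_trait = "lactate_larva",
                                   n_decoys = 300,
                                   threshold = 1e-5) {
  assert_that(n_shared_variants <= min(n_basal, n_shift),
              "shared variants exceed a condition total")
  assert_that(n_shared_genes <= min(n_basal_genes, n_shift_genes),
              "shared genes exceed a condition gene pool")
  assert_that(n_basal_genes + n_shared_variants <= n_basal &&
                n_shift_genes + n_shared_variants <= n_shift,
              "gene pools larger than the variant lists can carry")
  assert_that(focal_trait_n <= n_basal, "focal trait count exceeds n_basal")
  chroms <- c("2L" = 23.5e6, "2R" = 25.3e6, "3L" = 28.1e6, "3R" = 32.1e6,
              "X" = 23.5e6)
  shared_v <- sprintf("snp_shared_%03d", seq_len(n_shared_variants))
  basal_v <- c(shared_v, sprintf("snp_bas_%05d",
                                 seq_len(n_basal - n_shared_variants)))
  shift_v <- c(shared_v, sprintf("snp_shf_%05d",
                                 seq_len(n_shift - n_shared_variants)))
  genes_sh <- sprintf("Gshare%03d", seq_len(n_shared_genes))
  genes_b <- c(genes_sh, sprintf("Gbas%04d",
                                 seq_len(n_basal_genes - n_shared_genes)))
  genes_s <- c(genes_sh, sprintf("Gshf%04d",
                                 seq_len(n_shift_genes - n_shared_genes)))
  basal_traits <- c(focal_trait, "TAG_larva", "TAG_female", "glycogen_female",
                    "glucose_male", "glycerol_female", "protein_male")
  shift_traits <- c("glucose_female_HSD", "glycogen_female_HSD",
                    "TAG_male_HSD", "glycerol_male_SD", "glucose_male_SD")

  build <- function(variants, genes, traits, focal = NULL, focal_n = 0,
                    condition) {
    nv <- length(variants)
    gene_col <- rep(NA_character_, nv)
    # every shared variant carries a shared gene; every pool gene appears
    # at least once; remaining variants are unclear or reuse pool genes
    n_sh <- sum(startsWith(variants, "snp_shared"))
    gene_col[seq_len(n_sh)] <- genes[((seq_len(n_sh) - 1) %%
                                        n_shared_genes) + 1]
    rest_genes <- setdiff(genes, gene_col[seq_len(n_sh)])
    slot <- n_sh + seq_along(rest_genes)
    gene_col[slot] <- rest_genes
    open <- which(is.na(gene_col))
    reuse <- open[runif(length(open)) < 0.3]
    gene_col[reuse] <- sample(genes, length(reuse), replace = TRUE)
    trait_col <- rep(NA_character_, nv)
    if (!is.null(focal)) {
      trait_col[sample(nv, focal_n)] <- focal
      others <- setdiff(traits, focal)
    } else others <- traits
    trait_col[is.na(trait_col)] <- sample(others, sum(is.na(trait_col)),
                                          replace = TRUE)
    chrom <- sample(names(chroms), nv, replace = TRUE)
    df <- data.frame(variant_id = variants, chrom = chrom,
                     pos = floor(runif(nv, 1, chroms[chrom])),
                     trait = trait_col,
                     pval = runif(nv, 1e-9, threshold * 0.999),
                     gene = gene_col, condition = condition,
                     stringsAsFactors = FALSE)
    decoy_tr <- c(traits, if (condition == "basal") empty_trait)
    decoys <- data.frame(
      variant_id = sprintf("snp_ns_%s_%05d", condition, seq_len(n_decoys)),
      chrom = sample(names(chroms), n_decoys, replace = TRUE),
      trait = sample(decoy_tr, n_decoys, replace = TRUE),
      pval = runif(n_decoys, threshold * 2, 0.99),
      gene = NA_character_, condition = condition, stringsAsFactors = FALSE)
    decoys$pos <- floor(runif(n_decoys, 1, chroms[decoys$chrom]))
    association_table(rbind(df, decoys[names(df)]))
  }
  with_seed(substream_seed(seed, 8L), {
    basal <- build(basal_v, genes_b, basal_traits, focal = focal_trait,
                   focal_n = focal_trait_n, condition = "basal")
    shift <- build(shift_v, genes_s, shift_traits, condition = "diet_shift")
  })
  truth <- list(n_basal = n_basal, n_shift = n_shift,
                n_shared_variants = n_shared_variants,
                n_basal_genes = n_basal_genes, n_shift_genes = n_shift_genes,
                n_shared_genes = n_shared_genes, focal_trait = focal_trait,
                focal_trait_n = focal_trait_n, empty_trait = empty_trait,
                threshold = threshold, chrom_lengths = chroms)
  list(basal = basal, shift = shift, truth = truth)
}
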