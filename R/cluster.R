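.panel_matrix <- function(panel) {
  mets <- panel_metabolites(panel)
  x <- as.matrix(as.data.frame(panel)[, mets, drop = FALSE])
  rownames(x) <- panel$sample_id
  if (anyNA(x))
    stop_config("panel has missing values; run impute_below_detection() ",
                "before normalising and clustering")
  x
}

#' K-means metabotype clustering
#'
#' Partitions the samples of a (z-score normalised, imputed) panel into k
#' metabotypes with k-means, keeping the best of `n_init` random restarts
#' by total within-cluster sum of squares. The seed makes the restarts —
#' and hence the assignment — reproducible. On a combined
#' larva/female/male panel `k = 3` recovers the stage/sex strata; within
#' a single stratum larger k (6 for larval prototypes) resolves line
#' cohorts.
#'
#' @param panel normalised [metabolite_panel()] with no missing values.
#' @param k number of clusters, at most the number of distinct samples.
#' @param n_init number of random restarts.
#' @param seed integer seed.
#' @return object of class `"cluster_assignment"`: list with `cluster`
#'   (named integer vector, labels 1..k), `k`, `wss`, `n_init`, `seed`,
#'   `centers`.
#' @export
kmeans_metabotypes <- function(panel, k, n_init = 50, seed = 1) {
  x <- .panel_matrix(panel)
  if (k > nrow(unique(x)))
    stop_config("k exceeds the number of distinct samples")
  km <- with_seed(seed, kmeans(x, centers = k, nstart = n_init,
                               iter.max = 50))
  structure(list(cluster = setNames(as.integer(km$cluster), rownames(x)),
                 k = k, wss = km$tot.withinss, n_init = n_init, seed = seed,
                 centers = km$centers),
            class = "cluster_assignment")
}

#' Principal component analysis of a metabolite panel
#'
#' Eigen-decomposition of the covariance matrix of the (z-scored) panel
#' columns. Loadings are orthonormal; each component's sign is fixed so
#' its largest-magnitude loading is positive, which makes scores
#' comparable across runs. Variance-explained fractions are
#' non-increasing and sum to at most 1.
#'
#' @param panel normalised [metabolite_panel()] with no missing values
#'   and at least two samples.
#' @return object of class `"panel_pca"`: list with `scores` (samples x
#'   PCs), `loadings` (metabolites x PCs), `var_explained`, `meta`
#'   (metadata columns of the panel).
#' @export
panel_pca <- function(panel) {
  x <- .panel_matrix(panel)
  if (nrow(x) < 2) stop_config("PCA needs at least 2 samples")
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  loadings <- sweep(pc$rotation, 2, flip, `*`)
  scores <- sweep(pc$x, 2, flip, `*`)
  structure(list(scores = scores, loadings = loadings,
                 var_explained = pc$sdev^2 / sum(pc$sdev^2),
                 meta = as.data.frame(panel)[, intersect(panel_meta_cols,
                                                         names(panel))]),
            class = "panel_pca")
}

#' Call virago lines from the adult metabolite profile
#'
#' A virago line is one whose adult females carry a male-like metabolite
#' profile. The call is made in principal-component space: the adult
#' samples are imputed, z-scored and projected onto the top `n_pc`
#' components; a 2-means clustering of the scores defines the two sex
#' clusters (each must have a clear sex majority); every line whose mean
#' female score lies nearer the male-cluster centroid than the
#' female-cluster centroid is flagged.
#'
#' @param panel a [metabolite_panel()] with adult samples of both sexes
#'   (raw amounts; normalisation happens internally).
#' @param n_pc number of leading principal components used (default 2).
#' @param n_init,seed restart count and seed for the 2-means step.
#' @return data frame with one row per line having female adult samples:
#'   `line`, `dist_female`, `dist_male` (centroid distances of the line's
#'   mean female score) and `virago` (logical call).
#' @export
call_viragos <- function(panel, n_pc = 2, n_init = 50, seed = 1) {
  adult <- panel[panel$stage == "adult", , drop = FALSE]
  if (!all(c("female", "male") %in% adult$sex))
    stop_config("need adult samples of both sexes")
  norm <- zscore_normalize(impute_below_detection(adult))
  pc <- panel_pca(norm)
  n_pc <- min(n_pc, ncol(pc$scores))
  sc <- pc$scores[, seq_len(n_pc), drop = FALSE]
  km <- with_seed(seed, kmeans(sc, centers = 2, nstart = n_init))
  maj <- vapply(1:2, function(cl) {
    sx <- adult$sex[km$cluster == cl]
    tab <- table(sx)
    if (max(tab) * 2 <= length(sx)) NA_character_ else names(which.max(tab))
  }, character(1))
  if (anyNA(maj) || length(unique(maj)) != 2 ||
      !setequal(maj, c("female", "male")))
    stop_config("degenerate clustering: no clear male/female sex majority")
  cen_f <- km$centers[which(maj == "female"), ]
  cen_m <- km$centers[which(maj == "male"), ]
  fem <- adult$sex == "female"
  lines <- unique(adult$line[fem])
  res <- do.call(rbind, lapply(lines, function(l) {
    s <- colMeans(sc[fem & adult$line == l, , drop = FALSE])
    data.frame(line = l,
               dist_female = sqrt(sum((s - cen_f)^2)),
               dist_male = sqrt(sum((s - cen_m)^2)),
               stringsAsFactors = FALSE)
  }))
  res$virago <- res$dist_male < res$dist_female
  rownames(res) <- NULL
  res
}
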