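# Independent brute-force oracles used across the suite.

# All permutations of 1..n as an (n!) x n integer matrix.
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  p <- all_perms(n - 1)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    left <- p[, seq_len(i - 1), drop = FALSE]
    right <- if (i <= n - 1) p[, i:(n - 1), drop = FALSE] else
      matrix(integer(0), nrow(p), 0)
    out[[i]] <- cbind(left, n, right)
  }
  do.call(rbind, out)
}

# Exact two-sided permutation p-value of Spearman's rho for tie-free data.
spearman_perm_p <- function(x, y) {
  n <- length(x)
  rx <- rank(x)
  perms <- all_perms(n)
  rs <- 1 - 6 * rowSums(sweep(perms, 2, rx)^2) / (n * (n^2 - 1))
  r_obs <- cor(x, y, method = "spearman")
  min(1, 2 * min(mean(rs >= r_obs - 1e-12), mean(rs <= r_obs + 1e-12)))
}

# Site-by-site enumeration of shared-allele percent (independent of the
# vectorised implementation).
brute_sharing <- function(G, a, b, cls) {
  va <- G$calls[a, ]; vb <- G$calls[b, ]
  code <- if (cls == "alt") 1L else 0L
  both <- 0L; joint <- 0L
  for (j in seq_along(va)) {
    if (!is.na(va[j]) && !is.na(vb[j])) {
      joint <- joint + 1L
      if (va[j] == code && vb[j] == code) both <- both + 1L
    }
  }
  100 * both / joint
}

# Site-by-site enumeration of group-unique alleles.
brute_unique <- function(G, group, cls) {
  code <- if (cls == "alt") 1L else 0L
  gi <- match(group, G$lines)
  hits <- character()
  for (j in seq_len(ncol(G$calls))) {
    g <- G$calls[gi, j]
    o <- G$calls[-gi, j]
    if (!anyNA(g) && all(g == code) && all(o[!is.na(o)] != code))
      hits <- c(hits, colnames(G$calls)[j])
  }
  hits
}

# Minimal within-cluster sum of squares over all 2-partitions of 1D points.
brute_kmeans2_wss <- function(x) {
  n <- length(x)
  best <- Inf
  for (mask in 1:(2^n - 2)) {
    grp <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    wss <- sum((x[grp] - mean(x[grp]))^2) + sum((x[!grp] - mean(x[!grp]))^2)
    best <- min(best, wss)
  }
  best
}

# Top-95% retained set by direct per-sample cumulative enumeration.
brute_top95 <- function(prop, cum = 0.95) {
  retained <- character()
  for (i in seq_len(nrow(prop))) {
    v <- sort(prop[i, ], decreasing = TRUE)
    acc <- 0
    for (k in seq_along(v)) {
      acc <- acc + v[k]
      retained <- c(retained, names(v)[k])
      if (acc >= cum - 1e-12) break
    }
  }
  sort(unique(retained))
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
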