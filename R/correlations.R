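#' Spearman rank correlation matrix with AS89 p-values
#'
#' Computes pairwise Spearman rank correlations between the numeric
#' columns of a line-mean table, with midrank handling of ties and
#' pairwise-complete observations. Two-sided p-values come from the AS89
#' algorithm as implemented by [stats::cor.test()]: the exact null
#' distribution of the rank statistic for tie-free small samples, an
#' Edgeworth-series approximation otherwise, and the
#' t-approximation when ties force the midrank correction
#' (`method = "t"` selects the t-approximation throughout).
#'
#' @param x data frame or matrix of line means; non-numeric columns are
#'   dropped.
#' @param method `"as89"` (default) or `"t"`.
#' @param min_pairs minimum number of complete pairs required for a
#'   coefficient (default 4); pairs with fewer are left missing.
#' @return object of class `"correlation_result"`: list with symmetric
#'   matrices `r`, `p`, `n`, plus `variables` and `method`. Diagonal r is
#'   1 with p fixed at 1 (self-correlation carries no evidence).
#' @export
spearman_matrix <- function(x, method = c("as89", "t"), min_pairs = 4) {
  method <- match.arg(method)
  x <- as.data.frame(x)
  num <- vapply(x, is.numeric, logical(1))
  x <- x[, num, drop = FALSE]
  vars <- names(x)
  k <- length(vars)
  assert_that(k >= 2, "need at least two numeric variables")
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  diag(r) <- 1
  diag(p) <- 1
  diag(n) <- colSums(!is.na(x))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      ok <- complete.cases(x[[i]], x[[j]])
      n[i, j] <- n[j, i] <- sum(ok)
      if (sum(ok) < min_pairs) next
      xi <- x[[i]][ok]; xj <- x[[j]][ok]
      if (sd(xi) == 0 || sd(xj) == 0) {
        warning("constant variable in pair ", vars[i], " / ", vars[j],
                "; correlation undefined")
        next
      }
      ct <- suppressWarnings(
        cor.test(xi, xj, method = "spearman",
                 exact = if (method == "as89") NULL else FALSE))
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      # the Edgeworth tail of AS89 can underflow to 0; floor at the
      # smallest attainable two-sided permutation p so p stays in (0, 1]
      p_floor <- exp(log(2) - lfactorial(sum(ok)))
      p[i, j] <- p[j, i] <- min(1, max(ct$p.value, p_floor))
    }
  }
  structure(list(r = r, p = p, n = n, variables = vars, method = method),
            class = "correlation_result")
}

#' Mask non-significant entries of a result table
#'
#' Generic over the package's result containers. For a
#' [spearman_matrix()] result, correlation coefficients whose p-value is
#' `>= alpha` are masked to `NA` (the diagonal is retained); for an
#' association table, see
#' [filter_significant.association_table()].
#'
#' @param x result object.
#' @param alpha significance level in (0, 1) (or p-value threshold).
#' @param ... passed to methods.
#' @return an object of the same class as `x`.
#' @export
filter_significant <- function(x, alpha, ...) UseMethod("filter_significant")

#' @rdname filter_significant
#' @export
filter_significant.correlation_result <- function(x, alpha = 0.05, ...) {
  assert_that(alpha > 0 && alpha <= 1, "alpha must be in (0, 1]")
  mask <- !is.na(x$p) & x$p >= alpha
  diag(mask) <- FALSE
  x$r[mask] <- NA_real_
  x$alpha <- alpha
  x
}

#' Long-format view of a correlation result
#'
#' @param res a [spearman_matrix()] result (possibly filtered).
#' @return data frame `var1`, `var2`, `r`, `p`, `n`, `significant` (one
#'   row per unordered variable pair).
#' @export
correlation_long <- function(res) {
  vars <- res$variables
  idx <- which(upper.tri(res$r), arr.ind = TRUE)
  data.frame(var1 = vars[idx[, 1]], var2 = vars[idx[, 2]],
             r = res$r[idx], p = res$p[idx], n = res$n[idx],
             significant = !is.na(res$p[idx]) &
               res$p[idx] < (res$alpha %||% 0.05),
             stringsAsFactors = FALSE)
}

#' One-way ANOVA with Bonferroni-corrected comparisons against controls
#'
#' Fits a one-way ANOVA across all groups, then compares every
#' non-control group with every control group by a two-sided pooled-SD
#' two-sample t-test, multiplying each p-value by the number of
#' comparisons (Bonferroni) and capping at 1. This is the egg-laying
#' style analysis: candidate lines against designated control lines.
#'
#' @param values numeric vector of observations.
#' @param group group label per observation.
#' @param control_labels labels of the control group(s).
#' @return list with `f`, `p_anova`, and `comparisons` (data frame
#'   `group`, `control`, `estimate` (group mean minus control mean), `t`,
#'   `p_raw`, `p_adj`).
#' @export
anova_bonferroni <- function(values, group, control_labels) {
  group <- as.character(group)
  assert_that(length(values) == length(group), "values/group length mismatch")
  labs <- unique(group)
  assert_that(length(labs) >= 2, "need at least two groups")
  assert_that(all(table(group) >= 2), "each group needs n >= 2")
  bad <- setdiff(control_labels, labs)
  if (length(bad))
    stop_config("control label(s) not present: ", paste(bad, collapse = ", "))
  if (all(vapply(split(values, group), var, numeric(1)) == 0))
    stop_config("zero within-group variance in every group")
  fit <- aov(values ~ factor(group))
  tab <- anova(fit)
  cand <- setdiff(labs, control_labels)
  cmp <- expand.grid(group = cand, control = control_labels,
                     stringsAsFactors = FALSE)
  m <- nrow(cmp)
  res <- do.call(rbind, lapply(seq_len(m), function(i) {
    a <- values[group == cmp$group[i]]
    b <- values[group == cmp$control[i]]
    tt <- stats::t.test(a, b, var.equal = TRUE)
    data.frame(group = cmp$group[i], control = cmp$control[i],
               estimate = mean(a) - mean(b), t = unname(tt$statistic),
               p_raw = tt$p.value, p_adj = min(1, tt$p.value * m),
               stringsAsFactors = FALSE)
  }))
  list(f = tab[["F value"]][1], p_anova = tab[["Pr(>F)"]][1],
       comparisons = res)
}
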