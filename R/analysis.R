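#' Pearson correlation coefficient
#'
#' `r = sum((x - mean(x)) (y - mean(y))) / sqrt(sum((x - mean(x))^2)
#' sum((y - mean(y))^2))`.  Errors (rather than silently returning 0) when
#' either variable has zero variance.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (var(x) == 0 || var(y) == 0)
    stop("undefined correlation: zero variance")
  cor(x, y)
}

#' Averaged within-group correlation matrix between feature categories
#'
#' For every feature pair the Pearson correlation is computed within each
#' condition group separately and the coefficients are averaged over
#' groups, so that between-group mean shifts do not masquerade as feature
#' redundancy.  A feature constant within a group is skipped for that
#' group (pairwise, with a message); the within-category matrix is
#' symmetric with an exact unit diagonal.
#'
#' @param table a [assemble_feature_table()] result.
#' @param category_a,category_b category names (may be equal).
#' @return numeric matrix of averaged correlations (rows = `category_a`
#'   features, columns = `category_b` features).
#' @export
correlation_heatmap <- function(table, category_a, category_b = category_a) {
  ca <- category_columns(table, category_a)
  cb <- category_columns(table, category_b)
  groups <- split(seq_along(table$condition), table$condition)
  if (any(lengths(groups) < 3L))
    stop("each condition group needs at least 3 cells")
  acc <- matrix(0, length(ca), length(cb))
  cnt <- matrix(0, length(ca), length(cb))
  for (g in groups) {
    A <- table$values[g, ca, drop = FALSE]
    B <- table$values[g, cb, drop = FALSE]
    suppressWarnings(r <- cor(A, B, use = "pairwise.complete.obs"))
    bad <- is.na(r)
    if (any(bad))
      message(sprintf("%d feature pair(s) skipped in one group (constant or missing)",
                      sum(bad)))
    r[bad] <- 0
    acc <- acc + r
    cnt <- cnt + !bad
  }
  out <- acc / pmax(cnt, 1)
  out[cnt == 0] <- NA_real_
  dimnames(out) <- list(colnames(table$values)[ca], colnames(table$values)[cb])
  if (identical(category_a, category_b)) {
    out[cbind(seq_along(ca), seq_along(ca))] <- 1
    out <- (out + t(out)) / 2
  }
  out
}

#' Principal component analysis of one feature category
#'
#' Features are z-scored by default (the categories mix units: px^2, px,
#' dimensionless), constant or missing-heavy columns are dropped, and the
#' loading signs follow a deterministic convention (the largest-magnitude
#' loading of each component is positive).
#'
#' @param table a [assemble_feature_table()] result.
#' @param category feature category to analyze.
#' @param k number of retained components (default 4; truncated to the
#'   rank with a warning).
#' @param standardize z-score the features first?
#' @return An object of class `pca_result`: list with `scores` (cells x
#'   k), `loadings` (features x k), `explained_variance_ratio`, `k`,
#'   `condition`.
#' @export
pca_category <- function(table, category, k = 4L, standardize = TRUE) {
  cols <- category_columns(table, category)
  X <- table$values[, cols, drop = FALSE]
  keep <- apply(X, 2, function(v) !anyNA(v) && var(v) > 0)
  if (!all(keep)) X <- X[, keep, drop = FALSE]
  if (ncol(X) < 1L) stop("no usable features in category")
  stopifnot(nrow(X) >= k + 1L)
  pc <- prcomp(X, center = TRUE, scale. = standardize)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-9)
  if (k > rank) {
    warning(sprintf("k truncated from %d to rank %d", k, rank))
    k <- rank
  }
  flip <- vapply(seq_len(k), function(j) {
    sign(pc$rotation[which.max(abs(pc$rotation[, j])), j])
  }, numeric(1))
  structure(list(scores = sweep(pc$x[, seq_len(k), drop = FALSE], 2, flip, `*`),
                 loadings = sweep(pc$rotation[, seq_len(k), drop = FALSE], 2, flip, `*`),
                 explained_variance_ratio = evr[seq_len(k)],
                 k = k, condition = table$condition),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d cells, %d components; explained: %s\n",
              nrow(x$scores), x$k,
              paste(sprintf("%.1f%%", 100 * x$explained_variance_ratio),
                    collapse = " ")))
  invisible(x)
}

#' Welch two-sample t-test p-value
#'
#' Two-sided, unequal-variance.  Degenerate zero-variance samples yield
#' p = 1 when the means agree and p = 0 when they do not.
#'
#' @param a,b numeric vectors of length >= 3.
#' @return p-value in `[0, 1]`.
#' @export
welch_ttest <- function(a, b) {
  stopifnot(length(a) >= 3L, length(b) >= 3L)
  if (var(a) == 0 && var(b) == 0)
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  t.test(a, b, var.equal = FALSE)$p.value
}

#' Primary principal component (PPC) selection
#'
#' For each of the first `k` principal components, the worst-case
#' (largest) Welch p-value over all requested condition comparisons is
#' recorded (`MAX-P`); the PPC is the component minimizing `MAX-P`, i.e.
#' the single score axis that best separates every comparison at once.
#' Ties go to the lowest component index.  The p-values serve only as a
#' ranking device, not as significance tests, so no multiplicity
#' correction is applied here.
#'
#' @param result a [pca_category()] result (carries scores and per-cell
#'   condition labels).
#' @param comparisons data frame (or 2-column matrix) with columns
#'   `group_a`, `group_b` of condition labels; each side needs >= 3 cells.
#' @return list with `ppc_index`, `max_p` (one per component), and the
#'   full `p_matrix` (comparisons x components).
#' @export
select_ppc <- function(result, comparisons) {
  stopifnot(inherits(result, "pca_result"))
  comparisons <- as.data.frame(comparisons)
  colnames(comparisons)[1:2] <- c("group_a", "group_b")
  stopifnot(nrow(comparisons) >= 1L)
  k <- result$k
  P <- matrix(NA_real_, nrow(comparisons), k)
  for (i in seq_len(nrow(comparisons))) {
    ia <- result$condition == comparisons$group_a[i]
    ib <- result$condition == comparisons$group_b[i]
    if (sum(ia) < 3L || sum(ib) < 3L)
      stop("each comparison needs at least 3 cells per side")
    for (j in seq_len(k))
      P[i, j] <- welch_ttest(result$scores[ia, j], result$scores[ib, j])
  }
  c(ppc_from_pvalues(P), list(p_matrix = P))
}

#' MAX-P / argmin selection from a p-value matrix
#'
#' The worst-case (column maximum) p-value per component, and the index
#' of the component with the smallest worst case; ties go to the lowest
#' index.
#'
#' @param p_matrix comparisons x components matrix of p-values.
#' @return list with `ppc_index` and `max_p`.
#' @export
ppc_from_pvalues <- function(p_matrix) {
  p_matrix <- as.matrix(p_matrix)
  max_p <- apply(p_matrix, 2, max)
  list(ppc_index = which.min(max_p), max_p = max_p)
}

#' Per-feature group comparison report
#'
#' Welch t-test p-value for every feature between two condition groups,
#' with Benjamini-Hochberg adjusted q-values (set `adjust = FALSE` for
#' raw p-values only).
#'
#' @param table a [assemble_feature_table()] result.
#' @param group_a,group_b condition labels.
#' @param adjust apply Benjamini-Hochberg correction?
#' @return data frame with `feature`, `category`, `p`, and (if adjusted)
#'   `q`.
#' @export
feature_significance <- function(table, group_a, group_b, adjust = TRUE) {
  ia <- table$condition == group_a
  ib <- table$condition == group_b
  p <- apply(table$values, 2, function(v) {
    a <- v[ia]; b <- v[ib]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 3L || length(b) < 3L) return(NA_real_)
    welch_ttest(a, b)
  })
  out <- data.frame(feature = colnames(table$values),
                    category = table$category, p = p, row.names = NULL)
  if (adjust) out$q <- stats::p.adjust(out$p, method = "BH")
  out
}
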