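test_that("Pearson correlation follows the definition and rejects degenerate input", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson(x, x), 1)
  expect_equal(pearson(x, -2 * x + 7), -1)

  y <- c(1, 2, 3, 10)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson(x, y), r_hand)

  expect_error(pearson(x, rep(5, 4)), "zero variance")
})

test_that("feature tables assemble with categories, order and failure handling", {
  spec <- small_spec()
  cells <- generate_cells(spec, condition = "ctl")
  ft <- assemble_feature_table(cells, categories = c("geometry", "waviness"))
  expect_equal(nrow(ft$values), 4)
  expect_setequal(unique(ft$category), c("geometry", "waviness"))
  expect_equal(ft$cell_id, vapply(cells, `[[`, "", "cell_id"))

  # identical cells give identical rows
  ft2 <- assemble_feature_table(list(cells[[1]], cells[[1]]),
                                categories = "geometry")
  expect_equal(ft2$values[1, ], ft2$values[2, ])

  # single-category request yields only that category's columns
  ftg <- assemble_feature_table(cells, categories = "geometry")
  expect_true(all(startsWith(colnames(ftg$values), "geo_")))

  # a failing cell is dropped with a warning
  broken <- cells
  broken[[2]]$cell_mask <- matrix(0L, 8, 8)
  broken[[2]]$gray <- matrix(0, 8, 8)
  expect_warning(ftb <- assemble_feature_table(broken, categories = "geometry"),
                 "failed")
  expect_equal(nrow(ftb$values), 3)
})

test_that("full default feature set lands in the expected width with no constant columns", {
  spec <- small_spec(texture = "speckle")
  cells <- generate_cells(spec, n = 6L, condition = "ctl")
  ft <- assemble_feature_table(cells)
  expect_gte(ncol(ft$values), 250)
  expect_lte(ncol(ft$values), 280)
  non_nuc <- ft$values[, ft$category != "nucleus"]
  expect_false(anyNA(non_nuc))
})

test_that("averaged within-group correlation has unit diagonal and flags duplicates", {
  set.seed(50)
  vals <- matrix(rnorm(200 * 8), 200, 8)
  vals[, 8] <- vals[, 1]                       # duplicated feature
  tab <- fake_feature_table(vals, rep("a", 8),
                            rep(c("g1", "g2"), each = 100))
  cm <- correlation_heatmap(tab, "a")
  expect_equal(unname(diag(cm)), rep(1, 8))
  expect_equal(cm, t(cm))
  expect_equal(unname(cm[1, 8]), 1, tolerance = 1e-12)
  # independent features: small average off-diagonal correlation
  off <- abs(cm[upper.tri(cm)])
  off <- off[off < 0.999]
  expect_lt(mean(off), 0.15)
})

test_that("group-wise correlation removes between-group mean shifts", {
  # two features shifted jointly across groups but independent within:
  # pooled correlation would be strong, group-averaged is near zero
  set.seed(8)
  n <- 150
  shift <- rep(c(0, 10), each = n)
  x <- rnorm(2 * n) + shift; y <- rnorm(2 * n) + shift
  tab <- fake_feature_table(cbind(x, y), c("a", "a"),
                            rep(c("g1", "g2"), each = n))
  cm <- correlation_heatmap(tab, "a")
  expect_lt(abs(cm[1, 2]), 0.2)
  expect_gt(abs(cor(x, y)), 0.9)
})

test_that("per-category PCA is deterministic with ordered explained variance", {
  set.seed(60)
  line <- cbind(1:20, 2 * (1:20) + 3, -(1:20))
  tabl <- fake_feature_table(line + 0, rep("a", 3), rep(c("u", "v"), 10))
  pl <- suppressWarnings(pca_category(tabl, "a", k = 2, standardize = FALSE))
  expect_equal(pl$explained_variance_ratio[1], 1, tolerance = 1e-9)

  iso <- matrix(rnorm(500 * 4), 500, 4)
  tabi <- fake_feature_table(iso, rep("a", 4), rep(c("u", "v"), 250))
  pi4 <- pca_category(tabi, "a", k = 4)
  expect_true(all(abs(pi4$explained_variance_ratio - 0.25) < 0.05))
  expect_true(all(diff(pi4$explained_variance_ratio) <= 1e-12))

  # determinism and the sign convention
  pi4b <- pca_category(tabi, "a", k = 4)
  expect_identical(pi4$scores, pi4b$scores)
  for (j in 1:4)
    expect_gt(pi4$loadings[which.max(abs(pi4$loadings[, j])), j], 0)

  # feature reordering leaves scores unchanged (sign convention fixed)
  perm <- c(3, 1, 4, 2)
  tabp <- fake_feature_table(iso[, perm], rep("a", 4), rep(c("u", "v"), 250))
  pp <- pca_category(tabp, "a", k = 4)
  expect_equal(abs(pp$scores), abs(pi4$scores), tolerance = 1e-9)

  # rank truncation warns
  expect_warning(pca_category(tabl, "a", k = 3, standardize = FALSE), "rank")
})

test_that("Welch t-test handles identity, separation and degenerate variance", {
  a <- c(1.2, 3.4, 2.2, 5.1, 0.3)
  expect_equal(welch_ttest(a, a), 1)
  set.seed(4)
  x <- rnorm(50); y <- rnorm(50, 5)
  expect_lt(welch_ttest(x, y), 1e-10)
  expect_equal(welch_ttest(rep(2, 5), rep(2, 6)), 1)
  expect_equal(welch_ttest(rep(2, 5), rep(3, 6)), 0)
})

test_that("PPC selection minimizes the worst-case p-value with ties to the lowest index", {
  sel <- ppc_from_pvalues(matrix(c(0.8, 1e-6, 0.5, 0.9), 1))
  expect_equal(sel$ppc_index, 2)

  P <- rbind(c(1e-6, 0.3, 0.5, 0.2), c(0.2, 1e-5, 0.1, 0.4))
  sel2 <- ppc_from_pvalues(P)
  expect_equal(sel2$max_p, c(0.2, 0.3, 0.5, 0.4))   # column maxima by hand
  expect_equal(sel2$ppc_index, 1)

  expect_equal(ppc_from_pvalues(matrix(0.5, 3, 4))$ppc_index, 1)

  # brute-force oracle over random p-matrices
  set.seed(12)
  for (i in 1:20) {
    P <- matrix(runif(12), 3, 4)
    sel <- ppc_from_pvalues(P)
    best <- Inf; arg <- NA
    for (j in 1:4) {
      worst <- -Inf
      for (r in 1:3) if (P[r, j] > worst) worst <- P[r, j]
      if (worst < best) { best <- worst; arg <- j }
    }
    expect_equal(sel$ppc_index, arg)
    expect_equal(unname(sel$max_p[arg]), best)
  }
})

test_that("select_ppc wires scores, conditions and comparisons together", {
  set.seed(77)
  scores <- cbind(rnorm(60), c(rnorm(30), rnorm(30, 4)), rnorm(60), rnorm(60))
  res <- structure(list(scores = scores, k = 4L,
                        condition = rep(c("ctl", "drug"), each = 30)),
                   class = "pca_result")
  sel <- select_ppc(res, data.frame(group_a = "ctl", group_b = "drug"))
  expect_equal(sel$ppc_index, 2)
  expect_equal(dim(sel$p_matrix), c(1L, 4L))
  expect_error(select_ppc(res, data.frame(group_a = "ctl", group_b = "nope")),
               "at least 3")
})
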