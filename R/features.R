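FEATURE_CATEGORIES <- c("band", "fd", "glcm", "waviness", "roughness",
                        "geometry", "nucleus", "hull", "zernike")

#' Extract all features of one cell
#'
#' Runs the requested feature categories on a single [cell_image()] and
#' returns one named numeric vector.  At default settings the nine
#' categories yield 268 features: 15 band, 4 fractal-dimension, 23 GLCM,
#' 36 waviness, 8 roughness, 14 geometric, 15 nucleus, 7 convex-hull and
#' 146 Zernike.
#'
#' @param cell a [cell_image()].
#' @param categories subset of
#'   `c("band", "fd", "glcm", "waviness", "roughness", "geometry",
#'   "nucleus", "hull", "zernike")`.
#' @param control named list of parameters: `band$n_bands`, `glcm$g`,
#'   `fd$methods`, `waviness$n_max`, `zernike$order_max`,
#'   `zernike$rep_max`.
#' @return named numeric vector (absent nucleus gives `NA` markers).
#' @export
extract_features <- function(cell, categories = FEATURE_CATEGORIES,
                             control = list()) {
  categories <- match.arg(categories, FEATURE_CATEGORIES, several.ok = TRUE)
  ctl <- function(cat, key, default)
    if (!is.null(control[[cat]][[key]])) control[[cat]][[key]] else default
  out <- list()
  for (cat in categories) {
    out[[cat]] <- switch(cat,
      band = band_features(band_profile(cell, n_bands = ctl("band", "n_bands", 10L))),
      fd = fractal_features(cell, methods = ctl("fd", "methods",
                              c("sobel", "prewitt", "roberts", "canny"))),
      glcm = glcm_features(cell, g = ctl("glcm", "g", 8L)),
      waviness = waviness_features(cell, n_max = ctl("waviness", "n_max", 35L)),
      roughness = roughness_features(cell, n_max = ctl("waviness", "n_max", 35L)),
      geometry = geometric_features(cell$cell_mask),
      nucleus = nucleus_features(cell$nucleus_mask, cell$cell_mask),
      hull = convex_hull_features(cell$cell_mask),
      zernike = zernike_magnitudes(cell$cell_mask,
                                   order_max = ctl("zernike", "order_max", 30L),
                                   rep_max = ctl("zernike", "rep_max", 10L)))
  }
  unlist(out, use.names = FALSE) -> vals
  nms <- unlist(lapply(out, names), use.names = FALSE)
  names(vals) <- nms
  attr(vals, "category") <- rep(names(out), lengths(out))
  vals
}

#' Assemble a per-cell feature table
#'
#' Extracts features for every cell and stacks them into a cells-by-
#' features matrix with per-column category tags and per-row condition
#' labels.  A cell whose extraction fails is dropped with a warning.
#'
#' @param cells list of [cell_image()] objects (at least 2).
#' @inheritParams extract_features
#' @return An object of class `feature_table`: list with `values`
#'   (numeric matrix, rownames = cell ids), `category` (character vector,
#'   one tag per column), `condition` (one label per row), `cell_id`.
#' @export
assemble_feature_table <- function(cells, categories = FEATURE_CATEGORIES,
                                   control = list()) {
  stopifnot(length(cells) >= 2L)
  rows <- vector("list", length(cells))
  ok <- logical(length(cells))
  for (i in seq_along(cells)) {
    rows[[i]] <- tryCatch(extract_features(cells[[i]], categories, control),
                          error = function(e) {
                            warning(sprintf("cell '%s' failed feature extraction: %s",
                                            cells[[i]]$cell_id, conditionMessage(e)))
                            NULL
                          })
    ok[i] <- !is.null(rows[[i]])
  }
  if (sum(ok) < 2L) stop("fewer than 2 cells with successful extraction")
  vals <- do.call(rbind, rows[ok])
  rownames(vals) <- vapply(cells[ok], function(c) c$cell_id, character(1))
  structure(list(values = vals,
                 category = attr(rows[which(ok)[1]][[1]], "category"),
                 condition = vapply(cells[ok], function(c) c$condition, character(1)),
                 cell_id = rownames(vals)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d cells x %d features (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$category), collapse = ", ")))
  invisible(x)
}

## columns of a feature table belonging to one category
category_columns <- function(table, category) {
  stopifnot(inherits(table, "feature_table"))
  which(table$category %in% category)
}

#' Write a feature table to CSV
#'
#' One row per cell with `cell_id` and `condition` columns first; a
#' second header-like sidecar CSV records the per-feature category tags.
#'
#' @param table a [assemble_feature_table()] result.
#' @param path output CSV path; the category map goes to
#'   `<path>.categories.csv`.
#' @export
write_feature_table <- function(table, path) {
  df <- data.frame(cell_id = table$cell_id, condition = table$condition,
                   table$values, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  write.csv(data.frame(feature = colnames(table$values),
                       category = table$category),
            paste0(path, ".categories.csv"), row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path CSV path (with `<path>.categories.csv` alongside).
#' @return a `feature_table`.
#' @export
read_feature_table <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  cats <- read.csv(paste0(path, ".categories.csv"))
  vals <- as.matrix(df[, setdiff(colnames(df), c("cell_id", "condition")),
                       drop = FALSE])
  rownames(vals) <- df$cell_id
  structure(list(values = vals,
                 category = cats$category[match(colnames(vals), cats$feature)],
                 condition = as.character(df$condition),
                 cell_id = as.character(df$cell_id)),
            class = "feature_table")
}
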