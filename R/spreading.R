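## shoelace area/centroid/second moments of a polygon given as an n x 2
## matrix of (row, col) vertices; returns central second moments in the
## (x = col, y = row) frame
polygon_moments <- function(pts) {
  x <- pts[, 2]; y <- pts[, 1]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cross <- x * y2 - x2 * y
  A <- sum(cross) / 2
  if (abs(A) < 1e-12)
    return(list(area = 0, cx = mean(x), cy = mean(y),
                mu20 = 0, mu02 = 0, mu11 = 0))
  cx <- sum((x + x2) * cross) / (6 * A)
  cy <- sum((y + y2) * cross) / (6 * A)
  ixx <- sum((y^2 + y * y2 + y2^2) * cross) / 12      # about origin
  iyy <- sum((x^2 + x * x2 + x2^2) * cross) / 12
  ixy <- sum((x * y2 + 2 * x * y + 2 * x2 * y2 + x2 * y) * cross) / 24
  list(area = abs(A), cx = cx, cy = cy,
       mu20 = iyy / A - cx^2,                          # var of x
       mu02 = ixx / A - cy^2,                          # var of y
       mu11 = ixy / A - cx * cy)
}

ellipse_from_moments <- function(mu20, mu02, mu11) {
  common <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  l1 <- (mu20 + mu02 + common) / 2
  l2 <- (mu20 + mu02 - common) / 2
  l2 <- max(l2, 0)
  list(major = 4 * sqrt(l1), minor = 4 * sqrt(l2),
       eccentricity = if (l1 > 0) sqrt(1 - l2 / l1) else 0,
       orientation = 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi)
}

## convex hull of boundary pixel centers with collinear-vertex pruning;
## falls back to pixel corners for degenerate (collinear) masks
hull_polygon <- function(pts, tol = 1e-9) {
  h <- grDevices::chull(pts[, 2], pts[, 1])
  poly <- pts[h, , drop = FALSE]
  if (abs(polygon_signed_area(poly)) < tol && nrow(pts) >= 2) {
    # 1-px-thin mask: thicken to the half-pixel-buffered rectangle
    corners <- rbind(cbind(pts[, 1] - 0.5, pts[, 2] - 0.5),
                     cbind(pts[, 1] - 0.5, pts[, 2] + 0.5),
                     cbind(pts[, 1] + 0.5, pts[, 2] - 0.5),
                     cbind(pts[, 1] + 0.5, pts[, 2] + 0.5))
    h <- grDevices::chull(corners[, 2], corners[, 1])
    poly <- corners[h, , drop = FALSE]
  }
  # prune collinear vertices
  n <- nrow(poly)
  if (n > 3) {
    keep <- vapply(seq_len(n), function(i) {
      p0 <- poly[if (i == 1) n else i - 1, ]
      p1 <- poly[i, ]
      p2 <- poly[if (i == n) 1 else i + 1, ]
      abs((p1[1] - p0[1]) * (p2[2] - p0[2]) -
          (p2[1] - p0[1]) * (p1[2] - p0[2])) > tol
    }, logical(1))
    poly <- poly[keep, , drop = FALSE]
  }
  poly
}

polygon_perimeter <- function(poly) {
  d <- rbind(poly[-1, , drop = FALSE], poly[1, , drop = FALSE]) - poly
  sum(sqrt(rowSums(d^2)))
}

#' Geometric shape measures of a binary mask
#'
#' Area (pixel count), chain-code perimeter of the traced boundary
#' (axial steps count 1, diagonal steps `sqrt(2)`), moment-equivalent
#' ellipse axes, circularity `4*pi*A/P^2`, bounding-box extent, equivalent
#' diameter, centroid-to-boundary radii and solidity (area over convex
#' hull area).
#'
#' @param mask binary matrix with one 8-connected component of area >= 4.
#' @param prefix prefix for the feature names (default `"geo_"`).
#' @return named numeric vector of 14 features.
#' @export
geometric_features <- function(mask, prefix = "geo_") {
  mask <- as_binary_matrix(mask)
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask")
  area <- nrow(idx)
  bnd <- trace_boundary(mask)
  per <- chain_perimeter(bnd$points)
  ctr <- bnd$centroid
  # population second moments of the pixel coordinates
  mu20 <- mean((idx[, 2] - mean(idx[, 2]))^2)   # var of col (x)
  mu02 <- mean((idx[, 1] - mean(idx[, 1]))^2)
  mu11 <- mean((idx[, 1] - mean(idx[, 1])) * (idx[, 2] - mean(idx[, 2])))
  el <- ellipse_from_moments(mu20, mu02, mu11)
  radii <- sqrt((bnd$points[, 1] - ctr[1])^2 + (bnd$points[, 2] - ctr[2])^2)
  bbox <- (diff(range(idx[, 1])) + 1) * (diff(range(idx[, 2])) + 1)
  hull <- hull_polygon(bnd$points)
  hull_area <- abs(polygon_signed_area(hull))
  out <- c(area = area,
           perimeter = per,
           major_axis = el$major,
           minor_axis = el$minor,
           aspect_ratio = if (el$minor > 0) el$major / el$minor else Inf,
           eccentricity = el$eccentricity,
           orientation = el$orientation,
           circularity = 4 * pi * area / per^2,
           extent = area / bbox,
           equivalent_diameter = sqrt(4 * area / pi),
           mean_radius = mean(radii),
           max_radius = max(radii),
           min_radius = min(radii),
           solidity = if (hull_area > 0) area / hull_area else 1)
  names(out) <- paste0(prefix, names(out))
  out
}

#' Nucleus shape measures
#'
#' The geometric feature set evaluated on the nucleus mask, plus the
#' nucleus-to-cell area ratio.  A missing nucleus channel yields `NA`
#' markers (absent, not zero), which downstream statistics exclude
#' pairwise.
#'
#' @param nucleus_mask binary matrix or `NULL`.
#' @param cell_mask binary matrix of the cell.
#' @return named numeric vector of 15 `nuc_*` features.
#' @export
nucleus_features <- function(nucleus_mask, cell_mask) {
  nms <- c(paste0("nuc_", c("area", "perimeter", "major_axis", "minor_axis",
                            "aspect_ratio", "eccentricity", "orientation",
                            "circularity", "extent", "equivalent_diameter",
                            "mean_radius", "max_radius", "min_radius",
                            "solidity")),
           "nuc_cell_area_ratio")
  if (is.null(nucleus_mask) || sum(nucleus_mask != 0) < 4) {
    out <- rep(NA_real_, length(nms)); names(out) <- nms
    return(out)
  }
  nucleus_mask <- extract_largest_object(nucleus_mask)
  g <- geometric_features(nucleus_mask, prefix = "nuc_")
  c(g, nuc_cell_area_ratio = sum(nucleus_mask) / sum(as_binary_matrix(cell_mask)))
}

#' Convex-hull shape measures
#'
#' The hull is taken over boundary pixel centers with collinear vertices
#' pruned.  Solidity compares mask and hull areas; convexity compares hull
#' and mask perimeters (both 1 for convex shapes, smaller for cells with
#' protrusions or indentations).
#'
#' @param mask binary matrix with one 8-connected component of area >= 4.
#' @return named numeric vector: `hull_area`, `hull_perimeter`,
#'   `hull_solidity`, `hull_convexity`, `hull_circularity`,
#'   `hull_eccentricity`, `hull_n_vertices`.
#' @export
convex_hull_features <- function(mask) {
  mask <- as_binary_matrix(mask)
  area <- sum(mask)
  bnd <- trace_boundary(mask)
  per <- chain_perimeter(bnd$points)
  hull <- hull_polygon(bnd$points)
  hm <- polygon_moments(hull)
  hper <- polygon_perimeter(hull)
  el <- ellipse_from_moments(hm$mu20, hm$mu02, hm$mu11)
  c(hull_area = hm$area,
    hull_perimeter = hper,
    hull_solidity = if (hm$area > 0) area / hm$area else 1,
    hull_convexity = if (per > 0) hper / per else 1,
    hull_circularity = if (hper > 0) 4 * pi * hm$area / hper^2 else 0,
    hull_eccentricity = el$eccentricity,
    hull_n_vertices = nrow(hull))
}
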