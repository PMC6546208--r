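#' Trace the outer boundary of a single-object mask
#'
#' Moore-neighbor tracing with Jacob's stopping criterion.  The walk starts
#' at the uppermost-then-leftmost boundary pixel and proceeds
#' counterclockwise (positive signed polygon area in the (row, col)
#' convention used throughout the package).  Interior holes are ignored;
#' for 1-pixel-thin protrusions the walk passes a pixel more than once
#' (out-and-back), which is the intended closed-walk behavior.
#'
#' @param mask binary matrix with exactly one 8-connected component of
#'   area at least 4.
#' @return An object of class `cell_boundary`: list with `points` (n x 2
#'   integer matrix of (row, col) in traversal order, implicitly closed),
#'   `centroid` (center of mass of the mask, (row, col)), and `n_pixel`.
#' @export
trace_boundary <- function(mask) {
  mask <- as_binary_matrix(mask)
  area <- sum(mask)
  if (area < 4L) stop("mask area must be at least 4")
  if (n_components8(mask) != 1L) stop("mask must have exactly one component")
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- function(r, c) r >= 1L && r <= nr && c >= 1L && c <= nc && mask[r, c] != 0L
  # start: uppermost, then leftmost foreground pixel (row-major scan)
  idx <- which(t(mask) != 0)[1]                  # row-major first pixel
  start <- c((idx - 1L) %/% nc + 1L, (idx - 1L) %% nc + 1L)
  # neighbor directions in counterclockwise visual order (row down):
  # E, NE, N, NW, W, SW, S, SE
  dr <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  dc <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
  dir_index <- function(from, to) {
    d <- to - from
    which(dr == d[1] & dc == d[2])
  }
  pts_r <- integer(0); pts_c <- integer(0)
  cur <- start
  b <- start + c(0L, -1L)                         # backtrack: west of start (background)
  second <- NULL
  max_iter <- 8L * area + 8L
  for (it in seq_len(max_iter)) {
    pts_r <- c(pts_r, cur[1]); pts_c <- c(pts_c, cur[2])
    d0 <- dir_index(cur, b)
    nxt <- NULL
    for (k in 1:8) {
      d <- ((d0 - 1L + k) %% 8L) + 1L
      p <- c(cur[1] + dr[d], cur[2] + dc[d])
      if (fg(p[1], p[2])) { nxt <- p; break }
      b <- p
    }
    if (is.null(nxt)) break                       # isolated pixel (area >= 4 excludes)
    if (is.null(second)) {
      second <- nxt
    } else if (all(cur == start) && all(nxt == second) && it > 1L) {
      # Jacob's criterion: re-entering start with the same first move
      pts_r <- pts_r[-length(pts_r)]; pts_c <- pts_c[-length(pts_c)]
      break
    }
    cur <- nxt
  }
  pts <- cbind(row = pts_r, col = pts_c)
  # enforce CCW (positive signed area in (row, col) shoelace); the scan
  # order above yields CCW for simple blobs, degenerate walks have area 0
  if (polygon_signed_area(pts) < 0) {
    n <- nrow(pts)
    pts <- pts[c(1L, n:2L), , drop = FALSE]
  }
  structure(list(points = pts, centroid = mask_centroid(mask),
                 n_pixel = nrow(pts)),
            class = "cell_boundary")
}

#' @export
print.cell_boundary <- function(x, ...) {
  cat(sprintf("<cell_boundary> %d pixels, centroid (%.2f, %.2f)\n",
              x$n_pixel, x$centroid[1], x$centroid[2]))
  invisible(x)
}

## shoelace signed area; positive = counterclockwise in the package's
## (row, col) convention (row increasing downward)
polygon_signed_area <- function(pts) {
  r <- pts[, 1]; c <- pts[, 2]
  r2 <- c(r[-1], r[1]); c2 <- c(c[-1], c[1])
  0.5 * sum(r * c2 - r2 * c)
}

## chain length of the closed 8-connected boundary walk (1 for axial,
## sqrt(2) for diagonal steps)
chain_perimeter <- function(pts) {
  r <- pts[, 1]; c <- pts[, 2]
  dr <- abs(c(r[-1], r[1]) - r); dc <- abs(c(c[-1], c[1]) - c)
  sum(ifelse(dr + dc == 2L, sqrt(2), ifelse(dr + dc == 1L, 1, 0)))
}

#' Radial boundary signal
#'
#' Distance from the mask center of mass to each boundary pixel, indexed
#' by traversal order.  This parametrization stays single-valued for
#' strongly non-convex cells where the radius as a function of polar angle
#' would not be.
#'
#' @param boundary a [trace_boundary()] result.
#' @return list with `rho` (radii), `x`/`y` (col/row coordinate signals),
#'   `n_pixel`, and `w` (fundamental angular frequency `2*pi/n_pixel`).
#' @export
radial_signal <- function(boundary) {
  stopifnot(inherits(boundary, "cell_boundary"))
  if (boundary$n_pixel < 8L) stop("boundary too short (need >= 8 pixels)")
  dr <- boundary$points[, 1] - boundary$centroid[1]
  dc <- boundary$points[, 2] - boundary$centroid[2]
  list(rho = sqrt(dr^2 + dc^2),
       x = boundary$points[, 2], y = boundary$points[, 1],
       n_pixel = boundary$n_pixel, w = 2 * pi / boundary$n_pixel)
}
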