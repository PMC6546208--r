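#' Single-cell image container
#'
#' Bundles the grayscale intensity frame of one segmented cell with its
#' binary cell mask and an optional nucleus mask.  All three arrays share
#' the same square frame; the cell mask holds exactly one 8-connected
#' object whose center of mass sits within half a pixel of the geometric
#' frame center (the contract produced by [center_cell()]).
#'
#' @param gray numeric matrix, intensities in `[0, 255]`.
#' @param cell_mask binary (0/1 or logical) matrix, same dimensions.
#' @param nucleus_mask optional binary matrix, same dimensions.
#' @param cell_id,condition opaque labels carried through to feature tables.
#' @param check validate the invariants (single object, centering)?
#'
#' @return An object of class `cell_image`: a list with elements `gray`,
#'   `cell_mask`, `nucleus_mask` (possibly `NULL`), `cell_id`, `condition`.
#' @export
cell_image <- function(gray, cell_mask, nucleus_mask = NULL,
                       cell_id = "cell", condition = "none", check = TRUE) {
  gray <- as_gray_matrix(gray)
  cell_mask <- as_binary_matrix(cell_mask)
  if (!identical(dim(gray), dim(cell_mask)))
    stop("gray and cell_mask dimensions differ")
  if (!is.null(nucleus_mask)) {
    nucleus_mask <- as_binary_matrix(nucleus_mask)
    if (!identical(dim(gray), dim(nucleus_mask)))
      stop("nucleus_mask dimensions differ")
  }
  obj <- structure(list(gray = gray, cell_mask = cell_mask,
                        nucleus_mask = nucleus_mask,
                        cell_id = cell_id, condition = condition),
                   class = "cell_image")
  if (check) validate_cell_image(obj)
  obj
}

validate_cell_image <- function(x) {
  if (sum(x$cell_mask) < 1L) stop("empty cell mask")
  if (n_components8(x$cell_mask) != 1L)
    stop("cell_mask must contain exactly one 8-connected component")
  ctr <- mask_centroid(x$cell_mask)
  target <- (dim(x$cell_mask) + 1) / 2
  if (any(abs(ctr - target) > 0.5 + 1e-9))
    stop("cell_mask centroid is not at the frame center (run center_cell)")
  invisible(x)
}

#' @export
print.cell_image <- function(x, ...) {
  d <- dim(x$gray)
  cat(sprintf("<cell_image> %s [%s]  frame %dx%d  area %d px%s\n",
              x$cell_id, x$condition, d[1], d[2], sum(x$cell_mask),
              if (is.null(x$nucleus_mask)) "" else
                sprintf("  nucleus %d px", sum(x$nucleus_mask))))
  invisible(x)
}

as_gray_matrix <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  x
}

as_binary_matrix <- function(x) {
  x <- as.matrix(x)
  m <- matrix(as.integer(x != 0), nrow(x), ncol(x))
  m
}

## center of mass of a binary mask, (row, col), 1-based
mask_centroid <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask")
  c(mean(idx[, 1]), mean(idx[, 2]))
}

#' Otsu threshold for an 8-bit grayscale image
#'
#' Picks the intensity threshold maximizing the between-class variance of
#' the two classes it induces, scanning all 256 candidate 8-bit levels via
#' cumulative histogram moments.  The foreground mask is `gray > threshold`.
#'
#' @param gray numeric matrix with values in `[0, 255]` (rounded to integer
#'   levels for the histogram).
#' @return list with `threshold` (integer level) and `mask` (0/1 matrix).
#' @export
threshold_otsu <- function(gray) {
  v <- pmin(pmax(round(as.vector(gray)), 0), 255)
  h <- tabulate(v + 1L, nbins = 256L)
  if (sum(h > 0) < 2L) stop("degenerate histogram: image has a single intensity level")
  lev <- 0:255
  w0 <- cumsum(h)                 # class 0: levels <= t
  m0 <- cumsum(h * lev)
  n <- w0[256]; mT <- m0[256]
  w1 <- n - w0
  # between-class variance at each candidate t = 0..255
  num <- (mT * w0 - m0 * n)^2
  den <- as.double(w0) * as.double(w1)
  bcv <- ifelse(den > 0, num / den, -Inf)
  t <- lev[which.max(bcv)]        # lowest maximizer
  list(threshold = t, mask = matrix(as.integer(gray > t), nrow(gray), ncol(gray)))
}

## 8-connected labeling of a binary mask via an igraph component pass.
## Returns an integer matrix of labels (0 = background); labels are renumbered
## so that label order follows the row-major scan order of each component's
## first pixel (deterministic tie-breaking downstream).
label8 <- function(mask) {
  mask <- as_binary_matrix(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask != 0)
  lab <- matrix(0L, nr, nc)
  if (length(fg) == 0L) return(lab)
  id <- matrix(0L, nr, nc)
  id[fg] <- seq_along(fg)
  edges <- integer(0)
  # link each foreground pixel to its S, E, SE, NE neighbors (covers all 8)
  offs <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  rc <- arrayInd(fg, c(nr, nc))
  for (o in offs) {
    r2 <- rc[, 1] + o[1]; c2 <- rc[, 2] + o[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    if (!any(ok)) next
    nb <- id[cbind(r2[ok], c2[ok])]
    keep <- nb > 0L
    if (any(keep)) {
      a <- id[fg[ok]][keep]
      edges <- c(edges, rbind(a, nb[keep]))
    }
  }
  g <- igraph::make_graph(edges = edges, n = length(fg), directed = FALSE)
  comp <- igraph::components(g)$membership
  # renumber by first appearance in row-major order
  ord <- order(rc[, 1], rc[, 2])
  first <- !duplicated(comp[ord])
  newlab <- integer(max(comp))
  newlab[comp[ord][first]] <- seq_len(sum(first))
  lab[fg] <- newlab[comp]
  lab
}

n_components8 <- function(mask) {
  l <- label8(mask)
  max(l)
}

#' Keep only the largest 8-connected object
#'
#' Ties in area are broken in favor of the component whose first pixel
#' comes first in row-major scan order.
#'
#' @param mask binary matrix.
#' @return 0/1 matrix containing the single retained component.
#' @export
extract_largest_object <- function(mask) {
  lab <- label8(mask)
  k <- max(lab)
  if (k == 0L) stop("no object: mask is empty")
  areas <- tabulate(lab[lab > 0L], nbins = k)
  # label8 numbers components in row-major first-pixel order, so the first
  # maximal-area label is the tie-break winner
  win <- which.max(areas)
  matrix(as.integer(lab == win), nrow(mask), ncol(mask))
}

#' Fill interior holes of a binary mask
#'
#' Background connectivity is 4-connected (the complement convention for
#' 8-connected objects).
#'
#' @param mask binary matrix.
#' @return 0/1 matrix with holes filled.
#' @export
fill_holes <- function(mask) {
  as_binary_matrix(EBImage::fillHull(as_binary_matrix(mask)))
}

#' Center a cell in a fixed square frame
#'
#' Translates the mask (and intensity image) by an integer offset so the
#' mask center of mass lands within half a pixel of the geometric frame
#' center; no resampling is performed.  Intensities outside the mask are
#' zeroed.
#'
#' @param gray numeric intensity matrix.
#' @param mask binary matrix, same dimensions as `gray`.
#' @param frame_side side of the output square frame in pixels.
#' @param nucleus_mask optional binary matrix translated with the same offset.
#' @param cell_id,condition labels passed to [cell_image()].
#' @return A [cell_image()] in the `frame_side` frame.
#' @export
center_cell <- function(gray, mask, frame_side = 1024L, nucleus_mask = NULL,
                        cell_id = "cell", condition = "none") {
  mask <- as_binary_matrix(mask)
  gray <- as_gray_matrix(gray)
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask")
  bb <- c(diff(range(idx[, 1])), diff(range(idx[, 2]))) + 1
  if (any(bb > frame_side)) stop("frame overflow: object larger than frame")
  ctr <- c(mean(idx[, 1]), mean(idx[, 2]))
  target <- c((frame_side + 1) / 2, (frame_side + 1) / 2)
  sh <- round(target - ctr)
  r2 <- idx[, 1] + sh[1]; c2 <- idx[, 2] + sh[2]
  if (any(r2 < 1 | r2 > frame_side | c2 < 1 | c2 > frame_side))
    stop("frame overflow: object does not fit at the frame center")
  out_mask <- matrix(0L, frame_side, frame_side)
  out_mask[cbind(r2, c2)] <- 1L
  out_gray <- matrix(0, frame_side, frame_side)
  out_gray[cbind(r2, c2)] <- gray[idx]
  out_nuc <- NULL
  if (!is.null(nucleus_mask)) {
    nucleus_mask <- as_binary_matrix(nucleus_mask)
    nidx <- which(nucleus_mask != 0, arr.ind = TRUE)
    out_nuc <- matrix(0L, frame_side, frame_side)
    if (nrow(nidx) > 0) {
      nr2 <- nidx[, 1] + sh[1]; nc2 <- nidx[, 2] + sh[2]
      keep <- nr2 >= 1 & nr2 <= frame_side & nc2 >= 1 & nc2 <= frame_side
      out_nuc[cbind(nr2[keep], nc2[keep])] <- 1L
    }
  }
  cell_image(out_gray, out_mask, out_nuc, cell_id = cell_id,
             condition = condition, check = FALSE)
}

#' Segment and center one cell from a raw grayscale frame
#'
#' Convenience pipeline: Otsu (or fixed) threshold, largest 8-connected
#' object, optional hole filling, centering into a square frame.
#'
#' @param gray numeric intensity matrix in `[0, 255]`.
#' @param threshold `"auto"` for Otsu's method or a numeric level override.
#' @param frame_side output frame side in pixels.
#' @param fill fill mask holes before centering?
#' @inheritParams center_cell
#' @return A [cell_image()].
#' @export
preprocess_cell <- function(gray, threshold = "auto", frame_side = 1024L,
                            fill = TRUE, nucleus_mask = NULL,
                            cell_id = "cell", condition = "none") {
  gray <- as_gray_matrix(gray)
  if (identical(threshold, "auto")) {
    mask <- threshold_otsu(gray)$mask
  } else {
    mask <- matrix(as.integer(gray > as.numeric(threshold)),
                   nrow(gray), ncol(gray))
  }
  mask <- extract_largest_object(mask)
  if (fill) mask <- fill_holes(mask)
  center_cell(gray, mask, frame_side = frame_side,
              nucleus_mask = nucleus_mask, cell_id = cell_id,
              condition = condition)
}
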