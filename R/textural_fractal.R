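## 2-D convolution with replicate padding (kernel flipped, true
## convolution); small kernels only, implemented as shift-and-add.
## Replicate padding avoids spurious gradients at the frame border.
conv2d <- function(img, k) {
  nr <- nrow(img); nc <- ncol(img)
  kr <- nrow(k); kc <- ncol(k)
  cr <- (kr + 1L) %/% 2L; cc <- (kc + 1L) %/% 2L
  out <- matrix(0, nr, nc)
  ridx <- pmin(pmax(seq_len(nr + kr - 1L) - (cr - 1L), 1L), nr)
  cidx <- pmin(pmax(seq_len(nc + kc - 1L) - (cc - 1L), 1L), nc)
  pad <- img[ridx, cidx, drop = FALSE]
  for (u in seq_len(kr)) for (v in seq_len(kc)) {
    w <- k[u, v]
    if (w == 0) next
    out <- out + w * pad[(kr - u + 1L):(kr - u + nr), (kc - v + 1L):(kc - v + nc)]
  }
  out
}

gradient_magnitude <- function(gray, method) {
  if (method == "sobel") {
    kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)       # d/dcol
  } else if (method == "prewitt") {
    kx <- matrix(c(-1, -1, -1, 0, 0, 0, 1, 1, 1), 3, 3)
  } else if (method == "roberts") {
    k1 <- matrix(c(1, 0, 0, -1), 2, 2)
    k2 <- matrix(c(0, 1, -1, 0), 2, 2)
    return(sqrt(conv2d(gray, k1)^2 + conv2d(gray, k2)^2))
  } else stop("unknown gradient method")
  gx <- conv2d(gray, kx)
  gy <- conv2d(gray, t(kx))
  sqrt(gx^2 + gy^2)
}

gaussian_kernel1d <- function(sigma) {
  r <- ceiling(3 * sigma)
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

## Canny edge detector: Gaussian smoothing, Sobel gradients, non-maximum
## suppression, dual-threshold hysteresis.  High threshold set so 70% of
## the in-mask gradient magnitudes fall below it; low = 0.4 * high.
canny_edges <- function(gray, mask, sigma = sqrt(2)) {
  k1 <- gaussian_kernel1d(sigma)
  sm <- conv2d(conv2d(gray, matrix(k1, ncol = 1)), matrix(k1, nrow = 1))
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  gx <- conv2d(sm, kx); gy <- conv2d(sm, t(kx))
  mag <- sqrt(gx^2 + gy^2)
  nr <- nrow(gray); nc <- ncol(gray)
  # non-maximum suppression over 4 quantized gradient directions
  ang <- atan2(gy, gx)
  sector <- (round(ang / (pi / 4)) %% 4)        # 0:E, 1:NE, 2:N, 3:NW
  shift <- function(m, dr, dc) {
    out <- matrix(0, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr); cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  drs <- c(0, -1, -1, -1); dcs <- c(1, 1, 0, -1)
  keep <- matrix(FALSE, nr, nc)
  for (s in 0:3) {
    n1 <- shift(mag, drs[s + 1], dcs[s + 1])
    n2 <- shift(mag, -drs[s + 1], -dcs[s + 1])
    keep <- keep | (sector == s & mag >= n1 & mag >= n2)
  }
  mag[!keep] <- 0
  inm <- mask != 0
  vals <- mag[inm & mag > 0]
  if (length(vals) == 0L) return(matrix(0L, nr, nc))
  hi <- quantile(vals, 0.7, names = FALSE)
  lo <- 0.4 * hi
  strong <- mag >= hi & inm
  weak <- mag >= lo & inm
  if (!any(strong)) return(matrix(0L, nr, nc))
  lab <- label8(weak)
  kept_labels <- unique(lab[strong])
  matrix(as.integer(lab %in% setdiff(kept_labels, 0L)), nr, nc)
}

#' Binarize a cell image by edge detection
#'
#' The four detectors pick up different aspects of the actin structure
#' (voids, fiber borders).  Gradient-magnitude methods (Sobel, Prewitt,
#' Roberts) threshold at four times the mean in-mask gradient magnitude;
#' Canny uses Gaussian smoothing (`sigma = sqrt(2)`) with dual-threshold
#' hysteresis.  Output is restricted to the cell mask; a constant image
#' yields an empty edge map.
#'
#' @param cell a [cell_image()].
#' @param method one of `"sobel"`, `"prewitt"`, `"roberts"`, `"canny"`.
#' @return 0/1 matrix of edge pixels.
#' @export
edge_binarize <- function(cell, method = c("sobel", "prewitt", "roberts", "canny")) {
  method <- match.arg(method)
  inm <- cell$cell_mask != 0
  if (method == "canny") return(canny_edges(cell$gray, cell$cell_mask))
  mag <- gradient_magnitude(cell$gray, method)
  thr <- 4 * mean(mag[inm])
  matrix(as.integer(mag > thr & inm), nrow(cell$gray), ncol(cell$gray))
}

#' Box-counting fractal dimension of a binary image
#'
#' Grids of box side `2^k` (k = 0 .. `floor(log2(min(dim)))`), anchored at
#' the array origin, are overlaid on the image; `N(eps)` counts boxes
#' containing at least one set pixel.  The dimension is the negated slope
#' of the least-squares line of `log N(eps)` against `log eps`.
#'
#' @param binary binary matrix with at least one set pixel.
#' @return fractal dimension (0 for a single pixel or a single scale).
#' @export
box_count_fd <- function(binary) {
  idx <- which(as_binary_matrix(binary) != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("no set pixels")
  kmax <- floor(log2(min(dim(binary))))
  if (kmax < 1L) return(0)
  eps <- 2^(0:kmax)
  n_boxes <- vapply(eps, function(e) {
    br <- (idx[, 1] - 1L) %/% e
    bc <- (idx[, 2] - 1L) %/% e
    length(unique(br * (max(bc) + 1L + 1L) + bc))
  }, numeric(1))
  if (length(unique(n_boxes)) == 1L) return(0)   # e.g. a single pixel
  -unname(coef(lm(log(n_boxes) ~ log(eps)))[2])
}

#' Grayscale fractal-dimension features
#'
#' One box-counting dimension per edge binarization of the actin image.
#' An empty edge map records dimension 0.
#'
#' @param cell a [cell_image()].
#' @param methods edge-detection methods to use.
#' @return named numeric vector `fd_<method>`.
#' @export
fractal_features <- function(cell,
                             methods = c("sobel", "prewitt", "roberts", "canny")) {
  out <- vapply(methods, function(m) {
    e <- edge_binarize(cell, m)
    if (sum(e) == 0L) 0 else box_count_fd(e)
  }, numeric(1))
  names(out) <- paste0("fd_", methods)
  out
}
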