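#' Quantize masked intensities into g gray levels
#'
#' Equal-width binning of the within-mask intensity range into levels
#' `1..g`; pixels outside the mask are `NA` (excluded from co-occurrence
#' pairs).  A constant cell maps to level 1 everywhere.
#'
#' @param cell a [cell_image()].
#' @param g number of gray levels (>= 2).
#' @return integer matrix of levels with `NA` outside the mask.
#' @export
quantize_gray <- function(cell, g = 8L) {
  stopifnot(inherits(cell, "cell_image"), g >= 2L)
  inside <- cell$cell_mask != 0
  v <- cell$gray[inside]
  q <- matrix(NA_integer_, nrow(cell$gray), ncol(cell$gray))
  rng <- range(v)
  if (diff(rng) == 0) {
    q[inside] <- 1L
  } else {
    lv <- pmin(1L + as.integer(floor((v - rng[1]) / diff(rng) * g)), g)
    q[inside] <- lv
  }
  q
}

## displacement (drow, dcol) for a 1-px offset at the given angle,
## measured counterclockwise from the +col axis with row increasing down
glcm_offset <- function(angle) {
  switch(as.character(angle),
         "0"   = c(0L, 1L),
         "45"  = c(-1L, 1L),
         "90"  = c(-1L, 0L),
         "135" = c(-1L, -1L),
         stop("angle must be one of 0, 45, 90, 135"))
}

#' Gray-level co-occurrence matrix for one direction
#'
#' Counts ordered pairs of quantized levels at a 1-pixel displacement,
#' skipping pairs where either pixel lies outside the mask, then
#' symmetrizes (`counts + t(counts)`) so each direction's statistics are
#' invariant to 180-degree reversal.
#'
#' @param quantized integer level matrix from [quantize_gray()] (`NA` =
#'   excluded).
#' @param angle offset direction in degrees: 0, 45, 90 or 135.
#' @param g number of gray levels (defaults to the maximum level present).
#' @return list with `g`, `angle`, `counts` (symmetrized g x g matrix) and
#'   `probs` (normalized to sum 1).
#' @export
compute_glcm <- function(quantized, angle = 0, g = max(quantized, na.rm = TRUE)) {
  off <- glcm_offset(angle)
  nr <- nrow(quantized); nc <- ncol(quantized)
  r1 <- seq_len(nr); c1 <- seq_len(nc)
  rs <- r1[r1 + off[1] >= 1L & r1 + off[1] <= nr]
  cs <- c1[c1 + off[2] >= 1L & c1 + off[2] <= nc]
  if (length(rs) == 0L || length(cs) == 0L) stop("empty GLCM: no valid pairs")
  a <- quantized[rs, cs, drop = FALSE]
  b <- quantized[rs + off[1], cs + off[2], drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) stop("empty GLCM: no valid pairs")
  i <- a[ok]; j <- b[ok]
  counts <- matrix(tabulate((j - 1L) * g + i, nbins = g * g), g, g)
  counts <- counts + t(counts)
  list(g = g, angle = angle, counts = counts, probs = counts / sum(counts))
}

#' The 23 GLCM texture statistics
#'
#' Computed from one normalized symmetric co-occurrence matrix.  Entropy
#' terms use the natural logarithm with `0*log(0) := 0`; correlation-type
#' statistics are defined as 0 when the marginal variance vanishes
#' (single-entry matrix).  Haralick's original convention is kept for the
#' sum variance (deviation about the sum entropy).
#'
#' @param P normalized symmetric g x g matrix (sums to 1).
#' @return named numeric vector of 23 statistics.
#' @export
glcm_statistics <- function(P) {
  g <- nrow(P)
  I <- row(P); J <- col(P)
  plog <- function(p) ifelse(p > 0, log(p), 0)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(seq_len(g) * px); muy <- sum(seq_len(g) * py)
  sx <- sqrt(sum((seq_len(g) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(g) - muy)^2 * py))
  # marginals of i+j (2..2g) and |i-j| (0..g-1)
  psum <- as.numeric(tapply(as.vector(P), factor(as.vector(I + J), levels = 2:(2 * g)), sum))
  psum[is.na(psum)] <- 0
  pdiff <- as.numeric(tapply(as.vector(P), factor(abs(as.vector(I - J)), levels = 0:(g - 1)), sum))
  pdiff[is.na(pdiff)] <- 0
  ks <- 2:(2 * g); kd <- 0:(g - 1)
  sum_avg <- sum(ks * psum)
  sum_ent <- -sum(psum * plog(psum))
  sum_var <- sum((ks - sum_ent)^2 * psum)
  mu_d <- sum(kd * pdiff)
  diff_var <- sum((kd - mu_d)^2 * pdiff)
  diff_ent <- -sum(pdiff * plog(pdiff))
  hxy <- -sum(P * plog(P))
  pxpy <- outer(px, py)
  hxy1 <- -sum(P * plog(pxpy))
  hxy2 <- -sum(pxpy * plog(pxpy))
  hx <- -sum(px * plog(px)); hy <- -sum(py * plog(py))
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy))))
  corr_m <- if (sx > 0 && sy > 0) sum((I - mux) * (J - muy) * P) / (sx * sy) else 0
  corr_h <- if (sx > 0 && sy > 0) (sum(I * J * P) - mux * muy) / (sx * sy) else 0
  c(autocorrelation    = sum(I * J * P),
    contrast           = sum((I - J)^2 * P),
    correlation_m      = corr_m,
    correlation_h      = corr_h,
    cluster_prominence = sum((I + J - mux - muy)^4 * P),
    cluster_shade      = sum((I + J - mux - muy)^3 * P),
    dissimilarity      = sum(abs(I - J) * P),
    energy             = sum(P^2),
    entropy            = hxy,
    homogeneity_a      = sum(P / (1 + abs(I - J))),
    homogeneity_s      = sum(P / (1 + (I - J)^2)),
    max_probability    = max(P),
    sum_of_squares     = sum((I - mux)^2 * P),
    sum_average        = sum_avg,
    sum_variance       = sum_var,
    sum_entropy        = sum_ent,
    difference_variance = diff_var,
    difference_entropy = diff_ent,
    imc1               = imc1,
    imc2               = imc2,
    inverse_difference = sum(P / (1 + abs(I - J))),
    inverse_difference_norm   = sum(P / (1 + abs(I - J) / g)),
    inverse_diff_moment_norm  = sum(P / (1 + (I - J)^2 / g^2)))
}

#' GLCM texture features, averaged over four directions
#'
#' Quantizes the masked intensities to `g` levels, computes the symmetric
#' co-occurrence matrix at 1-pixel displacement for directions 0, 45, 90
#' and 135 degrees, evaluates the 23 statistics for each, and reports the
#' per-statistic average over directions (rotation-invariant on the pixel
#' grid).
#'
#' @param cell a [cell_image()].
#' @param g number of gray levels (default 8).
#' @return named numeric vector of 23 `glcm_*` features.
#' @export
glcm_features <- function(cell, g = 8L) {
  q <- quantize_gray(cell, g)
  stats <- sapply(c(0, 45, 90, 135), function(a) {
    glcm_statistics(compute_glcm(q, a, g = g)$probs)
  })
  out <- rowMeans(stats)
  names(out) <- paste0("glcm_", rownames(stats))
  out
}
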