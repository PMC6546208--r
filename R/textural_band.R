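#' Concentric-band intensity profile
#'
#' Partitions the cell mask into `n_bands` equal-width concentric annuli
#' about the mask center of mass (band width `delta_r = R_max / n_bands`,
#' where `R_max` is the largest centroid-to-pixel distance) and records the
#' mean intensity in each band.  Radially symmetric actin reorganization —
#' e.g. the alternating dense/void rings seen under Cytochalasin D — shows
#' up directly in this profile.
#'
#' @param cell a [cell_image()].
#' @param n_bands number of annuli (default 10).
#' @return list with `n_bands`, `delta_r`, `band_means` (empty bands get
#'   mean 0), `global_mean` (mean intensity over the mask).
#' @export
band_profile <- function(cell, n_bands = 10L) {
  stopifnot(inherits(cell, "cell_image"))
  idx <- which(cell$cell_mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask")
  ctr <- mask_centroid(cell$cell_mask)
  r <- sqrt((idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2)
  rmax <- max(r)
  v <- cell$gray[idx]
  if (rmax == 0) {                       # single-pixel degenerate case
    bm <- c(mean(v), rep(0, n_bands - 1L))
    return(list(n_bands = n_bands, delta_r = 0, band_means = bm,
                global_mean = mean(v)))
  }
  dr <- rmax / n_bands
  band <- pmin(floor(r / dr), n_bands - 1L) + 1L   # last band closed above
  sums <- tapply(v, factor(band, levels = seq_len(n_bands)), sum)
  cnts <- tabulate(band, nbins = n_bands)
  bm <- ifelse(cnts > 0, ifelse(is.na(sums), 0, sums) / pmax(cnts, 1L), 0)
  list(n_bands = n_bands, delta_r = dr, band_means = as.numeric(bm),
       global_mean = mean(v))
}

#' Band-based intensity features
#'
#' The per-band means plus five summary quantifiers: index and value of the
#' minimum- and maximum-mean bands (1-based, ties to the innermost band) and
#' the above-average adjusted intensity
#' `AAAI = sum_b max(0, mean_b - global_mean) / (n_bands * global_mean)`,
#' a normalized measure of how much intensity is concentrated above the
#' cell-wide average.
#'
#' @param profile a [band_profile()] result.
#' @return named numeric vector of `n_bands + 5` features
#'   (`band_mean_1..n`, `band_min_index`, `band_min`, `band_max_index`,
#'   `band_max`, `band_aaai`).
#' @export
band_features <- function(profile) {
  bm <- profile$band_means
  gm <- profile$global_mean
  aaai <- if (gm > 0) sum(pmax(0, bm - gm)) / (profile$n_bands * gm) else 0
  out <- c(bm,
           which.min(bm), min(bm),
           which.max(bm), max(bm),
           aaai)
  names(out) <- c(paste0("band_mean_", seq_along(bm)),
                  "band_min_index", "band_min",
                  "band_max_index", "band_max", "band_aaai")
  out
}
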