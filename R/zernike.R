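## Zernike radial polynomial coefficients for (n, m): the coefficient of
## rho^(n - 2s) is (-1)^s (n-s)! / (s! ((n+m)/2 - s)! ((n-m)/2 - s)!).
## Evaluated through log-factorials to stay exact in double precision up
## to n = 30.
zernike_radial_coefs <- function(n, m) {
  s <- 0:((n - m) / 2)
  (-1)^s * exp(lfactorial(n - s) - lfactorial(s) -
               lfactorial((n + m) / 2 - s) - lfactorial((n - m) / 2 - s))
}

## the (n, m) pairs with n <= order_max, 0 <= m <= min(n, rep_max),
## n - m even
zernike_index_table <- function(order_max = 30L, rep_max = 10L) {
  out <- do.call(rbind, lapply(0:order_max, function(n) {
    m <- seq(n %% 2L, min(n, rep_max), by = 2L)
    if (length(m) == 0L) return(NULL)
    cbind(n = n, m = m)
  }))
  out
}

#' Zernike moment magnitudes of a centered binary mask
#'
#' Projects the mask onto the Zernike polynomial basis over the unit disk.
#' The frame's inscribed circle is mapped to the unit disk with one fixed
#' scale shared by the whole cohort (no per-cell size normalization), so
#' `|Z_00|` stays exactly proportional to cell area across cells in the
#' same frame.  Magnitudes are invariant to rotation about the frame
#' center; pixels outside the inscribed circle are ignored (with a
#' warning if any mask pixel is clipped).
#'
#' `Z_nm = (n+1)/pi * sum_pixels f(x, y) R_nm(rho) exp(-i m theta) dA`
#' with `f` binary and `dA = (2/F)^2` the pixel area in disk units.
#'
#' @param mask binary matrix in a square frame of side `F`, centered (the
#'   [cell_image()] contract).
#' @param order_max maximum order `n` (default 30).
#' @param rep_max maximum repetition `m` (default 10).
#' @return named numeric vector `z_<n>_<m>` of magnitudes `|Z_nm|` for all
#'   `(n, m)` with `n - m` even.
#' @export
zernike_magnitudes <- function(mask, order_max = 30L, rep_max = 10L) {
  mask <- as_binary_matrix(mask)
  F <- nrow(mask)
  if (ncol(mask) != F) stop("mask frame must be square")
  tab <- zernike_index_table(order_max, rep_max)
  idx <- which(mask != 0, arr.ind = TRUE)
  ctr <- (F + 1) / 2
  x <- (idx[, 2] - ctr) / (F / 2)
  y <- (idx[, 1] - ctr) / (F / 2)
  rho <- sqrt(x^2 + y^2)
  keep <- rho <= 1
  if (any(!keep)) warning("mask extends beyond the frame's inscribed circle; clipped")
  rho <- rho[keep]
  theta <- atan2(y[keep], x[keep])
  dA <- (2 / F)^2
  out <- numeric(nrow(tab))
  names(out) <- paste0("z_", tab[, "n"], "_", tab[, "m"])
  if (length(rho) == 0L) return(out)
  # cache rho powers and angular harmonics
  pow <- outer(rho, 0:order_max, `^`)
  cosm <- lapply(0:rep_max, function(m) cos(m * theta))
  sinm <- lapply(0:rep_max, function(m) sin(m * theta))
  for (k in seq_len(nrow(tab))) {
    n <- tab[k, "n"]; m <- tab[k, "m"]
    cf <- zernike_radial_coefs(n, m)
    R <- pow[, n - 2 * (seq_along(cf) - 1L) + 1L, drop = FALSE] %*% cf
    re <- sum(R * cosm[[m + 1L]])
    im <- -sum(R * sinm[[m + 1L]])
    out[k] <- (n + 1) / pi * dA * sqrt(re^2 + im^2)
  }
  out
}
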