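#' Fourier decomposition of a periodic boundary signal
#'
#' Expands a closed (periodic) signal of length `N` as
#' `C0 + sum_n A_n cos(w n t) + B_n sin(w n t)` with `w = 2*pi/N` and
#' `t = 0..N-1`.  The amplitudes carry the `2/N` normalization so that a
#' pure cosine of amplitude `a` yields `C_n = a`.  The rotation-invariant
#' amplitudes are `C_n = sqrt(A_n^2 + B_n^2)`, which discard the phase and
#' halve the number of descriptors.
#'
#' @param signal numeric vector (one period of the closed signal).
#' @param n_max number of harmonics (default 35); silently truncated to
#'   `floor((length(signal) - 1) / 2)` for short signals.
#' @return An object of class `fourier_expansion`: list with `C0`, `A`,
#'   `B`, `Cn` (each length `n_max`), `n_max`, `n_signal`.
#' @export
fourier_decompose <- function(signal, n_max = 35L) {
  N <- length(signal)
  if (N < 3L) stop("signal too short")
  n_max <- min(n_max, floor((N - 1) / 2))
  X <- fft(signal)
  n <- seq_len(n_max)
  A <- 2 / N * Re(X[n + 1L])
  B <- -2 / N * Im(X[n + 1L])
  structure(list(C0 = mean(signal), A = A, B = B,
                 Cn = sqrt(A^2 + B^2), n_max = n_max, n_signal = N),
            class = "fourier_expansion")
}

#' Reconstruct a signal from its truncated Fourier expansion
#'
#' @param expansion a [fourier_decompose()] result.
#' @param n_pixel length of the reconstructed period (defaults to the
#'   decomposed signal length).
#' @return numeric vector `C0 + sum_n A_n cos(w n t) + B_n sin(w n t)`.
#' @export
reconstruct_signal <- function(expansion, n_pixel = expansion$n_signal) {
  stopifnot(inherits(expansion, "fourier_expansion"))
  t <- 0:(n_pixel - 1L)
  w <- 2 * pi / n_pixel
  wt <- outer(t, seq_len(expansion$n_max)) * w
  as.numeric(expansion$C0 + cos(wt) %*% expansion$A + sin(wt) %*% expansion$B)
}

#' Boundary waviness features
#'
#' Rotation-invariant amplitudes `C0, C1, ..., C_n_max` of the Fourier
#' expansion of the radial boundary signal.  `C0` equals the mean cell
#' radius by construction; low-frequency amplitudes capture periodic
#' variation of the boundary (lobes, protrusion patterns).
#'
#' @param cell a [cell_image()].
#' @param n_max number of harmonics kept (default 35).
#' @return named numeric vector `wav_C0, wav_C1, ..., wav_C<n_max>`
#'   (`n_max + 1` values; harmonics beyond what a short boundary supports
#'   are reported as 0).
#' @export
waviness_features <- function(cell, n_max = 35L) {
  sig <- radial_signal(trace_boundary(cell$cell_mask))
  fe <- fourier_decompose(sig$rho, n_max = n_max)
  Cn <- c(fe$Cn, rep(0, n_max - fe$n_max))
  out <- c(fe$C0, Cn)
  names(out) <- paste0("wav_C", 0:n_max)
  out
}

#' Boundary roughness features
#'
#' Statistics of the residual between the radial boundary signal and its
#' `n_max`-term Fourier reconstruction: the high-frequency, non-periodic
#' component of boundary irregularity.  The eight statistics follow the
#' surface-roughness conventions: mean absolute deviation (Ra), root mean
#' square (Rq), maximum peak (Rp), minimum valley (Rv), peak-to-valley
#' height (Rt), standard deviation, skewness and (non-excess) kurtosis,
#' the last three in their population forms.
#'
#' @param cell a [cell_image()].
#' @param n_max harmonics in the reconstruction (default 35).
#' @return named numeric vector of 8 `rough_*` features.
#' @export
roughness_features <- function(cell, n_max = 35L) {
  sig <- radial_signal(trace_boundary(cell$cell_mask))
  fe <- fourier_decompose(sig$rho, n_max = n_max)
  if (fe$n_max < n_max)
    warning("boundary shorter than 2*n_max+1 pixels; residual of the truncated expansion")
  e <- sig$rho - reconstruct_signal(fe)
  m2 <- mean((e - mean(e))^2)
  sk <- if (m2 > 0) mean((e - mean(e))^3) / m2^1.5 else 0
  ku <- if (m2 > 0) mean((e - mean(e))^4) / m2^2 else 0
  c(rough_ra = mean(abs(e)),
    rough_rq = sqrt(mean(e^2)),
    rough_rp = max(e),
    rough_rv = min(e),
    rough_rt = max(e) - min(e),
    rough_sd = sqrt(m2),
    rough_skewness = sk,
    rough_kurtosis = ku)
}
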