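#' Specification for synthetic single-cell images
#'
#' Defines a population of star-shaped cells with boundary
#' `rho(theta) = R + sum_n a_n cos(n theta + phi_n)`: low-frequency
#' harmonics (`waviness`, n <= 35) model lobes and protrusion patterns,
#' high-frequency components (`rough_freqs`, n in 40..80) model fine
#' boundary roughness below the 35-harmonic cutoff.  Interior textures
#' emulate drug phenotypes: `"banded"` gives concentric rings of
#' alternating intensity (Cytochalasin-D-like), `"fibrous"` gives
#' oriented fiber bundles (stress-fiber-like), `"speckle"` gives punctate
#' foci, `"uniform"` is a flat noisy fill.
#'
#' @param n_cells cells per population.
#' @param seed base seed; each cell draws from a substream derived from
#'   `(seed, cell index)`, so populations are order-independent.
#' @param mean_radius_px,radius_sd_px mean cell radius R and its
#'   between-cell standard deviation, in pixels.
#' @param waviness data frame with columns `freq`, `mean`, `sd`: per-cell
#'   amplitudes `a_n ~ N(mean, sd)` at those harmonics (phases uniform).
#' @param roughness_amp amplitude of each high-frequency component.
#' @param rough_freqs harmonic numbers of the roughness components.
#' @param texture `"uniform"`, `"banded"`, `"fibrous"` or `"speckle"`.
#' @param band_pattern 10-vector of band intensities (banded mode).
#' @param base_intensity,noise_sd flat fill level and Gaussian pixel
#'   noise.
#' @param n_fibers,fiber_width_px,fiber_kappa fibrous mode: number of
#'   fibers, Gaussian profile width, von Mises orientation concentration.
#' @param speckle_density fraction of mask pixels turned into bright foci.
#' @param nucleus_radius_fraction nucleus radius as a fraction of R.
#' @param frame_side output frame side in pixels.
#' @return list of class `synth_spec`.
#' @export
synth_spec <- function(n_cells = 40L, seed = 1L,
                       mean_radius_px = 150, radius_sd_px = 20,
                       waviness = data.frame(freq = 2:8,
                                             mean = 12 / (2:8),
                                             sd = 4 / (2:8)),
                       roughness_amp = 1, rough_freqs = c(45L, 60L, 75L),
                       texture = c("uniform", "banded", "fibrous", "speckle"),
                       band_pattern = rep(c(60, 180), 5),
                       base_intensity = 120, noise_sd = 15,
                       n_fibers = 60L, fiber_width_px = 2, fiber_kappa = 4,
                       speckle_density = 0.01,
                       nucleus_radius_fraction = 0.35,
                       frame_side = 1024L) {
  texture <- match.arg(texture)
  stopifnot(mean_radius_px > sum(abs(waviness$mean)) + abs(roughness_amp) * length(rough_freqs))
  structure(as.list(environment()), class = "synth_spec")
}

## deterministic per-cell seed below 2^31
cell_seed <- function(seed, index) {
  as.integer((as.double(seed) * 7919 + index * 104729) %% 2147483647)
}

## von Mises sampler (Best & Fisher 1979 rejection scheme)
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 1e-8) return(runif(n, -pi, pi) + mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      c0 <- kappa * (r - f)
      if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
        out[i] <- mu + sign(u[3] - 0.5) * acos(f)
        break
      }
    }
  }
  out
}

## draw one boundary parameter set from the spec using the current RNG
draw_boundary_params <- function(spec) {
  for (try in 1:100) {
    R <- rnorm(1, spec$mean_radius_px, spec$radius_sd_px)
    freq <- c(spec$waviness$freq, spec$rough_freqs)
    amp <- c(rnorm(nrow(spec$waviness), spec$waviness$mean, spec$waviness$sd),
             rep(spec$roughness_amp, length(spec$rough_freqs)))
    phase <- runif(length(freq), 0, 2 * pi)
    th <- seq(0, 2 * pi, length.out = 721)[-721]
    rho <- R + as.numeric(cos(outer(th, freq) + rep(phase, each = length(th))) %*% amp)
    if (min(rho) > 2 && max(rho) < spec$frame_side / 2 - 2)
      return(list(R = R, freq = freq, amp = amp, phase = phase))
  }
  stop("could not draw a valid boundary (radius negative or cell larger than ",
       "the frame's inscribed circle); lower the amplitudes or the mean ",
       "radius relative to frame_side")
}

#' Rasterize one synthetic cell boundary
#'
#' Evaluates `rho(theta)` exactly at every pixel (the boundary is
#' star-shaped about the frame center, so containment is
#' `r <= rho(theta)`), then re-centers the mask on its center of mass.
#' Uses the current RNG state; see [generate_cells()] for the seeded
#' population interface.
#'
#' @param spec a [synth_spec()].
#' @return list with `mask` (0/1 matrix), `boundary`
#'   ([trace_boundary()] result) and `params` (drawn `R`, `freq`, `amp`,
#'   `phase`).
#' @export
make_boundary <- function(spec) {
  p <- draw_boundary_params(spec)
  F <- spec$frame_side
  ctr <- (F + 1) / 2
  dr <- row(matrix(0, F, F)) - ctr
  dc <- col(matrix(0, F, F)) - ctr
  th <- atan2(dr, dc)
  rho <- matrix(p$R, F, F)
  for (i in seq_along(p$freq))
    rho <- rho + p$amp[i] * cos(p$freq[i] * th + p$phase[i])
  mask <- matrix(as.integer(sqrt(dr^2 + dc^2) <= rho), F, F)
  mask <- extract_largest_object(mask)
  mask <- fill_holes(mask)
  cent <- center_cell(mask * 0, mask, frame_side = F)
  list(mask = cent$cell_mask, boundary = trace_boundary(cent$cell_mask),
       params = p)
}

#' Synthesize an interior texture for a mask
#'
#' Uses the current RNG state.  All modes clip to `[0, 255]` and are zero
#' outside the mask; masks stay binary (anti-aliasing happens only in
#' textures).
#'
#' @param mask 0/1 matrix.
#' @param spec a [synth_spec()] (fields `texture`, `band_pattern`,
#'   `base_intensity`, `noise_sd`, fiber and speckle parameters).
#' @return numeric intensity matrix.
#' @export
make_texture <- function(mask, spec) {
  inm <- mask != 0
  nr <- nrow(mask); nc <- ncol(mask)
  g <- matrix(0, nr, nc)
  n_in <- sum(inm)
  if (spec$texture == "uniform") {
    g[inm] <- spec$base_intensity + rnorm(n_in, 0, spec$noise_sd)
  } else if (spec$texture == "banded") {
    idx <- which(inm, arr.ind = TRUE)
    ctr <- mask_centroid(mask)
    r <- sqrt((idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2)
    nb <- length(spec$band_pattern)
    band <- pmin(floor(r / (max(r) / nb)), nb - 1L) + 1L
    g[inm] <- spec$band_pattern[band] + rnorm(n_in, 0, spec$noise_sd)
  } else if (spec$texture == "fibrous") {
    idx <- which(inm, arr.ind = TRUE)
    ctr <- mask_centroid(mask)
    rmax <- max(sqrt((idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2))
    centers <- idx[sample.int(nrow(idx), spec$n_fibers, replace = TRUE), , drop = FALSE]
    angs <- rvonmises(spec$n_fibers, mu = 0, kappa = spec$fiber_kappa)
    len <- runif(spec$n_fibers, 0.3, 0.8) * rmax
    acc <- matrix(0, nr, nc)
    w <- spec$fiber_width_px
    rad <- ceiling(2 * w)
    for (i in seq_len(spec$n_fibers)) {
      t <- seq(-len[i] / 2, len[i] / 2, by = 0.5)
      pr <- centers[i, 1] + t * sin(angs[i])
      pc <- centers[i, 2] + t * cos(angs[i])
      for (j in seq_along(t)) {      # Gaussian-profile splat around each sample
        r0 <- round(pr[j]); c0 <- round(pc[j])
        rs <- max(1, r0 - rad):min(nr, r0 + rad)
        cs <- max(1, c0 - rad):min(nc, c0 + rad)
        d2 <- outer((rs - pr[j])^2, (cs - pc[j])^2, `+`)
        acc[rs, cs] <- acc[rs, cs] + exp(-d2 / (2 * w^2))
      }
    }
    acc <- acc / max(acc[inm], 1e-12)
    g[inm] <- spec$base_intensity / 2 + 200 * acc[inm] + rnorm(n_in, 0, spec$noise_sd)
  } else if (spec$texture == "speckle") {
    g[inm] <- spec$base_intensity + rnorm(n_in, 0, spec$noise_sd)
    hot <- runif(n_in) < spec$speckle_density
    g[inm][hot] <- 255
  }
  g[inm] <- pmin(pmax(g[inm], 0), 255)
  g
}

#' Generate a synthetic cell population in memory
#'
#' Each cell is drawn from its own RNG substream keyed by
#' `(seed, index)`, so the same cell index always produces the same cell
#' regardless of how many cells are generated.
#'
#' @param spec a [synth_spec()].
#' @param n number of cells (default `spec$n_cells`).
#' @param condition condition label attached to each cell.
#' @param seed base seed (default `spec$seed`).
#' @return list of [cell_image()] objects.
#' @export
generate_cells <- function(spec, n = spec$n_cells, condition = "synthetic",
                           seed = spec$seed) {
  lapply(seq_len(n), function(i) {
    set.seed(cell_seed(seed, i))
    b <- make_boundary(spec)
    gray <- make_texture(b$mask, spec)
    nuc <- NULL
    if (!is.null(spec$nucleus_radius_fraction) &&
        spec$nucleus_radius_fraction > 0) {
      F <- spec$frame_side
      ctr <- (F + 1) / 2
      rn <- spec$nucleus_radius_fraction * b$params$R
      nuc <- matrix(0L, F, F)
      dr <- row(nuc) - ctr; dc <- col(nuc) - ctr
      nuc[dr^2 + dc^2 <= rn^2 & b$mask != 0] <- 1L
    }
    cell_image(gray, b$mask, nuc,
               cell_id = sprintf("%s_%03d", condition, i),
               condition = condition, check = FALSE)
  })
}

#' Write a synthetic population to disk
#'
#' Emits per-cell `<cell_id>_gray.png` / `<cell_id>_mask.png` (and
#' `_nucleus.png` when present) plus a `manifest.csv` consumable by
#' [load_manifest()].  Deterministic for a given spec and seed.
#'
#' @param specs_by_condition named list of [synth_spec()]s, one per
#'   condition.
#' @param out_dir output directory.
#' @param force overwrite an existing directory?
#' @return path of the manifest CSV, invisibly.
#' @export
make_population <- function(specs_by_condition, out_dir, force = FALSE) {
  stopifnot(length(specs_by_condition) >= 1L, !is.null(names(specs_by_condition)))
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force)
    stop("output directory exists; use force = TRUE to overwrite")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (cond in names(specs_by_condition)) {
    spec <- specs_by_condition[[cond]]
    cells <- generate_cells(spec, condition = cond)
    for (cell in cells) {
      gp <- file.path(out_dir, paste0(cell$cell_id, "_gray.png"))
      mp <- file.path(out_dir, paste0(cell$cell_id, "_mask.png"))
      png::writePNG(cell$gray / 255, gp)
      png::writePNG(cell$cell_mask + 0, mp)
      np <- ""
      if (!is.null(cell$nucleus_mask)) {
        np <- file.path(out_dir, paste0(cell$cell_id, "_nucleus.png"))
        png::writePNG(cell$nucleus_mask + 0, np)
      }
      rows[[length(rows) + 1L]] <-
        data.frame(cell_id = cell$cell_id, condition = cond,
                   gray_path = gp, cell_mask_path = mp,
                   nucleus_mask_path = np)
    }
  }
  manifest <- do.call(rbind, rows)
  mpath <- file.path(out_dir, "manifest.csv")
  write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}
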