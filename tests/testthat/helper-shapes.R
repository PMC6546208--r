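# fixture builders, all generated in code

disk_mask <- function(frame, r, ctr = (frame + 1) / 2) {
  m <- matrix(0L, frame, frame)
  m[(row(m) - ctr)^2 + (col(m) - ctr)^2 <= r^2] <- 1L
  m
}

# star-shaped mask rho(theta) = R + sum amp_i cos(freq_i * theta + phase_i),
# centered on the frame
star_mask <- function(frame, R, amp = 0, freq = 5, phase = 0) {
  m <- matrix(0L, frame, frame)
  ctr <- (frame + 1) / 2
  dr <- row(m) - ctr; dc <- col(m) - ctr
  th <- atan2(dr, dc)
  rho <- R
  for (i in seq_along(freq)) rho <- rho + amp[i] * cos(freq[i] * th + phase[i])
  m[sqrt(dr^2 + dc^2) <= rho] <- 1L
  m
}

flat_cell <- function(mask, value = 100) {
  cell_image(mask * value, mask, check = FALSE)
}

# rotate a square matrix by 90 degrees counterclockwise
rot90 <- function(m) t(m)[ncol(m):1, , drop = FALSE]

# depth-d Sierpinski carpet (3^d x 3^d binary matrix)
sierpinski_carpet <- function(depth) {
  m <- matrix(1L, 1, 1)
  for (i in seq_len(depth)) {
    n <- nrow(m)
    M <- matrix(0L, 3 * n, 3 * n)
    for (u in 0:2) for (v in 0:2)
      if (!(u == 1 && v == 1)) M[u * n + seq_len(n), v * n + seq_len(n)] <- m
    m <- M
  }
  m
}

# brute-force GLCM statistics: explicit double loops over the g x g matrix
glcm_statistics_bruteforce <- function(P) {
  g <- nrow(P)
  lg <- function(p) if (p > 0) log(p) else 0
  px <- rowSums(P); py <- colSums(P)
  mux <- 0; muy <- 0
  for (i in 1:g) { mux <- mux + i * px[i]; muy <- muy + i * py[i] }
  sx2 <- 0; sy2 <- 0
  for (i in 1:g) { sx2 <- sx2 + (i - mux)^2 * px[i]; sy2 <- sy2 + (i - muy)^2 * py[i] }
  sx <- sqrt(sx2); sy <- sqrt(sy2)
  acc <- ctr <- cm <- ch <- cp <- cs <- dis <- ene <- ent <- ha <- hs <- ssq <- 0
  inv <- invn <- idmn <- 0
  psum <- rep(0, 2 * g - 1); pdiff <- rep(0, g)
  for (i in 1:g) for (j in 1:g) {
    p <- P[i, j]
    acc <- acc + i * j * p
    ctr <- ctr + (i - j)^2 * p
    cm <- cm + (i - mux) * (j - muy) * p
    cp <- cp + (i + j - mux - muy)^4 * p
    cs <- cs + (i + j - mux - muy)^3 * p
    dis <- dis + abs(i - j) * p
    ene <- ene + p^2
    ent <- ent - p * lg(p)
    ha <- ha + p / (1 + abs(i - j))
    hs <- hs + p / (1 + (i - j)^2)
    ssq <- ssq + (i - mux)^2 * p
    inv <- inv + p / (1 + abs(i - j))
    invn <- invn + p / (1 + abs(i - j) / g)
    idmn <- idmn + p / (1 + (i - j)^2 / g^2)
    psum[i + j - 1] <- psum[i + j - 1] + p
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + p
  }
  corr_m <- if (sx > 0 && sy > 0) cm / (sx * sy) else 0
  corr_h <- if (sx > 0 && sy > 0) (acc - mux * muy) / (sx * sy) else 0
  sa <- se <- 0
  for (k in seq_along(psum)) {
    sa <- sa + (k + 1) * psum[k]
    se <- se - psum[k] * lg(psum[k])
  }
  sv <- 0
  for (k in seq_along(psum)) sv <- sv + (k + 1 - se)^2 * psum[k]
  mud <- 0
  for (k in seq_along(pdiff)) mud <- mud + (k - 1) * pdiff[k]
  dv <- de <- 0
  for (k in seq_along(pdiff)) {
    dv <- dv + (k - 1 - mud)^2 * pdiff[k]
    de <- de - pdiff[k] * lg(pdiff[k])
  }
  hxy1 <- hxy2 <- hx <- hy <- 0
  for (i in 1:g) { hx <- hx - px[i] * lg(px[i]); hy <- hy - py[i] * lg(py[i]) }
  for (i in 1:g) for (j in 1:g) {
    hxy1 <- hxy1 - P[i, j] * lg(px[i] * py[j])
    hxy2 <- hxy2 - px[i] * py[j] * lg(px[i] * py[j])
  }
  imc1 <- if (max(hx, hy) > 0) (ent - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - ent))))
  mp <- max(P)
  c(autocorrelation = acc, contrast = ctr, correlation_m = corr_m,
    correlation_h = corr_h, cluster_prominence = cp, cluster_shade = cs,
    dissimilarity = dis, energy = ene, entropy = ent, homogeneity_a = ha,
    homogeneity_s = hs, max_probability = mp, sum_of_squares = ssq,
    sum_average = sa, sum_variance = sv, sum_entropy = se,
    difference_variance = dv, difference_entropy = de, imc1 = imc1,
    imc2 = imc2, inverse_difference = inv, inverse_difference_norm = invn,
    inverse_diff_moment_norm = idmn)
}

# brute-force Zernike magnitude: direct per-pixel complex summation with
# the radial polynomial evaluated from plain factorials
zernike_bruteforce <- function(mask, n, m) {
  F <- nrow(mask)
  ctr <- (F + 1) / 2
  acc <- complex(real = 0, imaginary = 0)
  for (r in seq_len(F)) for (c in seq_len(F)) {
    if (mask[r, c] == 0) next
    x <- (c - ctr) / (F / 2); y <- (r - ctr) / (F / 2)
    rho <- sqrt(x^2 + y^2)
    if (rho > 1) next
    th <- atan2(y, x)
    R <- 0
    for (s in 0:((n - m) / 2))
      R <- R + (-1)^s * factorial(n - s) /
        (factorial(s) * factorial((n + m) / 2 - s) * factorial((n - m) / 2 - s)) *
        rho^(n - 2 * s)
    acc <- acc + R * exp(-1i * m * th) * (2 / F)^2
  }
  (n + 1) / pi * Mod(acc)
}

# in-memory feature table with prescribed values for analysis tests
fake_feature_table <- function(values, category, condition) {
  colnames(values) <- paste0("f", seq_len(ncol(values)))
  structure(list(values = values, category = category,
                 condition = condition,
                 cell_id = paste0("c", seq_len(nrow(values)))),
            class = "feature_table")
}

# independent re-implementations of small geometric primitives used to
# check package invariants
mask_centroid_for_test <- function(m) {
  idx <- which(m != 0, arr.ind = TRUE)
  c(mean(idx[, 1]), mean(idx[, 2]))
}

polygon_area_for_test <- function(pts) {
  r <- pts[, 1]; c <- pts[, 2]
  r2 <- c(r[-1], r[1]); c2 <- c(c[-1], c[1])
  0.5 * sum(r * c2 - r2 * c)
}

# 8-connected component count by breadth-first flood fill
n_components_for_test <- function(mask) {
  mask <- mask != 0
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  ncomp <- 0
  for (start in which(mask & !seen)) {
    if (seen[start]) next
    ncomp <- ncomp + 1
    queue <- start
    seen[start] <- TRUE
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      r <- (p - 1) %% nr + 1; c <- (p - 1) %/% nr + 1
      for (dr in -1:1) for (dc in -1:1) {
        r2 <- r + dr; c2 <- c + dc
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
            mask[r2, c2] && !seen[r2, c2]) {
          seen[r2, c2] <- TRUE
          queue <- c(queue, (c2 - 1) * nr + r2)
        }
      }
    }
  }
  ncomp
}

# small synthetic population spec used across tests
small_spec <- function(...) {
  synth_spec(n_cells = 4L, seed = 11L, mean_radius_px = 45, radius_sd_px = 5,
             waviness = data.frame(freq = c(3, 5), mean = c(4, 3), sd = c(1, 1)),
             roughness_amp = 0.5, frame_side = 160L, ...)
}
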