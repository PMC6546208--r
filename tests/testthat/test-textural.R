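test_that("band profile bins mask pixels into concentric annuli", {
  ci <- flat_cell(disk_mask(128, 40))
  bp <- band_profile(ci)
  expect_equal(bp$band_means, rep(100, 10))
  bf <- band_features(bp)
  expect_equal(unname(bf["band_min_index"]), 1)
  expect_equal(unname(bf["band_max_index"]), 1)
  expect_equal(unname(bf["band_aaai"]), 0)

  # bright ring at r in [0.5R, 0.6R) lands in band 6 (1-based)
  m <- disk_mask(128, 40)
  ctr <- 64.5
  rr <- sqrt((row(m) - ctr)^2 + (col(m) - ctr)^2)
  g <- ifelse(rr >= 20 & rr < 24, 200, 20); g[m == 0] <- 0
  bf2 <- band_features(band_profile(cell_image(g, m, check = FALSE)))
  expect_equal(unname(bf2["band_max_index"]), 6)

  # single-pixel mask: innermost band carries the pixel, others are 0
  one <- matrix(0L, 9, 9); one[5, 5] <- 1L
  bp1 <- band_profile(cell_image(one * 77, one, check = FALSE))
  expect_equal(bp1$band_means, c(77, rep(0, 9)))
})

test_that("band summary quantifiers follow the stated formulas", {
  prof <- list(n_bands = 10L, delta_r = 1,
               band_means = c(10, 10, 10, 10, 10, 100, 10, 10, 10, 10),
               global_mean = 19)
  bf <- band_features(prof)
  expect_equal(unname(bf["band_max_index"]), 6)   # 1-based
  expect_equal(unname(bf["band_max"]), 100)
  expect_equal(unname(bf["band_min_index"]), 1)
  expect_equal(unname(bf["band_min"]), 10)
  expect_equal(unname(bf["band_aaai"]), (100 - 19) / (10 * 19))

  inc <- list(n_bands = 10L, delta_r = 1, band_means = 1:10, global_mean = 5.5)
  bfi <- band_features(inc)
  expect_equal(unname(bfi["band_min_index"]), 1)
  expect_equal(unname(bfi["band_max_index"]), 10)

  # zero global mean: AAAI defined as 0
  z <- list(n_bands = 10L, delta_r = 1, band_means = rep(0, 10), global_mean = 0)
  expect_equal(unname(band_features(z)["band_aaai"]), 0)
})

test_that("gray quantization uses equal-width within-mask bins", {
  m <- matrix(1L, 4, 4)
  g <- matrix(c(0, 255), 4, 4)
  q <- quantize_gray(cell_image(g, m, check = FALSE), g = 2L)
  expect_setequal(unique(as.vector(q)), c(1L, 2L))

  ramp <- matrix(seq(0, 255, length.out = 256), 16, 16)
  q8 <- quantize_gray(cell_image(ramp, matrix(1L, 16, 16), check = FALSE), g = 8L)
  # level boundaries at multiples of 255/8
  expect_equal(as.vector(q8),
               as.integer(1L + pmin(7, floor(as.vector(ramp) / 255 * 8))))

  const <- quantize_gray(cell_image(matrix(77, 4, 4), m, check = FALSE), g = 8L)
  expect_true(all(const == 1L))

  # outside-mask pixels are excluded
  m2 <- matrix(0L, 4, 4); m2[2:3, 2:3] <- 1L
  q2 <- quantize_gray(cell_image(g, m2, check = FALSE), g = 2L)
  expect_true(all(is.na(q2[m2 == 0])))
})

test_that("co-occurrence counting matches hand enumeration and symmetrizes", {
  q <- rbind(c(1L, 1L), c(2L, 2L))
  gl <- compute_glcm(q, 0, g = 2L)
  expect_equal(gl$counts, rbind(c(2, 0), c(0, 2)))
  expect_equal(sum(gl$probs), 1)

  const <- matrix(1L, 4, 4)
  glc <- compute_glcm(const, 45, g = 1L)
  expect_equal(glc$probs, matrix(1, 1, 1))

  checker <- matrix(1L + (row(matrix(0, 6, 6)) + col(matrix(0, 6, 6))) %% 2L, 6, 6)
  glk <- compute_glcm(checker, 0, g = 2L)
  expect_equal(glk$counts[1, 1], 0)
  expect_equal(glk$counts[2, 2], 0)
  expect_gt(glk$counts[1, 2], 0)
  expect_equal(glk$counts, t(glk$counts))

  allna <- matrix(NA_integer_, 3, 3)
  expect_error(compute_glcm(allna, 0, g = 2L), "empty GLCM")
})

test_that("the 23 GLCM statistics match a brute-force double loop", {
  set.seed(101)
  for (i in 1:10) {
    q <- matrix(sample.int(5L, 64, replace = TRUE), 8, 8)
    for (a in c(0, 45, 90, 135)) {
      P <- compute_glcm(q, a, g = 5L)$probs
      expect_equal(glcm_statistics(P), glcm_statistics_bruteforce(P),
                   tolerance = 1e-12)
    }
  }
})

test_that("GLCM features have the expected structure and degenerate limits", {
  ci <- flat_cell(disk_mask(64, 20))
  f <- glcm_features(ci)
  expect_length(f, 23)
  expect_false(any(duplicated(names(f))))
  expect_equal(unname(f["glcm_contrast"]), 0)
  expect_equal(unname(f["glcm_energy"]), 1)
  expect_equal(unname(f["glcm_entropy"]), 0)
  expect_equal(unname(f["glcm_max_probability"]), 1)
  expect_equal(unname(f["glcm_correlation_m"]), 0)   # zero-variance convention

  # checkerboard: every 0-degree pair differs by exactly one level
  m <- matrix(1L, 8, 8)
  g <- matrix(ifelse((row(m) + col(m)) %% 2 == 0, 0, 255), 8, 8)
  q <- quantize_gray(cell_image(g, m, check = FALSE), g = 2L)
  st <- glcm_statistics(compute_glcm(q, 0, g = 2L)$probs)
  expect_equal(unname(st["contrast"]), 1)
  expect_equal(unname(st["energy"]), sum(compute_glcm(q, 0, g = 2L)$probs^2))
})

test_that("GLCM features are invariant to 90-degree rotation (4-direction averaging)", {
  set.seed(21)
  m <- disk_mask(48, 16)
  g <- matrix(0, 48, 48)
  g[m == 1] <- sample(0:255, sum(m), replace = TRUE)
  f1 <- glcm_features(cell_image(g, m, check = FALSE))
  f2 <- glcm_features(cell_image(rot90(g), rot90(m), check = FALSE))
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("intensity shifts leave contrast, dissimilarity and entropy unchanged", {
  set.seed(33)
  m <- disk_mask(48, 16)
  g <- matrix(0, 48, 48)
  g[m == 1] <- sample(40:200, sum(m), replace = TRUE)
  f1 <- glcm_features(cell_image(g, m, check = FALSE))
  g2 <- g; g2[m == 1] <- g[m == 1] + 30      # quantization range shifts along
  f2 <- glcm_features(cell_image(g2, m, check = FALSE))
  for (k in c("glcm_contrast", "glcm_dissimilarity", "glcm_entropy"))
    expect_equal(f1[k], f2[k], tolerance = 1e-12)
})
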