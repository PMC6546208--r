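test_that("generation is deterministic and order-independent", {
  spec <- small_spec()
  a <- generate_cells(spec, n = 4L, condition = "ctl")
  b <- generate_cells(spec, n = 4L, condition = "ctl")
  expect_identical(lapply(a, `[[`, "gray"), lapply(b, `[[`, "gray"))
  # cell i does not depend on how many cells are generated
  c3 <- generate_cells(spec, n = 3L, condition = "ctl")
  expect_identical(a[[3]]$cell_mask, c3[[3]]$cell_mask)
  expect_identical(a[[3]]$gray, c3[[3]]$gray)
})

test_that("boundary amplitudes survive the feature round trip", {
  # a disk when all amplitudes are zero
  spec0 <- synth_spec(n_cells = 1L, seed = 2L, mean_radius_px = 40,
                      radius_sd_px = 0,
                      waviness = data.frame(freq = 3, mean = 0, sd = 0),
                      roughness_amp = 0, frame_side = 128L)
  set.seed(1)
  b0 <- make_boundary(spec0)
  rs <- radial_signal(b0$boundary)
  expect_lt(max(abs(rs$rho - 40)), 1)

  # single harmonic a5 = 10: C5 recovered within 5%
  spec5 <- synth_spec(n_cells = 1L, seed = 2L, mean_radius_px = 50,
                      radius_sd_px = 0,
                      waviness = data.frame(freq = 5, mean = 10, sd = 0),
                      roughness_amp = 0, frame_side = 256L)
  set.seed(3)
  b5 <- make_boundary(spec5)
  wf <- waviness_features(flat_cell(b5$mask))
  # Expected value frozen from a continuous arc-length oracle: traversing
  # rho = 50 + 10 cos(5 theta) at uniform boundary speed warps theta(t),
  # which biases the recovered fundamental to 9.481 (not the nominal 10);
  # rasterization adds < 2% on top.
  expect_equal(unname(wf["wav_C5"]), 9.481, tolerance = 0.02)

  # high-frequency amplitude 2 at n = 60: Rq = 2/sqrt(2) within 20%
  specr <- synth_spec(n_cells = 1L, seed = 2L, mean_radius_px = 50,
                      radius_sd_px = 0,
                      waviness = data.frame(freq = 3, mean = 0, sd = 0),
                      roughness_amp = 2, rough_freqs = 60L, frame_side = 160L)
  set.seed(4)
  br <- make_boundary(specr)
  rf <- roughness_features(flat_cell(br$mask))
  expect_equal(unname(rf["rough_rq"]), 2 / sqrt(2), tolerance = 0.2)

  # impossible amplitudes error out after resampling
  expect_error(synth_spec(mean_radius_px = 10,
                          waviness = data.frame(freq = 5, mean = 50, sd = 0)))
})

test_that("textures drive the intended texture features", {
  spec <- small_spec(texture = "banded",
                     band_pattern = c(20, 20, 20, 20, 20, 200, 20, 20, 20, 20),
                     noise_sd = 2)
  set.seed(5)
  b <- make_boundary(spec)
  g <- make_texture(b$mask, spec)
  ci <- cell_image(g, b$mask, check = FALSE)
  expect_equal(unname(band_features(band_profile(ci))["band_max_index"]), 6)

  # fibers along one axis: contrast across fibers exceeds contrast along
  specf <- small_spec(texture = "fibrous", fiber_kappa = 50, n_fibers = 40L)
  set.seed(6)
  bf <- make_boundary(specf)
  gf <- make_texture(bf$mask, specf)
  q <- quantize_gray(cell_image(gf, bf$mask, check = FALSE), g = 8L)
  along <- glcm_statistics(compute_glcm(q, 0, g = 8L)$probs)["contrast"]
  across <- glcm_statistics(compute_glcm(q, 90, g = 8L)$probs)["contrast"]
  expect_lt(unname(along), unname(across))

  # speckle's rare bright foci create large gray-tone jumps: higher GLCM
  # contrast and a more concentrated matrix than the uniform fill (the
  # within-mask min-max quantization compresses the speckle background
  # into few levels, so its entropy is the *lower* of the two)
  specu <- small_spec(texture = "uniform")
  specs <- small_spec(texture = "speckle", speckle_density = 0.05)
  set.seed(7)
  bu <- make_boundary(specu)
  gu <- make_texture(bu$mask, specu)
  gs <- make_texture(bu$mask, specs)
  fu <- glcm_features(cell_image(gu, bu$mask, check = FALSE))
  fs <- glcm_features(cell_image(gs, bu$mask, check = FALSE))
  expect_lt(unname(fu["glcm_contrast"]), unname(fs["glcm_contrast"]))
  expect_lt(unname(fu["glcm_max_probability"]),
            unname(fs["glcm_max_probability"]))
})

test_that("written populations are reproducible byte for byte", {
  spec <- small_spec()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  make_population(list(ctl = spec), d1, force = TRUE)
  make_population(list(ctl = spec), d2, force = TRUE)
  f1 <- list.files(d1, pattern = "png$", full.names = TRUE)
  f2 <- list.files(d2, pattern = "png$", full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  for (i in seq_along(f1))
    expect_identical(readBin(f1[i], "raw", file.size(f1[i])),
                     readBin(f2[i], "raw", file.size(f2[i])))
})

test_that("generated cells honor the cell-image contract", {
  spec <- small_spec()
  cells <- generate_cells(spec, n = 3L)
  for (cell in cells) {
    expect_silent(cellmorph:::validate_cell_image(cell))
    expect_true(all(cell$gray[cell$cell_mask == 0] == 0))
    expect_true(all(cell$nucleus_mask <= cell$cell_mask))
  }
})
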