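test_that("gabor patches render with the specified amplitude and support", {
  canvas <- c(41, 41)
  expect_equal(gabor_patch(gabor_spec(c(21, 21), 0, amplitude = 0), canvas),
               matrix(0, 41, 41))
  img <- gabor_patch(gabor_spec(c(21, 21), 0, amplitude = 0.85), canvas)
  expect_equal(img[21, 21], 0.85, tolerance = 1e-12)
  expect_equal(max(img), 0.85, tolerance = 1e-12)
  expect_true(all(img >= 0))
})

test_that("patch rendering validates its specification", {
  expect_error(gabor_spec(c(5, 5), 0, envelope_sd = 0), "envelope_sd")
  expect_error(gabor_spec(c(5, 5), 0, wavelength = -1), "wavelength")
  expect_error(gabor_spec(c(5, 5), 0, amplitude = -0.1), "amplitude")
  expect_error(gabor_patch(gabor_spec(c(90, 5), 0), c(50, 50)), "outside")
  expect_warning(gabor_patch(gabor_spec(c(3, 25), 0), c(50, 50)), "clipped")
})

test_that("mirrored vertical/horizontal patch pair is left-right symmetric", {
  canvas <- c(60, 41)
  img <- compose_display(list(gabor_spec(c(20, 21), 0),
                              gabor_spec(c(41, 21), pi / 2)), canvas)
  # mirror x and swap the two orientations: same display
  img2 <- compose_display(list(gabor_spec(c(41, 21), 0),
                               gabor_spec(c(20, 21), pi / 2)), canvas)
  expect_equal(img[, ncol(img):1], img2, tolerance = 1e-12)
})

test_that("displays compose additively", {
  canvas <- c(80, 40)
  s1 <- gabor_spec(c(20, 20), 0)
  s2 <- gabor_spec(c(60, 20), pi / 2)
  expect_identical(compose_display(list(s1), canvas), gabor_patch(s1, canvas))
  both <- compose_display(list(s1, s2), canvas)
  i1 <- gabor_patch(s1, canvas); i2 <- gabor_patch(s2, canvas)
  expect_equal(both, i1 + i2)
  # disjoint supports: pixel sums add exactly
  expect_equal(sum(both), sum(i1) + sum(i2))
  # two well-separated single-lobe patches (wavelength much larger than
  # the envelope, so rectification leaves one blob each) give exactly two
  # connected nonzero column blocks
  blobs <- compose_display(list(gabor_spec(c(20, 20), 0, wavelength = 30),
                                gabor_spec(c(60, 20), 0, wavelength = 30)),
                           canvas)
  nz <- which(colSums(blobs) > 1e-9)
  expect_equal(sum(diff(nz) > 1), 1L)
  expect_error(compose_display(list(), canvas), "non-empty")
})

test_that("rendering is translation-equivariant for integer shifts", {
  canvas <- c(50, 50)
  a <- gabor_patch(gabor_spec(c(20, 25), pi / 4), canvas)
  b <- gabor_patch(gabor_spec(c(26, 22), pi / 4), canvas)
  expect_equal(a[6:45, 5:40], b[3:42, 11:46], tolerance = 1e-12)
})

test_that("amplitude scales patches linearly at cosine phase", {
  canvas <- c(41, 41)
  a1 <- gabor_patch(gabor_spec(c(21, 21), pi / 8, amplitude = 0.5), canvas)
  a2 <- gabor_patch(gabor_spec(c(21, 21), pi / 8, amplitude = 1.0), canvas)
  expect_equal(2 * a1, a2, tolerance = 1e-12)
})

test_that("whitened noise patches are seeded, non-negative and spectrally flat", {
  a <- whitened_noise_patches(3, 16, seed = 42)
  b <- whitened_noise_patches(3, 16, seed = 42)
  expect_identical(a, b)
  expect_false(identical(a, whitened_noise_patches(3, 16, seed = 43)))
  expect_true(all(vapply(a, min, numeric(1)) >= 0))
  expect_error(whitened_noise_patches(0, 16, seed = 1), "n must be")
  # average power spectrum: low vs high frequency annuli within [0.5, 2]
  ps <- Reduce(`+`, lapply(whitened_noise_patches(500, 32, seed = 5),
                           function(p) Mod(stats::fft(p))^2)) / 500
  f <- c(0:16, 15:1) / 32
  fr <- sqrt(outer(f^2, f^2, `+`))
  lo <- mean(ps[fr > 0.05 & fr <= 0.2])
  hi <- mean(ps[fr > 0.35 & fr <= 0.5])
  expect_gt(lo / hi, 0.5)
  expect_lt(lo / hi, 2)
})

test_that("images round-trip through CSV exactly and PNG approximately", {
  img <- gabor_patch(gabor_spec(c(11, 11), pi / 3, amplitude = 0.7), c(21, 21))
  csv <- tempfile(fileext = ".csv")
  write_image_csv(img, csv)
  expect_equal(read_image_csv(csv), img, ignore_attr = TRUE)
  pngf <- tempfile(fileext = ".png")
  write_image_png(img, pngf)
  scale <- jsonlite::read_json(paste0(pngf, ".json"))$scale
  back <- png::readPNG(pngf) * scale
  expect_lt(max(abs(back - img)), scale / 255)
})
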