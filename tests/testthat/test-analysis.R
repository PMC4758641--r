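test_that("gaussian fits recover known parameters", {
  x <- seq(-4, 4, by = 0.5)
  y <- 0.2 + 1.7 * exp(-(x - 0.8)^2 / (2 * 1.3^2))
  f <- fit_gaussian(x, y)
  expect_equal(f$amplitude, 1.7, tolerance = 1e-5)
  expect_equal(f$center, 0.8, tolerance = 1e-5)
  expect_equal(f$width, 1.3, tolerance = 1e-5)
  expect_equal(f$baseline, 0.2, tolerance = 1e-5)
  expect_lt(f$rms_residual, 1e-6)
  expect_error(fit_gaussian(x, rep(1, length(x))), "constant")
})

test_that("circular gaussian fits handle wrap-around tuning curves", {
  th <- (0:7) * pi / 8
  y <- 0.05 + 0.9 * exp(-orientation_distance(th, 7 * pi / 8)^2 / (2 * 0.5^2))
  f <- fit_gaussian(th, y, circular = TRUE)
  expect_equal(orientation_distance(f$center, 7 * pi / 8), 0, tolerance = 1e-4)
  expect_equal(f$width, 0.5, tolerance = 1e-4)
})

test_that("gaussian fits are robust to modest noise", {
  x <- seq(-4, 4, by = 0.4)
  true <- c(amplitude = 1.5, center = -0.3, width = 1.1, baseline = 0.4)
  errs <- t(vapply(1:100, function(i) {
    set.seed(i)
    y <- true["baseline"] + true["amplitude"] *
      exp(-(x - true["center"])^2 / (2 * true["width"]^2)) +
      stats::rnorm(length(x), sd = 0.01 * true["amplitude"])
    f <- fit_gaussian(x, y)
    abs(c(f$amplitude, f$center, f$width, f$baseline) - true) /
      c(true[c("amplitude")], 1, true[c("width", "baseline")])
  }, numeric(4)))
  expect_true(all(apply(errs, 2, stats::median) < 0.05))
})

test_that("fitters are invariant to uniform response rescaling", {
  x <- seq(-4, 4, by = 0.5)
  y <- 0.2 + 1.7 * exp(-(x - 0.8)^2 / (2 * 1.3^2))
  f1 <- fit_gaussian(x, y); f2 <- fit_gaussian(x, 10 * y)
  expect_equal(f2$amplitude / f1$amplitude, 10, tolerance = 1e-4)
  expect_equal(f2$center, f1$center, tolerance = 1e-4)
  expect_equal(f2$width, f1$width, tolerance = 1e-4)
  cc <- seq(0.05, 2, length.out = 10)
  r <- 0.02 + 0.9 * cc^3 / (cc^3 + 0.6^3)
  n1 <- fit_naka_rushton(cc, r); n2 <- fit_naka_rushton(cc, 5 * r)
  expect_equal(n2$r_max / n1$r_max, 5, tolerance = 1e-3)
  expect_equal(n2$c50, n1$c50, tolerance = 1e-3)
  expect_equal(n2$exponent, n1$exponent, tolerance = 1e-2)
})

test_that("naka-rushton fits recover noiseless curves and reject junk", {
  cc <- seq(0.05, 3, length.out = 12)
  r <- 0.1 + 1.2 * cc^2.5 / (cc^2.5 + 0.8^2.5)
  f <- fit_naka_rushton(cc, r)
  expect_equal(f$r_max, 1.2, tolerance = 1e-4)
  expect_equal(f$c50, 0.8, tolerance = 1e-4)
  expect_equal(f$exponent, 2.5, tolerance = 1e-3)
  expect_error(fit_naka_rushton(cc, rev(r)), "non-monotone")
})

test_that("gain classification compares r_max against c50 changes", {
  cc <- seq(0.05, 3, length.out = 12)
  nr <- function(rmax, c50) 0.05 + rmax * cc^4 / (cc^4 + c50^4)
  base <- fit_naka_rushton(cc, nr(1, 1))
  expect_equal(gain_classification(fit_naka_rushton(cc, nr(1.5, 0.99)), base),
               "response")
  expect_equal(gain_classification(fit_naka_rushton(cc, nr(1.01, 0.6)), base),
               "contrast")
  expect_equal(gain_classification(fit_naka_rushton(cc, nr(1.2, 0.8)), base),
               "mixed")
})

test_that("rf statistics compute half-max centroid and area", {
  m <- matrix(0, 15, 15)
  m[8, 8] <- 1
  s <- rf_statistics(m)
  expect_equal(unname(s$centroid), c(0, 0))
  expect_equal(s$area, 1L)
  expect_equal(s$peak, 1)
  # point-symmetric map: centroid at the grid center
  g <- exp(-((row(m) - 8)^2 + (col(m) - 8)^2) / 18)
  expect_equal(unname(rf_statistics(g)$centroid), c(0, 0), tolerance = 1e-12)
  expect_error(rf_statistics(matrix(0, 5, 5)), "all-zero")
  # brute-force oracle on a random map
  set.seed(9)
  rmap <- matrix(runif(225), 15, 15)
  s2 <- rf_statistics(rmap)
  mask <- rmap >= max(rmap) / 2
  expect_equal(s2$area, sum(mask))
  gx <- (col(rmap) - 8); gy <- (row(rmap) - 8)
  expect_equal(unname(s2$centroid),
               c(sum(gx[mask] * rmap[mask]), sum(gy[mask] * rmap[mask])) /
                 sum(rmap[mask]))
})

test_that("normalized difference is bounded, antisymmetric and masked", {
  set.seed(4)
  a <- matrix(runif(64), 8, 8); b <- matrix(runif(64), 8, 8)
  d <- normalized_difference(a, b)
  expect_true(all(abs(d) <= 1))
  expect_equal(normalized_difference(b, a), -d)
  expect_equal(normalized_difference(a, a), matrix(0, 8, 8))
  expect_equal(normalized_difference(a, 0 * a), matrix(1, 8, 8))
  z <- a; z[1, 1] <- 0
  expect_true(is.na(normalized_difference(z, 0 * z)[1, 1]))
  expect_error(normalized_difference(a, matrix(1, 4, 4)), "shape")
})
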