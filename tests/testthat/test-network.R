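test_that("the filter bank has 8 zero-DC kernels with rotation symmetry", {
  p <- attnet_params()
  bank <- gabor_filter_bank(p)
  expect_length(bank, 8L)
  expect_equal(orientations(p), (0:7) * pi / 8)
  for (k in bank) expect_lt(abs(sum(k)), 1e-10)
  # 90-degree rotation: the horizontal kernel is the transposed vertical one
  expect_equal(bank[[5]], t(bank[[1]]), tolerance = 1e-12)
})

test_that("feedforward drive matches a brute-force convolution", {
  p <- small_params()
  m <- attnet_model(p)
  expect_equal(feedforward_drive(matrix(0, 9, 9), m),
               array(0, c(9, 9, 8)))
  set.seed(3)
  img <- matrix(runif(81), 9, 9)
  drv <- feedforward_drive(img, m, rectify = FALSE)
  bank <- gabor_filter_bank(p)
  for (k in c(1L, 4L, 7L))
    expect_equal(drv[, , k], brute_conv2(img, bank[[k]]), tolerance = 1e-10)
  # impulse reproduces the (symmetric) kernel around the impulse pixel
  imp <- matrix(0, 9, 9); imp[5, 5] <- 1
  di <- feedforward_drive(imp, m, rectify = FALSE)
  r <- (nrow(bank[[2]]) - 1) / 2
  expect_equal(di[, , 2], bank[[2]][(r - 3):(r + 5), (r - 3):(r + 5)],
               tolerance = 1e-10)
})

test_that("divisive normalization matches closed form and brute force", {
  expect_equal(divisive_normalize(array(0, c(5, 5, 8)), 1, 0.5),
               array(0, c(5, 5, 8)))
  expect_error(divisive_normalize(array(1, c(5, 5, 8)), 1, 0), "positive")
  # uniform single-channel excitation: R = e / (e + c) away from borders
  e <- array(0, c(15, 15, 8)); e[, , 3] <- 2
  r <- divisive_normalize(e, 1, 0.7)
  expect_equal(r[8, 8, 3], 2 / (2 + 0.7), tolerance = 1e-12)
  expect_equal(r[8, 8, 1], 0)
  ex <- random_map(5, 5, seed = 7)
  expect_equal(divisive_normalize(ex, 0.8, 0.3),
               brute_divisive_normalize(ex, 0.8, 0.3), tolerance = 1e-10)
})

test_that("bottom pass implements modulated squaring then normalization", {
  p <- small_params()
  m <- attnet_model(p)
  drv <- random_map(9, 9, seed = 2)
  z <- array(0, dim(drv))
  expect_equal(bottom_pass(drv, z, m),
               divisive_normalize(drv^2, p$sigma_inh, p$c_bottom),
               tolerance = 1e-12)
  expect_equal(bottom_pass(z, random_map(9, 9, seed = 3), m), z)
  expect_error(bottom_pass(drv, -drv, m), "excitatory")
  # uniform drive and feedback: closed form in the interior
  pu <- attnet_params(canvas = c(21, 21), c_bottom = 0.4, c_top = 0.01)
  mu <- attnet_model(pu)
  e <- array(0, c(21, 21, 8)); e[, , 1] <- 0.5
  fb <- array(0, c(21, 21, 8)); fb[, , 1] <- 1.2
  r <- bottom_pass(e, fb, mu)
  expect_equal(r[11, 11, 1],
               (2.2 * 0.5)^2 / ((2.2 * 0.5)^2 + 0.4), tolerance = 1e-12)
})

test_that("top pass pools over space and circular orientation", {
  p <- small_params()
  m <- attnet_model(p)
  resp <- random_map(9, 9, seed = 4)
  # A = 0: squared pooling, normalized
  pool <- brute_pool(resp, p$sigma_top, p$sigma_ori)
  expect_equal(top_pass(resp, array(0, dim(resp)), m),
               divisive_normalize(pool^2, p$sigma_inh, p$c_top),
               tolerance = 1e-10)
  expect_error(top_pass(resp, array(-1, dim(resp)), m), "non-negative")
  # wrap-around: channel 8 leaks into channels 1 and 7 equally
  e <- array(0, c(9, 9, 8)); e[5, 5, 8] <- 1
  t8 <- top_pass(e, array(0, dim(e)), m)
  expect_equal(t8[5, 5, 1], t8[5, 5, 7], tolerance = 1e-12)
  expect_gt(t8[5, 5, 1], 0)
})

test_that("the feedback field is the linear pooled top response", {
  p <- small_params()
  m <- attnet_model(p)
  expect_equal(feedback_field(array(0, c(9, 9, 8)), m), array(0, c(9, 9, 8)))
  r1 <- random_map(9, 9, seed = 5)
  expect_equal(feedback_field(2 * r1, m), 2 * feedback_field(r1, m),
               tolerance = 1e-12)
  expect_equal(feedback_field(r1, m),
               p$alpha_fb * brute_pool(r1, p$sigma_top, p$sigma_ori),
               tolerance = 1e-10)
})

test_that("run_to_equilibrium composes the passes and equilibrates", {
  p <- default_params()
  m <- default_model()
  ctr <- c(50, 50)
  zero <- run_to_equilibrium(matrix(0, 100, 100), no_attention(p), m,
                             probes = data.frame(x = 50, y = 50, channel = 1,
                                                 layer = "top"))
  expect_true(all(zero$top_response == 0))
  expect_true(all(zero$traces == 0))
  img <- gabor_patch(gabor_spec(ctr, 0), p$canvas)
  pr <- data.frame(x = 50, y = 50, channel = 1,
                   layer = c("bottom", "top"))
  s30 <- run_to_equilibrium(img, no_attention(p), m, probes = pr)
  # the slowest recurrent mode decays by ~0.70 per iteration; after 30
  # iterations the per-iteration change and the residual drift are both
  # well below the >= 5% effects the experiments measure
  s29 <- run_to_equilibrium(img, no_attention(p), m, n_iterations = 29)
  expect_lt(max(abs(s30$top_response - s29$top_response)),
            1e-3 * max(s30$top_response))
  s60 <- run_to_equilibrium(img, no_attention(p), m, probes = pr,
                            n_iterations = 60)
  expect_lt(max(abs(s60$traces[60, ] - s30$traces[30, ]) / s60$traces[60, ]),
            2e-3)
  # responses are non-negative and bounded by E / c
  expect_true(all(s30$bottom_response >= 0))
  drive <- feedforward_drive(img, m)
  e_bottom <- ((1 + s30$feedback) * drive)^2
  expect_true(all(s30$bottom_response <= e_bottom / p$c_bottom + 1e-12))
})

test_that("a diverging configuration reports the failing iteration", {
  p <- attnet_params(alpha_fb = 1e200, c_bottom = 1e-12, c_top = 1e-300,
                     canvas = c(20, 20))
  img <- gabor_patch(gabor_spec(c(10, 10), 0), p$canvas)
  expect_error(run_to_equilibrium(img, no_attention(p), attnet_model(p)),
               "iteration")
})

test_that("responses shift with the stimulus and mirror with the display", {
  p <- default_params()
  m <- default_model()
  # translation equivariance, away from borders
  img1 <- gabor_patch(gabor_spec(c(46, 48), 0), p$canvas)
  img2 <- gabor_patch(gabor_spec(c(51, 51), 0), p$canvas)
  s1 <- run_to_equilibrium(img1, spatial_attention(c(46, 48), p), m)
  s2 <- run_to_equilibrium(img2, spatial_attention(c(51, 51), p), m)
  win1 <- s1$top_response[28:68, 26:66, 1]
  win2 <- s2$top_response[31:71, 31:71, 1]
  expect_lt(max(abs(win1 - win2)) / max(win2), 0.01)
  # mirror symmetry: flip x, swap channels k <-> mirrored orientation
  imgm <- img1[, ncol(img1):1]
  sm <- run_to_equilibrium(imgm, spatial_attention(c(100 + 1 - 46, 48), p), m)
  chmap <- c(1, 8:2)   # theta -> pi - theta
  for (k in c(1, 2, 5)) {
    expect_equal(sm$top_response[, 100:1, chmap[k]], s1$top_response[, , k],
                 tolerance = 1e-8)
  }
})

test_that("calibration converges to a self-consistent fixed point", {
  p <- default_params()
  tr <- attr(p, "trace")
  expect_lt(nrow(tr), 100)
  # first-iteration constant scales with the squared stimulus amplitude
  ctr <- c(50, 50)
  p0 <- attnet_params()
  c1 <- calibrate_constants(p0, gabor_patch(gabor_spec(ctr, 0, 1), p0$canvas))
  c2 <- calibrate_constants(p0, gabor_patch(gabor_spec(ctr, 0, 2), p0$canvas))
  expect_equal(attr(c2, "trace")[1, 1], 4 * attr(c1, "trace")[1, 1],
               tolerance = 1e-10)
  # fixed point: at equilibrium, c equals sigma_norm times max excitation
  m <- attnet_model(p)
  img <- gabor_patch(gabor_spec(ctr, 0), p$canvas)
  s <- run_to_equilibrium(img, no_attention(p), m, n_iterations = 60)
  e_bottom <- ((1 + s$feedback) * feedforward_drive(img, m))^2
  expect_equal(p$sigma_norm * max(e_bottom), p$c_bottom, tolerance = 1e-5)
  # re-running calibration reproduces the constants exactly
  p2 <- calibrate_constants(attnet_params())
  expect_equal(p2$c_bottom, p$c_bottom)
  expect_equal(p2$c_top, p$c_top)
})
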