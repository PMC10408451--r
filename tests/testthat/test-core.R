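test_that("Gaussian kernels are odd, unit-sum, symmetric, correctly sized", {
  for (sigma in c(0.2, 1, 1.74, 5)) {
    k <- make_gaussian_kernel(sigma)
    r <- ceiling(3 * sigma)
    expect_identical(dim(k), rep(as.integer(2 * r + 1), 2))
    expect_equal(sum(k), 1, tolerance = 1e-12)
    expect_equal(unclass(k)[, ncol(k):1], unclass(k), ignore_attr = TRUE)
    expect_equal(unclass(k)[nrow(k):1, ], unclass(k), ignore_attr = TRUE)
    expect_equal(t(unclass(k)), unclass(k), ignore_attr = TRUE)  # 90 deg
  }
  # frozen value from the brute-force normalization oracle
  expect_equal(make_gaussian_kernel(1)[4, 4], 0.1592411, tolerance = 1e-6)
  expect_equal(make_gaussian_kernel(1)[4, 4],
               oracle_gauss2d(1)[4, 4], tolerance = 1e-14)
  # near-delta limit
  expect_gt(make_gaussian_kernel(0.2)[2, 2], 0.999)
  expect_error(make_gaussian_kernel(0), "positive")
  expect_error(make_gaussian_kernel(-1), "positive")
})

test_that("convolve_symmetric matches identities and the double-loop oracle", {
  k <- make_gaussian_kernel(1)
  # constant image is a fixed point of a unit-sum kernel
  cimg <- matrix(0.4, 10, 12)
  expect_equal(convolve_symmetric(cimg, k), cimg, tolerance = 1e-12)
  # delta image reproduces the kernel around the impulse
  delta <- matrix(0, 15, 15); delta[8, 8] <- 1
  out <- convolve_symmetric(delta, k)
  expect_equal(out[5:11, 5:11], unclass(k), ignore_attr = TRUE,
               tolerance = 1e-12)
  # ramp image vs brute force
  ramp <- matrix(rep(seq(0, 1, length.out = 8), each = 8), 8, 8)
  expect_equal(convolve_symmetric(ramp, k), oracle_conv2(ramp, unclass(k)),
               tolerance = 1e-10)
  # random images, including a kernel wider than the image
  for (seed in 1:3) {
    img <- rand_image(9, seed)
    for (sigma in c(0.8, 2, 4)) {
      kk <- make_gaussian_kernel(sigma)
      expect_equal(convolve_symmetric(img, kk),
                   oracle_conv2(img, unclass(kk)), tolerance = 1e-10)
    }
  }
})

test_that("separable and full-kernel convolution agree", {
  for (seed in 1:3) {
    img <- rand_image(12, seed)
    for (sigma in c(0.7, 1.74, 3)) {
      r <- ceiling(3 * sigma)
      sep <- inrfqa:::sep_conv2_symm(img, inrfqa:::gaussian_taps(sigma, r))
      full <- convolve_symmetric(img, make_gaussian_kernel(sigma))
      expect_equal(sep, full, tolerance = 1e-12)
    }
  }
})

test_that("sigmoid is atan with odd symmetry; unknown tags rejected", {
  expect_identical(sigmoid_eval(0), 0)
  expect_equal(sigmoid_eval(1), pi / 4)
  z <- seq(-5, 5, by = 0.25)
  expect_equal(sigmoid_eval(z), -sigmoid_eval(-z))
  expect_true(all(abs(sigmoid_eval(c(-1e6, 1e6))) < pi / 2))
  expect_error(sigmoid_eval(1, "tanh"), "unknown sigmoid")
  expect_error(inrf_params(sigmoid = "relu"), "unknown sigmoid")
})

test_that("parameter defaults and validation", {
  p <- inrf_params()
  expect_equal(p$sigma_m, 1.74)
  expect_equal(p$sigma_w, 25)
  expect_equal(p$sigma_g, 1)
  expect_equal(p$lambda, 3)
  expect_identical(p$sigmoid, "atan")
  expect_error(inrf_params(sigma_w = 0), "positive")
  expect_error(inrf_params(n_levels = 1), "n_levels")
  expect_error(inrf_params(truncate = 0.5), "truncate")
})

test_that("naive transform matches an independently coded summation", {
  # 16x16 image with a bright 4x4 square, small sigma_w
  img <- matrix(0.2, 16, 16); img[7:10, 7:10] <- 0.9
  p <- inrf_params(sigma_w = 3)
  expect_equal(inrf_transform_naive(img, p),
               oracle_inrf(img, sigma_w = 3), tolerance = 1e-10)
  # and on random content with other kernel widths
  for (seed in 1:2) {
    img <- rand_image(12, seed)
    expect_equal(inrf_transform_naive(img, inrf_params(sigma_w = 2)),
                 oracle_inrf(img, sigma_w = 2), tolerance = 1e-10)
  }
})

test_that("constant images are fixed points of both paths", {
  for (c0 in c(0, 0.3, 1)) {
    cimg <- matrix(c0, 14, 11)
    for (sw in c(2, 25)) {
      p <- inrf_params(sigma_w = sw)
      expect_lt(max(abs(inrf_transform_naive(cimg, p) - c0)), 1e-10)
      expect_lt(max(abs(inrf_transform(cimg, p) - c0)), 1e-10)
    }
  }
})

test_that("lambda = 0 reduces both paths to Gaussian blur by m", {
  img <- rand_image(16, 4)
  p <- inrf_params(sigma_w = 5, lambda = 0)
  blur <- convolve_symmetric(img, make_gaussian_kernel(p$sigma_m))
  expect_equal(inrf_transform_naive(img, p), blur, tolerance = 1e-12)
  expect_equal(inrf_transform(img, p), blur, tolerance = 1e-12)
})

test_that("gray-shift covariance: transform(I + d) = transform(I) + d", {
  img <- matrix(runif(20 * 20, 0, 0.8), 20, 20)
  set.seed(9); img[] <- runif(400, 0, 0.8)
  for (d in c(0.05, 0.2)) {
    for (sw in c(3, 25)) {
      p <- inrf_params(sigma_w = sw)
      expect_lt(max(abs(inrf_transform(img + d, p) -
                        (inrf_transform(img, p) + d))), 1e-8)
    }
  }
})

test_that("translation equivariance holds in the interior", {
  set.seed(12)
  big <- matrix(runif(48 * 48), 48, 48)
  p <- inrf_params(sigma_m = 1, sigma_w = 2, sigma_g = 1)
  dx <- 3L
  shifted <- big[, c((dx + 1):48, 1:dx)]  # circular shift left by dx
  O1 <- inrf_transform_naive(big, p)
  O2 <- inrf_transform_naive(shifted, p)
  # total influence radius: w-support + g-support (and m-support)
  r <- ceiling(3 * 2) + ceiling(3 * 1)
  rows <- (r + 1):(48 - r)
  cols <- (r + 1):(48 - r - dx)
  expect_equal(O2[rows, cols], O1[rows, cols + dx], tolerance = 1e-10)
})

test_that("fast path tracks the naive oracle and refinement helps", {
  for (sw in c(2, 5, 25)) {
    img <- rand_image(32, 100 + sw)
    p64 <- inrf_params(sigma_w = sw, n_levels = 64)
    p128 <- inrf_params(sigma_w = sw, n_levels = 128)
    On <- inrf_transform_naive(img, p64)
    d64 <- max(abs(inrf_transform(img, p64) - On))
    d128 <- max(abs(inrf_transform(img, p128) - On))
    expect_lt(d64, 1e-3)
    expect_lte(d128, d64)
  }
})

test_that("outputs are finite and respect the analytic bound", {
  for (seed in 1:5) {
    img <- rand_image(24, seed)
    p <- inrf_params(sigma_w = 5)
    O <- inrf_transform(img, p)
    expect_true(all(is.finite(O)))
    expect_lte(max(abs(O)), 1 + abs(p$lambda) * pi / 2)
  }
})

test_that("input validation rejects bad images", {
  p <- inrf_params()
  expect_error(inrf_transform(matrix(NA_real_, 4, 4), p), "finite")
  expect_error(inrf_transform("x", p), "matrix")
  expect_error(convolve_symmetric(matrix(1, 3, 3), matrix(1, 2, 2)), "odd")
})
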