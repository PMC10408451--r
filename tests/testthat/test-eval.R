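test_that("srcc matches the rank-formula oracle and handles ties", {
  expect_equal(srcc(1:6, (1:6)^3), 1)          # monotone transform
  expect_equal(srcc(1:6, -(1:6)^3), -1)
  # rank formula by hand: d = (0,-1,1,-1,1), sum d^2 = 4,
  # rho = 1 - 6*4/(5*24) = 0.8 (verified by the independent oracle)
  expect_equal(srcc(1:5, c(1, 3, 2, 5, 4)), 0.8)
  expect_equal(srcc(1:5, c(1, 3, 2, 5, 4)),
               oracle_srcc(1:5, c(1, 3, 2, 5, 4)))
  # ties -> average ranks, still matches the oracle
  a <- c(1, 2, 2, 3, 4, 4); b <- c(2, 1, 3, 3, 5, 4)
  expect_equal(srcc(a, b), oracle_srcc(a, b))
  # invariance under strictly monotone transforms
  set.seed(1); x <- rnorm(30); y <- rnorm(30)
  expect_equal(srcc(exp(x), y), srcc(x, y))
  expect_equal(srcc(x, y^3 + y), srcc(x, y))
  expect_error(srcc(rep(1, 5), 1:5), "constant")
  expect_error(srcc(1:2, 2:1), "at least 3")
  expect_error(srcc(c(1, 2, NA), 1:3), "finite")
})

test_that("logistic4 has the stated midpoint, asymptotes, monotonicity", {
  b <- c(3, -1, 2, 0.5)
  expect_equal(logistic4(2, b), 1)            # (b1 + b2) / 2
  expect_equal(logistic4(1e6, b), 3, tolerance = 1e-9)
  expect_equal(logistic4(-1e6, b), -1, tolerance = 1e-9)
  x <- seq(-5, 5, 0.1)
  expect_true(all(diff(logistic4(x, b)) > 0))
  expect_true(all(diff(logistic4(x, c(-1, 3, 2, 0.5))) < 0))  # b1 < b2
  expect_equal(logistic4(0.5, c(1, 0, 0, 1)), 1 / (1 + exp(-0.5)))
  # beta4 enters as |beta4|
  expect_equal(logistic4(x, b), logistic4(x, b * c(1, 1, 1, -1)))
  expect_error(logistic4(1, c(1, 0, 0, 0)), "beta4")
})

test_that("fit_logistic4 recovers a noiseless logistic curve", {
  set.seed(3)
  x <- sort(runif(50, -2, 4))
  beta <- c(4.5, 1.2, 1.0, 0.6)
  y <- logistic4(x, beta)
  f <- fit_logistic4(x, y)
  expect_lt(sqrt(mean((f$fitted - y)^2)), 1e-6)
  # idempotence: refitting the fitted curve reproduces it
  f2 <- fit_logistic4(x, f$fitted)
  expect_lt(max(abs(f2$fitted - f$fitted)), 1e-8)
})

test_that("fit_logistic4 approximates affine data on a narrow range", {
  set.seed(4)
  x <- seq(0, 1, length.out = 40)
  y <- 2.5 * x + 1
  f <- fit_logistic4(x, y)
  expect_lt(sqrt(mean((f$fitted - y)^2)) / diff(range(y)), 0.01)
})

test_that("fit_logistic4 flips orientation for anti-monotone data", {
  set.seed(5)
  x <- sort(runif(40))
  y <- logistic4(x, c(1, 5, 0.5, 0.2))   # decreasing: beta1 < beta2
  f <- fit_logistic4(x, y)
  expect_lt(f$beta[1], f$beta[2])
  expect_true(all(diff(logistic4(sort(x), f$beta)) <= 0))
})

test_that("plcc_after_fit is exact on logistic data and null on noise", {
  set.seed(6)
  x <- sort(runif(50, -1, 3))
  y <- logistic4(x, c(5, 1, 1, 0.5))
  expect_equal(plcc_after_fit(x, y), 1, tolerance = 1e-6)
  # anti-monotone logistic relation: mapping absorbs the direction
  y2 <- logistic4(x, c(1, 5, 1, 0.5))
  expect_equal(plcc_after_fit(x, y2), 1, tolerance = 1e-6)
  # independent scores: small correlation
  set.seed(7)
  xo <- rnorm(100); yo <- sample(xo)
  expect_lt(abs(plcc_after_fit(xo, yo)), 0.3)
  # invariance under increasing affine rescaling of the subjective axis
  expect_equal(plcc_after_fit(x, 10 * y + 3), plcc_after_fit(x, y),
               tolerance = 1e-6)
})

test_that("grid_search returns single points and breaks ties lexicographically", {
  ds <- make_scored_dataset(n_contents = 3, levels = 2, seed = 11, size = 24,
                            planted_params = inrf_params(sigma_w = 4))
  single <- list(sigma_m = 1.74, sigma_w = 4, sigma_g = 1, lambda = 3)
  best <- grid_search(ds$pairs, ds$subjective, grid = single)
  expect_equal(best$sigma_w, 4)
  # a duplicated grid point produces exact ties; the smaller lexicographic
  # tuple must win, and the duplicate must collapse
  dup <- list(sigma_m = c(1.74, 1.74), sigma_w = 4, sigma_g = 1,
              lambda = c(3, 5))
  best2 <- grid_search(ds$pairs, ds$subjective, grid = dup,
                       objective_fn = "srcc")
  log2 <- attr(best2, "scan_log")
  expect_identical(nrow(log2), 2L)
  if (log2$criterion[1] == log2$criterion[2]) {
    expect_equal(best2$lambda, 3)
  }
  expect_error(grid_search(ds$pairs[1:3], ds$subjective[1:3]), "at least 5")
  expect_error(grid_search(ds$pairs, ds$subjective,
                           grid = list(sigma_m = 1)), "missing candidate")
})

test_that("grid_search recovers a planted optimum among decoys", {
  planted <- inrf_params()   # defaults: 1.74 / 25 / 1 / 3
  ds <- make_scored_dataset(n_contents = 4, levels = 4, seed = 5,
                            planted_params = planted)
  grid <- list(sigma_m = c(1, 1.74, 3), sigma_w = c(10, 25, 50),
               sigma_g = 1, lambda = 3)      # 9 points incl. the optimum
  best <- grid_search(ds$pairs, ds$subjective, grid = grid)
  expect_equal(best$sigma_m, planted$sigma_m)
  expect_equal(best$sigma_w, planted$sigma_w)
  expect_equal(attr(best, "criterion"), 1, tolerance = 1e-6)
  # reproducible bit for bit
  best2 <- grid_search(ds$pairs, ds$subjective, grid = grid)
  expect_identical(attr(best, "scan_log")$criterion,
                   attr(best2, "scan_log")$criterion)
})

test_that("failing grid points are logged and skipped, not fatal", {
  ds <- make_scored_dataset(n_contents = 3, levels = 2, seed = 13, size = 24,
                            planted_params = inrf_params(sigma_w = 4))
  # constant subjective makes the fit degenerate at every point, so errors
  # must propagate with context
  expect_error(grid_search(ds$pairs, rep(1, length(ds$subjective)),
                           grid = list(sigma_m = 1.74, sigma_w = 4,
                                       sigma_g = 1, lambda = 3)),
               "every grid point failed")
})
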