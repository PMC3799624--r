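# Detector-model transforms: magnification gradients, bottom shadow,
# Gaussian convolution, composition order/linearity, and the power-law
# non-linearity pair.

cellA <- cell_model(6.0, 7.2, rpm = 50000)

test_that("T_rt applies the first-order magnification field", {
  radii <- seq(6, 7.2, 0.01); times <- c(0, 3600, 7200)
  chi <- matrix(1, length(radii), length(times))
  # both coefficients zero: exact identity
  expect_identical(apply_rt(chi, 6.0, 0, 0, radii, times), chi)
  # dE/dr = 0.28 /cm at r - m = 0.5 cm, t = 0 (low-focal-depth magnitude)
  out <- apply_rt(chi, 6.0, 0.28, 0, radii, times)
  expect_equal(out[radii == 6.5, 1], 1.14)
  # 1%/h drift at t = 2 h, at the meniscus
  out2 <- apply_rt(chi, 6.0, 0, 0.01 / 3600, radii, times)
  expect_equal(out2[1, 3], 1.02)
  # normalization point: eps(m, 0) = 1 always
  out3 <- apply_rt(chi, 6.0, 0.3, 0.05 / 3600, radii, times)
  expect_equal(out3[1, 1], 1)
  expect_warning(apply_rt(chi, 6.0, -2, 0, radii, times), "magnification")
})

test_that("shadow fraction is the circular-segment area fraction", {
  b <- 7.2; delta <- 0.1
  expect_equal(shadow_fraction(b, b, delta), 0.5)
  expect_equal(shadow_fraction(b - delta, b, delta), 0)
  # half-delta depth: analytic segment area (arccos(1/2) - (1/2)sqrt(3/4))/pi
  expect_equal(shadow_fraction(b - delta / 2, b, delta),
               (acos(0.5) - 0.5 * sqrt(0.75)) / pi, tolerance = 1e-12)
  expect_equal(shadow_fraction(b - delta / 2, b, delta), 0.1955,
               tolerance = 1e-4)
  # continuous, non-decreasing, total on [0, 1]
  r <- seq(6.9, 7.5, by = 1e-3)
  B <- shadow_fraction(r, b, delta)
  expect_true(all(diff(B) >= 0))
  expect_true(all(B >= 0 & B <= 1))
  expect_lt(max(abs(diff(B))), 0.05)  # no jumps for delta > 0
  expect_identical(shadow_fraction(c(6.5, 7.0), b, delta), c(0, 0))
  expect_identical(shadow_fraction(7.4, b, delta), 1)
  # delta = 0 collapses to a step at b
  expect_identical(shadow_fraction(c(7.19, 7.2, 7.21), b, 0), c(0, 0.5, 1))
})

test_that("T_S halves the signal at the bottom and is linear", {
  radii <- seq(6, 7.2, 0.002); times <- 1:3
  x <- matrix(rnorm(length(radii) * 3, 50, 5), length(radii))
  y <- matrix(rnorm(length(radii) * 3, 20, 5), length(radii))
  out <- apply_shadow(x, 7.2, 0.15, radii)
  expect_equal(out[length(radii), ], x[length(radii), ] / 2)
  # identity for r < b with delta = 0
  expect_identical(apply_shadow(x, 7.2, 0, radii)[-length(radii), ],
                   x[-length(radii), ])
  # superposition to machine precision
  lhs <- apply_shadow(2 * x + 3 * y, 7.2, 0.15, radii)
  rhs <- 2 * apply_shadow(x, 7.2, 0.15, radii) +
    3 * apply_shadow(y, 7.2, 0.15, radii)
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("Gaussian kernel convention has FWHM close to 1.67 sigma", {
  sigma <- 0.03
  # kernel K(dr) = exp(-(dr/sigma)^2): FWHM = 2 sigma sqrt(ln 2)
  fwhm <- 2 * sigma * sqrt(log(2))
  expect_equal(fwhm / sigma, 1.67, tolerance = 0.01)
})

test_that("radial convolution matches a dense brute-force oracle", {
  r <- seq(6, 7.2, by = 0.002)
  x <- as.numeric(r >= 6.6)  # unit step
  sigma <- 0.03
  y <- gaussian_convolve(x, sigma, 3, r)
  # independent dense convolution with edge renormalization
  K <- floor(3 * sigma / 0.002 + 1e-9); k <- -K:K
  w <- exp(-((k * 0.002) / sigma)^2)
  oracle <- vapply(seq_along(r), function(i) {
    j <- i + k; ok <- j >= 1 & j <= length(r)
    sum(w[ok] * x[j[ok]]) / sum(w[ok])
  }, 0)
  expect_lt(max(abs(y - oracle)), 1e-10)
  # at the step the response is half the plateau (within one kernel tap)
  w0 <- w[K + 1] / sum(w)
  expect_equal(y[which(r == 6.6)], 0.5, tolerance = w0)
  # sigma = 0 and sub-resolution sigma are exact identities
  expect_identical(gaussian_convolve(x, 0, 3, r), x)
  expect_identical(gaussian_convolve(x, 5e-4, 3, r), x)
  # constants preserved exactly, including near data edges
  cst <- rep(2.5, length(r))
  expect_equal(gaussian_convolve(cst, 0.05, 3, r), cst, tolerance = 1e-14)
  expect_error(gaussian_convolve(x, 0.03, 3, r^1.2), "uniformly spaced")
})

test_that("composite transform is linear in chi and order-sensitive", {
  radii <- seq(6, 7.2, 0.004); times <- c(0, 1800, 3600)
  fds <- fds_params(de_dr = 0.25, de_dt = 0.01, delta = 0.15, sigma = 0.02)
  set.seed(4)
  x <- matrix(runif(length(radii) * 3, 0, 100), length(radii))
  y <- matrix(runif(length(radii) * 3, 0, 100), length(radii))
  # all parameters zero: chi unchanged
  expect_equal(compose_fds(x, cellA, fds_params(), radii, times), x,
               tolerance = 1e-14)
  # superposition
  lhs <- compose_fds(0.7 * x + 1.3 * y, cellA, fds, radii, times)
  rhs <- 0.7 * compose_fds(x, cellA, fds, radii, times) +
    1.3 * compose_fds(y, cellA, fds, radii, times)
  expect_equal(lhs, rhs, tolerance = 1e-10)
  # T_C after T_S differs from T_S after T_C when both act
  a <- gaussian_convolve(apply_shadow(x, 7.2, 0.15, radii), 0.02, 3, radii)
  b <- apply_shadow(gaussian_convolve(x, 0.02, 3, radii), 7.2, 0.15, radii)
  expect_gt(max(abs(a - b)), 1e-3)
  # compose_fds applies the convolution last
  expect_equal(compose_fds(x, cellA, fds_params(delta = 0.15, sigma = 0.02),
                           radii, times), a, tolerance = 1e-12)
})

test_that("power-law linearization inverts the detector response", {
  nl2 <- nonlinearity_params(a0 = 0, kappa = 2)
  expect_equal(linearize_signal(9, nl2), 3, ignore_attr = TRUE)
  expect_equal(delinearize_signal(3, nl2), 9)
  # kappa = 1: identity up to the baseline offset
  nl1 <- nonlinearity_params(a0 = 5, kappa = 1)
  x <- c(5, 10, 105)
  expect_equal(linearize_signal(x, nl1), x - 5, ignore_attr = TRUE)
  # exact inverse pair across the working kappa range
  for (k in c(0.8, 0.9, 1, 1.1, 1.25)) {
    nl <- nonlinearity_params(a0 = 2, kappa = k)
    v <- seq(0, 500, length.out = 101)
    expect_equal(linearize_signal(delinearize_signal(v, nl), nl), v,
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  # the reported near-unity coefficient changes a 1000-count signal by < 3%
  nlr <- nonlinearity_params(a0 = 0, kappa = 1.0036)
  expect_lt(abs(delinearize_signal(1000, nlr) / 1000 - 1), 0.03)
  # below-baseline values are clamped (and counted) for the power branch
  out <- linearize_signal(c(1, 3, 10), nonlinearity_params(a0 = 4, kappa = 2))
  expect_identical(attr(out, "n_clamped"), 2L)
  expect_equal(as.numeric(out), c(0, 0, sqrt(6)))
  # kappa = 1 is a pure offset: no clamping, negatives preserved
  neg <- linearize_signal(c(-1, 2), nonlinearity_params(a0 = 0, kappa = 1))
  expect_identical(as.numeric(neg), c(-1, 2))
  expect_identical(attr(neg, "n_clamped"), 0L)
  expect_error(nonlinearity_params(kappa = 0), "kappa")
})

test_that("temporal drift modes agree to first order and start at unity", {
  fl <- fds_params(de_dt = 0.02, drift_mode = "linear")
  fe <- fds_params(de_dt = 0.02, drift_mode = "exponential")
  expect_identical(temporal_drift_factor(0, fl), 1)
  expect_identical(temporal_drift_factor(0, fe), 1)
  # |de_dt * t| <= 0.01: linear and exponential within 1e-4
  t_small <- 0.01 / (0.02 / 3600)
  ts <- seq(0, t_small, length.out = 20)
  expect_lt(max(abs(temporal_drift_factor(ts, fl) -
                      temporal_drift_factor(ts, fe))), 1e-4)
  expect_true(all(diff(temporal_drift_factor(seq(0, 7200, 600), fe)) > 0))
})
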