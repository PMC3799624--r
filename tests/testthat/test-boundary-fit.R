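# Linear subproblem algebra, distribution integration, fit-range rule, and
# small end-to-end c(s) fits on synthetic data.

# small synthetic basis shared by the subproblem tests: 4 "boundary" shapes
# on a 40-radius x 6-scan grid (smooth, linearly independent)
make_small_basis <- function(nr = 40, nt = 6, K = 4, seed = 3) {
  set.seed(seed)
  r <- seq(0, 1, length.out = nr)
  t <- seq_len(nt)
  lapply(seq_len(K), function(k)
    outer(r, t, function(r, t) pnorm(r, mean = 0.1 * k + 0.05 * t, sd = 0.1)))
}

test_that("subproblem reproduces an exactly representable model", {
  basis <- make_small_basis()
  c_true <- c(2, 0.5, 1.5, 3)
  ti_true <- sin(seq(0, 3, length.out = 40))
  data <- Reduce(`+`, Map(`*`, basis, c_true)) + ti_true
  fit <- solve_linear_subproblem(data, basis, reg_alpha = 0, fit_ti = TRUE)
  expect_equal(fit$amplitudes, c_true, tolerance = 1e-8)
  expect_lt(fit$rmsd, 1e-8)
  expect_equal(fit$ti, ti_true, tolerance = 1e-7)
  expect_equal(fit$fitted, data, tolerance = 1e-8)
})

test_that("amplitudes and rmsd are invariant to arbitrary TI and RI offsets", {
  basis <- make_small_basis()
  set.seed(9)
  data <- Reduce(`+`, Map(`*`, basis, c(1, 2, 0.5, 1))) +
    matrix(rnorm(40 * 6, 0, 0.01), 40, 6)
  base <- solve_linear_subproblem(data, basis, 0, fit_ti = TRUE, fit_ri = TRUE)
  ti_arb <- 5 * cos(seq(0, 7, length.out = 40)) + (1:40) * 0.3
  ri_arb <- rnorm(6, 0, 4)
  shifted <- data + ti_arb + rep(ri_arb, each = 40)
  after <- solve_linear_subproblem(shifted, basis, 0, fit_ti = TRUE,
                                   fit_ri = TRUE)
  expect_equal(after$amplitudes, base$amplitudes, tolerance = 1e-8)
  expect_equal(after$rmsd, base$rmsd, tolerance = 1e-8)
  # with only TI fitted, a TI offset alone is likewise absorbed
  base_ti <- solve_linear_subproblem(data, basis, 0, fit_ti = TRUE)
  after_ti <- solve_linear_subproblem(data + ti_arb, basis, 0, fit_ti = TRUE)
  expect_equal(after_ti$amplitudes, base_ti$amplitudes, tolerance = 1e-8)
})

test_that("subproblem equals a dense projection + least-squares oracle", {
  # tiny instances: <= 5 scans x 50 radii x 5 s-values
  for (seed in 1:3) {
    set.seed(seed)
    nr <- 50; nt <- 5; K <- 5
    basis <- make_small_basis(nr, nt, K, seed = seed)
    c_true <- runif(K, 0.5, 2)   # interior optimum: NNLS == unconstrained
    data <- Reduce(`+`, Map(`*`, basis, c_true)) +
      outer(rnorm(nr, 0, 1), rep(1, nt)) +
      matrix(rnorm(nr * nt, 0, 1e-3), nr, nt)
    fit <- solve_linear_subproblem(data, basis, 0, fit_ti = TRUE,
                                   fit_ri = TRUE)
    # oracle: explicit offset design, projector from its SVD, dense lstsq
    n <- nr * nt
    Oti <- kronecker(rep(1, nt), diag(nr))
    Ori <- kronecker(diag(nt), rep(1, nr))
    O <- cbind(Oti, Ori)
    sv <- svd(O)
    U <- sv$u[, sv$d > 1e-8 * sv$d[1], drop = FALSE]
    P <- diag(n) - U %*% t(U)
    C <- P %*% vapply(basis, as.vector, numeric(n))
    d <- P %*% as.vector(data)
    c_oracle <- qr.solve(C, d)
    rmsd_oracle <- sqrt(mean((d - C %*% c_oracle)^2))
    expect_equal(fit$amplitudes, as.vector(c_oracle), tolerance = 1e-8)
    expect_equal(fit$rmsd, rmsd_oracle, tolerance = 1e-8)
  }
})

test_that("regularization smooths monotonically with alpha", {
  basis <- make_small_basis(60, 8, 6, seed = 5)
  set.seed(6)
  data <- Reduce(`+`, Map(`*`, basis, c(0.2, 2, 0.1, 1.5, 0.3, 1))) +
    matrix(rnorm(60 * 8, 0, 0.05), 60, 8)
  L <- diff(diag(6), differences = 2)
  rough <- vapply(10^seq(-3, 3, by = 1), function(a) {
    cc <- solve_linear_subproblem(data, basis, a, fit_ti = TRUE)$amplitudes
    sum((L %*% cc)^2)
  }, 0)
  expect_true(all(diff(rough) <= 1e-10))
  # rmsd cannot improve as alpha grows
  rms <- vapply(c(0, 1, 100), function(a)
    solve_linear_subproblem(data, basis, a, fit_ti = TRUE)$rmsd, 0)
  expect_true(all(diff(rms) >= -1e-12))
})

test_that("automatic alpha lands at the one-sigma F-ratio level", {
  basis <- make_small_basis(60, 8, 6, seed = 8)
  set.seed(8)
  data <- Reduce(`+`, Map(`*`, basis, c(1, 1.5, 0.5, 2, 0.2, 0.8))) +
    matrix(rnorm(60 * 8, 0, 0.05), 60, 8)
  f0 <- solve_linear_subproblem(data, basis, 0, fit_ti = TRUE)
  fa <- solve_linear_subproblem(data, basis, "auto", fit_ti = TRUE)
  nu <- 60 * 8 - 6
  expect_gt(fa$alpha, 0)
  expect_lte(fa$rmsd / f0$rmsd, sqrt(qf(0.68, nu, nu)) + 1e-6)
})

test_that("integrate_cs matches quadrature oracles and handles point masses", {
  s <- seq(1, 5, length.out = 41)
  # single nonzero grid point
  cc <- rep(0, 41); cc[13] <- 7
  m1 <- cs_model(s, 1.4, cc)
  expect_equal(integrate_cs(m1)$s_w, s[13])
  # symmetric two-peak with equal areas
  cc2 <- rep(0, 41); cc2[c(6, 36)] <- 2
  expect_equal(integrate_cs(cs_model(s, 1.4, cc2))$s_w, (s[6] + s[36]) / 2)
  # random density: trapezoid vs fine-grid oracle of the interpolant
  set.seed(2)
  cc3 <- abs(rnorm(41, 1, 0.3))
  m3 <- cs_model(s, 1.4, cc3)
  fine <- seq(1, 5, length.out = 40001)
  cf <- approx(s, cc3, fine)$y
  amp_oracle <- pracma::trapz(fine, cf)
  sw_oracle <- pracma::trapz(fine, fine * cf) / amp_oracle
  out <- integrate_cs(m3)
  expect_equal(out$amplitude, amp_oracle, tolerance = 1e-10)
  expect_equal(out$s_w, sw_oracle, tolerance = 1e-10)
  # sub-range integration and the zero-integral flag
  expect_equal(integrate_cs(m1, s[10], s[20])$s_w, s[13])
  expect_warning(out0 <- integrate_cs(m1, s[20], s[40]), "zero integral")
  expect_true(is.na(out0$s_w))
})

test_that("meniscus-exclusion rule sets the default fit range", {
  cell <- cell_model(6.0, 7.2, 50000)
  expect_identical(default_fit_range(cell, 0), c(6.0, 7.2))
  expect_equal(default_fit_range(cell, 0.15), c(6.30, 7.2))
  # r_min grows monotonically with delta
  r_mins <- vapply(c(0, 0.05, 0.1, 0.2), function(d)
    default_fit_range(cell, d)[1], 0)
  expect_true(all(diff(r_mins) > 0))
  expect_error(default_fit_range(cell, 0.65), "no radial range")
})

test_that("noise-free single species is recovered essentially exactly", {
  sim <- simulate_scanset(quick_spec(s = 2.5, ff0 = 1.39, noise_sigma = 0,
                                     seed = 7))
  rep <- fit_cs(sim$scansets$gain1, quick_config())
  # s on-grid: the distribution collapses onto the generating species
  expect_equal(rep$s_w, 2.5, tolerance = 1e-4)
  expect_identical(rep$cs$s_grid[which.max(rep$cs$c)], 2.5)
  expect_equal(rep$params[["ff0"]], 1.39, tolerance = 0.01)
  expect_lt(rep$rmsd, 1e-6 * 100)       # rmsd below 1e-6 of the amplitude
  expect_equal(rep$amplitude, 100, tolerance = 1e-4)
  expect_true(rep$converged)
})

test_that("kappa = 1 nonlinear path is identical to the linear path", {
  sim <- simulate_scanset(quick_spec(s = 2.5, noise_sigma = 0.5, seed = 21))
  ss <- sim$scansets$gain1
  lin <- fit_cs(ss, quick_config(fit_ff0 = FALSE, ff0 = 1.39))
  non <- fit_cs(ss, quick_config(fit_ff0 = FALSE, ff0 = 1.39,
                                 nonlinear = TRUE, kappa = 1, a0 = 0))
  expect_identical(lin$rmsd, non$rmsd)
  expect_identical(lin$cs$c, non$cs$c)
  expect_identical(lin$s_w, non$s_w)
  expect_identical(lin$residuals, non$residuals)
})

test_that("a known power-law distortion is inverted by the linearized fit", {
  nl <- nonlinearity_params(a0 = 10, kappa = 1.1)
  sim <- simulate_scanset(quick_spec(s = 2.5, noise_sigma = 0, seed = 5,
                                     nonlinearity = nl))
  rep <- fit_cs(sim$scansets$gain1,
                quick_config(nonlinear = TRUE, kappa = 1.1, a0 = 10))
  expect_equal(rep$s_w, 2.5, tolerance = 1e-3)
  expect_equal(rep$params[["ff0"]], 1.39, tolerance = 0.02)
  expect_lt(rep$rmsd, 1e-4 * 100)
  # amplitude is reported in concentration-linear units
  expect_equal(rep$amplitude, 100, tolerance = 1e-3)
})
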