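# Detector signal model of the confocal fluorescence optics: radial/temporal
# magnification gradients, bottom beam-shadow, Gaussian radial convolution,
# and the power-law signal non-linearity with its linearizing back-transform.

#' FDS detector parameters
#'
#' The four detector-specific parameters of the fluorescence signal model.
#'
#' @param de_dr first-order radial magnification gradient (d eps/d r)_0, 1/cm
#' @param de_dt first-order temporal intensity drift (d eps/d t)_0, per hour
#'   (the customary reporting unit; converted to 1/s internally)
#' @param delta beam cross-section radius (half the detection-cone diameter)
#'   in the plane of the column bottom, cm
#' @param sigma Gaussian radial convolution width, cm (kernel
#'   `exp(-(dr/sigma)^2)`, FWHM about 1.67 sigma)
#' @param trunc_n kernel truncation: support is `|dr| <= trunc_n * sigma`
#' @param drift_mode `"linear"` (first-order Taylor drift) or `"exponential"`
#'   (intensity decay `exp(de_dt * t)`, for strongly bleaching fluorophores)
#' @return object of class `fds_params`
#' @export
#' @examples
#' fds_params(de_dr = 0.28, de_dt = 0.0127, delta = 0.183, sigma = 0.03)
fds_params <- function(de_dr = 0, de_dt = 0, delta = 0, sigma = 0,
                       trunc_n = 3, drift_mode = c("linear", "exponential")) {
  drift_mode <- match.arg(drift_mode)
  if (delta < 0) stop("delta must be >= 0")
  if (sigma < 0) stop("sigma must be >= 0")
  if (trunc_n < 1) stop("trunc_n must be >= 1")
  structure(list(de_dr = de_dr, de_dt = de_dt, delta = delta, sigma = sigma,
                 trunc_n = trunc_n, drift_mode = drift_mode),
            class = "fds_params")
}

#' Power-law signal non-linearity parameters
#'
#' Describes an inner-filter-type non-linear detector response
#' `a_obs = a0 + c^kappa`, with `a0` a baseline offset restricting the power
#' law to the macromolecular signal.
#'
#' @param a0 baseline offset, counts
#' @param kappa power coefficient (> 0); 1 means a linear detector
#' @return object of class `nonlinearity_params`
#' @export
nonlinearity_params <- function(a0 = 0, kappa = 1) {
  if (kappa <= 0) stop("kappa must be > 0")
  structure(list(a0 = a0, kappa = kappa), class = "nonlinearity_params")
}

#' Temporal intensity drift factor
#'
#' Multiplicative intensity factor at elapsed time `t`: `1 + de_dt * t` in
#' linear mode, `exp(de_dt * t)` in exponential mode (both equal 1 at t = 0
#' and agree to first order in `de_dt * t`). `de_dt` here is taken from
#' `fds$de_dt` in per-hour units.
#'
#' @param t elapsed time(s), s
#' @param fds an [fds_params()]
#' @return numeric vector of drift factors
#' @export
temporal_drift_factor <- function(t, fds) {
  stopifnot(inherits(fds, "fds_params"), all(t >= 0))
  k <- fds$de_dt / 3600
  if (fds$drift_mode == "linear") 1 + k * t else exp(k * t)
}

#' Radial/temporal magnification transform T_rt
#'
#' Applies the first-order signal magnification model
#' `s(r,t) = [1 + de_dr (r - m) + de_dt t] * chi(r,t)`, normalized so the
#' magnification equals 1 at the meniscus at t = 0; concentration amplitudes
#' are therefore in signal units at the meniscus at the start of
#' centrifugation. This low-level interface takes both gradients in base
#' units (`de_dt` in 1/s); [compose_fds()] converts from [fds_params()].
#'
#' @param chi concentration matrix, radii x times
#' @param m meniscus radius, cm
#' @param de_dr radial magnification gradient, 1/cm
#' @param de_dt temporal drift, 1/s
#' @param radii radii, cm (rows of `chi`)
#' @param times elapsed times, s (columns of `chi`)
#' @return transformed signal matrix of the same shape
#' @export
apply_rt <- function(chi, m, de_dr, de_dt, radii, times) {
  stopifnot(nrow(chi) == length(radii), ncol(chi) == length(times))
  eps <- outer(1 + de_dr * (radii - m), de_dt * times, `+`)
  if (any(eps <= 0))
    warning("magnification factor <= 0 within the radius/time range")
  eps * chi
}

#' Fractional beam shadow at the cell bottom
#'
#' Fraction of a uniformly illuminated circular beam cross-section of radius
#' `delta`, centered at radius `r`, that is obscured by the cell bottom at
#' `b`: the area fraction of the circular segment beyond the bottom line. It
#' is 0 for `r <= b - delta`, rises smoothly to exactly 0.5 at `r = b`, and
#' continues symmetrically to 1 at `r >= b + delta`. With `delta = 0` it is a
#' step at `b` (value 0.5 at exactly `b`).
#'
#' @param r radius (vectorized), cm
#' @param b bottom of the solution column, cm
#' @param delta beam cross-section radius, cm
#' @return shadow fraction in `[0, 1]`
#' @export
#' @examples
#' shadow_fraction(7.2, b = 7.2, delta = 0.1)    # 0.5
#' shadow_fraction(7.1, b = 7.2, delta = 0.1)    # 0
shadow_fraction <- function(r, b, delta) {
  stopifnot(delta >= 0)
  if (delta == 0) return(ifelse(r < b, 0, ifelse(r > b, 1, 0.5)))
  h <- b - r  # distance of beam center below the bottom line
  out <- numeric(length(r))
  out[h >= delta] <- 0
  out[h <= -delta] <- 1
  inside <- abs(h) < delta
  if (any(inside)) {
    hi <- h[inside]
    seg <- (delta^2 * acos(hi / delta) - hi * sqrt(delta^2 - hi^2)) /
      (pi * delta^2)
    out[inside] <- pmin(pmax(seg, 0), 1)  # clamp fp cancellation at |h| = delta
  }
  out
}

#' Bottom shadow transform T_S
#'
#' Attenuates the signal by the visible-beam fraction near the cell bottom:
#' `(1 - B(r, b, delta)) * signal`, applied per radius. Linear in the signal.
#'
#' @param signal signal matrix, radii x times
#' @param b bottom radius, cm
#' @param delta beam cross-section radius, cm
#' @param radii radii, cm
#' @return attenuated signal matrix
#' @export
apply_shadow <- function(signal, b, delta, radii) {
  stopifnot(nrow(signal) == length(radii))
  if (delta == 0) return(signal)  # zero-width beam casts no shadow
  (1 - shadow_fraction(radii, b, delta)) * signal
}

# internal: banded Gaussian smoothing with edge renormalization, applied to
# every column of X (radii down the rows)
band_convolve <- function(X, sigma, trunc_n, h) {
  n <- nrow(X); m <- ncol(X)
  K <- floor(trunc_n * sigma / h + 1e-9)  # inclusive support |dr| <= n*sigma
  if (K < 1) return(X)
  w <- exp(-(((-K:K) * h) / sigma)^2)
  Xp <- rbind(matrix(0, K, m), X, matrix(0, K, m))
  ones <- c(rep(0, K), rep(1, n), rep(0, K))
  num <- matrix(0, n, m)
  den <- numeric(n)
  for (j in seq_len(2 * K + 1)) {
    rows <- j:(j + n - 1)
    num <- num + w[j] * Xp[rows, , drop = FALSE]
    den <- den + w[j] * ones[rows]
  }
  num / den  # den < full kernel sum only within K points of the data edges
}

#' Gaussian radial convolution transform T_C
#'
#' Discrete convolution of each scan with a Gaussian kernel
#' `K(dr) = exp(-(dr/sigma)^2)` truncated at `|dr| <= trunc_n * sigma` and
#' renormalized to unit sum, including at the data edges, so constants are
#' preserved exactly. Under this kernel convention the full width at half
#' maximum is `2 sigma sqrt(ln 2)`, about 1.67 sigma. `sigma` below half the
#' radial spacing returns the input unchanged.
#'
#' @param signal signal matrix, radii x times (a vector is treated as one scan)
#' @param sigma convolution width, cm
#' @param trunc_n kernel truncation multiple
#' @param radii uniformly spaced radii, cm
#' @return convolved signal of the same shape
#' @export
gaussian_convolve <- function(signal, sigma, trunc_n = 3, radii) {
  vec <- is.null(dim(signal))
  if (vec) signal <- matrix(signal, ncol = 1)
  stopifnot(nrow(signal) == length(radii), sigma >= 0, trunc_n >= 1)
  if (length(radii) < 2) return(if (vec) drop(signal) else signal)
  h <- diff(radii)
  if (diff(range(h)) > 1e-6)
    stop("gaussian_convolve requires uniformly spaced radii (tolerance 1e-6 cm)")
  h <- mean(h)
  if (sigma >= h / 2)  # below half the spacing the kernel is unresolvable
    signal <- band_convolve(signal, sigma, trunc_n, h)
  if (vec) drop(signal) else signal
}

#' Composite FDS signal transform
#'
#' Applies the full detector model to a concentration field: magnification
#' gradients first, then the bottom shadow, then the radial convolution
#' (`T_C(T_S(T_rt(chi)))`). All three transforms are linear in `chi`, so the
#' composition can be imposed on each Lamm solution of a mixture or
#' distribution independently before the linear distribution analysis.
#'
#' @param chi concentration matrix, radii x times
#' @param cell a [cell_model()] (provides meniscus and bottom)
#' @param fds an [fds_params()]
#' @param radii radii, cm
#' @param times elapsed times, s
#' @return model signal matrix
#' @export
compose_fds <- function(chi, cell, fds, radii, times) {
  stopifnot(inherits(cell, "cell_model"), inherits(fds, "fds_params"))
  m <- cell$meniscus
  if (fds$drift_mode == "linear") {
    x <- apply_rt(chi, m, fds$de_dr, fds$de_dt / 3600, radii, times)
  } else {
    eps <- outer(fds$de_dr * (radii - m),
                 temporal_drift_factor(times, fds), `+`)
    x <- eps * chi
  }
  x <- apply_shadow(x, cell$bottom, fds$delta, radii)
  gaussian_convolve(x, fds$sigma, fds$trunc_n, radii)
}

#' Back-transform observed signal to concentration-linear units
#'
#' Inverts the power-law response `a_obs = a0 + c^kappa`:
#' `c = (a_obs - a0)^(1/kappa)`. Observed values below `a0` (possible with
#' noise) are clamped to 0; the number of clamped points is reported as an
#' attribute `n_clamped`. With `kappa = 1` this reduces exactly to
#' subtraction of `a0`.
#'
#' @param a_obs observed signal, counts (vector or matrix)
#' @param nl a [nonlinearity_params()]
#' @return values linear in concentration, same shape as `a_obs`
#' @export
linearize_signal <- function(a_obs, nl) {
  stopifnot(inherits(nl, "nonlinearity_params"))
  x <- a_obs - nl$a0
  if (nl$kappa == 1) {  # pure offset: exact inverse, no domain restriction
    attr(x, "n_clamped") <- 0L
    return(x)
  }
  n_clamped <- sum(x < 0)
  x[x < 0] <- 0
  out <- x^(1 / nl$kappa)
  attributes(out) <- attributes(a_obs)
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Forward power-law detector response
#'
#' Maps concentration-linear values into observed data space,
#' `a_obs = a0 + c^kappa`; used to return a fitted model to the raw data
#' space for inspection of residuals.
#'
#' @param c_lin concentration-linear values (>= 0)
#' @param nl a [nonlinearity_params()]
#' @return observed-signal values, counts
#' @export
delinearize_signal <- function(c_lin, nl) {
  stopifnot(inherits(nl, "nonlinearity_params"))
  if (nl$kappa == 1) return(c_lin + nl$a0)  # pure offset: negatives allowed
  if (any(c_lin < 0)) stop("concentration-linear values must be >= 0")
  c_lin^nl$kappa + nl$a0
}
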