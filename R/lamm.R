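# Lamm-equation core: cell geometry, species, solution conditions, and the
# finite-volume solver producing chi(r, t) on the experimental grid.

SVEDBERG <- 1e-13     # s per Svedberg unit
KB <- 1.380649e-16    # erg/K
RGAS <- 8.31446261815324e7  # erg/(mol K)

#' Centrifuge cell model
#'
#' Geometry and rotor-speed profile of one sector-shaped solution column.
#'
#' @param meniscus meniscus (air/solution) radius, cm
#' @param bottom bottom of the solution column (highest radius), cm
#' @param rpm rotor speed, revolutions per minute
#' @param t_acc rotor acceleration time, s: the rotor speed ramps linearly from
#'   0 to `rpm` over `[0, t_acc]`; `0` means instantaneous start.
#' @return object of class `cell_model`
#' @export
#' @examples
#' cell_model(meniscus = 6.0, bottom = 7.2, rpm = 50000)
cell_model <- function(meniscus, bottom, rpm, t_acc = 0) {
  stopifnot(is.numeric(meniscus), is.numeric(bottom), is.numeric(rpm))
  if (!(meniscus > 0 && bottom > meniscus))
    stop("cell geometry requires 0 < meniscus < bottom")
  if (rpm <= 0) stop("rpm must be positive")
  if (t_acc < 0) stop("t_acc must be >= 0")
  structure(list(meniscus = meniscus, bottom = bottom, rpm = rpm,
                 t_acc = t_acc), class = "cell_model")
}

#' Single sedimenting species
#'
#' @param s sedimentation coefficient, Svedberg (1 S = 1e-13 s)
#' @param D diffusion coefficient, cm^2/s
#' @param c0 loading concentration in signal units (counts), referenced to the
#'   meniscus at the start of centrifugation
#' @return object of class `species_params`
#' @export
species_params <- function(s, D, c0 = 1) {
  stopifnot(is.numeric(s), is.numeric(D), is.numeric(c0))
  if (D < 0) stop("D must be >= 0")
  if (c0 < 0) stop("c0 must be >= 0")
  structure(list(s = s, D = D, c0 = c0), class = "species_params")
}

#' Solution (buffer) conditions
#'
#' Density, viscosity, partial-specific volume and temperature used for
#' conversions between s, D and molar mass. Defaults are water at 20 degrees C
#' with a typical protein partial-specific volume, so sedimentation
#' coefficients pass through uncorrected for buffer effects.
#'
#' @param density solvent density, g/ml
#' @param viscosity solvent viscosity, poise
#' @param vbar partial-specific volume of the macromolecule, ml/g
#' @param temperature absolute temperature, K
#' @return object of class `solution_conditions`
#' @export
solution_conditions <- function(density = 0.99823, viscosity = 0.01002,
                                vbar = 0.73, temperature = 293.15) {
  stopifnot(density > 0, viscosity > 0, vbar > 0, temperature > 0)
  if (vbar * density >= 1)
    warning("vbar * density >= 1: species is neutrally buoyant or floats")
  structure(list(density = density, viscosity = viscosity, vbar = vbar,
                 temperature = temperature), class = "solution_conditions")
}

#' Squared-angular-velocity time integral under finite rotor acceleration
#'
#' Returns the accumulated integral of omega(t')^2 from 0 to each time,
#' for a rotor speed ramping linearly from rest to full speed over
#' `cell$t_acc` seconds. For `t >= t_acc` this equals
#' `omega^2 * (t - 2 t_acc / 3)`; with `t_acc = 0` it is exactly
#' `omega^2 * t`.
#'
#' @param times elapsed times since start of centrifugation, s
#' @param cell a [cell_model()]
#' @return numeric vector of the same length, rad^2/s
#' @export
effective_time <- function(times, cell) {
  stopifnot(inherits(cell, "cell_model"), all(times >= 0))
  omega2 <- (cell$rpm * pi / 30)^2
  ta <- cell$t_acc
  if (ta == 0) return(omega2 * times)
  ifelse(times <= ta,
         omega2 * times^3 / (3 * ta^2),
         omega2 * (times - 2 * ta / 3))
}

#' Solve the Lamm equation for one species
#'
#' Computes the concentration evolution chi(r, t) of a single ideal species in
#' a sector-shaped cell, starting from a uniform column at `c0`, with zero-flux
#' boundaries at the meniscus and bottom. The solver is a conservative
#' finite-volume discretization with exponentially fitted fluxes and
#' Crank-Nicolson time stepping on an internal uniform grid (default 1000
#' points); results are interpolated to the requested radii. Finite rotor
#' acceleration is handled by evaluating the constant-speed solution at the
#' equivalent time `effective_time(t) / omega^2`.
#'
#' @param species a [species_params()]
#' @param cell a [cell_model()]
#' @param times ascending elapsed times, s (>= 0)
#' @param radii radii at which to report the solution, cm, within
#'   `[meniscus, bottom]`
#' @param grid_points internal radial grid size
#' @param courant advective Courant-number cap per time substep
#' @return matrix `length(radii) x length(times)` of concentrations in the
#'   loading signal units
#' @export
#' @examples
#' cell <- cell_model(6.0, 7.2, rpm = 50000)
#' sp <- species_params(s = 2.6, D = 7.4e-7, c0 = 1)
#' chi <- solve_lamm(sp, cell, times = c(0, 600, 3000), radii = seq(6, 7.2, 0.01))
solve_lamm <- function(species, cell, times, radii, grid_points = 1000,
                       courant = 1.0) {
  stopifnot(inherits(species, "species_params"), inherits(cell, "cell_model"))
  if (is.unsorted(times, strictly = FALSE) || any(times < 0))
    stop("times must be ascending and >= 0")
  m <- cell$meniscus; b <- cell$bottom
  eps_r <- 1e-9
  if (any(radii < m - eps_r | radii > b + eps_r))
    stop("radii must lie within [meniscus, bottom]")
  omega2 <- (cell$rpm * pi / 30)^2
  t_eff <- effective_time(times, cell) / omega2
  grid <- seq(m, b, length.out = grid_points)
  chi_g <- .lamm_march(grid, species$s * SVEDBERG, species$D, omega2,
                       species$c0, t_eff, courant)
  # interpolate internal grid -> requested radii, per time column
  out <- matrix(0, nrow = length(radii), ncol = length(times))
  rr <- pmin(pmax(radii, m), b)
  for (j in seq_along(times))
    out[, j] <- approx(grid, chi_g[, j], xout = rr)$y
  dimnames(out) <- list(NULL, NULL)
  out
}

#' Diffusion coefficient from the frictional ratio (c(s) scaling law)
#'
#' Computes the hydrodynamic scaling relation used by the c(s) method to tie
#' the diffusion coefficient of every species to a single signal-average
#' frictional ratio:
#' `D(s) = (sqrt(2)/(18 pi)) kT s^(-1/2) (eta f/f0)^(-3/2) ((1 - vbar rho)/vbar)^(1/2)`.
#'
#' @param s sedimentation coefficient, Svedberg
#' @param ff0 frictional ratio f/f0 (>= 1)
#' @param cond a [solution_conditions()]
#' @return diffusion coefficient, cm^2/s
#' @export
diffusion_from_ff0 <- function(s, ff0, cond = solution_conditions()) {
  stopifnot(inherits(cond, "solution_conditions"))
  if (any(s <= 0)) stop("s must be > 0")
  if (any(ff0 < 1)) stop("frictional ratio must be >= 1")
  buoy <- 1 - cond$vbar * cond$density
  if (buoy <= 0) stop("vbar * density >= 1: Svedberg conversion undefined")
  kT <- KB * cond$temperature
  (sqrt(2) / (18 * pi)) * kT * (s * SVEDBERG)^(-0.5) *
    (cond$viscosity * ff0)^(-1.5) * sqrt(buoy / cond$vbar)
}

#' Molar mass from s and D via the Svedberg equation
#'
#' `M = s R T / (D (1 - vbar rho))`, reported in kDa.
#'
#' @inheritParams diffusion_from_ff0
#' @param D diffusion coefficient, cm^2/s
#' @return apparent molar mass, kDa
#' @export
svedberg_mass <- function(s, D, cond = solution_conditions()) {
  stopifnot(inherits(cond, "solution_conditions"))
  if (any(D <= 0)) stop("D must be > 0")
  buoy <- 1 - cond$vbar * cond$density
  if (buoy <= 0) stop("vbar * density >= 1: Svedberg conversion undefined")
  (s * SVEDBERG) * RGAS * cond$temperature / (D * buoy) / 1000
}
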