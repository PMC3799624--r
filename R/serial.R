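# Batch orchestration and cross-run analyses: serial fitting of sorted scan
# sets, gain-linearity regression of boundary amplitudes, signal-increment
# surfaces over concentration and focal depth, and the detection-beam angle.

#' Serial c(s) analysis of sorted scan sets
#'
#' Runs [fit_cs()] over every (cell, gain) group produced by
#' [sort_by_gain()], collecting one fit report per group. Failures are
#' logged and skipped rather than fatal; an error is raised only if every
#' group fails. Optionally writes the batch summary CSV.
#'
#' @param groups named list of [scan_set()] objects
#' @param config a [fit_config()]
#' @param summary_path if non-`NULL`, path of the summary CSV
#'   ([write_summary()])
#' @return named list of `fit_report` objects (failed groups omitted)
#' @export
serial_fit <- function(groups, config, summary_path = NULL) {
  stopifnot(length(groups) > 0)
  reports <- list()
  for (key in names(groups)) {
    rep <- tryCatch(fit_cs(groups[[key]], config), error = function(e) {
      message("fit failed for group ", key, ": ", conditionMessage(e))
      NULL
    })
    if (!is.null(rep)) reports[[key]] <- rep
  }
  if (length(reports) == 0) stop("all serial fits failed")
  if (!is.null(summary_path)) write_summary(reports, summary_path)
  reports
}

#' Gain-linearity analysis of boundary amplitudes
#'
#' Ordinary least-squares regression of fitted boundary amplitudes
#' `a_b(c, g)` against amplifier gain `g` for one sample. Reports both the
#' free-intercept slope and the zero-intercept slope `a_b*` (the average
#' boundary height normalized to a gain of unity), plus the residual
#' fraction (rms residual over mean amplitude) as a linearity diagnostic.
#'
#' @param gains amplifier gains (>= 2 distinct values)
#' @param amplitudes boundary amplitudes at those gains, counts. As an
#'   alternative to two vectors, pass a list of `fit_report`s as `gains`.
#' @return object of class `gain_series`: `slope` (free intercept),
#'   `intercept`, `slope0` (zero intercept, the a_b* normalization),
#'   `residual_fraction`, and the `(gain, amplitude)` table
#' @export
gain_linearity <- function(gains, amplitudes = NULL) {
  if (is.list(gains) && is.null(amplitudes)) {
    reports <- gains
    gains <- vapply(reports, function(r) r$meta$gain, 0)
    amplitudes <- vapply(reports, `[[`, 0, "amplitude")
  }
  stopifnot(length(gains) == length(amplitudes))
  if (length(unique(gains)) < 2)
    stop("gain-linearity fit needs >= 2 distinct gains")
  free <- lm(amplitudes ~ gains)
  zero <- lm(amplitudes ~ gains - 1)
  resid_frac <- sqrt(mean(free$residuals^2)) / mean(amplitudes)
  structure(list(slope = unname(coef(free)[2]),
                 intercept = unname(coef(free)[1]),
                 slope0 = unname(coef(zero)[1]),
                 residual_fraction = resid_frac,
                 table = data.frame(gain = gains, amplitude = amplitudes)),
            class = "gain_series")
}

#' @export
print.gain_series <- function(x, ...) {
  cat(sprintf(
    "<gain_series> a_b* = %.4g counts/gain (zero-intercept %.4g), residual fraction %.3g\n",
    x$slope, x$slope0, x$residual_fraction))
  invisible(x)
}

#' Signal-increment surface
#'
#' Converts gain-normalized boundary amplitudes `a_b*(c)` into effective
#' signal increments `eps*(c) = a_b*(c) / c` (counts per nM), tabulated
#' against concentration (and optional focal depth). A strictly monotone
#' decrease of `eps*` with concentration -- the signature of inner-filter
#' signal non-linearity -- raises `nonlinearity_flag`.
#'
#' @param series list of `gain_series` (one per concentration), or a numeric
#'   vector of gain-normalized amplitudes `a_b*`
#' @param concentrations loading concentrations, nM (> 0), matching `series`
#' @param focal_um optional focal depths, micrometers, recycled to length
#' @return object of class `increment_surface`: `table` with columns
#'   `concentration_nM`, `focal_depth_um`, `eps_star`, and
#'   `nonlinearity_flag`
#' @export
increment_surface <- function(series, concentrations, focal_um = NA_real_) {
  ab <- if (is.numeric(series)) series
        else vapply(series, `[[`, 0, "slope")
  stopifnot(length(ab) == length(concentrations))
  if (any(concentrations <= 0)) stop("concentrations must be > 0")
  eps <- ab / concentrations
  ord <- order(concentrations)
  flag <- length(eps) >= 2 && all(diff(eps[ord]) < 0)
  tab <- data.frame(concentration_nM = concentrations[ord],
                    focal_depth_um = rep_len(focal_um, length(eps))[ord],
                    eps_star = eps[ord])
  structure(list(table = tab, nonlinearity_flag = flag),
            class = "increment_surface")
}

#' @export
print.increment_surface <- function(x, ...) {
  cat(sprintf("<increment_surface> %d conditions%s\n", nrow(x$table),
              if (x$nonlinearity_flag)
                " | eps* decreases monotonically with c (non-linearity flag)"
              else ""))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Effective detection-beam angle from focal-depth dependence of delta
#'
#' The best-fit beam cross-section radius delta grows linearly with focal
#' depth; the least-squares slope d(delta)/dz gives an effective beam
#' half-angle `atan(d delta / d z)` in degrees.
#'
#' @param focal_um focal depths, micrometers (>= 2 distinct values)
#' @param delta_cm best-fit beam radii at those depths, cm
#' @return list with `angle_deg`, `slope` (cm/cm) and `intercept_cm`
#' @export
beam_angle <- function(focal_um, delta_cm) {
  stopifnot(length(focal_um) == length(delta_cm))
  if (length(unique(focal_um)) < 2)
    stop("beam-angle fit needs >= 2 distinct focal depths")
  z_cm <- focal_um * 1e-4
  fit <- lm(delta_cm ~ z_cm)
  slope <- unname(coef(fit)[2])
  list(angle_deg = atan(slope) * 180 / pi, slope = slope,
       intercept_cm = unname(coef(fit)[1]))
}
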