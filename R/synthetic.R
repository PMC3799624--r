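# Synthetic FDS-SV data with known ground truth: the package's only data
# source. Emulates EGFP-like acquisitions (12 mm column, 50,000 rpm, 1-min
# scan schedule, 0.002 cm radial spacing, gains 1/2/4/8, count-scale noise)
# with every detector distortion the fitter is expected to recover.

#' Simulation specification
#'
#' Full description of a simulated FDS-SV experiment: species, cell
#' geometry, detector parameters, non-linearity, scan schedule, radial
#' spacing, gains, noise model, systematic-noise amplitudes, and RNG seed.
#' A fixed seed makes the output bit-reproducible.
#'
#' @param species list of [species_params()]
#' @param cell a [cell_model()]
#' @param fds an [fds_params()]
#' @param nonlinearity a [nonlinearity_params()]
#' @param schedule list with `start` (s), `interval` (s), `count` (>= 2)
#' @param spacing radial spacing, cm (> 0)
#' @param gains amplifier gains to emit, one scan set each
#' @param noise list with `sigma` (additive Gaussian sd, counts) and
#'   optional `proportional` (sd fraction of the local signal)
#' @param ti_amplitude amplitude of a smooth low-order-polynomial
#'   time-invariant baseline, counts (0 disables)
#' @param ti_spikes number of single-radius TI spikes (amplitude
#'   `5 * ti_amplitude`)
#' @param ri_amplitude sd of per-scan radial-invariant offsets, counts
#' @param seed RNG seed (integer)
#' @param run run identifier stored in the scan-set metadata
#' @param focal_um focal depth recorded in the metadata, micrometers
#' @return object of class `simulation_spec`
#' @export
simulation_spec <- function(species, cell, fds = fds_params(),
                            nonlinearity = nonlinearity_params(),
                            schedule = list(start = 60, interval = 60,
                                            count = 100),
                            spacing = 0.002, gains = c(1, 2, 4, 8),
                            noise = list(sigma = 1, proportional = 0),
                            ti_amplitude = 0, ti_spikes = 0,
                            ri_amplitude = 0, seed = 1L, run = "sim",
                            focal_um = NA_real_) {
  if (inherits(species, "species_params")) species <- list(species)
  stopifnot(all(vapply(species, inherits, TRUE, "species_params")),
            inherits(cell, "cell_model"), inherits(fds, "fds_params"),
            inherits(nonlinearity, "nonlinearity_params"))
  if (spacing <= 0) stop("spacing must be > 0")
  if (schedule$count < 2) stop("schedule count must be >= 2")
  if (is.null(noise$proportional)) noise$proportional <- 0
  structure(list(species = species, cell = cell, fds = fds,
                 nonlinearity = nonlinearity, schedule = schedule,
                 spacing = spacing, gains = gains, noise = noise,
                 ti_amplitude = ti_amplitude, ti_spikes = ti_spikes,
                 ri_amplitude = ri_amplitude, seed = as.integer(seed),
                 run = run, focal_um = focal_um),
            class = "simulation_spec")
}

#' EGFP-like run preset
#'
#' Conditions of a typical high-speed FDS-SV experiment on enhanced green
#' fluorescent protein: 12 mm solution column (meniscus 6.0 cm, bottom
#' 7.2 cm), 50,000 rpm with a 200 s linear acceleration ramp, scans every
#' minute through the full sedimentation process, 0.002 cm radial spacing,
#' gains 1/2/4/8, a single species at s = 2.584 S with frictional ratio 1.39
#' (diffusion via [diffusion_from_ff0()] in water at 20 C, vbar 0.73 ml/g),
#' and additive noise of 1 count.
#'
#' @param concentration_scale multiplies the loading signal; 1 gives a
#'   100-count boundary at gain 1, so the default signal/noise is 100
#' @param ... overrides passed on to [simulation_spec()] (e.g. `fds`,
#'   `nonlinearity`, `gains`, `seed`, `schedule`)
#' @return a [simulation_spec()]
#' @export
make_egfp_like_run <- function(concentration_scale = 1, ...) {
  if (concentration_scale <= 0) stop("concentration_scale must be > 0")
  cond <- solution_conditions()
  s0 <- 2.584; ff0 <- 1.39
  sp <- species_params(s0, diffusion_from_ff0(s0, ff0, cond),
                       c0 = 100 * concentration_scale)
  args <- list(...)
  defaults <- list(species = list(sp),
                   cell = cell_model(6.0, 7.2, rpm = 50000, t_acc = 200),
                   schedule = list(start = 60, interval = 60, count = 420),
                   spacing = 0.002, gains = c(1, 2, 4, 8),
                   noise = list(sigma = 1, proportional = 0))
  do.call(simulation_spec, utils::modifyList(defaults, args))
}

#' EGFP dilution-series concentrations
#'
#' A 14-point geometric dilution series from 5.5 nM to 5560 nM, spanning
#' three orders of magnitude of loading concentration.
#'
#' @return numeric vector of 14 concentrations, nM
#' @export
egfp_dilution_series <- function() {
  5.5 * (5560 / 5.5)^((0:13) / 13)
}

#' Simulate an FDS-SV experiment
#'
#' Forward-models the scan sets of one run: the summed Lamm solutions of all
#' species are passed through the composite detector transform
#' ([compose_fds()]), mapped through the power-law response
#' ([delinearize_signal()]), scaled by each amplifier gain, and perturbed
#' with the systematic (TI/RI) and random noise of the specification. The
#' noise-free truth is returned alongside the data.
#'
#' @param spec a [simulation_spec()]
#' @return object of class `fds_simulation`: `scansets` (named list, one
#'   [scan_set()] per gain), and `truth` with the spec, the radius/time
#'   grids, the noise-free signal per gain, and the realized TI/RI vectors
#' @export
simulate_scanset <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  cell <- spec$cell
  radii <- seq(cell$meniscus, cell$bottom, by = spec$spacing)
  times <- spec$schedule$start + spec$schedule$interval *
    (seq_len(spec$schedule$count) - 1)

  chi <- Reduce(`+`, lapply(spec$species, function(sp)
    solve_lamm(sp, cell, times, radii)))
  model_lin <- compose_fds(chi, cell, spec$fds, radii, times)
  obs <- delinearize_signal(pmax(model_lin, 0), spec$nonlinearity)

  nr <- length(radii); nt <- length(times)
  ti <- rep(0, nr); ri <- rep(0, nt)
  if (spec$ti_amplitude > 0) {
    x <- (radii - mean(radii)) / (diff(range(radii)) / 2)
    co <- rnorm(4, 0, spec$ti_amplitude)
    ti <- co[1] + co[2] * x + co[3] * x^2 + co[4] * x^3
    if (spec$ti_spikes > 0) {
      at <- sample.int(nr, spec$ti_spikes)
      ti[at] <- ti[at] + rnorm(spec$ti_spikes, 0, 5 * spec$ti_amplitude)
    }
  }
  if (spec$ri_amplitude > 0) ri <- rnorm(nt, 0, spec$ri_amplitude)

  scansets <- list(); clean <- list()
  for (g in spec$gains) {
    Yg <- g * obs + ti + rep(ri, each = nr)
    sdmat <- spec$noise$sigma + spec$noise$proportional * abs(Yg)
    Y <- Yg + matrix(rnorm(nr * nt, 0, 1), nr, nt) * sdmat
    scans <- lapply(seq_len(nt), function(j)
      radial_scan(radii, Y[, j], time = times[j], rpm = cell$rpm,
                  temperature = 20, cell = 1L, gain = g,
                  focal_um = spec$focal_um))
    key <- sprintf("gain%g", g)
    scansets[[key]] <- scan_set(scans, meta = list(run = spec$run,
                                                   focal_um = spec$focal_um))
    clean[[key]] <- Yg
  }
  structure(list(scansets = scansets,
                 truth = list(spec = spec, radii = radii, times = times,
                              chi = chi, signal = clean, ti = ti, ri = ri)),
            class = "fds_simulation")
}

#' Write a simulated run to scan files plus a ground-truth record
#'
#' One scan file per (gain, scan) via [write_scan()], named
#' `<run>_c<cell>_g<gain>_<index>.fds`, plus `<run>_truth.json` holding the
#' generating parameters.
#'
#' @param sim an `fds_simulation` from [simulate_scanset()]
#' @param dir output directory (created if needed)
#' @return invisibly, character vector of the scan-file paths
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "fds_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- sim$truth$spec
  paths <- character(0)
  for (key in names(sim$scansets)) {
    ss <- sim$scansets[[key]]
    for (i in seq_along(ss$scans)) {
      sc <- ss$scans[[i]]
      p <- file.path(dir, sprintf("%s_c%d_g%g_%04d.fds", spec$run, sc$cell,
                                  sc$gain, i))
      write_scan(sc, p)
      paths <- c(paths, p)
    }
  }
  sp <- spec$species
  truth <- list(run = spec$run, seed = spec$seed,
                species = lapply(sp, function(x) x[c("s", "D", "c0")]),
                meniscus = spec$cell$meniscus, bottom = spec$cell$bottom,
                rpm = spec$cell$rpm, t_acc = spec$cell$t_acc,
                fds = sim$truth$spec$fds[c("de_dr", "de_dt", "delta", "sigma")],
                nonlinearity = spec$nonlinearity[c("a0", "kappa")],
                gains = spec$gains, noise = spec$noise,
                focal_um = spec$focal_um)
  jsonlite::write_json(truth, file.path(dir, paste0(spec$run, "_truth.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
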