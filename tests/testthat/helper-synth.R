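# Shared fixtures, all generated in code: a small fast EGFP-like simulation
# and compact fit configurations used across test files.

egfp_cond <- solution_conditions()

# single-species spec on a coarse grid: cheap enough for many unit tests
quick_spec <- function(s = 2.5, ff0 = 1.39, c0 = 100, fds = fds_params(),
                       noise_sigma = 0, seed = 1, gains = 1, n_scans = 14,
                       spacing = 0.005, rpm = 50000, t_acc = 0, ...) {
  sp <- species_params(s, diffusion_from_ff0(s, ff0, egfp_cond), c0 = c0)
  simulation_spec(sp, cell_model(6.0, 7.2, rpm, t_acc = t_acc), fds = fds,
                  schedule = list(start = 300, interval = 1500,
                                  count = n_scans),
                  spacing = spacing, gains = gains,
                  noise = list(sigma = noise_sigma), seed = seed, ...)
}

# matching fit configuration (s = 2.5 lies exactly on this grid)
quick_config <- function(...) {
  args <- utils::modifyList(
    list(s_grid = seq(1, 4, by = 0.25), meniscus = 6.0, bottom = 7.2,
         ff0 = 1.6, fit_ff0 = TRUE, alpha = 0, fit_ti = TRUE,
         grid_points = 1000, reltol = 1e-12),  # grid matches the simulator
    list(...))
  do.call(fit_config, args)
}

# a tiny radial_scan for I/O tests
toy_scan <- function(n = 3, time = 60, gain = 2, cell = 1L, rpm = 50000) {
  radial_scan(radii = 6 + 0.002 * (0:(n - 1)), signal = 10 + seq_len(n) - 1,
              time = time, rpm = rpm, temperature = 20, cell = cell,
              gain = gain, channel = "A")
}
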