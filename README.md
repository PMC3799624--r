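# fdsvel

Direct boundary modeling of sedimentation velocity (SV) data recorded with
the confocal **fluorescence detection system (FDS)** for the analytical
ultracentrifuge.

FDS detection reaches nanomolar protein concentrations, but its optics
distort the recorded boundaries in characteristic ways: radial
magnification gradients from scanning slightly out of the plane of
rotation (sloping plateaus), temporal intensity drift from laser power and
photo-bleaching, shadowing of the conical beam by the cell assembly near
the column bottom, Gaussian-like radial convolution from the finite beam
cross-section, and potential inner-filter signal non-linearity. `fdsvel`
fits FDS-SV scan sets with Lamm-equation boundary models augmented by
parametric forms of all of these effects, so the affected data stay in the
fit and the sedimentation parameters stay quantitative.

The signal model composes three linear detector transforms (convolution
applied last) on each Lamm solution χ(r, t):

    s(r,t) = T_C( T_S( T_rt( χ ) ) )

    T_rt:  [1 + (dε/dr)₀ (r − m) + (dε/dt)₀ t] · χ     magnification gradients
    T_S :  [1 − B(r, b, δ)] · χ                         bottom beam shadow
    T_C :  Gaussian radial convolution, width σ         finite beam width

with B the circular-segment area fraction of a beam of radius δ obscured
by the bottom at b (0 at r = b − δ, exactly ½ at r = b), and an optional
power-law response a_obs = a₀ + c^κ handled by analyzing back-transformed,
concentration-linear data. Distributions c(s) are fitted by regularized
non-negative least squares over Lamm solutions tied to one frictional
ratio f/f₀, with time-invariant (TI) and radial-invariant (RI) systematic
offsets eliminated algebraically, and any subset of
{meniscus, bottom, f/f₀, dε/dr, dε/dt, δ, σ, κ} refined by an outer
simplex. Serial tools sort raw scan files by (cell, gain), run batch fits,
regress boundary amplitudes against amplifier gain, tabulate signal
increments ε*(c) = a_b*(c)/c, and estimate the effective beam angle from
the focal-depth dependence of δ.

## Worked example

Simulate an EGFP-like run (12 mm column, 50,000 rpm, 1-min scans, 0.002 cm
radial spacing, a 2.584 S / f/f₀ = 1.39 species, 100-count boundary, 1
count of noise) distorted with all four detector effects, then recover
them by direct boundary fitting (a few minutes of compute):

```r
library(fdsvel)

sim <- simulate_scanset(make_egfp_like_run(
  1, fds = fds_params(de_dr = 0.25, de_dt = 0.01, delta = 0.15, sigma = 0.02),
  gains = 1, seed = 42))
scans <- thin_scans(sim$scansets$gain1, every_k = 14)  # 30 scans of the run

cfg <- fit_config(s_grid = seq(0.8, 5.2, length.out = 45),
                  meniscus = 6.0, bottom = 7.2, t_acc = 200,
                  ff0 = 1.5, fit_ff0 = TRUE,
                  delta = 0.1, sigma = 0.01,
                  fit_de_dr = TRUE, fit_de_dt = TRUE,
                  fit_delta = TRUE, fit_sigma = TRUE,
                  fit_range = c(6.3, 7.2), grid_points = 500)
fit <- fit_cs(scans, cfg)
print(fit)
```

```
<fit_report> cell 1 gain 1 | rmsd 0.9922 counts (n = 13530)
  s_w = 2.583 S, boundary amplitude = 100.1 counts, f/f0 = 1.392, M_app = 31.47 kDa
  de/dr = 0.2497 /cm, de/dt = 0.01007 /h, delta = 0.1499 cm, sigma = 0.02004 cm
```

Reading the output: the fit rmsd (0.99 counts) matches the injected noise,
so the detector model accounts for the systematic signal structure; the
weighted-average sedimentation coefficient from integrating c(s) is 2.583 S
(truth 2.584); the boundary amplitude is reported in signal units at the
meniscus at the start of centrifugation (truth 100); and all four detector
parameters are recovered within about 1% of their generating values.
Fitting the same data *without* the detector terms degrades the rmsd
severalfold and biases f/f₀ — the practical cost of using conventional
absorbance-era models on FDS data.

Batch workflow from the shell (thin wrappers over the same functions):

```sh
exec/fdsvel simulate --out run1 --seed 7 --de-dr 0.25 --delta 0.15
exec/fdsvel sort --out-dir run1/lists run1/*.fds
exec/fdsvel serial --dir run1 --config fit.yaml --out summary.csv
exec/fdsvel gains --summary summary.csv --out gains.csv
```

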