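---
title: "Direct boundary modeling of fluorescence-detected sedimentation velocity data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Direct boundary modeling of fluorescence-detected sedimentation velocity data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Sedimentation velocity (SV) analytical ultracentrifugation observes the
radial and temporal evolution of macromolecular concentration boundaries
under a strong centrifugal field. The confocal fluorescence detection
system (FDS) extends SV to nanomolar concentrations, but its optics imprint
several systematic signatures on the recorded scans that conventional
sedimentation models (developed for absorbance and interference detection)
do not describe:

* **sloping solution plateaus** -- the scan head travels slightly out of the
  plane of rotation, so the focal depth, and with it the signal
  magnification, changes linearly along a radial scan;
* **temporal intensity drift** -- laser power fluctuations and
  photo-bleaching change the overall signal level by on the order of a
  percent per hour, which is clearly visible against the strict geometric
  radial-dilution law of a sector-shaped cell;
* **a shadow at the cell bottom** -- the sample holder obscures a growing
  fraction of the conical excitation/detection beam within one beam radius
  of the bottom, attenuating the last ~1 mm of the column;
* **finite radial resolution** -- the finite beam cross-section convolves
  the signal radially, visible as smooth transitions at concentration
  steps;
* **optional signal non-linearity** -- inner-filter effects at high
  fluorophore concentration bend the concentration-to-signal response.

`fdsvel` fits FDS-SV data directly with sedimentation boundary models
augmented by parametric forms of all five effects, so that the affected
data can stay in the fit instead of being cut away, and the sedimentation
parameters of interest (sedimentation coefficient distributions, frictional
ratios, apparent molar masses, boundary amplitudes) can be interpreted
quantitatively.

## The signal model

A single ideal species in a sector-shaped cell evolves according to the
Lamm equation; its solution on the column $[m, b]$ (meniscus to bottom) is
$\chi(r, t)$ for loading signal $c_0$. The detector model maps a
concentration field to the recorded signal through three linear transforms
applied in a fixed order, magnification first, convolution last:

$$ s(r,t) = T_C\,\big(T_S\,(T_{rt}\,\chi)\big) $$

* **$T_{rt}$, magnification gradients.** A first-order Taylor expansion of
  the space- and time-dependent magnification,
  $\varepsilon(r,t) = 1 + (d\varepsilon/dr)_0\,(r-m) +
  (d\varepsilon/dt)_0\, t$, multiplies the concentration field. The
  normalization $\varepsilon(m, 0) = 1$ anchors all fitted concentration
  parameters in *signal units at the meniscus at the start of
  centrifugation*; boundary amplitudes from different gains or times are
  therefore directly comparable. We use the additive two-term expansion
  (no $r\!\cdot\!t$ cross term): both gradients are declared first-order
  corrections, and a multiplicative variant would differ only at second
  order. An exponential intensity-decay mode
  $\varepsilon_t(t) = e^{(d\varepsilon/dt)_0 t}$ is available for strongly
  bleaching fluorophores; it agrees with the linear mode to first order.
* **$T_S$, bottom shadow.** The beam is modeled as a uniformly illuminated
  circular cross-section of radius $\delta$ centered at the scan radius; at
  distances $b - r < \delta$ the cell bottom obscures the circular segment
  beyond $b$, and the visible-area fraction $1 - B(r, b, \delta)$
  multiplies the signal. $B$ rises smoothly from 0 at $r = b - \delta$ to
  exactly $1/2$ at $r = b$. For optimizer robustness the segment formula is
  continued symmetrically above the bottom ($B \to 1$ at $r \ge b +
  \delta$), even though fit ranges normally end at $b$. With $\delta = 0$
  the transform is the identity: a zero-width beam casts no shadow.
* **$T_C$, radial convolution.** An empirical Gaussian kernel
  $K(\Delta r) \propto \exp(-(\Delta r/\sigma)^2)$, truncated at
  $|\Delta r| \le n\sigma$ (default $n = 3$) and renormalized to unit sum
  including at the data edges, so constants pass through exactly. Under
  this convention the kernel FWHM is $2\sigma\sqrt{\ln 2} \approx
  1.67\sigma$ (the standard-deviation convention would give
  $2.355\sigma$). Below half the radial spacing the kernel is
  unresolvable and the transform is the identity.

Because all three transforms are linear in $\chi$, they can be imposed on
each Lamm solution of a mixture or distribution *before* the linear
distribution analysis, which leaves the whole c(s) machinery intact.

**Non-linearity.** An inner-filter-type response is modeled as the power
law $a_{obs} = a_0 + c^{\kappa}$. Since this breaks the linearity that the
distribution analysis requires, the data are back-transformed into
concentration-linear units, $c = (a_{obs} - a_0)^{1/\kappa}$, the analysis
runs in that space, and the fitted model is mapped forward again so that
residuals and the reported rmsd live in the raw data space. With
$\kappa = 1$ both directions reduce to a pure baseline offset, no clamping
is applied, and the non-linear code path is exactly identical to the linear
one. For $\kappa \ne 1$, observed values below $a_0$ (possible with noise)
are clamped to zero and counted.

## The Lamm solver

The solver (`solve_lamm()`, compiled core in C++) uses a conservative
finite-volume discretization on a uniform internal grid (default 1000
points) with sector-cell control volumes, exponentially fitted
(Scharfetter--Gummel) face fluxes, and Crank--Nicolson time stepping. The
exponential fitting makes the same scheme robust from diffusion-dominated
to advection-dominated regimes (it reduces to central differencing at low
cell Peclet number and to upwinding at high), and the conservative form
makes total mass conservation hold to rounding error with zero-flux
boundaries at meniscus and bottom. Time substeps are capped by an
advective Courant number of 1; Crank--Nicolson is unconditionally stable,
so the cap serves accuracy, not stability. Sedimentation coefficients are
entered in Svedberg (1 S = $10^{-13}$ s) and converted internally;
$\omega = \text{rpm}\cdot\pi/30$.

Finite rotor acceleration (a linear speed ramp over `t_acc` seconds) is
handled by the standard first-order effective-time treatment: the
constant-speed solution is evaluated at the equivalent time
$\int_0^t \omega(t')^2 dt' / \omega^2$, which equals
$t - \tfrac{2}{3}t_{acc}$ once the ramp is complete.

Solver validation in the test suite: no transport when $s = D = 0$; mass
conservation against a trapezoidal quadrature oracle to better than 0.1%;
plateau decay matching the sector-cell radial dilution law
$e^{-2 s \omega^2 t}$ to 0.5%; grid-halving convergence below 0.1%; and
boundary-midpoint migration matching $\ln(r_{mid}/m) = s\int\omega^2 dt$
in the small-diffusion limit.

## c(s) analysis with systematic noise decomposition

The distribution model is a non-negative linear combination of
detector-transformed Lamm solutions on an s-grid (default 100 linear points
over a user range), all sharing one signal-average frictional ratio
$f/f_0$ that ties each $s$ to a diffusion coefficient via the hydrodynamic
scaling law
$D(s) = \tfrac{\sqrt{2}}{18\pi} kT\, s^{-1/2} (\eta f/f_0)^{-3/2}
\big((1-\bar v \rho)/\bar v\big)^{1/2}$.
Apparent molar masses follow from the Svedberg equation
$M = sRT / D(1 - \bar v \rho)$. Default solution conditions are water at
20 °C with $\bar v = 0.73$ ml/g, so s-values pass through uncorrected for
buffer effects unless conditions are supplied.

Time-invariant (TI, per-radius) and radial-invariant (RI, per-scan) offsets
are eliminated algebraically: both offset families span a linear subspace,
and projecting data and basis onto its orthogonal complement (row/column
centering) yields the exact profile-likelihood solution without explicit
offset parameters. Amplitudes come from a Lawson--Hanson non-negative
least-squares solve of the (optionally Tikhonov-regularized) normal
equations, reduced to the $K \times K$ triangular form first. TI and RI
vectors are recovered from the residual afterwards; the additive degeneracy
between them (a constant can move freely between the two) is resolved by
absorbing the RI mean into TI. The fitted amplitudes are converted to a
distribution density (signal per Svedberg) by trapezoid weights, so that
integrating c(s) returns exactly the total fitted loading signal.

**Regularization.** The penalty is the squared second difference of the
amplitude vector. The weight can be fixed or chosen automatically by the
one-standard-deviation F-ratio criterion (P = 0.68), the convention of the
established c(s) method: the largest smoothing whose rmsd stays within the
F-distributed one-sigma band of the unregularized optimum, found by
bisection on $\log \alpha$. Degenerate normal equations (noise-free data
exactly in the basis span, or extreme optimizer excursions) receive a
progressive ridge floor with a warning.

**Outer refinement.** Any subset of $\{m, b, f/f_0, (d\varepsilon/dr)_0,
(d\varepsilon/dt)_0, \delta, \sigma, \kappa\}$ can be refined by a
derivative-free Nelder--Mead simplex (Brent line search when only one
parameter is free), with box constraints imposed through a logistic
transform; the inner linear subproblem is solved at every evaluation. The
inner problem is non-smooth in $m$ and $b$ through grid alignment, which is
why a simplex rather than a gradient method is used. Meniscus and bottom
move within $\pm 0.05$ cm boxes by default. The radial fit window is fixed
at the initial geometry so the objective stays smooth; Lamm bases are
memoized on $(m, b, f/f_0)$ so fits with fixed geometry build the basis
once. With fewer than 10 scans the temporal drift is weakly identified
(it is disentangled from radial dilution only by multi-scan information)
and a warning is issued.

**Fit-range rule.** FDS data near the meniscus are affected by reflection
and refraction at the air/solution interface, which the model deliberately
does not describe. The default window therefore starts at $m + 2\delta$ --
one detection-cone diameter, as measured from the shadow at the bottom --
and extends to $b$, since the shadow transform makes the bottom region
usable.

## Tunable parameters

| parameter | units | default | meaning |
|---|---|---|---|
| `de_dr` | 1/cm | 0 | radial magnification gradient |
| `de_dt` | 1/h | 0 | temporal intensity drift (linear or exponential mode) |
| `delta` | cm | 0 | beam cross-section radius at the bottom |
| `sigma` | cm | 0 | Gaussian radial convolution width |
| `trunc_n` | -- | 3 | kernel truncation multiple |
| `kappa`, `a0` | --, counts | 1, 0 | power-law response and baseline |
| `ff0` | -- | 1.2 | signal-average frictional ratio |
| `alpha` | -- | 0 | Tikhonov weight, or `"auto"` for the P = 0.68 rule |
| `grid_points` | -- | 1000 | internal Lamm grid |
| `mb_window` | cm | 0.05 | meniscus/bottom search half-width |

## The synthetic-data generator

Because no public FDS raw data sets exist, the package carries its own
forward model as a first-class module, and every fitter test consumes only
its output. `make_egfp_like_run()` encodes the acquisition conditions of a
typical high-speed FDS experiment on enhanced green fluorescent protein:
a 12 mm column (6.0--7.2 cm) in an 8-hole rotor at 50,000 rpm with a 200 s
acceleration ramp, scans every minute through the full sedimentation
process (420 scans; in analysis one thins to the usual 50--100 scans
evenly covering the run), 0.002 cm radial spacing, gains 1/2/4/8, a single
2.584 S species with frictional ratio 1.39 (about 31--34 kDa apparent
mass), a 100-count boundary at gain 1 and additive Gaussian noise of 1
count -- i.e. a signal/noise ratio of 100, typical of mid-range
concentrations. A 14-member geometric dilution series spanning three
orders of magnitude (5.5 nM to 5.56 uM) is provided for concentration
series work. Simulated gains scale the noise-free signal exactly 1:2:4:8
before count-scale noise is added, mirroring amplifier behavior.

The generator applies the full composed detector transform and power-law
response, optional smooth polynomial TI baselines with spikes, per-scan RI
offsets, and additive (optionally signal-proportional) Gaussian noise; a
fixed seed makes runs bit-reproducible, and the noise-free truth is
returned and serialized alongside the scan files.

What the generator deliberately does **not** emulate: photon-counting
statistics and detector dead time, meniscus-region reflection/refraction
optics, focal (z-direction) scans, rotor stretch, and finite scan time.
Passing recovery tests therefore demonstrate correctness of the inverse
problem under the stated signal model, not robustness to every optical
effect of real hardware.

## Parameter recovery and the conventional-analysis contrast

The acceptance suite simulates an EGFP-like run distorted with
`de_dr` = 0.25 /cm, `de_dt` = 1 %/h, `delta` = 0.15 cm, `sigma` = 0.02 cm
and 1% noise, thins it to 30 scans, and refines all four detector
parameters plus the frictional ratio from generic starting values. Each
parameter must come back within 10%, the weighted-average s within 0.5%,
and the fit rmsd within 5% of the injected noise.

The same data are then re-fit *without* the detector terms, in the two
variants a conventional analysis admits. Over the same radial window the
unmodeled bottom shadow dominates and the misfit grows severalfold -- the
motivation for modeling the bottom region at all. Over the conventional
window (bottom shadow excluded, the pre-correction practice) the remaining
magnification-gradient misfit biases the frictional ratio upward, i.e.
toward an overestimated apparent molar mass; partially compensating curved
TI baselines absorb some, but not all, of the sloping plateaus. Both
directions are asserted in the tests.

Problem sizes used in the test suite are chosen as the smallest that keep
each check's physics unambiguous: unit tests run single fits on 14 scans
at 0.005 cm spacing with a 13-point s-grid and the simulator-matched
internal grid; the acceptance recovery fit uses 30 scans at 0.002 cm
spacing, a 45-point s-grid over 0.8--5.2 S and a 500-point internal grid
(solver error well below the 1% noise floor).

## Known limitations

* Single multiplicative shadow factor: whether the bottom shadow
  attenuates excitation, emission, or their product is not resolved; one
  factor represents the combined effect.
* The Gaussian convolution is an empirical stand-in for the true beam
  power-density profile; reported `sigma` values should be read as
  effective widths.
* The exponential drift mode is a simple single-exponential decay.
* Interacting (reaction-coupled) systems, maximum-entropy regularization,
  Bayesian priors and multi-signal global fits are out of scope.
* rmsd for non-linear fits is reported in the raw data space; the
  least-squares objective operates in the linearized space, where data
  errors are slightly distorted. At the high signal/noise ratios where
  non-linearity matters this distortion is negligible.
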