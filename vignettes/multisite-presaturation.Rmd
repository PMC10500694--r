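---
title: "Multisite presaturation: models, methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multisite presaturation: models, methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(presatr)
```

## The problem

Carbon-13 NMR analysis of plant extracts prepared in high-boiling-point
solvents (glycerol, propanediols, butanediols) is complicated by the solvents'
few but enormous resonances: under imperfect broadband decoupling they spawn
artifacts of intensity comparable to the analyte signals. Attenuating the
solvent lines before excitation — presaturation during the relaxation delay —
removes both the lines and their artifacts. Because these solvents show two to
four resonances, the irradiation must act at several frequencies at once, which
a multiple-frequency-shifted laminar shaped pulse provides: a single low-power
pulse whose complex envelope is a sum of phase ramps, one per target site.

`presatr` covers the desk side of this workflow: turning a picked peak list
into a spectrometer-ready shaped pulse, and predicting by simulation how the
pulse train saturates magnetization as a function of resonance offset.

## Magnetization model

The macroscopic magnetization $M = (M_x, M_y, M_z)$ in the rotating frame obeys
the Bloch equations

$$
\begin{aligned}
\dot M_x &= \Omega_0 M_y - \Omega_{1y} M_z - R_2 M_x,\\
\dot M_y &= \Omega_{1x} M_z - \Omega_0 M_x - R_2 M_y,\\
\dot M_z &= \Omega_{1y} M_x - \Omega_{1x} M_y - R_1 (M_z - M_z^{eq}),
\end{aligned}
$$

with resonance offset $\Omega_0$, RF components $(\Omega_{1x}, \Omega_{1y})$,
and relaxation rates $R_1 = 1/T_1$, $R_2 = 1/T_2$. All angular frequencies are
rad/s internally; every public interface speaks Hz and the conversion happens
exactly once per entry point. $M_z^{eq}$ is normalized to 1, so all outputs are
fractions of the equilibrium magnetization.

Under constant on-resonance irradiation the longitudinal component tends to
the stationary value

$$ M_z^{stat} = \frac{M_z^{eq}}{1 + \Omega_1^2 T_1 T_2}, $$

implemented in `stationary_mz()`; its off-resonance generalization
(`cw_offres_steady_state()`, solving the $3\times3$ stationary linear system)
serves as a closed-form oracle for long-irradiation profiles and bandwidths.

### Rotation–relaxation splitting

A shaped pulse is a train of $N$ piecewise-constant slices of duration
$\delta t$. Within one slice, precession plus nutation alone is exactly a
rotation at $\Omega_{eff} = |(\Omega_{1x}, \Omega_{1y}, \Omega_0)|$, and
relaxation alone is an exact exponential map. The propagator alternates the
two: rotation($\delta t$) then relaxation($\delta t$) per slice. This is a
first-order (Lie–Trotter) splitting; subdividing each slice into $2^k$
sub-slices (`propagate_with_refinement()`) halves the error per level and the
difference between consecutive levels is a practical error estimate. The test
suite measures the deviation against `oracle_propagate()`, a
controlled-accuracy `lsoda` integration of the full system, and checks the
halving ratio on randomized pulse trains.

One sign convention deserves a note. The equations above give the torque form
$\dot M = M \times \Omega$ (relaxation apart), which equals
$(-\Omega) \times M$. `rotation_matrix()` is the standard Rodrigues form
$R_{u,\theta} = \cos\theta\, I + (1-\cos\theta)\, u u^\top + \sin\theta\,[u]_\times$,
which propagates $\dot M = \omega \times M$ about $u = \omega/|\omega|$.
`effective_field()` therefore reports the axis as the *negated* unit field
vector, $u = -(\Omega_{1x}, \Omega_{1y}, \Omega_0)/\Omega_{eff}$, with positive
$\theta = \Omega_{eff}\,\delta t$; with this choice an on-resonance field along
$+x$ turns $+z$ toward $+y$, consistent with $\dot M_y = +\Omega_{1x} M_z$, and
the splitting propagator converges to the ODE oracle component by component.
Saturation profiles plot $|M_z|$-symmetric quantities and are invariant to the
overall handedness; the choice matters only for transverse-component
comparisons.

Numerical details, fixed once:

* slices with $\Omega_{eff}\,\delta t < 10^{-15}$ rad apply the identity
  rotation (the axis is undefined at zero effective field);
* the propagation loop over an offset grid is compiled (Rcpp) and strictly
  per-offset, so batched profiles are bit-identical to scalar calls;
* nothing in the core is stochastic; randomized tests own their seeds.

## Waveform synthesis

Given $n$ site offsets $\Omega_k^{sat}$ (relative to the auxiliary carrier),
slice $j$ of the envelope is

$$ \Omega_{1x} + i\,\Omega_{1y}(t_j) \;=\; \frac{\Omega_1}{n}
   \sum_{k=0}^{n-1} \exp\!\left(i\,\Omega_k^{sat}\, j\,\delta t\right),
   \qquad 0 \le j < N, $$

evaluated at the slice start time $j\,\delta t$ (no mid-slice averaging: the
envelope is defined piecewise-constant from the slice-start phase). RF power is
split equally among sites and all phases are zero at $t = 0$, so slice 0 is
always full amplitude along $+x$. Duplicate site offsets are permitted — they
add coherently, doubling the field at that site — but trigger a warning.

The sum is accumulated in symmetric pair order (outermost offset pair first),
an associativity choice that makes the imaginary part cancel *exactly* in
floating point for symmetric site sets $\{\pm f_1, \pm f_2, \dots\}$; such
envelopes are pure amplitude modulations along $x$.

### Carrier bookkeeping

`plan_carrier()` places the auxiliary carrier at the midpoint of the extreme
peak frequencies; site offsets are taken relative to it, and the shaped-pulse
offset is auxiliary carrier minus transmitter. For ppm input the conversion is
`hz = ppm * spectrometer_mhz` with the transmitter given on the same ppm scale.
For glycerol at 150.91 MHz (shifts 63.66 and 73.09 ppm) this yields sites at
±711.5 Hz around a carrier at 68.375 ppm — a 9.43 ppm (1423 Hz) separation.

### Timing

The slice duration is set by a precession-angle rule: the fastest site phase
ramp must advance less than a small threshold per slice, default $\pi/15$ rad,
so `dt = threshold / (2π · max|site offset|)` and the module duration follows
as $T = N\,\delta t$. $N$ defaults to 50000 (sequencer shape memories are the
practical ceiling; larger is better). When all offsets are zero — a single
site, i.e. plain CW presaturation — the rule is degenerate and the module
duration must be imposed via `choose_timing_from_duration()`. The same
override lets one impose a round module duration (say 0.5 s) so that a chosen
relaxation delay is an integer number of modules.

## Saturation profiles and bandwidth

`simulate_profile()` starts a magnetization vector at equilibrium for each
offset of a regular grid, applies the module `n_modules` times, and records the
final $M_z$. The module count must tile the relaxation delay exactly; a
non-integer ratio is an error rather than a silently truncated module, since
acquisition schemes only ever repeat whole modules. Only $M_z$ is recorded:
with the usual two-step phase cycle the detected peak height is proportional
to the longitudinal magnetization present at the end of the presaturation
period, and transverse leftovers are cancelled.

Suppression quality is summarized by two figures:

* `attenuation_percent()` — $100\,(1 - M_z)$ at a site, linearly interpolated
  on the grid. During the oscillatory transient $M_z$ can overshoot slightly
  below zero, so values marginally above 100 % are possible and are reported
  as computed.
* `bandwidth_at_half()` — the width of the offset interval around the site in
  which the signal is reduced by at least 50 %, the standard
  suppression-selectivity metric. Interval edges are located by linear
  interpolation between grid samples (the default 1 Hz grid makes higher-order
  fitting pointless). By default only the contiguous interval nearest the
  requested site counts; the satellite dips of the close-frequency regime are
  excluded. `rule = "union"` instead returns the total measure of all
  intervals reaching the level — both are printed by `cmd_profile()` in
  verbose mode, since reasonable people can disagree about whether detached
  satellites belong to "the" bandwidth.

### The close-frequency (wavy) regime

When two sites lie closer than the single-site suppression bandwidth, the two
phase ramps interfere: the envelope beats at the offset difference, and the
profile develops irregular ripples on the flanks plus a merged central feature
wider than an isolated site's dip at the same per-site RF level. With sites at
±10 Hz, $\Omega_1/2\pi = 50$ Hz, $T_1 = T_2 = 0.5$ s and a 5 s delay, the
simulated profile shows satellite half-reduction dips near ±36 Hz and several
derivative sign changes outside the central region — the regime relevant to
1,2-propanediol, whose two oxygen-bearing carbons sit only 0.06 ppm
(≈ 9 Hz at 150.91 MHz) apart.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `peak_rf_hz` | 11.7 Hz | peak RF amplitude $\Omega_1/2\pi$, shared equally among sites; 11.7 Hz is a practical compromise between suppression depth and band narrowness |
| `n_points` | 50000 | slices per module; tests and examples use 5000 to keep runtimes in seconds at unchanged module durations |
| `threshold_rad` | $\pi/15$ | per-slice phase-advance cap for the fastest ramp |
| `t1_s`, `t2_s` | 0.5 s, 0.5 s | relaxation times of the simulated site; solvent carbons in viscous matrices are not routinely measured, so profiles are illustrative unless you supply measured values |
| `relaxation_delay_s` | 5 s | total presaturation time, tiled by whole modules |
| grid | −50..50 Hz, 1 Hz | profile grid; per-site figures use a local ±50 Hz window around each site, mirroring the experimental practice of stepping the irradiation frequency in 1 Hz steps |

## What the simulations do and do not show

The simulated conditions are idealized: a single isolated spin species per
offset, perfectly homogeneous $B_0$ and $B_1$, complete relaxation between
scans, and exactly the programmed envelope (no amplifier droop, no 16-bit
shape quantization). Real attenuations and bandwidths also depend on the
solvent's actual $T_1$/$T_2$ and on hardware calibration, so quantitative
agreement with any particular spectrometer measurement is not expected; the
simulations reproduce structure (dip positions, interference ripples,
power/width trade-offs), not instrument-specific numbers. Radiation damping,
chemical exchange and coupled-spin dynamics are out of scope.

## Problem sizes in the tests

The test suite and the reproduction script run at $N = 5000$ slices per
0.5 s module (slice duration 0.1 ms), ten modules per 5 s delay, and 201-point
offset grids; convergence checks use 25-slice randomized trains against an
`lsoda` integration at tolerance $10^{-12}$. These sizes keep the full suite
under a few seconds while leaving the slice phase advance far below the
$\pi/15$ cap for every simulated site.
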