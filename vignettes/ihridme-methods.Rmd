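---
title: "Modelling and inverting ih-RIDME decay traces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and inverting ih-RIDME decay traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ihridme)
```

## The experiment and the model

Intermolecular hyperfine RIDME (ih-RIDME) stores electron magnetization
longitudinally for a mixing time `T_mix` while the surrounding proton bath
evolves. Hyperfine couplings to nearby protons make the electron resonance
frequency drift stochastically (longitudinal spectral diffusion, LSD), which
levels the frequency-oscillatory polarization grid imprinted by the pulse
sequence and attenuates the refocused echo. Because the hyperfine shift
distribution is Gaussian with width proportional to the local proton
concentration, the decay of the echo as a function of the dipolar-axis time
τ reports on how many protons surround the label: the experiment is a
proton-concentration meter with a spatial range of a few nanometres.

`ihridme` models the echo amplitude for a single environment of local
proton concentration `C_H` (mol/L) as

\[
V(\tau; T_\mathrm{mix}, C_H)
 = \exp\!\big(-4\,\beta\,C_H^2\,\tau^2\, f(\tau, T_\mathrm{mix}, \sigma)\big),
\qquad
f = 1 - e^{-k_3 \sigma^3 \tau^2 T_\mathrm{mix}},
\qquad
\sigma = \gamma_\sigma C_H .
\]

Three calibrated constants enter ([`kernel_constants()`]):

* `beta = 7.23e-5 (μs·mol/L)⁻²` — the Gaussian decay calibration of the
  homogeneous, fully levelled limit `F(τ) = exp(−4βC_H²τ²)`. The factor 4
  is this package's time-axis convention; with it the 1/e times are exactly
  `1/(2·√β·C_H)`, which reproduces the canonical sensitivity-window
  boundaries: 4.2 μs at 14 M, 8.4 μs at 7 M, 12.8 μs at 4.6 M
  (`sensitivity_windows(c(14, 7, 4.6))`). Those boundaries partition the
  trace into windows with dominant sensitivity to high, medium and low
  concentrations — rough guidance only, since every concentration
  contributes at every time.
* `gamma_sigma = 0.0214 MHz·L/mol` — the proportionality between the
  hyperfine shift width σ and `C_H`. σ and β are treated as independent
  calibrations; neither is derived from the other.
* `k3` (default `0.01 MHz⁻³·μs⁻³`) — the concentration-invariant D/σ³
  normalization of the frequency-diffusion coefficient, `D = k₃σ³`. The
  saturation factor `f` is a Gauss–Markov stand-in, not a first-principles
  correlation function: spectral diffusion must cross one period `1/τ` of
  the polarization grid to level it, which takes a time `∝ 1/(D τ²)`, hence
  the `σ³τ²T_mix` argument. The grid-finesse dependence is essential: a
  saturation depending on `σ³T_mix` alone cannot simultaneously make the
  longest standard mixing time (1920 μs) effectively saturated near the
  printed window thresholds *and* leave a 60 μs reference far from
  saturation at 20–30 M — the two anchors differ by less than a factor of
  ten in `σ³T`, so any monotone function of that product fails one of them.
  With the `τ²` factor both hold, because each concentration matters most
  near its own 1/e time `∝ 1/C_H`. The default value is calibrated so that
  `f > 0.95` at (4.6 M, τ = 12.8 μs, T_mix = 1920 μs) while the 60 μs
  reference stays below ~0.5 saturation at 28.5 M near its decay time;
  `k3` is exposed as a config entry and can be refined from data
  (`global_fit(..., fit_k3 = TRUE)`).

## Reference deconvolution and what dividing really does

A measured set consists of several main traces at different mixing times
plus one reference trace at a short mixing time. Dividing the main traces
by the reference (`reference_deconvolve()`) cancels every multiplicative
instrumental factor that does not depend on `T_mix` — the package's
synthetic generator can inject such an artifact and the division removes it
exactly. Division by near-zero reference values amplifies noise without
bound, so all traces are truncated at the first time the reference falls
below a floor (default 0.05); truncation, not clipping, is the conservative
contract. Main traces are linearly interpolated onto the reference grid
first — the traces are smooth decays, and higher-order schemes risk ringing
near the truncation point.

For a heterogeneous sample the divided trace is **not** a linear functional
of the concentration distribution: with kernels `K_i` (mixing time `T_i`)
and `K_ref`,

\[
V_i(\tau) = \frac{(K_i\,p)(\tau)}{(K_\mathrm{ref}\,p)(\tau)},
\]

a ratio of two integrals over `p`. Environments that decay completely in
both numerator and denominator cancel from the ratio at later times — the
division renormalizes onto the surviving sub-ensemble. Fitting divided
traces with a single linear kernel is therefore systematically biased, and
a naive cross-multiplied linear system is degenerate under noise (mass
placed where the reference model vanishes zeroes the equations trivially).
`global_fit()` fits the ratio model itself.

## The global inversion

`global_fit()` minimizes, over non-negative cell masses `x = p·Δc` and
per-trace amplitudes `a_i`,

\[
\sum_t \big\lVert \Sigma_t^{-1/2}\big(V(t) - a \circ (K x)(t)/(K_\mathrm{ref} x)(t)\big)\big\rVert^2
 + \lambda \lVert L x\rVert^2
 + \mu (\textstyle\sum x - 1)^2
 + \sum_i \frac{(a_i - 1)^2}{2\sigma_i^2}.
\]

The pieces, and why each exists:

* **Error covariance `Σ_t`.** Reference division shapes the noise: the
  per-trace white noise (estimated per trace by local cubic detrending,
  `estimate_noise()`, window 9, order 3) is amplified by `1/r(t)` where the
  reference has decayed, and the *same* reference noise enters all divided
  traces, producing a correlated common mode along the model-value
  direction. Both effects are whitened by a Sherman–Morrison rank-1
  transform per time point. Without the common-mode term the fit chases
  reference noise with spurious structure in `p`.
* **Amplitude nuisances `a_i`.** Each trace is normalized to its own noisy
  first point, so the whole trace carries a coherent scale error with
  variance `≈ 2σ_i²` (one noisy point from the main trace, one from the
  reference). A coherent percent-level scale error across ~140 points is a
  large χ² pull that the shape model would otherwise absorb by distorting
  `p`; the `a_i` are estimated jointly with `x` under their known prior.
* **Curvature penalty.** Second differences of `p` with zero boundary
  conditions (`p` is taken to vanish outside the 0.5–40 mol/L grid), so
  weakly identified mass cannot park for free in the edge cells. The default
  `λ = 10` is set by the penalty scale on the default grid: a smooth
  multi-component density has `‖Lx‖² ~ 1e-5` while grid-scale oscillation
  reaches `~1e-2`, so `λ = 10` prices wiggle at the level of the misfit of
  a typical five-trace set and leaves smooth structure essentially
  unpenalized. `select_lambda()` offers a data-driven alternative (the
  largest λ whose noise-normalized residual stays within 15% of the point
  count); on this problem the residual is nearly flat in λ — the classical
  L-curve has no usable corner — so the fixed, documented default is the
  recommended choice.
* **Unit-mass anchor.** The ratio model is scale-invariant in `x`; the
  anchor removes the flat direction and the result is renormalized exactly
  afterwards.

The optimizer is Gauss–Newton: the ratio model is linearized in `(x, a)`,
each subproblem is solved exactly by active-set non-negative least squares
on the normal equations (a fast NNLS written for this package; it is
cross-checked against an independent solver in the test suite), and steps
are halved until the true objective does not increase. The problem is
smooth and the iteration is deterministic; no randomness enters the fit.

Why a *global* fit: the mixing-time dependence of the whole set is governed
by the single invariant `D/σ³`. Fitting one or two traces leaves `p`
strongly correlated with `k₃` — `degeneracy_diagnostic()` makes this
visible by refitting `p` over a ±50% scan of `k₃` and scoring the convexity
of the objective profile: a full five-trace ladder produces a pronounced
interior minimum, one or two traces a flat or monotonically sliding
profile. The package's trace-count study (in the acceptance suite) shows
the mean absolute recovery error of `p` falling as the number of traces
grows from one to five at fixed total measurement time when `k₃` must be
inferred alongside `p`.

Uncertainty is quantified by residual-resampling bootstrap
(`uncertainty_band()`): per-trace residuals are resampled onto the fitted
model, the fit is repeated with the same λ and k₃, and the pointwise 5th
and 95th percentiles of `p` form the band. Component *positions* are
typically stable; component *widths* — especially of the highest
concentration component — are the least certain quantities, and the band is
the honest way to see that.

## Gaussian decomposition

`fit_mixture()` approximates the fitted curve by `Σ cᵢ·N(μᵢ, σᵢ)` with
`cᵢ ≥ 0`, `Σcᵢ = 1` (softmax parameterization), seeded multi-start
`nlminb`, and a start inherited from the (n−1)-component solution so the
residual never increases with model order. "Width" always means the
Gaussian standard deviation, not the FWHM. Three deliberate choices:

* The least squares are taken in the **cumulative** domain, with the model
  CDF evaluated at cell right edges (where the discrete cumulative mass
  lives). Pointwise wiggle from the regularized inversion integrates out in
  the CDF, and a broad low component carrying a few percent of mass —
  nearly invisible in a density-domain metric — appears as a persistent
  step.
* CDF residuals are **weighted by local mass** plus an equal uniform floor.
  Unweighted CDF fitting lets long empty stretches of the concentration
  axis outvote the populated region; when weakly identified high-`C_H` mass
  smears into a fourth cluster, an unweighted fit can prefer merging the
  two low components over tracking the tail. Mass weighting makes the
  comparison approximately uniform in probability.
* Component widths are capped at a quarter of the grid span: anything
  broader is background, not an interpretable environment class.

The object decomposed is a fitted curve, not sample data, so EM on samples
would be the wrong tool. `compare_mixtures()` matches components of two
decompositions by nearest means and reports signed parameter differences;
`mixture_order_scan()` reports residuals for n = 1…5 — model order itself
is chosen by inspection, not automatically.

## The synthetic generator

`simulate_traceset()` is first-class, tested code: it discretizes a known
Gaussian-mixture truth onto the concentration grid using exact cell masses
(CDF differences, so the discrete cumulative mass matches the mixture CDF
at every cell edge), forward-simulates all traces as mass-weighted kernel
sums, applies an optional shared multiplicative artifact, and adds i.i.d.
Gaussian amplitude noise. All randomness flows from one seed;
the same seed reproduces a set bit-for-bit, and the caller's RNG state is
left untouched.

Defaults emulate the standard acquisition: time axis 0–14 μs in 0.1 μs
steps (covering all three sensitivity windows; the last boundary is
12.8 μs), five mixing times on the geometric ladder 120, 240, 480, 960,
1920 μs (published sets print 240 and 1920 μs plus a 60 μs reference; a
geometric ladder spanning them is the natural five-trace choice), a 60 μs
reference, and noise σ = 0.01 on unit-normalized traces (SNR 100) —
echo-integrated detection noise is amplitude-domain and approximately
white. The concentration grid is 0.5–40 mol/L in 0.25 mol/L steps, wide
enough for all reported mixture components with margin.

What the generator does **not** emulate: ESEEM oscillations, instrument
drift, phase errors, electron–electron dipolar backgrounds, or deviations
of the true LSD correlation function from the Gauss–Markov stand-in.
Passing round-trip tests therefore demonstrates internal consistency of
the pipeline under the declared model, not validity of that model for any
particular spectrometer record.

## Ensemble cross-check

`local_proton_concentration()` counts hydrogens within a solid sphere
(default radius 2.5 nm — read as a solid sphere; a genuine shell would
need an inner radius that is not part of the standard protocol, though an
optional `inner_radius` is provided) around a designated label atom and
converts the count to mol/L via `N_H/(N_A·V)`. Exchangeable hydrogens
(O–H/N–H, identified by their nearest heavy atom within 0.13 nm) are
excluded by default because labile protons are deuterated in a
D₂O/d₆-DMSO matrix; a flag includes them. Structures without explicit
hydrogens are rejected rather than guessing positions. For 394 hydrogens
inside 2.5 nm the conversion gives 10.0 mol/L.
`ensemble_histogram()` pools all (conformer, label site) pairs of a PDB or
XYZ ensemble into a normalized histogram on the concentration grid — the
coordinate-based prediction of `p(C_H)` that the trace-derived distribution
can be compared against. Whether to centre on the nitroxide midpoint or the
attachment atom is not standardized; the package uses the designated site
atom.

## Numerical choices and degenerate inputs

* Root finding for 1/e times: closed form in the levelled-grid limit,
  bisection to 1e-4 μs otherwise.
* `fnnls` tolerance `1e-12·max|A'b|`; near-singular passive sets fall back
  to a ridge-stabilized solve.
* Traces with a zero first point cannot be normalized (error); reference
  traces below the division floor from the start are rejected; mixture
  components narrower than half a grid cell are rejected rather than
  aliased.
* Ties in the multi-start decomposition are broken by the smaller total
  width.
* Problem sizes used in the validation suite: full-resolution round trips
  (141 time points × 5 traces, 159 concentration cells) for the recovery
  studies; coarser grids (57 × 80) for unit tests and the 20-seed
  trace-count study. These are the package's own test-design choices.

## Known limitations

* The saturation function is a declared stand-in for the true LSD
  correlation function; the real kernel may discriminate concentrations
  more (or less) strongly, and `k₃` is a placeholder calibration, not a
  measured constant.
* At SNR 100 with five traces, the split of mass between two overlapping
  low components is information-limited: a direct Fisher-information
  calculation at the three-component reference truth gives
  `sd(μ₂) ≈ 1.2 M` and `sd(c₁) ≈ 0.14` for any unbiased estimator, so
  per-realization component parameters should be read together with the
  bootstrap band, not as point truths. Seed-averaged recoveries are
  accurate to ~0.2 M in the low means and ~0.03 in the low fraction.
* The highest-concentration component's width is essentially undetermined
  by divided traces (the reference division suppresses most of its
  signature); its position and fraction carry meaning, its width does not.
* Real experimental artifacts beyond a shared multiplicative envelope are
  out of scope.
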