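# ihridme

Local proton concentration distributions from ih-RIDME decay traces.

## What this package is for

Intermolecular hyperfine RIDME (ih-RIDME) is a pulse EPR experiment in
which electron magnetization is stored longitudinally for a mixing time
`T_mix` while the surrounding proton spin bath evolves. Spectral diffusion
of the electron frequency — driven by hyperfine couplings to nearby
protons — levels the stored polarization grid and attenuates the echo, the
faster the more protons surround the spin label. A set of decay traces
recorded at several mixing times therefore encodes the *distribution* of
effective local proton concentration, `p(C_H)`, over the label sites of an
ensemble: a nanoscale crowding meter for intrinsically disordered proteins,
polymer aggregates and other heterogeneous macromolecular systems.

`ihridme` is for spectroscopists and modellers who want to turn such trace
sets into quantitative `p(C_H)` and compare the result against atomistic
conformer ensembles. It implements:

* the forward decay model
  `V(τ; T_mix, C_H) = exp(−4β C_H² τ² f)`, with the Gauss–Markov
  saturation factor `f = 1 − exp(−k₃σ³τ²T_mix)`, `σ = γ_σ C_H`
  (defaults: `β = 7.23e-5 (μs·mol/L)⁻²`, `γ_σ = 0.0214 MHz·L/mol`), and
  the sensitivity-window boundaries it implies (1/e times
  `1/(2√β·C_H)`: 4.2, 8.4, 12.8 μs at 14, 7, 4.6 M);
* preprocessing: normalization, reference deconvolution (division by a
  short-`T_mix` reference trace with floor truncation), per-trace noise
  estimation, stretched-exponential fits `exp(−k·(t/μs)^β)`;
* a global model-free inversion of all reference-divided traces at once
  into a non-negative, unit-mass `p(C_H)` on a concentration grid —
  penalized Gauss–Newton with exact NNLS subproblems, generalized least
  squares for the division-induced noise structure, and bootstrap
  uncertainty bands;
* Gaussian-mixture decomposition of the fitted distribution
  (Mean / Width / Fraction tables) and mixture comparison across samples;
* a synthetic-data generator (known mixture truth → noisy trace sets) so
  the entire pipeline is testable without spectrometer data;
* proton counting in conformer ensembles (PDB/XYZ): hydrogens within a
  2.5 nm sphere of a label site → mol/L, pooled into the coordinate-based
  prediction of `p(C_H)`.

A command-line interface (`inst/cli/ihridme.R`) exposes the pipeline as
`simulate | preprocess | fit | decompose | windows | ensemble`
subcommands over plain-text trace files with a YAML manifest.

## Worked example

Simulate a five-trace set from a known three-component truth (mixing times
120–1920 μs, 60 μs reference, SNR 100), then run the full pipeline:

```r
library(ihridme)

sensitivity_windows(c(14, 7, 4.6))
#> [1]  4.200228  8.400455 12.783301

truth <- example_mixture("BBG1")
spec  <- simulation_spec(truth, seed = 17)
set   <- simulate_traceset(spec)
set$main      <- lapply(set$main, normalize_trace)
set$reference <- normalize_trace(set$reference)
divided <- reference_deconvolve(set)

fit <- global_fit(divided)
fit
#> ih-RIDME global fit
#>   lambda = 10
#>   per-trace residual norms: 0.253, 0.253, 0.264, 0.248, 0.228
#> p(C_H) on [0.5, 40] mol/L (step 0.25): mean 9.18 mol/L, mode at 4.5 mol/L

fit_mixture(fit$density, n_components = 3, seed = 1)
#> Gaussian mixture (mol/L):
#>       Mean    Width   Fraction
#>   4.499973 1.529751 0.45168375
#>  11.047922 3.274078 0.48168948
#>  27.105649 1.012427 0.06662677
```

Reading the numbers: the three window boundaries are the times at which the
fully-saturated decay of a 14, 7 and 4.6 M environment reaches 1/e — they
delimit where the traces are most sensitive to high, medium and low
concentrations. The fit's residual norms (~0.25 over 141 points) sit at the
noise floor of the divided traces. The decomposition recovers the
generating components (means 4.35 / 10.35 / 28.5 M, fractions
0.40 / 0.54 / 0.06) to within the resolution the data support at this
signal-to-noise ratio; component widths — especially of the highest
component — are the least determined parameters and should be read together
with `uncertainty_band()`. No experimental trace sets are distributed with
the package; published mixture decompositions serve as *generating truths*
for synthetic round trips, which is what all recovery figures here refer
to.

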