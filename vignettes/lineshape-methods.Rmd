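---
title: "Simulating nitroxide CW-ESR lineshapes from orientational trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating nitroxide CW-ESR lineshapes from orientational trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinESR)
```

## The physical problem

A nitroxide spin label reports on its environment through the shape of its
continuous-wave (CW) ESR spectrum. The electron spin (S = 1/2) is coupled to
the nitrogen nucleus (I = 1 for ^14^N, I = 1/2 for ^15^N) through a hyperfine
tensor **A**, and to the static field through a g-tensor; both tensors are
fixed in the principal axes system (PAS) of the nitroxide ring (x along the
N–O bond, z along the ring normal). As the label reorients — through overall
protein tumbling and internal side-chain dynamics — the laboratory-frame
anisotropic couplings fluctuate, and these fluctuations determine the widths,
amplitudes and asymmetry of the hyperfine lines.

spinESR takes a time series of rotations R(t) mapping the PAS to the
laboratory frame (extracted from atomistic trajectories or produced by the
built-in stochastic generators) and predicts the CW spectrum two ways:

1. **Direct propagation** — numerically exact evolution of the spin density
   matrix through per-frame elementary propagators, followed by emulation of
   field-modulation detection.
2. **Redfield theory** — second-order relaxation theory driven by the
   trajectory's correlation functions, valid when the motional correlation
   time is short compared to the electron coherence lifetime.

Running both on the same trajectory brackets the truth: the direct scheme is
exact but stochastic, the Redfield scheme is deterministic but perturbative.

## The Hamiltonian and the rotating-frame reduction

The full laboratory-frame Hamiltonian contains the isotropic and anisotropic
electron Zeeman terms and the isotropic and anisotropic hyperfine coupling,
with the anisotropic PAS tensors transported to the lab frame by R(t).
`spinHamiltonian(..., frame = "lab")` implements this form verbatim and is
used in the tests (eigenvalue checks, similarity invariance).

Propagating at X band in the lab frame is wasteful and fragile: the 9.45 GHz
carrier phase cannot be tracked robustly over 10^6 picosecond steps. The
engine therefore works in the frame rotating at the isotropic electron
Zeeman frequency. Removing the carrier makes the terms that do not commute
with S~z~ (which are off-resonant by ~9.45 GHz in the lab) rapidly
oscillating, and they are dropped in the standard high-field secular
approximation. What remains is

H(t) = c~g~(t) S~z~ + S~z~ [a~x~(t) I~x~ + a~y~(t) I~y~ + a~z~(t) I~z~],

where c~g~ is the anisotropic-Zeeman frequency shift and (a~x~, a~y~, a~z~)
is the laboratory-z row of the full hyperfine tensor (`secularCoefficients`).
Nuclear Zeeman and ^14^N quadrupole terms are omitted deliberately — the
model keeps exactly the two interactions that dominate nitroxide X-band
lineshapes. Second-order hyperfine shifts (~A²/ω₀ ≈ 0.2 MHz) are the price
of the secular reduction; they are two orders of magnitude below the
linewidths of interest.

Because H(t) is block-diagonal in the electron projection, the elementary
propagators factorise into (2I+1)-dimensional nuclear blocks, and the
detected transverse magnetisation is

FID(τ) = ½ Tr[Γ₋(τ)^† Γ₊(τ)],

with Γ~±~ the ordered products of the block propagators exp(±i F(t) δ/2).
The compiled engine composes these products with a Horner-form Taylor
exponential (order 4 below ‖Hδ‖ ≈ 0.01 rad, order 8 beyond; at the 1 ps MD
step ‖Hδ‖ ≈ 3×10⁻⁴, so the per-step error is ~10⁻²⁰) and monitors the
unitarity of the accumulated propagator; drift stays below 10⁻¹⁰ over 10⁶
steps. The pure-R `engine = "reference"` path evolves the full density
matrix and checks Hermiticity and trace conservation explicitly.

### Ensemble averaging

The trajectory average of the detected FID is taken over start windows
(default stride 1 ns). A single window contributes one random phase path, so
the average converges with the number of *statistically independent*
windows — for fast motion (long FIDs) this requires tens of microseconds of
trajectory. `brownianEnsembleFid` streams a chunked Brownian trajectory
through the engine, and can additionally average over a Fibonacci grid of
global orientations. Because the secular coefficients depend only on the
laboratory z direction, that grid completes the powder average exactly and
multiplies the effective ensemble size at fixed trajectory length.

A practical point that matters when comparing engines: with a finite
trajectory, the sample mean of a~z~ differs from A~iso~ by ~1 MHz-scale
amounts (1.6 σ for 2 µs at τ~c~ = 0.1 ns). Line positions follow the sample
mean, so a direct ensemble and a Redfield model built from *different*
realisations disagree on line frequencies by that wobble, which shows up as
a few-percent pointwise deviation on the line flanks. The engines must be
fed the same orientational statistics — the same trajectory, or matched
means (`correlationFunctions(..., meanCoef = )`, with the ensemble mean
reported in the FID diagnostics).

### Detection emulation and broadening

CW spectrometers record the first derivative of absorption through field
modulation and phase-sensitive detection. `modulatedSpectrum` implements the
transform s(ω) = −Im ∫ FID(τ) J₁(H~m~τ/2) e^{−iωτ} dτ with the peak-to-peak
modulation amplitude H~m~ (default 0.05 mT) converted to rad/s. Angular
frequency maps to field offset via ΔB = −ħΔω/(g~iso~µ~B~), so a positive
A~iso~ puts the m~I~ = −1 line at high field; g-dispersion across the 12 mT
sweep (~0.1%) is neglected. No apodization is applied by default — a
truncation warning is raised instead, so lineshapes stay unbiased.

Two extra broadening mechanisms are modelled after air-equilibrated aqueous
samples: a Lorentzian from collisions with dissolved O₂, applied as
exp(−τ/T₂^O2^) with default T₂^O2^ = 0.83 µs (equivalent to a 13.5 µT
full-width Lorentzian), and a Gaussian of 126 µT FWHH from field
inhomogeneity and unresolved ^1^H/^13^C couplings, applied by convolution on
the field axis. Both defaults are collective-fit values for the free label
and are plain parameters of `broadeningModel()`.

## Redfield engine

The fluctuating part of the secular Hamiltonian is S~z~ ⊗ δF(t) with
δF = δc~g~·1 + δa~x~I~x~ + δa~y~I~y~ + δa~z~I~z~. Because δH commutes with
S~z~, relaxation cannot mix electron coherence orders: the Redfield "kite"
of this system is exactly block-diagonal by electron coherence order, and
the spectrum is governed by the electron single-quantum block of dimension
(2I+1)². On that block the master equation reads

dX/dt = −i(H̄X + XH̄) − ¼ Σ~pq~ ∫₀^∞ C~pq~(τ) [B~p~B̃~q~X + B̃~q~XB~p~ +
B~p~XB̃~q~ + XB̃~q~B~p~] dτ,

with H̄ the motionally averaged F̄/2 and the tilded operators carrying the
interaction-frame phases of the two electron manifolds. All four dissipator
terms enter with the *same* sign — a consequence of the ±½ electron factors
on the two sides of the coherence — which the test suite pins down against
two exactly solvable limits (pure a~z~ dephasing and a commuting a~x~-only
model). The time integrals reduce to one-sided spectral densities J~pq~(ω)
evaluated at the nuclear eigenfrequency differences; no secular truncation
is applied within the block (the full non-Hermitian Liouvillian is
diagonalised, which handles near-degeneracies exactly). Imaginary parts of
J (dynamic frequency shifts) are kept by default and can be switched off.

Correlation functions are estimated with lag-dependent normalisation by FFT,
symmetrised, and extrapolated beyond the sampled lag range with a fitted
exponential tail before transforming. The g × A *cross-correlations* are
the J~1q~ entries; `includeCrossCorrelations = FALSE` zeroes them, which
renders the ^15^N doublet symmetric — the TROSY-like interference between
the anisotropic Zeeman and hyperfine relaxation pathways is exactly what
makes one doublet component sharp and tall and the other broad and short.

`validityReport` quantifies the Redfield validity condition τ~c~ ≪ T~2e~.
T~2e~ is reported both as the slowest detectable eigenmode decay time (used
for the verdict) and as the 1/e time of the predicted FID envelope; the
tiers are valid (ratio < 0.05), marginal (< 0.2) and invalid. Typical
solvent-exposed-label conditions (τ~c~ ≈ 1 ns) are comfortably valid;
tumbling-dominated buried labels (τ~c~ ≈ 3 ns) are marginal, and the
direct–Redfield deviation grows accordingly.

## Synthetic motion models

The generators emulate the motional regimes of spin-labeled globular
proteins and serve as the ground-truth source for every test:

* `isotropic_diffusion` / `axial_diffusion` — Brownian rotational diffusion
  composed from per-step Gaussian axis-angle increments in the molecular
  frame (variance 2Dδ per axis). Default tumbling time 3.35 ns and axial
  anisotropy D~∥~/D~⊥~ ≈ 1.4 mirror a small globular protein at room
  temperature. The Gaussian-increment scheme is valid for δ ≪ 1/D; the
  constructor enforces 6Dδ < 0.01.
* `cone_diffusion` — wobble of the body z axis inside a cone (Metropolis
  rejection at the boundary, uniform equilibrium inside), the standard
  minimal model of restricted internal label motion. The P₂ plateau equals
  S² with S = cosβ(1+cosβ)/2.
* `discrete_jump` — continuous-time Markov chain over discrete orientations
  (rotamer jumps; nanosecond lifetimes for χ₁/χ₂-like dynamics).
* `multistate_exchange` — slow Markov switching between sub-models,
  emulating microsecond-lifetime environment states (e.g. a solvent-exposed
  and a surface-immobilised state).

All generators are exactly reproducible from (seed, parameters); seeds are
recorded in file headers and CLI manifests. What these models deliberately
do *not* capture: correlated multi-torsion jumps, the self-compensating
linker geometry of the real R1 side chain, and transient specific contacts.
Passing tests therefore validate the spin-dynamics machinery and the
statistical estimators, not the fidelity of any particular motional model to
a real protein.

## Tumbling rescaling

`rescaleTumbling` implements the pseudo-trajectory construction that changes
the tumbling rate while leaving internal dynamics untouched: elementary
global rotations e~k~ = Q(t~k~)⁻¹∘Q(t~k+1~) are expressed in the molecular
frame, converted to axis–angle, scaled by λ, and re-accumulated from
Q′(0) = Q(0). Working in the molecular frame is what preserves the tumbling
anisotropy (the distribution of rotation axes in the body frame is
untouched). Since per-step angles scale by λ, the rotational diffusion
tensor scales by λ² and the correlation time by λ⁻²; λ = 0.5 slows tumbling
four-fold. Re-accumulation is anchored at the first frame; with λ = 1 the
round trip is stable to < 10⁻⁹ per frame over 10⁶ steps.

τ~rot~ is estimated from the average P₂ autocorrelation of the three
molecular axes, fitted with a single exponential over lags [0, 5τ̂] with
log-linear initialisation (the 1/e crossing). The S² plateau estimator is
the mean of C(τ) over the final 10% of the computed lag range.

## Lineshape fitting

The Voigt machinery evaluates the profile through the Faddeeva function
(complex error function near the origin, Laplace continued fraction beyond
|z| = 6 where the naive expression degenerates to 0·∞) with the first
derivative computed analytically — finite differences are too unstable for
the narrow-line fits. Per-line fits follow the published windowing rule
literally: the window runs from the leftmost point at 80% of the line
maximum to the rightmost point at 80% of the line minimum, selected on the
raw data, and the least-squares fit (unweighted; no noise model is imposed)
runs over that window only. Peak-to-peak widths Δ~(i)~ and amplitudes
h~(i)~ are measured on the *best-fit function*, not on raw samples. Line
windows are seeded at the first-order resonance offsets (0, ±A~iso~ in
field units) and refined by the fit.

`collectiveVoigtFit` reproduces the air/degassed analysis: both spectra
share the Gaussian width G, line centers and per-line Lorentzians L~(i)~;
the air-equilibrated lines carry L~(i)~ + L~O2~. The oxygen Lorentzian
converts to the electron T₂ via T₂ = h/(g~iso~µ~B~πΔB), the relation behind
the 13.5 µT ↔ 0.83 µs equivalence.

## Numerical choices and degenerate inputs

* Rotations are unit quaternions (scalar-first), composed right-to-left;
  sequences are sign-aligned on construction. Accumulation renormalises
  every 1024 steps.
* PAS extraction orthogonalises the ring normal against the N–O axis and
  keeps its sign continuous across frames; colinear ring atoms raise an
  error naming the frame.
* Least-squares superposition uses the SVD solution with a determinant
  guard against reflections; fewer than three non-colinear fit atoms is an
  error.
* Correlation estimators use every start frame (stride 1) with
  lag-dependent normalisation; no zero-padding bias.
* A defective (ill-conditioned) Liouvillian eigenbasis triggers a warning
  and, for spectra, amplitudes should then be treated with caution; the
  situation does not arise for physical nitroxide parameters.
* Static (non-decaying) trajectories: `estimateTauRot` raises an error,
  `correlationFunctions` flags `decays = FALSE`, and `buildRedfield`
  refuses the input.

## Problem sizes used in the shipped tests

The test and acceptance workloads were chosen as the smallest sizes at which
the statistical estimators are comfortably inside their tolerances: the
λ-rescaling check uses a 1 µs trajectory at τ~rot~ = 3 ns (±15% sampling
tolerance on the recovered ratio); the engine cross-validation uses 6 µs of
τ~c~ = 0.1 ns motion with a 16-point orientation grid and non-overlapping
windows (≈ 320 independent FID realisations, direct-ensemble noise near 1%);
rigid-limit comparisons use a 256-orientation Fibonacci grid. These
are study conditions of the validation suite, not limits of the
implementation.

## Known limitations

* The secular (high-field) reduction drops second-order hyperfine shifts;
  W-band or very large hyperfine systems would need the lab-frame path.
* No stochastic-Liouville solver: in the slow-motion regime (τ~c~ ≳ T~2e~)
  only the direct engine is trustworthy, at the cost of long trajectories.
* Saturation, passage effects, electron–electron couplings (DEER) and
  minor-isotopologue satellites are out of scope.
* Multicomponent (slow-exchange) spectra are simulated faithfully by the
  direct engine but the fitting layer models single-population lines only.
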