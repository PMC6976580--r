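# spinESR

Predicting continuous-wave ESR spectra of nitroxide spin labels from
orientational trajectories.

Site-directed spin labeling attaches a nitroxide radical (the R1 side
chain) to a protein; the shape of its CW ESR spectrum encodes how the
label reorients — overall protein tumbling, side-chain rotamer jumps,
steric confinement. spinESR closes the loop between motional models and
spectra for people who run molecular-dynamics or stochastic simulations of
spin-labeled proteins: given a time series of rotations R(t) that map the
nitroxide principal axes system into the laboratory frame, it predicts the
X-band spectrum by two independent routes and provides the analysis tools
around them.

**The spin dynamics.** The electron–nuclear Hamiltonian

H(t) = ω₀S_z + (µ_B/ħ) **S**·(R(t) g_aniso R(t)⁻¹)·**B₀** + A_iso **S**·**I**
+ **S**·(R(t) A_aniso R(t)⁻¹)·**I**

is propagated exactly through per-frame elementary propagators
U_k = exp(iH(t_k)δ) (δ = 1 ps), the free induction decay
FID(τ) = Tr{S₊σ(τ)} is averaged over trajectory windows, and
field-modulation detection is emulated via
s(ω) = −Im ∫ FID(τ)·J₁(H_mτ/2)·e^{−iωτ}dτ. Alternatively, a Redfield
relaxation supermatrix is assembled from the trajectory's rank-2
correlation functions — including the g×A cross-correlations that make
¹⁵N doublets asymmetric (the ESR analogue of TROSY) — and solved by
diagonalisation. Supporting machinery: molecular-frame rescaling of the
tumbling rate (λ-scaling of elementary rotations; τ_rot scales as λ⁻²),
seeded Brownian/cone/jump/multistate motion generators, P₂ and dihedral
correlation analysis, and first-derivative Voigt fitting with the
peak-to-peak descriptors Δ₍ᵢ₎ and h₍₀₎/h₍₋₁₎.

## Worked example

Slow the tumbling of a Brownian trajectory four-fold and watch the
correlation time respond:

```r
library(spinESR)

traj <- brownianRotation(1e6, tauRotNs = 3, deltaPs = 1, seed = 1)
estimateTauRot(traj, maxLagPs = 3e4)$tauRotNs
#> [1] 2.957326

ident <- orientationTrajectory(
  matrix(rep(c(1, 0, 0, 0), 1e6), ncol = 4, byrow = TRUE), 1)
slowed <- rescaleTumbling(composeTrajectory(traj, ident), lambda = 0.5)
estimateTauRot(globalPart(slowed), maxLagPs = 1.2e5)$tauRotNs
#> [1] 12.63735
```

The recovered 2.96 ns matches the 3 ns generator setting within sampling
error, and λ = 0.5 multiplies it by 4.27 ≈ λ⁻² = 4. Simulating and
characterising a fast-motion spectrum:

```r
ss  <- spinSystem("14N")          # typical nitroxide g and A tensors
fc  <- fieldConfig(gIso = gIso(ss))  # X band, 9.45 GHz
tr  <- brownianRotation(8e5, tauRotNs = 0.5, seed = 68)
sp  <- simulateRedfield(tr, ss, fc)  # first-derivative, 0.05 mT modulation
d   <- spectrumDescriptors(sp, ss)
round(d$deltaUt, 1)     # peak-to-peak widths, uT (mI = +1, 0, -1)
#> [1] 154.8 140.9 198.7
round(d$ratioH0Hm1, 2)  # central / high-field amplitude ratio
#> [1] 2.78
```

The central line is narrowest and tallest (h₍₀₎/h₍₋₁₎ > 1) and the
high-field (mI = −1) line broadest — the classic motional-narrowing
signature. The oxygen-broadening bookkeeping behind the default
`broadeningModel()`:

```r
lorentzianWidthToT2(13.5, gIso = 2.0059)  # uT -> us
#> [1] 0.8382977
```

A thin CLI (`inst/scripts/spinesr`) exposes the same functionality as
subcommands (`synth-traj`, `rescale`, `simulate-direct`,
`simulate-redfield`, `analyze`, `fit`, `descriptors`), each writing a JSON
manifest with seeds and package version for bit-reproducible reruns.

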