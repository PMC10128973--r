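---
title: "Counting with a spin network: model, decoder and virtual psychophysics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting with a spin network: model, decoder and virtual psychophysics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(numspin)
```

## The question

Animals — humans included — estimate the number of items or events in a
scene quickly, without counting, and with an uncertainty that grows in
proportion to the number itself (Weber's law). Simple accumulator models
fail this last property: event counts are Poisson-like, so their standard
deviation grows as the square root of the count, not linearly.
`numspin` implements a deliberately minimal alternative: a small,
fully-connected network of two-state units whose *collective dynamics*,
not a learned read-out, encode the number of transient inputs the system
has received. The mathematics is that of an open quantum spin-1/2
network; no claim is made (or needed) that any biological substrate is
quantum — the formalism is used as a statistical toolbox for
nonlinear network dynamics.

## Model

Each unit is a spin 1/2: down is rest, up is active. With ħ = 1,
energies in units of the exchange amplitude J and times in 1/J, the
Hamiltonian over `M` sites is

$$H = \sum_{i<j} J\,A_{ij}\,(\sigma^+_i \sigma^-_j + \mathrm{h.c.})
    + \sum_{i<j} \Delta_{ij}\, \sigma^z_i \sigma^z_j ,
\qquad
\Delta_{ij} = \Delta_0\, e^{-(i-j)^2 / 2\sigma^2},$$

where `A` is the 0/1 adjacency matrix (`nearest_neighbour` open chain,
`all_to_all`, or custom) and the Gaussian profile plays the role of a
built-in interaction neighbourhood of width `sigma_int` (in lattice
sites) acting on *all* pairs, linked or not. The exchange sum runs over
unordered pairs — the Hermitian conjugate is explicit — and the
$i = j$ interaction terms are dropped, being a constant shift
($\sigma_z^2 = I$). Two dissipation channels per site couple the system
to an environment: excitation loss $\sigma^-_m$ at rate `gamma_loss`
and dephasing $\sigma^z_m$ at rate `gamma_dephase`, entering the GKSL
(Lindblad) master equation

$$\dot\rho = -i[H, \rho] - \tfrac{1}{2}\sum_m \gamma_m
  \left(J_m^\dagger J_m \rho + \rho J_m^\dagger J_m
        - 2 J_m \rho J_m^\dagger\right).$$

Stimuli are instantaneous single-site rotations
$\exp(-i \theta \sigma^x / 2)$ at scheduled times: a $\pi$ rotation
flips a resting unit fully on, smaller angles create partial
activations. The rotation axis is a convention — any axis in the
xy-plane yields the same $\sigma^z$ observables up to phases — and is
fixed to x.

Key behaviours the package reproduces and tests:

* a chain spreads a single excitation in a light cone with revivals at
  the boundaries, while the all-to-all network sloshes it coherently
  between the flipped site and the rest at angular frequency
  $J\,M$ (the one-excitation spectral gap between the symmetric mode at
  $J(M{-}1)$ and the $(M{-}1)$-fold level at $-J$);
* each additional flip populates a new magnetization sector and adds
  one dominant peak, at a constant spacing, to the all-to-all
  magnetization spectrum — the number of low-frequency peaks *is* the
  numerosity code;
* the spin-flip symmetry of the model at $\Delta_0 = 0$ makes $N$ and
  $M - N$ excitations spectrally identical, capping decodable
  numerosity at $M/2$.

## Simulation machinery

**Quantum trajectories.** Dissipative dynamics are simulated by the
standard Monte-Carlo wave-function unraveling: between jumps the pure
state evolves under the non-Hermitian generator
$H - \tfrac{i}{2}\sum_m \gamma_m J_m^\dagger J_m$ (whose decay part is
diagonal in the computational basis here), a jump fires when the
squared norm crosses a uniform random threshold (waiting-time
algorithm; the crossing time is located by bisection), and the channel
is drawn with probability $\propto \gamma_m \|J_m \psi\|^2$. Averages
over trajectories reproduce the master equation; this is asserted
against an independent density-matrix integrator (`evolve_master`,
dense, capped at M = 8) written with separate numerics (pure-R Arnoldi
plus a complex Padé matrix exponential), so the two routes share no
code.

**Propagation.** Between events the propagator
$e^{-i (H - iD/2) \tau}$ is applied by Krylov subspace methods
(compiled; symmetric Lanczos when $D = 0$, Arnoldi otherwise) with an
a-posteriori error estimate and adaptive substepping. For closed
dynamics at dimension ≤ 2048 the package instead caches a dense
eigendecomposition of `H` once per network and maps whole recording
windows back to the site basis with BLAS-3 products — bit-identical
physics, roughly 30× faster for the psychophysics ensembles, and the
two paths are asserted equal in the tests. Deterministic π-flip
protocols exploit magnetization-sector block structure
(`sector_record`, dimension $\binom{M}{N}$), which is what makes
M = 18 tractable; the sector path is asserted against the full
2^M propagator.

**Reproducibility.** All randomness (event times, sites, angles, jump
thresholds, tie-breaks) flows through R's RNG; one master seed derives
every per-trajectory seed, and records, libraries and configs
round-trip through CSV/JSON with provenance sidecars.

## The estimation pipeline

1. **Record** the local magnetization $\langle\sigma^z_i\rangle(t)$ on
   every site in a fixed window after all stimuli (default
   $10 \le tJ \le 20$, stimuli in $[0, 10]$).
2. **Spectrum.** Magnitude of the DFT of the mean-subtracted signal,
   positive frequencies only; rectangular window, no taper or padding
   (the decoder's correlation is offset-invariant, so the dialect only
   needs to be fixed, not optimal). Frequencies are angular, units of
   J; amplitudes `Mod(fft(x))/n`, checked by a Parseval identity.
3. **Space average** the per-site amplitude spectra (magnitudes, not
   complex transforms — phases are random across realizations and
   would cancel; the same cancellation is why the *time-domain*
   trajectory average carries no information, which the tests assert).
4. **Templates.** For each numerosity N, average the space-averaged
   spectra of `n_traj` independent stimulus realizations
   (`build_template_library`). Production libraries use order $10^2$
   trajectories; the convergence experiment shows a handful suffices.
5. **Decode** a fresh probe by Pearson correlation against every
   template, picking the argmax (`decode_numerosity`). All
   correlations are accepted — no rejection threshold; exact ties
   (within 1e-12) break uniformly at random. Raw amplitudes are
   correlated (not log), and Pearson's affine invariance means the
   decoder cannot exploit overall signal energy — the point of the
   constant-energy control.
6. **Psychophysics.** A virtual 2AFC experiment (`run_2afc`): per
   trial, one probe at the reference and one at the variable
   numerosity are decoded, the variable is "judged more numerous" iff
   its decode is larger (fair coin on equal decodes, keeping outcomes
   Bernoulli). The proportions are fitted with a Probit —
   $F(N) = \Phi((N - \bar N)/\sigma)$, maximum-likelihood probit
   regression, no lapse parameters — giving the point of subjective
   equality $\bar N$ and width $\sigma$; Weber's law predicts
   $\sigma/N_\mathrm{ref}$ flat in the reference.

## Stimulus protocols

`protocol_spec` draws N events with times i.i.d. uniform on the
stimulus window (sorted), sites uniform on 1..M (with replacement by
default), and angles per mode: `fixed_pi`, `random_rotation` (RR,
uniform on $(0, \pi]$ — the source describes only "random
amplitudes", so the distribution is an explicit knob) or
`constant_energy` (CE: random angles constrained to an exact total,
drawn uniformly on the scaled simplex with rejection until every angle
is ≤ π; at the feasibility boundary total = Nπ the unique solution,
all π, is returned directly). The CE control removes total input
energy as a cue; the per-event cap (0, π] makes a total of 3π feasible
only for N ≥ 3, so the scaled M = 10 experiments use a constant total
of π, which keeps every level N ≥ 1 feasible and preserves the
control's logic. The deterministic demonstration protocol
(`demo_event_sequence`) flips sites 1, 3, 5 at evenly spaced times
from the start of the stimulus window; the source fixes the sites but
not the times, and the relative amplitude (not the position) of the
oldest peak depends on that choice.

## Numerical and design choices

* **Recording step.** Default `dt = 0.02` (Nyquist ≈ 157 J); the
  packaged experiments use 0.05 (M = 10) and 0.1 (M = 18 sector
  check), both comfortably above the largest signal frequencies
  (collective gaps ≈ 2(s+1) ≤ M + 2). Windows are half-open
  `[ta, tb)` so grid and FFT bins match exactly.
* **Peak counting** (`count_dominant_peaks`): local maxima above a
  relative threshold (default 0.2 of the global maximum — the
  "dominant peak" notion is inherently a threshold choice, so it is a
  parameter), merged when closer than one frequency bin.
* **Experiment sizes.** The packaged acceptance-scale experiments use
  M = 10, levels 1..5, references 2..4, 300 2AFC trials per level,
  RR template counts 3/5/10/40 against a 200-trajectory reference,
  2000 trajectories for the unraveling check (recorded at unit time
  steps), and 100 probit-recovery replicates. Probe spectra are drawn
  once per (level, trial) into a bank and reused across reference
  levels and template-library sizes: simulation dominates cost while
  decoding is free, reuse leaves marginal trial outcomes unbiased, and
  it makes the template-count comparison paired.
* **Degenerate inputs.** Zero-variance spectra are flagged and ranked
  as −∞ (a probe that is all zeros cannot be decoded and errors);
  degenerate psychometric data (all 0/1, or step data causing complete
  separation) are flagged non-convergent with σ pinned at a floor
  rather than silently fitted.

## What the synthetic data do and do not show

The generator realizes exactly the study conditions: seeded random
event sequences on an idealized homogeneous network, no measurement
noise, no parameter heterogeneity, stationarity across trials. Real
neural recordings would add 1/f-like background, heterogeneous
connectivity and drift — the classical grating experiments probe the
first of these (the decoder classifies sinusoidal activation maps
perfectly when clean, and degrades mostly at low frequencies under 1/f
noise, showing the error structure is the signal's, not the
decoder's), but passing tests here demonstrate properties of the
model, not of any biological system.

## Known limitations

* Full-space simulation is exponential in M (guarded at 2^14 by
  default); only deterministic π-flip protocols benefit from the
  sector fast path, so random-rotation experiments at M = 18 with
  hundreds of trajectories are an overnight batch, not a test-suite
  job — the packaged experiments scale to M = 10, which reproduces
  every qualitative effect.
* The master-equation oracle is dense and capped at M = 8.
* The sector fast path covers closed dynamics only; dissipative runs
  always use the full-space trajectory machinery.
* Weber-fraction estimates carry Monte-Carlo error even at 300
  trials/level; the acceptance checks use ratio bounds (flat within a
  factor of 2) rather than point targets for that reason.
* Scaling the psychophysics down to M = 10 truncates the numerosity
  axis at floor(M/2) = 5. With only three reference levels and no
  variable levels above 5, the reference-4 psychometric curve is
  compressed from above, and the decoder's confusion floor (adjacent
  templates grow more correlated with N) contributes a
  reference-independent component to σ. The acceptance experiment
  therefore measures how much of the Weber signature survives at this
  size rather than guaranteeing the full-size behaviour; the
  full-scale M = 18, N = 1..9 experiment is a batch job outside the
  test suite.
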