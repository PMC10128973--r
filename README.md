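# numspin

Simulation and ideal-observer decoding of *numerosity* — the number of
transient stimulation events — in small spin-1/2 networks, for
computational-neuroscience researchers interested in minimal,
training-free models of number sense and in whether such models obey
Weber's law (discrimination uncertainty growing in proportion to the
number itself, the hallmark that plain accumulator/Poisson models miss).

Each network unit is a two-state spin (down = rest, up = active). With
ħ = 1 and energies in units of the exchange amplitude J, the network
Hamiltonian is the XXZ-type model

    H = Σ_{i<j} J A_ij (σ⁺_i σ⁻_j + h.c.) + Σ_{i<j} Δ_ij σᶻ_i σᶻ_j,
    Δ_ij = Δ₀ exp[−(i−j)² / 2σ²],

with A the adjacency matrix (open chain or all-to-all) and a Gaussian
interaction profile of width σ sites. Per-site loss (σ⁻, rate γ_l) and
dephasing (σᶻ, rate γ_d) channels enter a GKSL/Lindblad master equation,
simulated by quantum-trajectory (Monte-Carlo wave function) unraveling
with Krylov propagation; an independent density-matrix integrator serves
as the correctness oracle at small sizes.

Stimuli are instantaneous single-site rotations exp(−iθσˣ/2) at random
(or fixed) times, sites and angles. The pipeline records per-site
magnetization ⟨σᶻ_i⟩(t) in a window after stimulation, Fourier-transforms
it, averages amplitude spectra over sites and stimulus realizations into
per-numerosity templates, and classifies fresh probes by Pearson
correlation against the template library (an ideal observer with no
rejection threshold). A virtual two-alternative forced-choice experiment
with Probit fits, F(N) = Φ((N − N̄)/σ), then measures the psychometric
width σ and the Weber fraction σ/N_ref per reference numerosity.

## Worked example

A single full flip in an all-to-all network oscillates at the collective
gap J·M — the lowest-level "clock" of the numerosity code:

```r
library(numspin)
oscillation_frequency_check(sizes = c(5, 7, 9))
#>   n_sites peak_freq expected bin_width
#> 1       5  5.026548        5 0.6283185
#> 2       7  6.911504        7 0.6283185
#> 3       9  8.796459        9 0.6283185
```

The FFT peak of the flipped site's magnetization lands within one
frequency bin (2π/10 ≈ 0.63 rad, from the 10/J recording window) of the
predicted angular frequency J·M for every size.

Each additional flip adds one equally spaced dominant peak — the
spectrum literally counts the events:

```r
staggered_peak_experiment()
#>   n_flips n_peaks spacing_range
#> 1       1       1            NA
#> 2       2       2            NA
#> 3       3       3  8.881784e-16
```

Three staggered π flips (sites 1, 3, 5 at fixed times, M = 7,
Δ₀ = 0.1, σ = 1/√2) produce exactly 3 dominant peaks whose adjacent
spacings agree to machine precision; `spacing_range` is the spread
(max − min) of those gaps.

A full psychophysics run on a 10-spin network — templates, probe
decoding, 2AFC comparisons at reference numerosities 2–4, Probit fits —
is one call, `weber_experiment()`; its output includes the fitted σ per
reference, the Weber fractions for the random-rotation and
constant-energy protocols, and the template-count convergence table.

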