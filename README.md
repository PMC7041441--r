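# photonfret

Photon budgets and precision bounds for FRET imaging.

## The problem

Förster resonance energy transfer (FRET) imaging infers a biochemical
quantity — the transfer efficiency *E*, or the apparent efficiencies
*f<sub>D</sub>E* / *f<sub>A</sub>E* when only a fraction of fluorophores
interact — from photon counts that carry at least Poisson noise.  Anyone
designing a FRET experiment (choice of modality, fluorophore pair,
exposure, laser power) implicitly trades precision against photon budget,
photodamage and acquisition time.  photonfret makes that trade-off
explicit for the two dominant quantitative modalities:

* **three-cube sensitized-emission FRET (seFRET)** — donor-excitation
  donor and acceptor channels plus an acceptor-excitation acceptor
  channel, unmixed with the crosstalk corrections
  `cFRET = I^DA − DER·I^DD − AER·I^AA`,
  `dFRET = η·cFRET / (I^DD + η·cFRET)`,
  `aFRET = ε·cFRET / I^AA`;
* **donor-lifetime imaging by TCSPC** — the binned periodic donor decay,
  a double exponential with quenched lifetime τ₀(1−E).

## The statistic at the core

Every precision result is expressed as the photon-normalized standard
deviation σ̃, defined by

    sd(estimate) = σ̃ · N_P^(−1/2)

with N_P the detected photon count.  σ̃ is exposure-invariant and is
computed three ways, which must (and do) agree:

* first-order error propagation through the unmixing map,
  Var = Σ_c (∂φ/∂I_c)²·μ_c (`delta_sigma()`);
* the Cramér-Rao lower bound from the Fisher information matrix
  J_ij = Σ_c μ_c⁻¹ (∂μ_c/∂θ_i)(∂μ_c/∂θ_j) of the three-channel Poisson
  model (`fisher_crlb()`) — identical to the former without background,
  because the plug-in unmix estimator is the exact MLE;
* Poisson Monte-Carlo simulation (`simulate_counts()`,
  `empirical_sigma()`, `validate_montecarlo()`).

For TCSPC, `tcspc_crlb_sigma()` evaluates the multinomial Fisher
information of the binned decay numerically, with unknown efficiency and
fraction (optionally an unknown background level), a Dirac/Gaussian/file
IRF, and normalization by donor signal photons.  The photon budget for a
target standard deviation σ is `N_D = σ̃²/σ²` (`photon_budget()`).

## Worked example

A cell where half the donors interact with acceptors at E = 50%
(f_D = 0.5, f_A = 1), imaged by three-cube seFRET:

```r
library(photonfret)
pop <- population_from_fractions(efficiency = 0.5, f_d = 0.5, f_a = 1)

delta_sigma(pop, fret_system(), which = "dfret", decompose = TRUE)
#> sigma_result (dfret, delta): sigma_tilde = 0.53033  [N_P = 300]
#>   components: sigma_E = 0.53033, sigma_SBT = 0, sigma_B = 0

delta_sigma(pop, fret_system_preset("confocal"), which = "dfret",
            decompose = TRUE)
#> sigma_result (dfret, delta): sigma_tilde = 3.56984  [N_P = 2247.62]
#>   components: sigma_E = 0.935209, sigma_SBT = 3.44516, sigma_B = 0
```

Reading: on an ideal (crosstalk-free) instrument, dFRET estimates
f_D·E = 0.25 with σ̃ = 0.53 — `photon_budget(0.53, 0.05)` says **113
photons** suffice for ±0.05 precision.  On a real confocal CFP–YFP
system (bleed-through DER = 0.42, direct excitation AER = 0.60), σ̃
rises to 3.57, almost entirely through the bleed-through term of the
decomposition, and the same precision costs
`photon_budget(3.57, 0.05)` ≈ **5,098 photons** — a 45-fold penalty paid
for crosstalk correction.

The TCSPC counterpart for the same population (τ₀ = 3 ns donor, 80 MHz,
256 bins, Dirac IRF, unknown fraction and quenched lifetime):

```r
m <- tcspc_model(tau0_ns = 3)
tcspc_crlb_sigma(m, molecular_to_photon_fraction(0.5, 0.5), e = 0.5)
#> sigma_result (tcspc, fisher): sigma_tilde = 4.0527
```

so with 10,000 donor photons a lifetime fit can at best reach
`predicted_sigma(4.05, 1e4)` ≈ ±0.04 in E.

A command-line front end wraps these functions (`exec/photonfret`):

```sh
photonfret budget --sigma-tilde 3 --sigma 0.05     # prints 3600
photonfret sigma-sefret --fd 0.5 --out curves.csv  # σ̃(E) curve table
photonfret validate --seed 7 --reps 10000          # MC-vs-analytic suite
photonfret table1                                  # benchmark case studies
```

Subcommands: `budget`, `sigma-sefret`, `sigma-tcspc`, `simulate`,
`unmix`, `calibrate`, `synth-image`, `validate`, `table1`.  Curve tables
are CSV with a JSON parameter echo; images are multi-page 16-bit TIFF
with a JSON ground-truth sidecar.

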