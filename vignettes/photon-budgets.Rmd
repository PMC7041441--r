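---
title: "Photon statistics and precision bounds for FRET imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Photon statistics and precision bounds for FRET imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photonfret)
```

# The question this package answers

Förster resonance energy transfer (FRET) imaging estimates a biochemical
quantity — the transfer efficiency $E$, or the apparent efficiencies
$f_D E$ and $f_A E$ when only a fraction of donors/acceptors interact —
from photon counts that are at best Poisson-distributed.  Every imaging
design therefore faces the same question: *how many photons must be
collected to resolve a given difference in FRET efficiency?*

photonfret answers it through the photon-normalized precision
$\tilde\sigma$, defined by
$$\mathrm{sd}(\hat q) = \tilde\sigma\, N_P^{-1/2},$$
where $N_P$ is the number of detected photons.  $\tilde\sigma$ depends on
the imaging configuration (crosstalk, fractions, lifetimes, background)
but not on the exposure, so it characterizes the *photon economy* of a
method.  Given a target standard deviation $\sigma$, the required budget
is $N_D = \tilde\sigma^2/\sigma^2$ (`photon_budget()`); given a budget,
the attainable precision is `predicted_sigma()`.

Two modalities are covered:

* **Three-cube sensitized-emission FRET (seFRET)** — intensities
  $I^{DD}$, $I^{DA}$, $I^{AA}$ unmixed into
  $cFRET = I^{DA} - \mathrm{DER}\,I^{DD} - \mathrm{AER}\,I^{AA}$ and the
  estimators $dFRET = \eta\,cFRET/(I^{DD}+\eta\,cFRET)$ and
  $aFRET = \varepsilon\,cFRET/I^{AA}$.
* **Donor-lifetime imaging by TCSPC** — the binned periodic donor decay,
  a double exponential with quenched lifetime $\tau_0(1-E)$, analyzed
  through the multinomial Fisher information.

# The seFRET forward model and its conventions

`channel_means()` parametrizes the expected counts in donor-brightness
units: one donor excitation that decays radiatively contributes one
expected photon to $I^{DD}$.  With $q = f_D E$, total donor brightness
$G = g\,n_D$ and abundance ratio $R = n_A/n_D$:

$$\mu_{DD} = G(1-q), \qquad
  \mu_{AA} = G R\,\varepsilon/\eta, \qquad
  \mu_{DA} = G q/\eta + \mathrm{DER}\,\mu_{DD} + \mathrm{AER}\,\mu_{AA},$$

plus per-channel background.  The correction factors $\eta$ and
$\varepsilon$ absorb all quantum-yield, detection and excitation ratios.
These conventions are chosen so that noise-free unmixing returns exactly
$f_D E$ and $f_A E$ — the defining property of the estimators — which the
test suite asserts to machine precision for random populations and
systems.  The acceptor amplitude $GR\varepsilon/\eta$ makes the $aFRET$
identity hold simultaneously; the abundance ratio $R$ is the only extra
degree of freedom.

Two reference crosstalk calibrations for cyan/yellow fluorescent-protein
pairs ship as presets (`fret_system_preset()`): a confocal system
(AER 0.60, DER 0.42, $\eta$ 0.52, $\varepsilon$ 6.3) and a wide-field
system (AER 0.29, DER 1.07, $\eta$ 0.015, $\varepsilon$ 42).

# Two equivalent routes to the seFRET bound

`delta_sigma()` propagates Poisson noise through the unmixing map with
analytic partial derivatives,
$\mathrm{Var} = \sum_c (\partial\varphi/\partial I_c)^2\,\mu_c$; the test
suite verifies the partials against central finite differences at step
$10^{-6}\mu$.  `fisher_crlb()` computes the Cramér-Rao bound of the
three-channel Poisson model under the minimal parametrization
$\theta = (q, G, R)$.

Without background the two coincide to machine precision — and must: with
three parameters and three Poisson channels the plug-in unmix estimator
*is* the exact maximum-likelihood estimator, so the first-order variance
equals the bound.  This equivalence is the package's strongest internal
consistency check and is asserted at hundreds of random interior points.
With a known background the plug-in estimator is no longer the MLE (an
MLE would subtract the background), so `delta_sigma()` then describes the
estimator actually used in practice while `fisher_crlb()` remains the
information-theoretic floor.

**Normalization.** $N_P$ sums all three channel means including
background.  The choice is a convention, not physics; a
`np_channels = "donor"` switch restricts $N_P$ to the two
donor-excitation channels for sensitivity analysis.  With the all-channel
convention the benchmark population ($E = 0.5$, $f_D = 0.5$, $f_A = 1$)
gives $\tilde\sigma = 0.53$ (dFRET) and $1.5$ (aFRET), and $3.57$ (dFRET)
under the confocal crosstalk preset — the values the acceptance tests
pin down.

**Decomposition.** `sigma_decomposition()` splits $\tilde\sigma^2$ into
intrinsic, bleed-through and background contributions by model ablation
(crosstalk off, background off), which makes the sum-of-squares identity
hold *by construction*; the package does not claim closed forms for the
individual terms.

# Background models, bias, and a scale-invariance caveat

Backgrounds enter either as absolute per-channel counts (`bg_counts()`)
or as a fraction $\beta$ of each channel's signal mean (`bg_fraction()`,
signal-to-background ratio $1/\beta$).  The estimators do not subtract
background, so background both degrades precision and biases the
estimates; `expected_bias()` evaluates the plug-in estimate at the exact
means.

One consequence of the ratio structure deserves emphasis: cFRET, dFRET
and aFRET are invariant under a common rescaling of all three channels.
A background *proportional to each channel's own signal* rescales the
channels jointly and therefore biases nothing — `expected_bias()` is
exactly zero under `bg_fraction()` for every configuration, although the
precision still degrades (more photons, same information).  Real-world
backgrounds (dark counts, autofluorescence, stray light) are *not*
channel-proportional, and any non-proportional background does bias the
estimators.  The bias tests and the Monte-Carlo validation therefore use
equal absolute counts per channel as the non-trivial case, and keep the
proportional case as an exact-zero check.

# The TCSPC bound

`tcspc_model()` describes a periodic acquisition: period $T$ = 1/(80 MHz)
= 12.5 ns and 256 bins by default.  Bin probabilities of a lifetime
$\tau$ follow the periodically wrapped exponential
$$p_k = \frac{e^{-t_k/\tau} - e^{-t_{k+1}/\tau}}{1 - e^{-T/\tau}},$$
the signal is $f\,p(\tau_0(1-E)) + (1-f)\,p(\tau_0)$, circularly
convolved with the instrument response function (IRF), and mixed with a
uniform uncorrelated background.  The IRF is a Dirac by default, a
wrapped Gaussian of configurable FWHM (38 ps is the reference value for a
high-end system), or an arbitrary two-column CSV; it is centered at a
configurable bin (bin 10 by default) to leave room for the rising edge.

`tcspc_crlb_sigma()` uses the multinomial (fixed total count) Fisher
information — the total count is treated as known, so only the histogram
*shape* informs the fit — with unknowns $(E, f)$, plus the background
level when `background_is_fit_param`.  Derivatives are central finite
differences (step $10^{-5}$, with an optional step-halving check),
because the circular IRF convolution makes closed-form partials
error-prone.  The bound is normalized by the donor *signal* photons and
is therefore independent of the simulated count.  Numerical guards: $E$
is capped at 0.99 (the quenched lifetime must stay away from zero under
binning), $f = 0$ and $E = 0$ are reported as unavailable (the
parameters are unidentifiable there, and the information matrix is
singular), never pseudo-inverted.

Two sanity anchors validate the machinery:

* With $f = 1$ fixed and only $E$ unknown (`fit_fraction = FALSE`), fine
  bins and $T \gg \tau$, the bound reproduces the classical
  single-exponential limit $\tilde\sigma = 1 - E$ (the
  $\sigma_\tau = \tau/\sqrt N$ law) to better than 0.1%.
* Maximum-likelihood fits of simulated decays (`fit_decay_mle()`, 500
  decays of $10^5$ photons at $\tau_0 = 3$ ns, $f = 0.5$, $E = 0.5$)
  attain the bound within a few percent and are unbiased.

**Molecular vs photon fractions.** A fraction $f_D$ of donor *molecules*
interacting at efficiency $E$ emits a *photon* fraction
$f = f_D(1-E)/\bigl((1-f_D) + f_D(1-E)\bigr)$ in the quenched component,
because quenched molecules are dimmer by $1-E$
(`molecular_to_photon_fraction()`).  Benchmark tables in the literature
are usually indexed by the molecular fraction; both readings are
computed wherever the distinction matters.

**Lifetime and repetition-rate trade-offs.** At 80 MHz the 12.5 ns
window holds only ~1.25 decay constants of a 10 ns donor, and the bound
*worsens* markedly for $\tau_0 = 10$ ns relative to 3 ns at essentially
all $(E, f)$; conversely a 1 ns donor loses precision at high $E$ where
the quenched lifetime approaches the 49 ps bin width.  "Longer lifetimes
are always better" is therefore *not* a property of this model at a fixed
80 MHz repetition rate — the repetition period must grow with the
lifetime for that intuition to hold.  Likewise, fitting an uncorrelated
background costs little precision at moderate-to-high $E$ (under a
factor 2 with 100 background photons against 2,000 signal photons at
$f = 0.5$) but substantially more at low $E$, where the two decay
components are barely distinguishable to begin with.

# Monte-Carlo validation and the synthetic scenes

All analytic claims are checked by simulation.  `simulate_counts()`
draws Poisson replicates of the three channels; `empirical_sigma()`
scales the sample standard deviation by $\sqrt{N_P}$ (from the
generating means, matching the analytic convention), reports the
normal-theory standard error $\mathrm{sd}/\sqrt{2(n-1)}$, and excludes —
with a count — replicates whose unmix is flagged invalid (negative
denominators at low counts); more than 50% exclusions is treated as a
degenerate regime, not summarized silently.
`validate_montecarlo()` runs a 5×5×3 grid (efficiency × donor fraction ×
system) at $10^4$ replicates per point and requires analytic-empirical
agreement within 3 standard errors, plus bias agreement over a
background sweep.  At $10^4$ replicates the standard error of the
standard deviation is ≈0.7%, sharp enough to catch real discrepancies
while keeping the full grid under a second of compute.

`synth_image()` renders per-pixel channel means for a labelled scene
(donor-only strip, acceptor-only strip, mixed region with an efficiency
gradient) and adds Poisson noise; the calibration regions feed
`calibrate_der_aer()` (which uses the ratio of channel *sums*, not the
mean of per-pixel ratios, avoiding ratio-of-Poisson bias at low counts).
The scenes emulate Poisson-limited multi-channel acquisitions only: no
camera read noise or gain, no spatial correlations, no realistic
morphology, no photobleaching.  Tests passing on these scenes therefore
demonstrate the correctness of the statistical machinery, not robustness
to every nuisance of real microscope data.

# Problem sizes and numerical choices

Defaults used by the shipped tests and validation: $10^4$ replicates per
Monte-Carlo point; 500 decays of $10^5$ photons for the attainability
check; 128-point efficiency grids on the power series
$E_i = 0.99\,(i/(n-1))^2$, denser near zero where the dFRET bound varies
fastest.  Decay fitting maximizes the multinomial log-likelihood with
`L-BFGS-B` from four deterministic starts; ties go to the best
likelihood.  All randomness flows from explicit integer seeds, and every
artifact the command line writes is accompanied by a JSON echo of its
full parameter set.

# Known limitations

* TCSPC pile-up, detector dead time and count-rate-dependent distortions
  are outside the model; the bounds describe an ideal photon-counting
  chain.
* The statistical error of the DER/AER/$\eta$/$\varepsilon$ calibration
  measurements themselves is not propagated; the calibrations are
  treated as exact when computing bounds.
* Detector excess noise (EM gain, read noise) and spectral unmixing with
  more than three channels are not modelled.
* The seFRET bias analysis is exact only at the channel means; at very
  low counts the ratio estimators acquire additional small-sample bias
  of order $1/N_P$, visible only below a few hundred photons per pixel.
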