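#' Molecular composition of a pixel or sample
#'
#' Describes the fluorophore population at one (homogeneous) location: the
#' number of FRET-competent donor-acceptor pairs, the free (non-interacting)
#' donors and acceptors, and the FRET efficiency `E` of the interacting pairs.
#' The fractions of interacting donors and acceptors,
#' `f_D = n_pairs / (n_pairs + n_d_free)` and
#' `f_A = n_pairs / (n_pairs + n_a_free)`, are derived, as are the total donor
#' and acceptor abundances `n_D` and `n_A`.
#'
#' @param n_pairs number of donor-acceptor pairs undergoing FRET (>= 0).
#' @param n_d_free number of donors not engaged in FRET (>= 0).
#' @param n_a_free number of acceptors not engaged in FRET (>= 0).
#' @param efficiency FRET efficiency `E` of the interacting pairs, in `[0, 1]`.
#' @return An object of class `sample_population` with fields `n_pairs`,
#'   `n_d_free`, `n_a_free`, `efficiency`, and derived `f_d`, `f_a`, `n_d`,
#'   `n_a`, `r` (= `n_A / n_D`).
#' @seealso [population_from_fractions()] to specify `f_D`/`f_A` directly.
#' @export
#' @examples
#' pop <- sample_population(100, 100, 0, efficiency = 0.5)
#' pop$f_d  # 0.5
sample_population <- function(n_pairs, n_d_free = 0, n_a_free = 0, efficiency) {
  stopifnot(length(n_pairs) == 1, length(n_d_free) == 1,
            length(n_a_free) == 1, length(efficiency) == 1)
  if (n_pairs < 0 || n_d_free < 0 || n_a_free < 0)
    stop("population counts must be non-negative")
  if (n_pairs + n_d_free <= 0 || n_pairs + n_a_free <= 0)
    stop("sample must contain at least one donor and one acceptor")
  if (efficiency < 0 || efficiency > 1)
    stop("FRET efficiency must lie in [0, 1]")
  n_d <- n_pairs + n_d_free
  n_a <- n_pairs + n_a_free
  structure(list(
    n_pairs = n_pairs, n_d_free = n_d_free, n_a_free = n_a_free,
    efficiency = efficiency,
    f_d = n_pairs / n_d, f_a = n_pairs / n_a,
    n_d = n_d, n_a = n_a, r = n_a / n_d
  ), class = "sample_population")
}

#' Build a population from apparent fractions
#'
#' Convenience constructor taking the FRET efficiency and the interacting
#' fractions `f_D`, `f_A` instead of raw molecule counts.  `n_pairs` sets the
#' absolute scale (100 pairs by default); the precision bounds are invariant
#' to it.
#'
#' @param efficiency FRET efficiency in `[0, 1]`.
#' @param f_d,f_a fractions of interacting donors/acceptors, in `(0, 1]`.
#' @param n_pairs number of interacting pairs (scale only).
#' @return A [sample_population()].
#' @export
population_from_fractions <- function(efficiency, f_d = 1, f_a = 1,
                                      n_pairs = 100) {
  if (f_d <= 0 || f_d > 1 || f_a <= 0 || f_a > 1)
    stop("f_d and f_a must lie in (0, 1]")
  sample_population(n_pairs,
                    n_d_free = n_pairs * (1 - f_d) / f_d,
                    n_a_free = n_pairs * (1 - f_a) / f_a,
                    efficiency = efficiency)
}

#' Instrument and fluorophore crosstalk description
#'
#' Calibration state of a three-cube sensitized-emission FRET system: the
#' donor spectral bleed-through ratio (DER), the acceptor direct-excitation
#' ratio (AER), and the correction factors eta and epsilon relating
#' donor/acceptor excitation intensities and detection efficiencies.  The
#' ideal system is `der = aer = 0`, `eta = epsilon = 1`.
#'
#' @param der donor emission ratio (spectral bleed-through), >= 0.
#' @param aer acceptor excitation ratio (direct excitation), >= 0.
#' @param eta donor-normalization correction factor, > 0.
#' @param epsilon acceptor-normalization correction factor, > 0.
#' @return An object of class `fret_system`.
#' @export
#' @examples
#' fret_system()                   # ideal system
#' fret_system_preset("confocal")  # published CFP-YFP confocal calibration
fret_system <- function(der = 0, aer = 0, eta = 1, epsilon = 1) {
  if (der < 0 || aer < 0) stop("der and aer must be non-negative")
  if (eta <= 0 || epsilon <= 0) stop("eta and epsilon must be positive")
  structure(list(der = der, aer = aer, eta = eta, epsilon = epsilon),
            class = "fret_system")
}

#' Published reference crosstalk systems
#'
#' Representative calibrations reported in the literature for cyan/yellow
#' fluorescent-protein FRET pairs: a confocal microscope (`"confocal"`,
#' AER = 0.60, DER = 0.42, eta = 0.52, epsilon = 6.3) and a wide-field
#' microscope (`"widefield"`, AER = 0.29, DER = 1.07, eta = 0.015,
#' epsilon = 42), plus the crosstalk-free `"ideal"` system.
#'
#' @param name one of `"ideal"`, `"confocal"`, `"widefield"`.
#' @return A [fret_system()].
#' @export
fret_system_preset <- function(name = c("ideal", "confocal", "widefield")) {
  switch(match.arg(name),
         ideal = fret_system(),
         confocal = fret_system(der = 0.42, aer = 0.60, eta = 0.52,
                                epsilon = 6.3),
         widefield = fret_system(der = 1.07, aer = 0.29, eta = 0.015,
                                 epsilon = 42))
}

#' Background signal specification
#'
#' Expected background photons in the three acquisition channels, either as
#' absolute per-channel counts or as a single relative fraction `beta` applied
#' to each channel's signal mean (`b_c = beta * signal mean of channel c`);
#' the signal-to-background ratio is `1 / beta`.
#'
#' @param b_dd,b_da,b_aa expected background photons per channel, >= 0.
#' @param beta relative background fraction in `[0, 1)`.
#' @return An object of class `fret_background`.
#' @export
#' @examples
#' bg_none()
#' bg_counts(5, 5, 5)
#' bg_fraction(0.2)   # 20% of each channel's signal mean
bg_counts <- function(b_dd = 0, b_da = 0, b_aa = 0) {
  if (b_dd < 0 || b_da < 0 || b_aa < 0)
    stop("background counts must be non-negative")
  structure(list(type = "counts", b_dd = b_dd, b_da = b_da, b_aa = b_aa),
            class = "fret_background")
}

#' @rdname bg_counts
#' @export
bg_fraction <- function(beta) {
  if (beta < 0 || beta >= 1) stop("beta must lie in [0, 1)")
  structure(list(type = "fraction", beta = beta), class = "fret_background")
}

#' @rdname bg_counts
#' @export
bg_none <- function() bg_counts(0, 0, 0)

#' Channel intensities for the three-cube acquisition
#'
#' Container for the donor-excitation donor channel (`I^DD`), the
#' donor-excitation acceptor (FRET) channel (`I^DA`) and the
#' acceptor-excitation acceptor channel (`I^AA`).  Values are either expected
#' means (non-negative reals) or observed counts (non-negative integers);
#' vectors of equal length represent pixels or replicates.
#'
#' @param i_dd,i_da,i_aa channel intensities (photons), same length.
#' @param role `"means"` or `"counts"`.
#' @return An object of class `channel_triplet`.
#' @export
channel_triplet <- function(i_dd, i_da, i_aa, role = c("means", "counts")) {
  role <- match.arg(role)
  n <- length(i_dd)
  stopifnot(length(i_da) == n, length(i_aa) == n)
  if (any(i_dd < 0) || any(i_da < 0) || any(i_aa < 0))
    stop("channel intensities must be non-negative")
  if (role == "counts" &&
      any(abs(c(i_dd, i_da, i_aa) - round(c(i_dd, i_da, i_aa))) > 1e-9))
    stop("channel counts must be integers")
  structure(list(i_dd = i_dd, i_da = i_da, i_aa = i_aa, role = role),
            class = "channel_triplet")
}

## Signal-only channel means (no background), in donor-brightness units:
## one radiative donor excitation contributes 1 expected photon to I^DD.
.signal_means <- function(pop, sys, exposure) {
  g <- exposure
  q <- pop$f_d * pop$efficiency            # apparent donor-side efficiency
  mu_dd <- g * pop$n_d * (1 - q)
  s <- g * pop$n_d * q / sys$eta           # sensitized emission
  mu_aa <- g * (sys$epsilon / sys$eta) * pop$n_a
  mu_da <- s + sys$der * mu_dd + sys$aer * mu_aa
  c(dd = mu_dd, da = mu_da, aa = mu_aa)
}

.background_counts <- function(bg, signal) {
  if (is.null(bg)) return(c(dd = 0, da = 0, aa = 0))
  stopifnot(inherits(bg, "fret_background"))
  if (bg$type == "fraction") {
    bg$beta * signal
  } else {
    c(dd = bg$b_dd, da = bg$b_da, aa = bg$b_aa)
  }
}

#' Expected three-cube channel intensities
#'
#' Forward model of the mean photon counts in the `I^DD`, `I^DA` and `I^AA`
#' channels for a given sample population, instrument crosstalk state,
#' exposure and background.  In the adopted brightness convention one donor
#' excitation that decays radiatively contributes one expected photon to
#' `I^DD`; eta and epsilon absorb all quantum-yield, detection and excitation
#' ratios, so that noise-free unmixing returns exactly `f_D E` and `f_A E`.
#'
#' @param pop a [sample_population()].
#' @param sys a [fret_system()].
#' @param exposure expected detected photons per donor per acquisition
#'   (donor-channel brightness units), > 0.
#' @param bg a [bg_counts()], [bg_fraction()] or `NULL` for none.
#' @return A [channel_triplet()] of means, with attribute `"background"`
#'   holding the per-channel background means.
#' @export
#' @examples
#' pop <- sample_population(100, 100, 0, efficiency = 0.5)
#' channel_means(pop, fret_system(), exposure = 1)  # (150, 50, 100)
channel_means <- function(pop, sys = fret_system(), exposure = 1, bg = NULL) {
  stopifnot(inherits(pop, "sample_population"), inherits(sys, "fret_system"))
  if (exposure <= 0) stop("exposure must be positive")
  sig <- .signal_means(pop, sys, exposure)
  b <- .background_counts(bg, sig)
  out <- channel_triplet(sig[["dd"]] + b[["dd"]], sig[["da"]] + b[["da"]],
                         sig[["aa"]] + b[["aa"]], role = "means")
  attr(out, "background") <- b
  out
}

#' Crosstalk-corrected FRET estimators
#'
#' Unmixes observed (or expected) three-cube intensities into the corrected
#' FRET signal `cFRET = I^DA - DER I^DD - AER I^AA` and the apparent
#' efficiencies `dFRET = eta cFRET / (I^DD + eta cFRET)` and
#' `aFRET = epsilon cFRET / I^AA`.  Estimates whose denominator is
#' non-positive are flagged invalid rather than clamped, so that per-pixel
#' unmixing degrades gracefully and Monte-Carlo moments stay unbiased.
#'
#' @param obs a [channel_triplet()] (vectors allowed).
#' @param sys a [fret_system()].
#' @return An object of class `fret_estimates`: list of numeric vectors
#'   `cfret`, `dfret`, `afret` and logical vectors `dfret_valid`,
#'   `afret_valid` (invalid entries are `NA` in the estimate vectors).
#' @export
#' @examples
#' unmix(channel_triplet(150, 50, 100), fret_system())
#' # cfret = 50, dfret = 0.25, afret = 0.5
unmix <- function(obs, sys = fret_system()) {
  stopifnot(inherits(obs, "channel_triplet"), inherits(sys, "fret_system"))
  cfret <- obs$i_da - sys$der * obs$i_dd - sys$aer * obs$i_aa
  d_den <- obs$i_dd + sys$eta * cfret
  dfret_valid <- d_den > 0
  dfret <- ifelse(dfret_valid, sys$eta * cfret / d_den, NA_real_)
  afret_valid <- obs$i_aa > 0
  afret <- ifelse(afret_valid, sys$epsilon * cfret / obs$i_aa, NA_real_)
  structure(list(cfret = cfret, dfret = dfret, afret = afret,
                 dfret_valid = dfret_valid, afret_valid = afret_valid),
            class = "fret_estimates")
}

#' Calibrate crosstalk ratios from single-fluorophore samples
#'
#' Estimates the donor emission ratio `DER = I^DA / I^DD` from a donor-only
#' acquisition and the acceptor excitation ratio `AER = I^DA / I^AA` from an
#' acceptor-only acquisition.  For image (vector) inputs the ratio of the
#' channel sums is used, not the mean of per-pixel ratios, which avoids the
#' ratio-of-Poisson bias at low counts.
#'
#' @param donor_only a [channel_triplet()] from a donor-only sample.
#' @param acceptor_only a [channel_triplet()] from an acceptor-only sample.
#' @return A list with elements `der` and `aer`.
#' @export
calibrate_der_aer <- function(donor_only, acceptor_only) {
  stopifnot(inherits(donor_only, "channel_triplet"),
            inherits(acceptor_only, "channel_triplet"))
  s_dd <- sum(donor_only$i_dd)
  s_aa <- sum(acceptor_only$i_aa)
  if (s_dd <= 0) stop("calibration error: donor-only I^DD sum is zero")
  if (s_aa <= 0) stop("calibration error: acceptor-only I^AA sum is zero")
  list(der = sum(donor_only$i_da) / s_dd,
       aer = sum(acceptor_only$i_da) / s_aa)
}

#' Calibrate eta and epsilon from a reference sample of known efficiency
#'
#' Given a reference acquisition from a sample where all donors and acceptors
#' interact (`f_D = f_A = 1`) with known FRET efficiency `e_ref`, solves the
#' dFRET and aFRET identities for the correction factors:
#' `eta = e_ref I^DD / (cFRET (1 - e_ref))` and
#' `epsilon = e_ref I^AA / cFRET`.
#'
#' @param reference a [channel_triplet()] from the reference sample (vector
#'   inputs are summed channel-wise).
#' @param e_ref known FRET efficiency of the reference, in `(0, 1)`.
#' @param der,aer crosstalk ratios of the system (from
#'   [calibrate_der_aer()]).
#' @return A list with elements `eta` and `epsilon`.
#' @export
calibrate_eta_epsilon <- function(reference, e_ref, der = 0, aer = 0) {
  stopifnot(inherits(reference, "channel_triplet"))
  if (e_ref <= 0 || e_ref >= 1)
    stop("calibration error: e_ref must lie in (0, 1)")
  i_dd <- sum(reference$i_dd)
  i_da <- sum(reference$i_da)
  i_aa <- sum(reference$i_aa)
  cfret <- i_da - der * i_dd - aer * i_aa
  if (cfret <= 0) stop("calibration error: reference cFRET is non-positive")
  list(eta = e_ref * i_dd / (cfret * (1 - e_ref)),
       epsilon = e_ref * i_aa / cfret)
}
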