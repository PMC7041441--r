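#' Binned TCSPC decay model description
#'
#' Describes a periodic time-correlated single-photon counting acquisition of
#' the donor decay: unquenched lifetime `tau0`, laser repetition rate (the
#' period is `T = 1/rep_rate`), number of time bins, instrument response
#' function (IRF) and uncorrelated-background fraction.  The donor decay is a
#' double exponential with a FRET-quenched component at lifetime
#' `tau0 (1 - E)`.
#'
#' @param tau0_ns unquenched donor lifetime, ns.
#' @param rep_rate_hz excitation repetition rate, Hz (default 80 MHz).
#' @param n_bins number of time bins (default 256).
#' @param irf normalized per-bin IRF vector of length `n_bins`, or `NULL`
#'   for a Dirac IRF (see [make_irf()]).
#' @param b_frac fraction of total counts contributed by a uniform
#'   uncorrelated background, in `[0, 1)` (`[0, 1]` for pure background in
#'   the forward model).
#' @param background_is_fit_param if `TRUE`, the background level is treated
#'   as an additional unknown in [tcspc_crlb_sigma()] and
#'   [fit_decay_mle()].
#' @param irf_center_bin bin at which a Dirac IRF places its mass and a
#'   Gaussian IRF is centered (default 10, leaving room for the rising
#'   edge).
#' @return An object of class `tcspc_model` with derived fields `period_ns`
#'   and `bin_width_ns`.
#' @export
#' @examples
#' m <- tcspc_model(tau0_ns = 3)
#' m$bin_width_ns  # 12.5/256 ns
tcspc_model <- function(tau0_ns = 3, rep_rate_hz = 80e6, n_bins = 256,
                        irf = NULL, b_frac = 0,
                        background_is_fit_param = FALSE,
                        irf_center_bin = 10) {
  if (tau0_ns <= 0) stop("tau0 must be positive")
  if (rep_rate_hz <= 0) stop("repetition rate must be positive")
  if (n_bins < 2) stop("need at least 2 time bins")
  if (b_frac < 0 || b_frac > 1) stop("b_frac must lie in [0, 1]")
  period <- 1 / rep_rate_hz * 1e9
  if (is.null(irf)) {
    irf <- numeric(n_bins)
    irf[irf_center_bin] <- 1
  } else {
    if (length(irf) != n_bins) stop("irf must have one entry per bin")
    if (any(irf < 0)) stop("irf entries must be non-negative")
    s <- sum(irf)
    if (s <= 0) stop("irf must have positive mass")
    if (abs(s - 1) > 1e-12) irf <- irf / s
  }
  structure(list(tau0_ns = tau0_ns, rep_rate_hz = rep_rate_hz,
                 n_bins = n_bins, irf = irf, b_frac = b_frac,
                 background_is_fit_param = background_is_fit_param,
                 irf_center_bin = irf_center_bin,
                 period_ns = period, bin_width_ns = period / n_bins),
            class = "tcspc_model")
}

## Bin probabilities of a periodically wrapped exponential decay:
## p_k = (exp(-t_k/tau) - exp(-t_{k+1}/tau)) / (1 - exp(-T/tau)).
.wrapped_exp_bins <- function(tau, period, n_bins) {
  tk <- seq(0, period, length.out = n_bins + 1)
  e <- exp(-tk / tau)
  (e[-(n_bins + 1)] - e[-1]) / (1 - e[n_bins + 1])
}

.circular_convolve <- function(x, irf) {
  n <- length(x)
  out <- Re(stats::fft(stats::fft(x) * stats::fft(irf), inverse = TRUE)) / n
  out[out < 0] <- 0     # clip FFT rounding noise
  out / sum(out)
}

#' Construct an instrument response function
#'
#' Either a Dirac IRF (unit mass in the center bin) or a Gaussian of given
#' full width at half maximum, discretized by bin-edge integrals of the
#' normal CDF, wrapped on the excitation period and renormalized to unit
#' mass.
#'
#' @param kind `"dirac"` or `"gaussian"`.
#' @param fwhm_ns full width at half maximum of the Gaussian, ns (>= 0).
#' @param model a [tcspc_model()] supplying period, bin count and center
#'   bin.
#' @return Numeric IRF vector of length `model$n_bins` summing to 1.
#' @export
#' @examples
#' m <- tcspc_model()
#' irf <- make_irf("gaussian", fwhm_ns = 0.038, model = m)
#' sum(irf)  # 1
make_irf <- function(kind = c("dirac", "gaussian"), fwhm_ns = 0,
                     model = tcspc_model()) {
  kind <- match.arg(kind)
  n <- model$n_bins
  irf <- numeric(n)
  if (kind == "dirac") {
    irf[model$irf_center_bin] <- 1
    return(irf)
  }
  if (fwhm_ns < 0) stop("fwhm must be non-negative")
  if (fwhm_ns == 0) {
    irf[model$irf_center_bin] <- 1
    return(irf)
  }
  sd <- fwhm_ns / (2 * sqrt(2 * log(2)))
  center <- (model$irf_center_bin - 0.5) * model$bin_width_ns
  edges <- seq(0, model$period_ns, length.out = n + 1)
  ## wrap the Gaussian mass over neighbouring periods
  mass <- numeric(n)
  for (k in -2:2) {
    lo <- stats::pnorm(edges[-(n + 1)], center + k * model$period_ns, sd)
    hi <- stats::pnorm(edges[-1], center + k * model$period_ns, sd)
    mass <- mass + (hi - lo)
  }
  mass / sum(mass)
}

#' Read an IRF from a two-column CSV
#'
#' Reads `(time_ns, amplitude)` pairs, bins the amplitude onto the model's
#' time grid by accumulation, and renormalizes.
#'
#' @param path CSV file with columns time (ns) and amplitude.
#' @param model a [tcspc_model()].
#' @return Numeric IRF vector of length `model$n_bins`.
#' @export
read_irf_csv <- function(path, model = tcspc_model()) {
  d <- utils::read.csv(path)
  if (ncol(d) < 2) stop("IRF file must have two columns: time_ns, amplitude")
  t <- d[[1]] %% model$period_ns
  bin <- pmin(floor(t / model$bin_width_ns) + 1, model$n_bins)
  irf <- numeric(model$n_bins)
  for (i in seq_along(bin)) irf[bin[i]] <- irf[bin[i]] + d[[2]][i]
  if (any(irf < 0)) stop("IRF amplitudes must be non-negative")
  irf / sum(irf)
}

#' Per-bin probabilities of the donor decay
#'
#' Double-exponential decay with a quenched component at lifetime
#' `tau0 (1 - e)` carrying a fraction `f` of the signal photons and the
#' unquenched component at `tau0` carrying `1 - f`, each periodically
#' wrapped, circularly convolved with the IRF, and mixed with a uniform
#' background: `p = (1 - b_frac) (f p(tau2) + (1-f) p(tau0)) (*) irf +
#' b_frac / n_bins`.
#'
#' @param model a [tcspc_model()].
#' @param f fraction of signal photons in the quenched component, `[0, 1]`.
#' @param e FRET efficiency, `[0, 0.99]` (the quenched lifetime is bounded
#'   away from zero; beyond 0.99 the binned model is numerically
#'   degenerate).
#' @return Probability vector over the `n_bins` bins (sums to 1).
#' @export
decay_model <- function(model, f, e) {
  stopifnot(inherits(model, "tcspc_model"))
  if (e < 0 || e > 0.99) stop("FRET efficiency must lie in [0, 0.99]")
  if (f < 0 || f > 1) stop("signal fraction f must lie in [0, 1]")
  sig <- f * .wrapped_exp_bins(model$tau0_ns * (1 - e), model$period_ns,
                               model$n_bins) +
    (1 - f) * .wrapped_exp_bins(model$tau0_ns, model$period_ns, model$n_bins)
  sig <- .circular_convolve(sig, model$irf)
  model$b_frac * (1 / model$n_bins) + (1 - model$b_frac) * sig
}

#' Convert a molecular interacting fraction to a photon fraction
#'
#' A fraction `f_mol` of donor molecules engaged in FRET at efficiency `e`
#' emits fewer photons per molecule (yield reduced by `1 - e`), so the
#' fraction of detected donor photons carried by the quenched decay
#' component is `f_mol (1-e) / ((1-f_mol) + f_mol (1-e))`.
#'
#' @param f_mol fraction of donor molecules interacting, `(0, 1]`.
#' @param e FRET efficiency, `[0, 1)`.
#' @return Photon fraction of the quenched component.
#' @export
#' @examples
#' molecular_to_photon_fraction(0.98, 0.75)  # ~0.9245
molecular_to_photon_fraction <- function(f_mol, e) {
  if (f_mol <= 0 || f_mol > 1) stop("f_mol must lie in (0, 1]")
  if (e < 0 || e >= 1) stop("e must lie in [0, 1)")
  f_mol * (1 - e) / ((1 - f_mol) + f_mol * (1 - e))
}

.tcspc_free_params <- function(model, f, e, fit_fraction = TRUE) {
  theta <- c(e = e)
  if (fit_fraction) theta <- c(theta, f = f)
  if (model$background_is_fit_param) theta <- c(theta, b = model$b_frac)
  theta
}

.tcspc_probs_theta <- function(theta, model, f_fixed = NULL) {
  m <- model
  if ("b" %in% names(theta)) m$b_frac <- unname(theta[["b"]])
  f <- if ("f" %in% names(theta)) unname(theta[["f"]]) else f_fixed
  decay_model(m, f, unname(theta[["e"]]))
}

.tcspc_fisher <- function(model, f, e, step = 1e-5, fit_fraction = TRUE) {
  theta <- .tcspc_free_params(model, f, e, fit_fraction)
  p <- .tcspc_probs_theta(theta, model, f_fixed = f)
  upper <- c(e = 0.99, f = 1, b = 1)    # parameter domain bounds
  dp <- vapply(seq_along(theta), function(i) {
    h <- step
    tp <- theta; tm <- theta
    tp[i] <- min(theta[i] + h, upper[[names(theta)[i]]])
    tm[i] <- max(theta[i] - h, 0)
    (.tcspc_probs_theta(tp, model, f_fixed = f) -
       .tcspc_probs_theta(tm, model, f_fixed = f)) / (tp[i] - tm[i])
  }, numeric(model$n_bins))
  pos <- p > 0
  crossprod(dp[pos, , drop = FALSE] / sqrt(p[pos]))
}

#' Cramér-Rao lower bound for FRET estimation from a TCSPC decay
#'
#' Numerical Fisher-information bound for the binned donor decay under the
#' multinomial (fixed total count) model: the unknowns are the FRET
#' efficiency `e` and signal fraction `f` (plus the background level when
#' `model$background_is_fit_param`), while `tau0` and the total count are
#' known.  Derivatives are central finite differences (step `1e-5`), with an
#' optional step-halving stability check.  The bound is normalized by the
#' donor *signal* photons: `sigma_tilde = sqrt(Var(e) * N_signal)`, which is
#' independent of the total count.
#'
#' @param model a [tcspc_model()].
#' @param f signal-photon fraction of the quenched component (see
#'   [molecular_to_photon_fraction()] for the molecular reading).
#' @param e FRET efficiency, `[0, 0.99]`.
#' @param step finite-difference step.
#' @param check_step if `TRUE`, recompute at half step and warn if the
#'   bound moves by more than `1e-4` relative.
#' @param fit_fraction if `FALSE`, treat `f` as known and fit only `e`
#'   (single-unknown variant; recovers the classical single-exponential
#'   lifetime limit at `f = 1`).
#' @return A [sigma_result] with `estimator = "tcspc"`.
#' @export
#' @examples
#' m <- tcspc_model(tau0_ns = 3)
#' tcspc_crlb_sigma(m, f = molecular_to_photon_fraction(0.98, 0.75), e = 0.75)
tcspc_crlb_sigma <- function(model, f, e, step = 1e-5, check_step = FALSE,
                             fit_fraction = TRUE) {
  stopifnot(inherits(model, "tcspc_model"))
  if (f <= 0)
    stop("Fisher bound unavailable: e is unidentifiable at f = 0")
  J <- .tcspc_fisher(model, f, e, step, fit_fraction)
  if (rcond(J) < 1e-14)
    stop("Fisher bound unavailable: information matrix is numerically ",
         "singular at this point (rcond = ", format(rcond(J)), ")")
  v <- solve(J)[1, 1]
  if (check_step) {
    J2 <- .tcspc_fisher(model, f, e, step / 2, fit_fraction)
    v2 <- solve(J2)[1, 1]
    if (abs(v2 - v) > 1e-4 * abs(v))
      warning("finite-difference step not converged: relative change ",
              format(abs(v2 - v) / abs(v)))
  }
  ## Var(e) for N total counts is v/N; normalizing by the signal photons
  ## N_signal = (1 - b_frac) N gives sigma_tilde = sqrt(v (1 - b_frac)).
  .sigma_result(sqrt(v * (1 - model$b_frac)), NA_real_, "tcspc",
                "fisher", var_raw = v)
}

#' TCSPC precision-bound sweep
#'
#' Tabulates [tcspc_crlb_sigma()] over grids of lifetime, signal fraction
#' and FRET efficiency, optionally with an uncorrelated background treated
#' as a fit parameter.  The default fraction grid is the photon-fraction set
#' `{1/11, 1/3, 10/11}` arising from fixed quenched-component photon counts
#' of 100, 500 and 10,000 against 1,000 unquenched photons.
#'
#' @param tau0_values unquenched lifetimes to sweep, ns.
#' @param f_values quenched-component photon fractions.
#' @param e_grid efficiency grid (default [efficiency_grid()] with 128
#'   points).
#' @param background_photons background photon counts to sweep (0 = none);
#'   the signal level defining the fraction is 1,000 photons plus the
#'   corresponding quenched-component count.
#' @param rep_rate_hz,n_bins,irf passed to [tcspc_model()].
#' @return Data frame with columns `tau0`, `f`, `E`, `background_photons`,
#'   `sigma_tilde`.
#' @export
tcspc_sweep <- function(tau0_values = 3,
                        f_values = c(100 / 1100, 500 / 1500, 10000 / 11000),
                        e_grid = efficiency_grid(),
                        background_photons = 0,
                        rep_rate_hz = 80e6, n_bins = 256, irf = NULL) {
  grid <- expand.grid(tau0 = tau0_values, f = f_values, E = e_grid,
                      background_photons = background_photons,
                      KEEP.OUT.ATTRS = FALSE)
  grid$sigma_tilde <- vapply(seq_len(nrow(grid)), function(i) {
    n_signal <- 1000 / (1 - grid$f[i])        # 1,000 unquenched photons
    b <- grid$background_photons[i]
    m <- tcspc_model(tau0_ns = grid$tau0[i], rep_rate_hz = rep_rate_hz,
                     n_bins = n_bins, irf = irf,
                     b_frac = b / (b + n_signal),
                     background_is_fit_param = b > 0)
    tryCatch(tcspc_crlb_sigma(m, grid$f[i], grid$E[i])$sigma_tilde,
             error = function(err) NA_real_)
  }, numeric(1))
  grid
}
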