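#' @name sigma_result
#' @title Normalized precision of a FRET estimator
#' @description
#' Objects of class `sigma_result` carry the photon-normalized standard
#' deviation `sigma_tilde` of a FRET estimate, defined through
#' `sd(estimate) = sigma_tilde / sqrt(N_P)` where `N_P` is the normalization
#' photon count.  `sigma_tilde` is a property of the imaging configuration
#' only: it is invariant to exposure.  Fields: `sigma_tilde`, `n_p`,
#' `estimator` (`"dfret"` or `"afret"`, or `"tcspc"`), `method`, and the
#' optional decomposition `sigma_e`, `sigma_sbt`, `sigma_b` satisfying
#' `sigma_tilde^2 = sigma_e^2 + sigma_sbt^2 + sigma_b^2`.
NULL

.sigma_result <- function(sigma_tilde, n_p, estimator, method,
                          components = NULL, var_raw = NA_real_) {
  out <- list(sigma_tilde = sigma_tilde, n_p = n_p, estimator = estimator,
              method = method, var_raw = var_raw)
  if (!is.null(components)) {
    out$sigma_e <- components[["sigma_e"]]
    out$sigma_sbt <- components[["sigma_sbt"]]
    out$sigma_b <- components[["sigma_b"]]
  }
  structure(out, class = "sigma_result")
}

#' @export
print.sigma_result <- function(x, ...) {
  cat(sprintf("sigma_result (%s, %s): sigma_tilde = %.6g", x$estimator,
              x$method, x$sigma_tilde))
  if (is.finite(x$n_p)) cat(sprintf("  [N_P = %.6g]", x$n_p))
  cat("\n")
  if (!is.null(x$sigma_e))
    cat(sprintf("  components: sigma_E = %.6g, sigma_SBT = %.6g, sigma_B = %.6g\n",
                x$sigma_e, x$sigma_sbt, x$sigma_b))
  invisible(x)
}

.np_count <- function(mu, np_channels) {
  switch(np_channels,
         all = sum(mu),
         donor = mu[["dd"]] + mu[["da"]],
         stop("unknown normalization channel scope"))
}

## Analytic partial derivatives of the unmix map with respect to the three
## channel intensities, evaluated at `i = c(dd, da, aa)`.
.unmix_partials <- function(i, sys, which) {
  der <- sys$der; aer <- sys$aer; eta <- sys$eta; eps <- sys$epsilon
  cfret <- i[["da"]] - der * i[["dd"]] - aer * i[["aa"]]
  if (which == "dfret") {
    den <- i[["dd"]] + eta * cfret
    if (den <= 0) stop("dFRET undefined at the channel means (denominator <= 0)")
    c(dd = (-eta * der * i[["dd"]] - eta * cfret) / den^2,
      da = eta * i[["dd"]] / den^2,
      aa = -eta * aer * i[["dd"]] / den^2)
  } else {
    if (i[["aa"]] <= 0) stop("aFRET undefined at the channel means (I^AA = 0)")
    c(dd = -eps * der / i[["aa"]],
      da = eps / i[["aa"]],
      aa = -eps * (aer * i[["aa"]] + cfret) / i[["aa"]]^2)
  }
}

.means_vec <- function(pop, sys, exposure, bg) {
  m <- channel_means(pop, sys, exposure, bg)
  c(dd = m$i_dd, da = m$i_da, aa = m$i_aa)
}

#' Precision of the seFRET estimators by error propagation
#'
#' First-order (delta-method) propagation of Poisson noise through the unmix
#' formulas: `Var(estimator) = sum_c (dphi/dI_c)^2 mu_c`, with the partial
#' derivatives evaluated analytically at the expected channel means.  The
#' result is normalized to `sigma_tilde = sqrt(Var * N_P)` with
#' `N_P = mu_DD + mu_DA + mu_AA` (signal plus background; set
#' `np_channels = "donor"` to normalize by the two donor-excitation channels
#' only, for sensitivity analysis).
#'
#' Without background this equals the Cramér-Rao lower bound
#' ([fisher_crlb()]) because the plug-in unmix estimator is the exact maximum
#' likelihood estimator of the three-channel Poisson model.
#'
#' @param pop a [sample_population()].
#' @param sys a [fret_system()].
#' @param exposure expected detected photons per donor (scale only;
#'   `sigma_tilde` is invariant to it).
#' @param bg background specification ([bg_counts()], [bg_fraction()] or
#'   `NULL`).
#' @param which `"dfret"` or `"afret"`.
#' @param np_channels `"all"` (default) or `"donor"`: channels included in
#'   the normalization count `N_P`.
#' @param decompose if `TRUE`, also compute the ablation decomposition (see
#'   [sigma_decomposition()]).
#' @return A [sigma_result].
#' @export
#' @examples
#' pop <- population_from_fractions(0.5, f_d = 0.5, f_a = 1)
#' delta_sigma(pop, fret_system(), which = "dfret")$sigma_tilde  # ~0.53
#' delta_sigma(pop, fret_system(), which = "afret")$sigma_tilde  # 1.5
delta_sigma <- function(pop, sys = fret_system(), exposure = 1, bg = NULL,
                        which = c("dfret", "afret"), np_channels = "all",
                        decompose = FALSE) {
  which <- match.arg(which)
  mu <- .means_vec(pop, sys, exposure, bg)
  pos <- mu > 0
  if (which == "dfret" && pop$f_d * pop$efficiency == 0 && mu[["da"]] == 0) {
    ## no sensitized photons and no crosstalk: dFRET is exactly 0 with
    ## zero variance
    np <- .np_count(mu, np_channels)
    return(.sigma_result(0, np, which, "delta", var_raw = 0))
  }
  d <- .unmix_partials(mu, sys, which)
  v <- sum(d[pos]^2 * mu[pos])
  np <- .np_count(mu, np_channels)
  comp <- if (decompose)
    sigma_decomposition(pop, sys, exposure, bg, which, np_channels)
  .sigma_result(sqrt(v * np), np, which, "delta", components = comp,
                var_raw = v)
}

## Means and their gradients under the minimal parametrization
## theta = (q, G, R): q the apparent efficiency targeted by the estimator,
## G = exposure * n_D the total donor brightness, R = n_A / n_D.
.theta_model <- function(theta, sys, which, b) {
  q <- theta[1]; G <- theta[2]; R <- theta[3]
  der <- sys$der; aer <- sys$aer; eta <- sys$eta; eps <- sys$epsilon
  if (which == "dfret") {
    qd <- q
    dqd <- c(1, 0, 0)
  } else {
    qd <- q * R               # donor-side apparent efficiency f_D E = q R
    dqd <- c(R, 0, q)
  }
  mu_dd <- G * (1 - qd) + b[["dd"]]
  g_dd <- c(-G * dqd[1], 1 - qd, -G * dqd[3])
  mu_aa <- G * R * eps / eta + b[["aa"]]
  g_aa <- c(0, R * eps / eta, G * eps / eta)
  mu_da <- G * qd / eta + der * (mu_dd - b[["dd"]]) +
    aer * (mu_aa - b[["aa"]]) + b[["da"]]
  g_da <- c(G * dqd[1] / eta, qd / eta, G * dqd[3] / eta) +
    der * g_dd + aer * g_aa
  list(mu = c(dd = mu_dd, da = mu_da, aa = mu_aa),
       grad = rbind(dd = g_dd, da = g_da, aa = g_aa))
}

#' Cramér-Rao lower bound for the seFRET estimators
#'
#' Fisher-information bound on the variance of the apparent-efficiency
#' estimate from the three Poisson channels.  The means are parametrized by
#' `theta = (q, G, R)` with `q = f_D E` (dFRET) or `q = f_A E` (aFRET),
#' `G` the total donor brightness and `R = n_A / n_D`; backgrounds enter as
#' known constants.  `J_ij = sum_c mu_c^{-1} (dmu_c/dtheta_i)(dmu_c/dtheta_j)`
#' and `Var(q) = (J^{-1})_11`, normalized as in [delta_sigma()].
#'
#' @inheritParams delta_sigma
#' @return A [sigma_result].
#' @export
fisher_crlb <- function(pop, sys = fret_system(), exposure = 1, bg = NULL,
                        which = c("dfret", "afret"), np_channels = "all") {
  which <- match.arg(which)
  stopifnot(inherits(pop, "sample_population"))
  sig <- .signal_means(pop, sys, exposure)
  b <- .background_counts(bg, sig)
  q <- if (which == "dfret") pop$f_d * pop$efficiency
       else pop$f_a * pop$efficiency
  theta <- c(q, exposure * pop$n_d, pop$r)
  m <- .theta_model(theta, sys, which, b)
  if (any(m$mu <= 0))
    stop("Fisher bound unavailable: a channel mean is zero at this point; ",
         "the parametrization is degenerate (see delta_sigma for limits)")
  J <- crossprod(m$grad / sqrt(m$mu))
  Jinv <- tryCatch(solve(J), error = function(e) NULL)
  if (is.null(Jinv) || !all(is.finite(Jinv)) || Jinv[1, 1] < 0)
    stop("Fisher bound unavailable: information matrix is singular at this ",
         "parameter point (rcond = ", format(rcond(J)), ")")
  v <- Jinv[1, 1]
  np <- .np_count(m$mu, np_channels)
  .sigma_result(sqrt(v * np), np, which, "fisher", var_raw = v)
}

#' Decomposition of the seFRET precision bound
#'
#' Splits `sigma_tilde^2` into additive contributions of intrinsic photon
#' noise (`sigma_E`), spectral bleed-through/direct excitation (`sigma_SBT`)
#' and background (`sigma_B`) by model ablation: `sigma_E` is the bound with
#' `der = aer = 0` and no background; `sigma_SBT^2` is the increase when
#' crosstalk is restored (still without background); `sigma_B^2` the further
#' increase when background is restored.  By construction
#' `sigma_tilde^2 = sigma_E^2 + sigma_SBT^2 + sigma_B^2`.
#'
#' @inheritParams delta_sigma
#' @return Named list `sigma_e`, `sigma_sbt`, `sigma_b`, `sigma_tilde`.
#' @export
sigma_decomposition <- function(pop, sys = fret_system(), exposure = 1,
                                bg = NULL, which = c("dfret", "afret"),
                                np_channels = "all") {
  which <- match.arg(which)
  sys0 <- fret_system(der = 0, aer = 0, eta = sys$eta, epsilon = sys$epsilon)
  s_e <- delta_sigma(pop, sys0, exposure, NULL, which, np_channels)$sigma_tilde
  s_nobg <- delta_sigma(pop, sys, exposure, NULL, which,
                        np_channels)$sigma_tilde
  s_full <- delta_sigma(pop, sys, exposure, bg, which,
                        np_channels)$sigma_tilde
  floor0 <- function(x) if (x < 0 && x > -1e-12) 0 else max(x, 0)
  list(sigma_e = s_e,
       sigma_sbt = sqrt(floor0(s_nobg^2 - s_e^2)),
       sigma_b = sqrt(floor0(s_full^2 - s_nobg^2)),
       sigma_tilde = s_full)
}

#' Systematic error of the seFRET estimators under background
#'
#' The dFRET and aFRET estimators do not subtract background, so a background
#' signal biases them.  This evaluates the plug-in estimate at the exact
#' channel means and returns its deviation from the true apparent efficiency
#' (`f_D E` or `f_A E`); the result is zero without background.
#'
#' @inheritParams delta_sigma
#' @return Numeric scalar bias (estimate at the means minus truth).
#' @export
expected_bias <- function(pop, sys = fret_system(), exposure = 1, bg = NULL,
                          which = c("dfret", "afret")) {
  which <- match.arg(which)
  est <- unmix(channel_means(pop, sys, exposure, bg), sys)
  val <- if (which == "dfret") est$dfret else est$afret
  if (is.na(val))
    stop("estimator invalid at the channel means for this configuration")
  truth <- if (which == "dfret") pop$f_d * pop$efficiency
           else pop$f_a * pop$efficiency
  val - truth
}

#' Photon budget for a target precision
#'
#' Number of photons `N_D = sigma_tilde^2 / sigma_target^2` that must be
#' detected to reach a standard deviation `sigma_target` on the FRET
#' estimate, given the photon-economy factor `sigma_tilde` of the method.
#' Rounded half-up to whole photons by default.
#'
#' @param sigma_tilde normalized precision of the method, > 0.
#' @param sigma_target desired standard deviation of the estimate, > 0.
#' @param round if `FALSE`, return the unrounded ratio.
#' @return Photon count (numeric scalar).
#' @export
#' @examples
#' photon_budget(3, 0.05)    # 3600 photons for E +/- 0.05
#' photon_budget(0.5, 0.05)  # 100
photon_budget <- function(sigma_tilde, sigma_target, round = TRUE) {
  if (sigma_tilde <= 0 || sigma_target <= 0)
    stop("sigma_tilde and sigma_target must be positive")
  n <- (sigma_tilde / sigma_target)^2
  if (round) floor(n + 0.5) else n
}

#' Predicted standard deviation at a given photon count
#'
#' `sigma = sigma_tilde / sqrt(N_P)`.
#'
#' @param sigma_tilde normalized precision, >= 0.
#' @param n_p detected photon count, >= 1.
#' @return Numeric scalar standard deviation.
#' @export
#' @examples
#' predicted_sigma(0.3, 1000)  # ~0.0095, i.e. E +/- 0.01
predicted_sigma <- function(sigma_tilde, n_p) {
  if (sigma_tilde < 0) stop("sigma_tilde must be non-negative")
  if (n_p < 1) stop("n_p must be at least 1 photon")
  sigma_tilde / sqrt(n_p)
}

#' Power-series efficiency grid
#'
#' `E_i = e_max (i/(n-1))^2`, denser near zero where the dFRET bound varies
#' fastest.
#'
#' @param n number of grid points.
#' @param e_max upper end of the grid (capped at 0.99).
#' @return Numeric vector of efficiencies.
#' @export
efficiency_grid <- function(n = 128, e_max = 0.99) {
  if (e_max > 0.99) stop("efficiency grid must stay within [0, 0.99]")
  e_max * (seq_len(n) - 1)^2 / (n - 1)^2
}

#' Precision-bound curves over a FRET-efficiency sweep
#'
#' Evaluates [delta_sigma()] and its decomposition over an efficiency grid at
#' fixed population fractions, system and background.  Deterministic; the
#' result is a plain data frame writable as CSV (see [write_curve_csv()]).
#'
#' @param e_grid efficiencies to evaluate (within `[0, 0.99]`).
#' @param f_d,f_a interacting fractions of the population template.
#' @param sys a [fret_system()].
#' @param bg background specification or `NULL`.
#' @param which estimators to tabulate (one or both of `"dfret"`,
#'   `"afret"`).
#' @param np_channels normalization scope, as in [delta_sigma()].
#' @return A data frame with columns `E`, `sigma_tilde`, `sigma_e`,
#'   `sigma_sbt`, `sigma_b`, `estimator`, `f_D`, `f_A`, `der`, `aer`, `eta`,
#'   `epsilon`, `beta`.
#' @export
sigma_sweep <- function(e_grid = efficiency_grid(), f_d = 1, f_a = 1,
                        sys = fret_system(), bg = NULL,
                        which = c("dfret", "afret"), np_channels = "all") {
  which <- match.arg(which, several.ok = TRUE)
  if (any(e_grid < 0 | e_grid > 0.99))
    stop("efficiency grid must lie within [0, 0.99]")
  beta <- if (!is.null(bg) && bg$type == "fraction") bg$beta else 0
  rows <- lapply(which, function(w) {
    res <- lapply(e_grid, function(e) {
      pop <- population_from_fractions(e, f_d, f_a)
      sigma_decomposition(pop, sys, 1, bg, w, np_channels)
    })
    data.frame(E = e_grid,
               sigma_tilde = vapply(res, `[[`, 0, "sigma_tilde"),
               sigma_e = vapply(res, `[[`, 0, "sigma_e"),
               sigma_sbt = vapply(res, `[[`, 0, "sigma_sbt"),
               sigma_b = vapply(res, `[[`, 0, "sigma_b"),
               estimator = w, f_D = f_d, f_A = f_a,
               der = sys$der, aer = sys$aer, eta = sys$eta,
               epsilon = sys$epsilon, beta = beta)
  })
  do.call(rbind, rows)
}
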