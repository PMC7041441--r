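#' Poisson replicate simulation of a three-cube acquisition
#'
#' Draws independent Poisson counts for each channel and replicate from the
#' expected channel means.  All randomness flows from the explicit seed, so
#' identical calls are bit-reproducible.
#'
#' @param means a [channel_triplet()] of expected means (scalar per
#'   channel).
#' @param n_rep number of replicates, >= 1.
#' @param seed integer random seed.
#' @return An object of class `replicate_set`: list with `counts` (an
#'   `n_rep x 3` integer matrix with columns `i_dd`, `i_da`, `i_aa`),
#'   `means`, `seed`.
#' @export
#' @examples
#' m <- channel_triplet(150, 50, 100)
#' r <- simulate_counts(m, n_rep = 1000, seed = 1)
#' colMeans(r$counts)
simulate_counts <- function(means, n_rep, seed) {
  stopifnot(inherits(means, "channel_triplet"), n_rep >= 1)
  mu <- c(means$i_dd[1], means$i_da[1], means$i_aa[1])
  set.seed(seed)
  counts <- cbind(i_dd = stats::rpois(n_rep, mu[1]),
                  i_da = stats::rpois(n_rep, mu[2]),
                  i_aa = stats::rpois(n_rep, mu[3]))
  structure(list(counts = counts, means = means, seed = seed),
            class = "replicate_set")
}

#' Empirical precision and bias of the seFRET estimators
#'
#' Unmixes every replicate and summarizes the estimator's sample standard
#' deviation, scaled to the photon-normalized precision
#' `sigma_tilde = sd * sqrt(N_P)` with `N_P` the sum of the generating
#' channel means (matching the analytic convention).  Replicates with an
#' invalid (flagged) estimate are excluded and counted.  The standard error
#' of `sigma_tilde` uses the normal-theory approximation
#' `SE(sd) = sd / sqrt(2 (n - 1))`.
#'
#' @param reps a [simulate_counts()] result.
#' @param sys the [fret_system()] used for unmixing.
#' @param which `"dfret"` or `"afret"`.
#' @param np_channels normalization scope, as in [delta_sigma()].
#' @return List with `sigma_tilde_emp`, `standard_error`, `mean_estimate`,
#'   `se_mean`, `n_valid`, `n_excluded`.
#' @export
empirical_sigma <- function(reps, sys = fret_system(),
                            which = c("dfret", "afret"),
                            np_channels = "all") {
  which <- match.arg(which)
  stopifnot(inherits(reps, "replicate_set"))
  obs <- channel_triplet(reps$counts[, "i_dd"], reps$counts[, "i_da"],
                         reps$counts[, "i_aa"], role = "counts")
  est <- unmix(obs, sys)
  vals <- if (which == "dfret") est$dfret else est$afret
  valid <- !is.na(vals)
  n_valid <- sum(valid)
  n <- length(vals)
  if (n_valid < n / 2)
    stop("degenerate regime: more than half of the replicates produced ",
         "invalid estimates (", n - n_valid, " of ", n, ")")
  if (n_valid < 100)
    stop("need at least 100 valid replicates, got ", n_valid)
  mu <- c(dd = reps$means$i_dd[1], da = reps$means$i_da[1],
          aa = reps$means$i_aa[1])
  np <- .np_count(mu, np_channels)
  s <- stats::sd(vals[valid])
  list(sigma_tilde_emp = s * sqrt(np),
       standard_error = s * sqrt(np) / sqrt(2 * (n_valid - 1)),
       mean_estimate = mean(vals[valid]),
       se_mean = s / sqrt(n_valid),
       n_valid = n_valid,
       n_excluded = n - n_valid)
}

#' Simulate a TCSPC decay histogram
#'
#' Multinomial draw of `n_photons` arrival times over the
#' [decay_model()] bin probabilities (fixed-total sampling, matching the
#' multinomial Fisher-information convention).
#'
#' @param model a [tcspc_model()].
#' @param f,e decay parameters, as in [decay_model()].
#' @param n_photons total photons in the histogram.
#' @param seed integer random seed.
#' @return Integer vector of per-bin counts summing to `n_photons`.
#' @export
simulate_decay <- function(model, f, e, n_photons, seed) {
  p <- decay_model(model, f, e)
  set.seed(seed)
  drop(stats::rmultinom(1, n_photons, p))
}

#' Maximum-likelihood fit of a TCSPC decay
#'
#' Maximizes the multinomial log-likelihood of a binned decay over the FRET
#' efficiency and signal fraction (and the background fraction when
#' `model$background_is_fit_param`).  Optimization uses `L-BFGS-B` from
#' four deterministic starting points; the best converged fit is returned.
#'
#' @param hist integer vector of per-bin counts (total >= 1000).
#' @param model a [tcspc_model()].
#' @return List with `e`, `f`, `b` (NA when not fitted), `loglik`,
#'   `convergence` (0 = success).
#' @export
fit_decay_mle <- function(hist, model) {
  stopifnot(inherits(model, "tcspc_model"), length(hist) == model$n_bins)
  if (sum(hist) < 1000)
    stop("decay fitting requires at least 1000 photons")
  fit_b <- model$background_is_fit_param
  nll <- function(th) {
    theta <- c(e = th[1], f = th[2])
    if (fit_b) theta <- c(theta, b = th[3])
    p <- .tcspc_probs_theta(theta, model)
    if (any(p[hist > 0] <= 0)) return(1e12)
    -sum(hist[hist > 0] * log(p[hist > 0]))
  }
  starts <- list(c(0.25, 0.25), c(0.25, 0.75), c(0.75, 0.25), c(0.75, 0.75))
  lower <- c(1e-6, 1e-6)
  upper <- c(0.99, 1)
  if (fit_b) {
    starts <- lapply(starts, c, 0.05)
    lower <- c(lower, 0)
    upper <- c(upper, 0.95)
  }
  best <- NULL
  diag_msgs <- character()
  for (s0 in starts) {
    fit <- tryCatch(
      stats::optim(s0, nll, method = "L-BFGS-B", lower = lower,
                   upper = upper),
      error = function(err) err)
    if (inherits(fit, "error")) {
      diag_msgs <- c(diag_msgs, conditionMessage(fit))
      next
    }
    if (fit$convergence != 0) {
      diag_msgs <- c(diag_msgs, paste("convergence code", fit$convergence))
      next
    }
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("decay fit failed from all starting points: ",
         paste(unique(diag_msgs), collapse = "; "))
  list(e = best$par[1], f = best$par[2],
       b = if (fit_b) best$par[3] else NA_real_,
       loglik = -best$value, convergence = best$convergence)
}

#' Synthetic imaging scene specification
#'
#' Per-pixel ground-truth maps for generating synthetic three-cube
#' acquisitions: FRET efficiency, interacting fractions, exposure, region
#' labels (`"donor_only"`, `"acceptor_only"`, `"mixed"`) and a relative
#' background fraction.  [default_scene()] builds a small test scene with a
#' donor-only strip, an acceptor-only strip and a mixed region with an
#' efficiency gradient.
#'
#' @param e_map,f_d_map,f_a_map numeric matrices (same dimensions) of
#'   per-pixel efficiency and interacting fractions.
#' @param exposure scalar or matrix of expected photons per donor.
#' @param regions character matrix of region labels.
#' @param beta relative background fraction in `[0, 1)`.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(e_map, f_d_map, f_a_map, exposure = 1,
                       regions = NULL, beta = 0) {
  dm <- dim(e_map)
  stopifnot(identical(dim(f_d_map), dm), identical(dim(f_a_map), dm))
  if (any(e_map < 0 | e_map > 1)) stop("e_map must lie in [0, 1]")
  if (any(f_d_map < 0 | f_d_map > 1) || any(f_a_map < 0 | f_a_map > 1))
    stop("fraction maps must lie in [0, 1]")
  if (beta < 0 || beta >= 1) stop("beta must lie in [0, 1)")
  if (is.null(regions))
    regions <- matrix("mixed", dm[1], dm[2])
  stopifnot(identical(dim(regions), dm),
            all(regions %in% c("donor_only", "acceptor_only", "mixed")))
  if (length(exposure) == 1) exposure <- matrix(exposure, dm[1], dm[2])
  structure(list(e_map = e_map, f_d_map = f_d_map, f_a_map = f_a_map,
                 exposure = exposure, regions = regions, beta = beta,
                 height = dm[1], width = dm[2]),
            class = "scene_spec")
}

#' @rdname scene_spec
#' @param height,width scene dimensions in pixels.
#' @param e_range efficiency range of the mixed-region gradient.
#' @param exposure_scalar expected photons per donor in the default scene.
#' @export
default_scene <- function(height = 24, width = 32, e_range = c(0.1, 0.8),
                          exposure_scalar = 50, beta = 0) {
  e_map <- matrix(0, height, width)
  f_d <- matrix(1, height, width)
  f_a <- matrix(1, height, width)
  regions <- matrix("mixed", height, width)
  strip <- max(2, floor(width / 8))
  regions[, seq_len(strip)] <- "donor_only"
  regions[, width - seq_len(strip) + 1] <- "acceptor_only"
  mixed_cols <- (strip + 1):(width - strip)
  grad <- seq(e_range[1], e_range[2], length.out = length(mixed_cols))
  for (j in seq_along(mixed_cols)) e_map[, mixed_cols[j]] <- grad[j]
  scene_spec(e_map, f_d, f_a, exposure = exposure_scalar,
             regions = regions, beta = beta)
}

## Per-pixel expected means for a scene (list of three matrices).
.scene_means <- function(scene, sys) {
  h <- scene$height; w <- scene$width
  mu <- list(i_dd = matrix(0, h, w), i_da = matrix(0, h, w),
             i_aa = matrix(0, h, w))
  bg <- if (scene$beta > 0) bg_fraction(scene$beta) else NULL
  for (i in seq_len(h)) for (j in seq_len(w)) {
    reg <- scene$regions[i, j]
    pop <- switch(reg,
      donor_only = sample_population(0, 100, 1, efficiency = 0),
      acceptor_only = sample_population(0, 1, 100, efficiency = 0),
      mixed = population_from_fractions(scene$e_map[i, j],
                                        max(scene$f_d_map[i, j], 1e-9),
                                        max(scene$f_a_map[i, j], 1e-9)))
    m <- channel_means(pop, sys, scene$exposure[i, j], bg)
    if (reg == "donor_only") {
      ## a donor-only sample has no acceptors: remove the acceptor signal
      sig_aa <- m$i_aa - attr(m, "background")[["aa"]]
      m$i_da <- m$i_da - sys$aer * sig_aa
      m$i_aa <- m$i_aa - sig_aa
    } else if (reg == "acceptor_only") {
      sig_dd <- m$i_dd - attr(m, "background")[["dd"]]
      m$i_da <- m$i_da - sys$der * sig_dd
      m$i_dd <- m$i_dd - sig_dd
    }
    mu$i_dd[i, j] <- m$i_dd; mu$i_da[i, j] <- m$i_da; mu$i_aa[i, j] <- m$i_aa
  }
  mu
}

#' Generate a synthetic three-cube image
#'
#' Renders per-pixel expected channel means for a [scene_spec()] under a
#' given crosstalk system, then adds Poisson noise.  Donor-only and
#' acceptor-only regions are directly usable for crosstalk calibration with
#' [calibrate_der_aer()].
#'
#' @param scene a [scene_spec()].
#' @param sys a [fret_system()].
#' @param seed integer random seed.
#' @param noise if `FALSE`, return the noise-free expected means as the
#'   image.
#' @return List with `counts` (array `height x width x 3`, channels
#'   `I^DD`, `I^DA`, `I^AA`), `means` (same layout, noise-free), and
#'   `truth` (the scene's ground-truth maps and region labels).
#' @export
synth_image <- function(scene, sys = fret_system(), seed = 1, noise = TRUE) {
  stopifnot(inherits(scene, "scene_spec"))
  mu <- .scene_means(scene, sys)
  h <- scene$height; w <- scene$width
  means <- array(c(mu$i_dd, mu$i_da, mu$i_aa), dim = c(h, w, 3),
                 dimnames = list(NULL, NULL, c("i_dd", "i_da", "i_aa")))
  counts <- means
  if (noise) {
    set.seed(seed)
    counts[] <- stats::rpois(length(means), means)
  }
  list(counts = counts, means = means,
       truth = list(e_map = scene$e_map, f_d_map = scene$f_d_map,
                    f_a_map = scene$f_a_map, regions = scene$regions,
                    beta = scene$beta))
}
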