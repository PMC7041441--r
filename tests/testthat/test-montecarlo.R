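test_that("Poisson replicate simulation is seeded and calibrated", {
  means <- channel_triplet(150, 50, 100)
  r1 <- simulate_counts(means, 1e4, seed = 1)
  r2 <- simulate_counts(means, 1e4, seed = 1)
  expect_identical(r1$counts, r2$counts)

  mu <- c(150, 50, 100)
  cm <- colMeans(r1$counts)
  for (k in 1:3)
    expect_lt(abs(cm[k] - mu[k]), 3 * sqrt(mu[k] / 1e4))

  z <- simulate_counts(channel_triplet(0, 0, 0), 100, seed = 2)
  expect_true(all(z$counts == 0))
})

test_that("empirical precision matches the analytic bound", {
  pop <- population_from_fractions(0.5, 0.5, 1)
  sys <- fret_system()
  means <- channel_means(pop, sys, exposure = 100)
  reps <- simulate_counts(means, 1e4, seed = 3)
  for (w in c("dfret", "afret")) {
    emp <- empirical_sigma(reps, sys, w)
    ana <- delta_sigma(pop, sys, 100, NULL, w)$sigma_tilde
    expect_lt(abs(emp$sigma_tilde_emp - ana), 3 * emp$standard_error)
  }
  # unbiased without background
  emp <- empirical_sigma(reps, sys, "dfret")
  expect_lt(abs(emp$mean_estimate - 0.25), 3 * emp$se_mean)
  expect_equal(emp$n_excluded, 0)
})

test_that("empirical bias matches the plug-in prediction under background", {
  pop <- population_from_fractions(0.5, 0.5, 1)
  sys <- fret_system()
  b <- 0.2 * channel_means(pop, sys, 100)$i_dd   # equal absolute counts
  bg <- bg_counts(b, b, b)
  reps <- simulate_counts(channel_means(pop, sys, 100, bg), 1e4, seed = 4)
  emp <- empirical_sigma(reps, sys, "dfret")
  pred <- expected_bias(pop, sys, 100, bg, "dfret")
  expect_gt(abs(pred), 0.01)   # the regime is genuinely biased
  expect_lt(abs((emp$mean_estimate - 0.25) - pred), 3 * emp$se_mean)
})

test_that("a degenerate low-count regime is reported, not summarized", {
  # aer = 2 with a dominant I^AA makes most cfret draws so negative that
  # the dFRET denominator goes non-positive
  means <- channel_triplet(1, 0.5, 5)
  reps <- simulate_counts(means, 500, seed = 5)
  expect_error(empirical_sigma(reps, fret_system(aer = 2), "dfret"),
               "degenerate")
})

test_that("decay simulation is exact-count, seeded and uniform under pure background", {
  m <- tcspc_model(tau0_ns = 3)
  h1 <- simulate_decay(m, 0.5, 0.5, 12345, seed = 6)
  h2 <- simulate_decay(m, 0.5, 0.5, 12345, seed = 6)
  expect_identical(h1, h2)
  expect_equal(sum(h1), 12345)

  mb <- tcspc_model(tau0_ns = 3, b_frac = 1)
  hb <- simulate_decay(mb, 0.5, 0.5, 256000, seed = 7)
  p <- 1 / 256
  expect_true(all(abs(hb - 1000) < 5 * sqrt(256000 * p * (1 - p))))
})

test_that("maximum-likelihood decay fitting is self-consistent", {
  m <- tcspc_model(tau0_ns = 3)
  # noise-free expected histogram: recover the generating parameters
  p <- decay_model(m, f = 0.5, e = 0.5)
  fit <- fit_decay_mle(round(1e6 * p), m)
  expect_equal(fit$e, 0.5, tolerance = 1e-3)
  expect_equal(fit$f, 0.5, tolerance = 1e-3)

  # single-exponential data: the fitted mean lifetime is tau0
  h <- simulate_decay(m, f = 1, e = 0, n_photons = 1e5, seed = 8)
  fit1 <- fit_decay_mle(h, m)
  tau_mean <- fit1$f * 3 * (1 - fit1$e) + (1 - fit1$f) * 3
  expect_equal(tau_mean, 3, tolerance = 3 * 3 / sqrt(1e5))

  expect_error(fit_decay_mle(rep(1, 256), m), "1000")
})

test_that("fitted background levels are recovered", {
  mb <- tcspc_model(tau0_ns = 3, b_frac = 0.2,
                    background_is_fit_param = TRUE)
  h <- simulate_decay(mb, f = 0.6, e = 0.6, n_photons = 2e5, seed = 9)
  fit <- fit_decay_mle(h, mb)
  expect_equal(fit$b, 0.2, tolerance = 0.05)
  expect_equal(fit$e, 0.6, tolerance = 0.05)
})

test_that("synthetic images carry usable ground truth and calibration regions", {
  sys <- fret_system(der = 0.3, aer = 0.5)
  scene <- default_scene(height = 16, width = 24, exposure_scalar = 200)
  img <- synth_image(scene, sys, seed = 10)
  img2 <- synth_image(scene, sys, seed = 10)
  expect_identical(img$counts, img2$counts)

  acc <- img$truth$regions == "acceptor_only"
  don <- img$truth$regions == "donor_only"
  expect_true(all(img$means[, , "i_dd"][acc] == 0))
  expect_true(all(img$means[, , "i_aa"][don] == 0))

  # noise-free unmix recovers the efficiency map exactly where f_D=f_A=1
  nf <- synth_image(default_scene(8, 16, exposure_scalar = 1e4), sys,
                    noise = FALSE)
  mixed <- nf$truth$regions == "mixed"
  est <- unmix(channel_triplet(nf$means[, , 1][mixed],
                               nf$means[, , 2][mixed],
                               nf$means[, , 3][mixed]), sys)
  expect_equal(est$dfret, nf$truth$e_map[mixed], tolerance = 1e-9)

  # crosstalk calibration from the synthetic calibration regions
  tri <- function(mask) channel_triplet(img$counts[, , 1][mask],
                                        img$counts[, , 2][mask],
                                        img$counts[, , 3][mask])
  cal <- calibrate_der_aer(tri(don), tri(acc))
  s_dd <- sum(img$counts[, , 1][don])
  s_aa <- sum(img$counts[, , 3][acc])
  se_der <- sys$der * sqrt(1 / (sys$der * s_dd) + 1 / s_dd)
  se_aer <- sys$aer * sqrt(1 / (sys$aer * s_aa) + 1 / s_aa)
  expect_lt(abs(cal$der - sys$der), 3 * se_der)
  expect_lt(abs(cal$aer - sys$aer), 3 * se_aer)
})

test_that("scene validation rejects inconsistent maps", {
  e <- matrix(0.5, 4, 4)
  expect_error(scene_spec(e, matrix(2, 4, 4), e), "fraction")
  expect_error(scene_spec(matrix(1.5, 4, 4), e, e), "e_map")
  expect_error(scene_spec(e, e, e, beta = 1), "beta")
})
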