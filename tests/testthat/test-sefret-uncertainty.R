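test_that("analytic error propagation matches a finite-difference oracle", {
  set.seed(7)
  for (i in 1:25) {
    pop <- rand_pop()
    sys <- rand_sys()
    bg <- if (i %% 3 == 0) bg_fraction(runif(1, 0, 0.5)) else NULL
    for (w in c("dfret", "afret")) {
      got <- delta_sigma(pop, sys, 1, bg, w)$sigma_tilde
      expect_equal(got, fd_sigma_oracle(pop, sys, 1, bg, w),
                   tolerance = 1e-6)
    }
  }
})

test_that("benchmark populations reproduce the hand-computed bounds", {
  pop <- population_from_fractions(0.5, 0.5, 1)
  # hand evaluation at means (150, 50, 100), N_P = 300:
  # dFRET: Var = (150/200^2)^2*50 + (50/200^2)^2*150 = 9.375e-4
  expect_equal(delta_sigma(pop, which = "dfret")$sigma_tilde,
               sqrt(9.375e-4 * 300), tolerance = 1e-12)
  # aFRET: Var = (1/100)^2*50 + (50/100^2)^2*100 = 7.5e-3
  expect_equal(delta_sigma(pop, which = "afret")$sigma_tilde,
               sqrt(7.5e-3 * 300), tolerance = 1e-12)
})

test_that("dFRET is infinitely precise at zero transfer in an ideal system", {
  pop <- population_from_fractions(0, 0.5, 1)
  expect_equal(delta_sigma(pop, which = "dfret")$sigma_tilde, 0)
})

test_that("sigma_tilde is invariant to exposure", {
  set.seed(8)
  for (i in 1:10) {
    pop <- rand_pop()
    sys <- rand_sys()
    bg <- if (i %% 2 == 0) bg_fraction(0.3) else NULL
    base <- delta_sigma(pop, sys, 1, bg, "dfret")$sigma_tilde
    for (lam in c(0.5, 2, 10)) {
      expect_equal(delta_sigma(pop, sys, lam, bg, "dfret")$sigma_tilde,
                   base, tolerance = 1e-9)
    }
  }
})

test_that("delta-method and Fisher bounds coincide without background", {
  set.seed(9)
  for (i in 1:50) {
    pop <- rand_pop()
    sys <- rand_sys()
    for (w in c("dfret", "afret")) {
      d <- delta_sigma(pop, sys, 1, NULL, w)$sigma_tilde
      f <- fisher_crlb(pop, sys, 1, NULL, w)$sigma_tilde
      expect_equal(f, d, tolerance = 1e-6)
    }
  }
})

test_that("the Fisher information matrix is well behaved", {
  pop <- population_from_fractions(0.5, 1, 1)
  J_ok <- fisher_crlb(pop, fret_system(), which = "dfret")
  expect_gt(J_ok$sigma_tilde, 0)
  # degenerate point: no sensitized photons in the ideal system
  expect_error(fisher_crlb(population_from_fractions(0, 1, 1),
                           fret_system(), which = "dfret"),
               "unavailable|degenerate")
})

test_that("the variance decomposition is an exact sum of squares", {
  # ideal system, no background: only the intrinsic term survives
  pop <- population_from_fractions(0.4, 0.7, 1)
  d0 <- sigma_decomposition(pop, fret_system(), 1, NULL, "dfret")
  expect_equal(d0$sigma_sbt, 0)
  expect_equal(d0$sigma_b, 0)
  expect_equal(d0$sigma_e, d0$sigma_tilde)

  # crosstalk without background: bleed-through term only
  dx <- sigma_decomposition(pop, fret_system_preset("confocal"), 1, NULL,
                            "dfret")
  expect_equal(dx$sigma_b, 0)
  expect_gt(dx$sigma_sbt, 0)

  set.seed(10)
  for (i in 1:20) {
    pop <- rand_pop()
    sys <- rand_sys()
    bg <- bg_fraction(runif(1, 0, 0.5))
    for (w in c("dfret", "afret")) {
      d <- sigma_decomposition(pop, sys, 1, bg, w)
      expect_equal(d$sigma_tilde^2,
                   d$sigma_e^2 + d$sigma_sbt^2 + d$sigma_b^2,
                   tolerance = 1e-9)
    }
  }
})

test_that("plug-in bias is zero without background and grows with constant-count background", {
  set.seed(11)
  for (i in 1:10) {
    pop <- rand_pop()
    sys <- rand_sys()
    expect_equal(expected_bias(pop, sys, 1, NULL, "dfret"), 0,
                 tolerance = 1e-12)
    expect_equal(expected_bias(pop, sys, 1, NULL, "afret"), 0,
                 tolerance = 1e-12)
  }

  # a background proportional to each channel's own signal cancels in the
  # ratio estimators (scale invariance), so it does not bias them
  pop <- population_from_fractions(0.5, 0.5, 1)
  expect_equal(expected_bias(pop, fret_system(), 1, bg_fraction(0.4),
                             "dfret"), 0, tolerance = 1e-12)

  # equal *absolute* background counts in each channel do bias the
  # estimators, increasingly so with the background level
  mu <- channel_means(pop, fret_system(), 1)
  for (e in c(0.2, 0.5, 0.8)) {
    p <- population_from_fractions(e, 0.5, 1)
    b <- vapply(c(0, 0.2, 0.4, 0.6), function(beta) {
      bb <- beta * mu$i_dd
      abs(expected_bias(p, fret_system(), 1, bg_counts(bb, bb, bb),
                        "dfret"))
    }, numeric(1))
    expect_true(all(diff(b) >= -1e-12))
    expect_gt(b[4], 0)
  }
})

test_that("photon budget and predicted sigma are consistent", {
  expect_identical(photon_budget(3, 0.05), 3600)
  expect_identical(photon_budget(0.5, 0.05), 100)
  expect_identical(photon_budget(1, 1), 1)
  expect_equal(photon_budget(sqrt(10.5), 1), 11)      # half-up rounding
  expect_equal(photon_budget(3, 0.05, round = FALSE), 3600)
  expect_error(photon_budget(0, 0.05), "positive")
  expect_error(photon_budget(3, 0), "positive")

  expect_equal(predicted_sigma(0.3, 1000), 0.3 / sqrt(1000))
  expect_equal(predicted_sigma(0.5, 1), 0.5)
  expect_error(predicted_sigma(0.3, 0.5), "at least 1")
  for (n in c(10, 100, 1e4))
    expect_equal(photon_budget(0.7, predicted_sigma(0.7, n)), n)
})

test_that("efficiency sweeps are clean and ordered", {
  sw <- sigma_sweep(efficiency_grid(128), f_d = 1, f_a = 1,
                    which = "dfret")
  expect_equal(nrow(sw), 128)
  expect_false(any(is.na(sw$sigma_tilde)))
  expect_equal(sw$sigma_tilde[1], 0)                 # E = 0 exactly
  # boundary trend: precision improves again approaching full transfer
  expect_lt(sw$sigma_tilde[nrow(sw)],
            sw$sigma_tilde[which.min(abs(sw$E - 0.5))])

  # dFRET has equal or better signal-to-noise than aFRET without
  # crosstalk: (f_D E)/sd_dfret >= (f_A E)/sd_afret pointwise; the raw
  # sigma_tilde ordering coincides when both estimate the same quantity
  # (f_D = f_A)
  for (fd in c(0.1, 0.5, 1)) for (fa in c(0.1, 0.5, 1)) {
    e <- efficiency_grid(16, 0.95)[-1]
    both <- sigma_sweep(e, f_d = fd, f_a = fa, which = c("dfret", "afret"))
    d <- both$sigma_tilde[both$estimator == "dfret"]
    a <- both$sigma_tilde[both$estimator == "afret"]
    expect_true(all(fd * e / d >= fa * e / a - 1e-9))
    if (fd == fa) expect_true(all(d <= a + 1e-9))
  }

  expect_error(sigma_sweep(c(0.5, 1.0)), "0.99")
})
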