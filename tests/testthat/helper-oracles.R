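# Shared generators and independent oracles for the test suite.

# Random interior parameter points (population + system), away from the
# degenerate boundaries.
rand_pop <- function() {
  population_from_fractions(runif(1, 0.05, 0.95),
                            f_d = runif(1, 0.1, 1),
                            f_a = runif(1, 0.1, 1),
                            n_pairs = 100)
}

rand_sys <- function(crosstalk = TRUE) {
  if (!crosstalk) return(fret_system())
  fret_system(der = runif(1, 0, 1), aer = runif(1, 0, 1),
              eta = runif(1, 0.1, 3), epsilon = runif(1, 0.3, 10))
}

# Independent delta-method oracle: propagate Poisson noise through the
# unmixing map using *numerical* central differences (step 1e-6 * mu) rather
# than the package's analytic partial derivatives.
fd_sigma_oracle <- function(pop, sys, exposure = 1, bg = NULL,
                            which = "dfret", np_channels = "all") {
  m <- channel_means(pop, sys, exposure, bg)
  mu <- c(m$i_dd, m$i_da, m$i_aa)
  est_at <- function(v) {
    e <- unmix(channel_triplet(v[1], v[2], v[3]), sys)
    if (which == "dfret") e$dfret else e$afret
  }
  v <- 0
  for (c in 1:3) {
    if (mu[c] <= 0) next
    h <- 1e-6 * mu[c]
    up <- mu; up[c] <- mu[c] + h
    dn <- mu; dn[c] <- mu[c] - h
    d <- (est_at(up) - est_at(dn)) / (2 * h)
    v <- v + d^2 * mu[c]
  }
  np <- if (np_channels == "all") sum(mu) else mu[1] + mu[2]
  sqrt(v * np)
}
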