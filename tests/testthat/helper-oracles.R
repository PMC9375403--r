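# Slow, independent reference computations used to check the quadrature
# implementations, plus small shared fixtures. All oracles integrate on a
# fine trapezoid grid and evaluate PCM probabilities through the plain-R
# category_probabilities() path, independent of the compiled likelihood.

# per-subject marginal log-likelihood by 2001-point trapezoid integration
grid_marginal_loglik <- function(data, thresholds, mu0 = 0, gamma = 0,
                                 sigma2 = 1, n_points = 2001) {
  if (inherits(thresholds, "item_bank")) thresholds <- thresholds$thresholds
  sdv <- sqrt(sigma2)
  th <- seq(-10 * sdv, 10 * sdv, length.out = n_points)
  dens <- dnorm(th, 0, sdv)
  vapply(seq_len(data$n), function(i) {
    mu <- mu0 + gamma * (if (is.null(data$group)) 0 else data$group[i])
    L <- dens
    for (j in seq_len(data$J)) {
      P <- category_probabilities(th + mu, thresholds[j, ])
      L <- L * P[, data$responses[i, j] + 1]
    }
    log(pracma::trapz(th, L))
  }, numeric(1))
}

# per-subject posterior mean by the same grid scheme
grid_eap <- function(data, thresholds, prior_mean, prior_var,
                     n_points = 2001) {
  if (inherits(thresholds, "item_bank")) thresholds <- thresholds$thresholds
  sdv <- sqrt(prior_var)
  th <- seq(prior_mean - 10 * sdv, prior_mean + 10 * sdv,
            length.out = n_points)
  dens <- dnorm(th, prior_mean, sdv)
  vapply(seq_len(data$n), function(i) {
    L <- dens
    for (j in seq_len(data$J)) {
      P <- category_probabilities(th, thresholds[j, ])
      L <- L * P[, data$responses[i, j] + 1]
    }
    sum(th * L) / sum(L)
  }, numeric(1))
}

# small deterministic trial dataset reused across estimation tests
make_test_trial <- function(J = 4, M = 3, n = 100, mu0 = 0.3, gamma = 0.4,
                            seed = 42, archetype = 2) {
  bank <- make_archetype_bank(J, M, archetype)
  set.seed(seed)
  list(bank = bank,
       data = simulate_trial(bank, trial_spec(n, mu0 = mu0, gamma = gamma)))
}
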