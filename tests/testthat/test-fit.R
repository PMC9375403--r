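test_that("identical arms yield a null treatment effect estimate", {
  bank <- make_archetype_bank(4, 3, 2)
  set.seed(21)
  arm <- simulate_responses(bank, rnorm(150, 0.2, 1))
  dup <- response_dataset(rbind(arm$responses, arm$responses), M = 3,
                          group = rep(0:1, each = 150))
  fit <- fit_random_pcm(dup, include_group = TRUE, fixed_items = bank,
                        options = fit_options(factr = 1e3))
  expect_true(fit$converged)
  expect_lt(abs(fit$gamma_hat), 1e-6)
})

test_that("the fitted likelihood dominates the generating parameters", {
  for (seed in 1:3) {
    tt <- make_test_trial(n = 80, mu0 = 0.2, gamma = 0.3, seed = seed)
    fit <- fit_random_pcm(tt$data, include_group = TRUE)
    expect_true(fit$converged)
    ll_true <- marginal_loglik(tt$data, list(thresholds = tt$bank, mu0 = 0.2,
                                             gamma = 0.3, sigma2 = 1))
    # refit parameterization: mu0 folded into centered thresholds
    ll_hat <- marginal_loglik(tt$data,
                              list(thresholds = fit$thresholds_hat - fit$mu0_hat,
                                   mu0 = 0, gamma = fit$gamma_hat,
                                   sigma2 = fit$sigma2_hat))
    expect_gte(ll_hat, ll_true - 1e-4)
    expect_equal(ll_hat, fit$loglik, tolerance = 1e-6)
  }
})

test_that("anchored estimation recovers the treatment effect", {
  bank <- make_archetype_bank(4, 3, 2)
  set.seed(33)
  trial <- simulate_trial(bank, trial_spec(1000, mu0 = 0, gamma = 0.5))
  fit <- fit_random_pcm(trial, include_group = TRUE, fixed_items = bank)
  expect_true(fit$converged)
  expect_lt(abs(fit$gamma_hat - 0.5), 0.10)   # ~2x the Monte-Carlo SD
  expect_true(is.finite(fit$se_gamma) && fit$se_gamma > 0)
  expect_identical(fit$thresholds_hat[1, 1], bank$thresholds[1, 1])
})

test_that("free-item calibration fits recover the generating thresholds", {
  bank <- make_archetype_bank(4, 3, 2)
  set.seed(44)
  cal <- simulate_responses(bank, rnorm(500, 0, 1))
  fit <- fit_random_pcm(cal, fix_latent_mean = TRUE)
  expect_true(fit$converged)
  expect_false(fit$fixed_items)
  expect_identical(fit$mu0_hat, 0)
  expect_lt(mean(abs(fit$thresholds_hat - bank$thresholds)), 0.3)
})

test_that("free-item trial fits identify the latent location by centering", {
  bank <- make_archetype_bank(4, 3, 2)
  set.seed(55)
  d <- simulate_responses(bank, rnorm(800, 2, 1))
  fit <- fit_random_pcm(d)
  expect_true(fit$converged)
  expect_equal(mean(fit$thresholds_hat), 0, tolerance = 1e-8)
  expect_lt(abs(fit$mu0_hat - 2), 0.25)
  expect_lt(abs(fit$sigma2_hat - 1), 0.35)
})

test_that("unobserved categories are flagged and bounded, not fatal", {
  bank <- make_archetype_bank(4, 3, 2)
  set.seed(66)
  d <- simulate_responses(bank, rnorm(120, -6, 0.3))  # top category unseen
  expect_true(any(tabulate(d$responses + 1L, 3) == 0))
  fit <- fit_random_pcm(d, fix_latent_mean = TRUE)
  expect_true("unobserved_category" %in% fit$flags)
  expect_true(all(abs(fit$thresholds_hat) <= fit_options()$delta_bound + 1e-9))
})

test_that("fits validate their inputs", {
  tt <- make_test_trial(n = 20)
  nogroup <- response_dataset(tt$data$responses, M = 3)
  expect_error(fit_random_pcm(nogroup, include_group = TRUE), "group")
  expect_error(fit_random_pcm(tt$data, fixed_items = matrix(0, 2, 2)),
               "J x")
  expect_error(fit_options(n_nodes = 10), "n_nodes")
})

test_that("fit reports round-trip as anchor input", {
  tt <- make_test_trial(n = 60)
  fit <- fit_random_pcm(tt$data, fix_latent_mean = TRUE)
  f <- withr::local_tempfile(fileext = ".txt")
  write_fit_report(fit, f)
  bank2 <- read_item_bank(paste0(f, ".bank.tsv"))
  expect_equal(bank2$thresholds, unname(fit$thresholds_hat),
               tolerance = 1e-8, ignore_attr = TRUE)
  refit <- fit_random_pcm(tt$data, include_group = TRUE, fixed_items = bank2)
  expect_true(refit$converged)
})
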