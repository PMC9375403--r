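quick_sc <- function(...) {
  scenario_spec(J = 4, M = 3, n_calibration = 100, n_trial = 50,
                n_replications = 4, seed = 123, ...)
}

test_that("replications are deterministic and order independent", {
  sc <- quick_sc(gamma = 0.2)
  r2a <- run_replication(sc, 2)
  r3 <- run_replication(sc, 3)
  r2b <- run_replication(sc, 2)
  expect_identical(r2a, r2b)
  expect_false(identical(r2a$effect, r3$effect))
  # four cells per replication
  expect_identical(nrow(r2a), 4L)
  expect_setequal(paste(r2a$approach, r2a$method),
                  c("non_calibrated wald_gamma", "non_calibrated ttest_eap",
                    "calibrated wald_gamma", "calibrated ttest_eap"))
})

test_that("an overwhelming effect is detected by all four cells", {
  sc <- scenario_spec(J = 4, M = 3, n_calibration = 100, n_trial = 100,
                      gamma = 3, n_replications = 1, seed = 7)
  rec <- run_replication(sc, 1)
  expect_true(all(rec$converged))
  expect_true(all(rec$p_value < 1e-6))
  expect_true(all(rec$effect > 1))
})

test_that("criteria are counted and summarized per cell", {
  records <- data.frame(
    approach = rep(c("calibrated", "non_calibrated"), each = 4),
    method = "wald_gamma",
    effect = c(0.2, 0.2, 0.2, 0.2, 0.1, 0.2, 0.3, 0.4),
    p_value = rep(c(0.01, 0.20, 0.03, 0.70), 2),
    converged = TRUE, replication = rep(1:4, 2))
  crit <- compute_criteria(records, gamma_true = 0.2)
  expect_equal(crit$rejection_rate, c(50, 50))
  cal <- crit[crit$approach == "calibrated", ]
  expect_equal(cal$bias, 0)
  expect_equal(cal$sd_estimates, 0)
  expect_equal(crit$criterion, rep("power", 2))
  expect_equal(compute_criteria(records, gamma_true = 0)$criterion,
               rep("type1_error", 2))
})

test_that("unusable replications are excluded with auditable counts", {
  records <- data.frame(
    approach = "calibrated", method = "wald_gamma",
    effect = c(0.1, 0.3, NA, 0.2), p_value = c(0.01, 0.2, NA, 0.04),
    converged = c(TRUE, TRUE, FALSE, TRUE), replication = 1:4)
  crit <- compute_criteria(records, 0.2)
  expect_equal(crit$n_used, 3)
  expect_equal(crit$n_flagged, 1)
  all_bad <- records; all_bad$converged <- FALSE
  expect_error(compute_criteria(all_bad, 0.2), "fewer than 2")
  expect_error(compute_criteria(records[0, ], 0.2), "usable|columns")
})

test_that("the grid runner produces one row per scenario and cell", {
  grid <- default_grid(n_replications = 2, seed = 9)[c(1, 13), ]
  grid$n_trial <- 50; grid$n_calibration <- 60
  out_dir <- withr::local_tempdir()
  res <- run_grid(grid, out_dir = out_dir, progress = FALSE)
  expect_equal(nrow(res), 8)   # 2 scenarios x 4 cells
  expect_true(all(c("type1_error", "power", "bias", "sd_estimates")
                  %in% names(res)))
  expect_true(file.exists(file.path(out_dir, "criteria.csv")))

  # execution order does not matter
  res_rev <- run_grid(grid[2:1, ], progress = FALSE)
  a <- res[res$J == grid$J[2] & res$M == grid$M[2], ]
  b <- res_rev[res_rev$J == grid$J[2] & res_rev$M == grid$M[2], ]
  expect_equal(a$power, b$power)
  expect_equal(a$type1_error, b$type1_error)
})

test_that("an empty scenario grid yields an empty table", {
  res <- run_grid(default_grid()[0, ], progress = FALSE)
  expect_equal(nrow(res), 0)
})

test_that("the default grid mirrors the headline design", {
  g <- default_grid()
  expect_equal(nrow(g), 36)
  expect_setequal(unique(g$J), c(4, 7, 10))
  expect_setequal(unique(g$n_trial), c(200, 500))
  expect_setequal(unique(g$mu), c(0, 0.5, 2))
  expect_true(all(g$archetype == 2 & g$n_calibration == 250 &
                    g$gamma == 0.2))
  expect_equal(anyDuplicated(g$seed), 0)
})

test_that("scenario and grid inputs are validated", {
  expect_error(scenario_spec(J = 5, M = 3, n_trial = 50), "'J'")
  expect_error(run_grid(data.frame(J = 4), progress = FALSE), "missing")
})
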