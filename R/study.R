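#' Define one simulation scenario
#'
#' A scenario is one cell of the simulation design: instrument (J, M,
#' archetype), calibration sample (size, latent variance; mean fixed at 0),
#' trial sample (per-arm size, latent mean `mu` of the placebo arm --
#' the mistargeting parameter -- and effect size `gamma`), and the
#' replication budget with its seed.
#'
#' @param J,M,archetype Instrument parameters, see [make_archetype_bank()].
#' @param n_calibration Calibration sample size.
#' @param calibration_variance Latent variance of the calibration sample.
#' @param n_trial Patients per arm in the trial.
#' @param mu Placebo-arm latent mean (0 = perfect targeting).
#' @param gamma Treatment effect (difference in latent means).
#' @param n_replications Number of Monte-Carlo replications.
#' @param seed Scenario seed; replication streams are derived from it, so
#'   replications can be computed in any order (or concurrently) with
#'   identical results.
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(J, M, archetype = 2, n_calibration = 250,
                          calibration_variance = 1, n_trial, mu = 0,
                          gamma = 0, n_replications = 500, seed = 1) {
  stopifnot(n_replications >= 1, n_calibration >= 2, n_trial >= 2)
  bank <- make_archetype_bank(J, M, archetype)   # validates J/M/archetype
  structure(list(J = J, M = M, archetype = archetype,
                 n_calibration = as.integer(n_calibration),
                 calibration_variance = calibration_variance,
                 n_trial = as.integer(n_trial), mu = mu, gamma = gamma,
                 n_replications = as.integer(n_replications),
                 seed = as.integer(seed), bank = bank),
            class = "scenario_spec")
}

# Derived per-replication seeds: a scenario-level stream is drawn once, so
# replication r is reproducible in isolation and independent of execution
# order. Within a replication, separate sub-seeds cover the calibration and
# trial draws.
replication_seeds <- function(scenario, replication) {
  stopifnot(replication >= 1, replication <= scenario$n_replications)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(scenario$seed)
  rep_seed <- sample.int(.Machine$integer.max - 1L,
                         scenario$n_replications)[replication]
  set.seed(rep_seed)
  sub <- sample.int(.Machine$integer.max - 1L, 2L)
  list(calibration = sub[1L], trial = sub[2L])
}

#' Run one replication of the calibrated vs non-calibrated comparison
#'
#' Generates a calibration sample (latent mean 0) and a two-arm trial
#' sample, then produces the four analysis cells:
#' * **calibrated**: item thresholds are estimated on the calibration sample
#'   (free items, latent mean fixed at 0) and anchored in the trial fits;
#' * **non-calibrated**: item thresholds are re-estimated on the trial data;
#' * within each approach, a **Wald** test of the treatment covariate and a
#'   **t-test** on EAP person estimates from a no-covariate fit.
#'
#' Cells whose fits fail or do not converge are flagged; remaining cells are
#' still produced.
#'
#' @param scenario A [scenario_spec()].
#' @param replication Replication index in `1..n_replications`.
#' @param options A [fit_options()].
#' @return A data.frame with one row per (approach, method): columns
#'   `approach`, `method`, `effect`, `p_value`, `converged`, `flags`.
#' @export
run_replication <- function(scenario, replication, options = fit_options()) {
  stopifnot(inherits(scenario, "scenario_spec"))
  seeds <- replication_seeds(scenario, replication)
  bank <- scenario$bank

  set.seed(seeds$calibration)
  cal <- simulate_responses(
    bank, draw_latent(population_spec(0, scenario$calibration_variance,
                                      scenario$n_calibration)))
  set.seed(seeds$trial)
  trial <- simulate_trial(
    bank, trial_spec(scenario$n_trial, mu0 = scenario$mu,
                     gamma = scenario$gamma))

  cal_fit <- tryCatch(
    fit_random_pcm(cal, fix_latent_mean = TRUE, options = options),
    error = function(e) NULL)
  cal_ok <- !is.null(cal_fit) && cal_fit$converged

  cell <- function(approach, method, fn) {
    res <- tryCatch(fn(), error = function(e) NULL)
    if (is.null(res)) {
      data.frame(approach = approach, method = method,
                 effect = NA_real_, p_value = NA_real_,
                 converged = FALSE, flags = "failed")
    } else {
      data.frame(approach = approach, method = method,
                 effect = res$comp$effect, p_value = res$comp$p_value,
                 converged = res$converged,
                 flags = paste(res$flags, collapse = ";"))
    }
  }

  wald_cell <- function(fixed) function() {
    fit <- fit_random_pcm(trial, include_group = TRUE, fixed_items = fixed,
                          options = options)
    ok <- fit$converged && (is.null(fixed) || cal_ok)
    list(comp = wald_group_test(fit), converged = ok,
         flags = union(fit$flags, if (!is.null(fixed) && !cal_ok) "calibration_failed"))
  }
  ttest_cell <- function(fixed) function() {
    fit <- fit_random_pcm(trial, fixed_items = fixed, options = options)
    eap <- eap_latent(trial, fit, n_nodes = options$n_nodes)
    ok <- fit$converged && (is.null(fixed) || cal_ok)
    list(comp = ttest_eap(eap, trial$group), converged = ok,
         flags = union(fit$flags, if (!is.null(fixed) && !cal_ok) "calibration_failed"))
  }

  anchor <- if (cal_ok) as_item_bank(cal_fit) else NULL
  out <- rbind(
    cell("non_calibrated", "wald_gamma", wald_cell(NULL)),
    cell("non_calibrated", "ttest_eap", ttest_cell(NULL)),
    if (cal_ok) cell("calibrated", "wald_gamma", wald_cell(anchor))
    else data.frame(approach = "calibrated", method = "wald_gamma",
                    effect = NA_real_, p_value = NA_real_,
                    converged = FALSE, flags = "calibration_failed"),
    if (cal_ok) cell("calibrated", "ttest_eap", ttest_cell(anchor))
    else data.frame(approach = "calibrated", method = "ttest_eap",
                    effect = NA_real_, p_value = NA_real_,
                    converged = FALSE, flags = "calibration_failed")
  )
  out$replication <- replication
  out
}

#' Run every replication of a scenario
#'
#' @param scenario A [scenario_spec()].
#' @param options A [fit_options()].
#' @param progress Print a dot every 25 replications.
#' @return Long data.frame of [run_replication()] records.
#' @export
run_scenario <- function(scenario, options = fit_options(), progress = FALSE) {
  recs <- vector("list", scenario$n_replications)
  for (r in seq_len(scenario$n_replications)) {
    recs[[r]] <- run_replication(scenario, r, options)
    if (progress && r %% 25L == 0L) message("  replication ", r, "/",
                                            scenario$n_replications)
  }
  do.call(rbind, recs)
}

#' Operating characteristics over replications
#'
#' For each (approach, method) cell, computes over the converged
#' replications: the rejection rate of the null at level `alpha` (in %,
#' interpreted as type-I error when `gamma_true = 0` and as power
#' otherwise), the position bias `mean(effect - gamma_true)` (signed, with
#' its absolute value alongside since sign conventions vary), and the SD of
#' the effect estimates. Counts of used and flagged replications are
#' reported so exclusions are auditable.
#'
#' @param records Long data.frame from [run_scenario()].
#' @param gamma_true True effect size under which the records were
#'   generated.
#' @param alpha Two-sided significance level.
#' @return Data.frame with one row per (approach, method): columns
#'   `approach`, `method`, `criterion` (`"type1_error"` or `"power"`),
#'   `rejection_rate`, `bias`, `abs_bias`, `sd_estimates`, `n_used`,
#'   `n_flagged`.
#' @export
compute_criteria <- function(records, gamma_true, alpha = 0.05) {
  needed <- c("approach", "method", "effect", "p_value", "converged")
  if (!all(needed %in% names(records)))
    stop("'records' must contain columns: ", paste(needed, collapse = ", "))
  if (nrow(records) == 0L) stop("no usable replication records")
  cells <- unique(records[, c("approach", "method")])
  out <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- records[records$approach == cells$approach[i] &
                     records$method == cells$method[i], ]
    ok <- sub[sub$converged & is.finite(sub$p_value), ]
    if (nrow(ok) < 2L)
      stop("fewer than 2 usable replications for cell ",
           cells$approach[i], " / ", cells$method[i])
    data.frame(
      approach = cells$approach[i], method = cells$method[i],
      criterion = if (gamma_true == 0) "type1_error" else "power",
      rejection_rate = 100 * mean(ok$p_value < alpha),
      bias = mean(ok$effect - gamma_true),
      abs_bias = abs(mean(ok$effect - gamma_true)),
      sd_estimates = stats::sd(ok$effect),
      n_used = nrow(ok), n_flagged = nrow(sub) - nrow(ok))
  })
  do.call(rbind, out)
}

#' Default scenario grid of the study
#'
#' The 36 headline scenarios: all combinations of J in {4, 7, 10}, M in
#' {3, 5}, per-arm trial size in {200, 500} and trial latent mean `mu` in
#' {0, 0.5, 2}, with the second archetype, a calibration sample of 250
#' (variance 1) and effect size 0.2 (rejection under `gamma = 0` supplies
#' the type-I error for the same cell).
#'
#' @param n_replications Replications per scenario.
#' @param seed Base seed; scenario i uses `seed + i - 1` for its `gamma = 0`
#'   run and `seed + i - 1 + 10000` for its `gamma` run.
#' @return Data.frame of scenario parameters.
#' @export
default_grid <- function(n_replications = 500, seed = 1) {
  g <- expand.grid(J = c(4, 7, 10), M = c(3, 5), n_trial = c(200, 500),
                   mu = c(0, 0.5, 2), KEEP.OUT.ATTRS = FALSE)
  g <- g[order(g$J, g$M, g$n_trial, g$mu), ]
  rownames(g) <- NULL
  g$archetype <- 2
  g$n_calibration <- 250
  g$calibration_variance <- 1
  g$gamma <- 0.2
  g$n_replications <- n_replications
  g$seed <- seed + seq_len(nrow(g)) - 1L
  g
}

#' Run a grid of scenarios and tabulate the four criteria
#'
#' For each scenario row, runs the replication loop twice -- once with
#' `gamma = 0` (type-I error) and once with the scenario's `gamma` (power,
#' bias, SD) -- and combines the criteria into one row per
#' (scenario, approach, method), mirroring the usual presentation of such
#' simulation studies.
#'
#' @param grid Data.frame of scenarios, as from [default_grid()] or
#'   [read_study_config()]; needs columns `J`, `M`, `archetype`,
#'   `n_calibration`, `calibration_variance`, `n_trial`, `mu`, `gamma`,
#'   `n_replications`, `seed`.
#' @param options A [fit_options()].
#' @param alpha Significance level.
#' @param out_dir Optional directory; writes `criteria.csv` and, if
#'   `keep_replications`, `replications.csv`.
#' @param keep_replications Also return/write the long per-replication
#'   records.
#' @param progress Log one message per scenario.
#' @return Data.frame of criteria (invisibly also written to `out_dir`);
#'   when `keep_replications`, a list `list(criteria, replications)`.
#' @export
run_grid <- function(grid, options = fit_options(), alpha = 0.05,
                     out_dir = NULL, keep_replications = FALSE,
                     progress = TRUE) {
  needed <- c("J", "M", "archetype", "n_calibration", "calibration_variance",
              "n_trial", "mu", "gamma", "n_replications", "seed")
  miss <- setdiff(needed, names(grid))
  if (length(miss) > 0L)
    stop("scenario grid is missing column(s): ", paste(miss, collapse = ", "))

  crit_rows <- list(); rep_rows <- list()
  for (i in seq_len(nrow(grid))) {
    row <- grid[i, ]
    if (progress)
      message(sprintf(
        "scenario %d/%d: J=%g M=%g arch=%g n_trial=%g mu=%g gamma=%g (%g reps)",
        i, nrow(grid), row$J, row$M, row$archetype, row$n_trial, row$mu,
        row$gamma, row$n_replications))
    runs <- list(type1 = 0, power = row$gamma)
    pieces <- list()
    for (nm in names(runs)) {
      gam <- runs[[nm]]
      if (nm == "power" && gam == 0) next   # null scenario: type-I only
      sc <- scenario_spec(row$J, row$M, row$archetype, row$n_calibration,
                          row$calibration_variance, row$n_trial, row$mu,
                          gamma = gam,
                          n_replications = row$n_replications,
                          seed = row$seed + if (nm == "power") 10000L else 0L)
      recs <- run_scenario(sc, options)
      crit <- compute_criteria(recs, gamma_true = gam, alpha = alpha)
      pieces[[nm]] <- crit
      if (keep_replications) {
        recs$scenario <- i; recs$gamma_true <- gam
        rep_rows[[paste(i, nm)]] <- recs
      }
    }
    combined <- pieces[[1]][, c("approach", "method")]
    combined <- cbind(scenario = i, row[rep(1, nrow(combined)), needed],
                      combined, row.names = NULL)
    combined$type1_error <- pieces$type1$rejection_rate
    if (!is.null(pieces$power)) {
      combined$power <- pieces$power$rejection_rate
      combined$bias <- pieces$power$bias
      combined$abs_bias <- pieces$power$abs_bias
      combined$sd_estimates <- pieces$power$sd_estimates
      combined$n_used <- pieces$power$n_used
      combined$n_flagged <- pieces$power$n_flagged
    }
    crit_rows[[i]] <- combined
  }
  criteria <- if (length(crit_rows)) do.call(rbind, crit_rows) else
    data.frame(scenario = integer(0))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(criteria, file.path(out_dir, "criteria.csv"),
                     row.names = FALSE)
    if (keep_replications && length(rep_rows))
      utils::write.csv(do.call(rbind, rep_rows),
                       file.path(out_dir, "replications.csv"),
                       row.names = FALSE)
  }
  if (keep_replications)
    list(criteria = criteria,
         replications = if (length(rep_rows)) do.call(rbind, rep_rows) else NULL)
  else criteria
}
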