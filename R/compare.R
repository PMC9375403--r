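#' Wald test of the treatment effect from a group-covariate fit
#'
#' Tests the nullity of the treatment effect `gamma` with the statistic
#' `gamma_hat / SE(gamma_hat)` referred to the standard normal distribution
#' (two-sided), the usual reference for marginal maximum likelihood
#' estimates.
#'
#' @param fit A converged `pcm_fit` with a group covariate and a finite
#'   `se_gamma`.
#' @return A `comparison_result`: list with `method = "wald_gamma"`,
#'   `effect` (`gamma_hat`, logit scale), `statistic`, `df` (`NA`),
#'   `p_value`.
#' @export
wald_group_test <- function(fit) {
  stopifnot(inherits(fit, "pcm_fit"))
  if (!fit$include_group) stop("fit has no group covariate")
  if (!fit$converged) stop("fit did not converge")
  if (!is.finite(fit$se_gamma) || fit$se_gamma <= 0)
    stop("fit has no usable standard error for gamma")
  z <- fit$gamma_hat / fit$se_gamma
  structure(list(method = "wald_gamma", effect = fit$gamma_hat,
                 statistic = z, df = NA_real_,
                 p_value = 2 * pnorm(-abs(z))),
            class = "comparison_result")
}

#' Two-sample t-test on EAP latent trait estimates
#'
#' Compares the expected a posteriori person estimates between arms with a
#' Student t-test (pooled variance; arms are equal-sized by design here, in
#' which case pooled and Welch coincide in spirit -- Welch is available
#' behind `var_equal = FALSE`).
#'
#' @param eap An [eap_latent()] result.
#' @param group 0/1 arm labels, both arms non-empty.
#' @param var_equal Pooled-variance Student t-test (default) or Welch.
#' @return A `comparison_result` with `method = "ttest_eap"`, `effect`
#'   (mean EAP in arm 1 minus arm 0), `statistic`, `df`, `p_value`.
#' @export
ttest_eap <- function(eap, group, var_equal = TRUE) {
  stopifnot(inherits(eap, "eap_result"))
  group <- as.integer(group)
  if (length(group) != length(eap$theta_hat) || !all(group %in% c(0L, 1L)))
    stop("'group' must be a 0/1 vector matching the EAP estimates")
  x0 <- eap$theta_hat[group == 0L]
  x1 <- eap$theta_hat[group == 1L]
  if (!length(x0) || !length(x1)) stop("both arms must be non-empty")
  effect <- mean(x1) - mean(x0)
  if (stats::sd(c(x0 - mean(x0), x1 - mean(x1))) == 0) {
    # degenerate: no within-arm variability
    if (effect == 0)
      return(structure(list(method = "ttest_eap", effect = 0, statistic = 0,
                            df = length(group) - 2, p_value = 1,
                            degenerate = TRUE),
                       class = "comparison_result"))
    return(structure(list(method = "ttest_eap", effect = effect,
                          statistic = sign(effect) * Inf,
                          df = length(group) - 2, p_value = 0,
                          degenerate = TRUE),
                     class = "comparison_result"))
  }
  tt <- stats::t.test(x1, x0, var.equal = var_equal)
  structure(list(method = "ttest_eap", effect = effect,
                 statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, degenerate = FALSE),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: effect = %.4f, statistic = %.4f%s, p = %.4g\n",
              x$method, x$effect, x$statistic,
              if (is.finite(x$df)) sprintf(" (df = %g)", x$df) else "",
              x$p_value))
  invisible(x)
}
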