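#' Population and trial specifications
#'
#' `population_spec()` describes a single normal latent-trait population,
#' used for calibration samples (mean 0 by convention, variance 1 or 2).
#' `trial_spec()` describes a two-arm parallel-group trial: the placebo arm
#' has latent mean `mu0`, the treated arm `mu0 + gamma`, both with the same
#' within-group variance (1 by default), so `gamma` is a standardized mean
#' difference. Arms are always of equal size.
#'
#' @param mean Latent mean on the logit scale.
#' @param variance Latent variance (`>= 0`; 0 gives a degenerate population).
#' @param n Sample size (`>= 1`).
#' @return A `population_spec` / `trial_spec` list.
#' @export
population_spec <- function(mean = 0, variance = 1, n) {
  stopifnot(is.finite(mean), is.finite(variance), variance >= 0,
            n >= 1, n == round(n))
  structure(list(mean = mean, variance = variance, n = as.integer(n)),
            class = "population_spec")
}

#' @rdname population_spec
#' @param n_per_group Patients per arm (`>= 2`).
#' @param mu0 Placebo-arm latent mean (mistargeting parameter).
#' @param gamma Treatment effect: difference in latent means between arms.
#' @export
trial_spec <- function(n_per_group, mu0 = 0, gamma = 0, variance = 1) {
  stopifnot(is.finite(mu0), is.finite(gamma), is.finite(variance),
            variance > 0, n_per_group >= 2, n_per_group == round(n_per_group))
  structure(list(n_per_group = as.integer(n_per_group), mu0 = mu0,
                 gamma = gamma, variance = variance),
            class = "trial_spec")
}

#' Draw latent traits for a population
#'
#' Draws from `Normal(mean, variance)` using R's global random number
#' stream, so results are reproducible given `set.seed()`.
#'
#' @param spec A [population_spec()].
#' @return Numeric vector of length `spec$n`.
#' @export
draw_latent <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  rnorm(spec$n, spec$mean, sqrt(spec$variance))
}

#' Bundle a response matrix with its simulation metadata
#'
#' @param responses Integer `N x J` matrix with entries in `0..M-1`.
#' @param M Number of response categories (kept explicitly because the top
#'   category may be unobserved in a finite sample).
#' @param theta_true Optional true latent traits (simulation only; the
#'   estimation functions never read it).
#' @param group Optional arm labels in `{0, 1}`.
#' @return An object of class `response_dataset`.
#' @export
response_dataset <- function(responses, M, theta_true = NULL, group = NULL) {
  responses <- as.matrix(responses)
  storage.mode(responses) <- "integer"
  M <- as.integer(M)
  if (anyNA(responses)) stop("missing responses are not supported")
  if (any(responses < 0L) || any(responses > M - 1L))
    stop("responses must lie in 0..M-1")
  if (!is.null(group)) {
    group <- as.integer(group)
    if (length(group) != nrow(responses) || !all(group %in% c(0L, 1L)))
      stop("'group' must be a 0/1 vector with one entry per subject")
  }
  if (!is.null(theta_true) && length(theta_true) != nrow(responses))
    stop("'theta_true' must have one entry per subject")
  structure(
    list(responses = responses, M = M, J = ncol(responses),
         n = nrow(responses), theta_true = theta_true, group = group),
    class = "response_dataset"
  )
}

#' @export
print.response_dataset <- function(x, ...) {
  cat(sprintf("response_dataset: %d subjects x %d items, categories 0..%d%s\n",
              x$n, x$J, x$M - 1L,
              if (!is.null(x$group)) sprintf(" (two arms: %d / %d)",
                                             sum(x$group == 0L), sum(x$group == 1L))
              else ""))
  invisible(x)
}

#' Simulate item responses from a partial credit model
#'
#' Each response is drawn independently from the category probabilities of
#' the item at the subject's latent trait value.
#'
#' @param bank An [item_bank()].
#' @param theta Numeric vector of latent traits.
#' @param group Optional 0/1 arm labels carried into the dataset.
#' @return A [response_dataset()] carrying `theta` as `theta_true`.
#' @export
simulate_responses <- function(bank, theta, group = NULL) {
  stopifnot(inherits(bank, "item_bank"))
  if (!all(is.finite(theta))) stop("'theta' must be finite")
  N <- length(theta)
  X <- matrix(0L, N, bank$J)
  for (j in seq_len(bank$J)) {
    p <- category_probabilities(theta, bank$thresholds[j, ])
    if (!is.matrix(p)) p <- matrix(p, nrow = 1L)
    cp <- p
    for (k in 2:bank$M) cp[, k] <- cp[, k - 1L] + p[, k]
    u <- runif(N)
    X[, j] <- rowSums(u > cp[, -bank$M, drop = FALSE])
  }
  response_dataset(X, M = bank$M, theta_true = theta, group = group)
}

#' Simulate a two-arm trial
#'
#' Draws `n_per_group` placebo patients with latent traits
#' `N(mu0, variance)` and `n_per_group` treated patients with
#' `N(mu0 + gamma, variance)`, then generates their item responses.
#'
#' @param bank An [item_bank()].
#' @param spec A [trial_spec()].
#' @return A [response_dataset()] with `group` labels (0 placebo, 1 treated).
#' @export
simulate_trial <- function(bank, spec) {
  stopifnot(inherits(spec, "trial_spec"))
  n <- spec$n_per_group
  sdv <- sqrt(spec$variance)
  theta <- c(rnorm(n, spec$mu0, sdv), rnorm(n, spec$mu0 + spec$gamma, sdv))
  simulate_responses(bank, theta, group = rep(0:1, each = n))
}

#' Read and write response datasets as wide CSV
#'
#' One row per patient with columns `id`, `group` (omitted when absent) and
#' `item1 .. itemJ` -- the layout consumed by most psychometric software.
#'
#' @param data A [response_dataset()].
#' @param file Path to write to / read from.
#' @param M Number of response categories; by default inferred as
#'   `max(responses) + 1` when reading.
#' @return `write_responses()` returns `file` invisibly; `read_responses()`
#'   a [response_dataset()].
#' @export
write_responses <- function(data, file) {
  stopifnot(inherits(data, "response_dataset"))
  df <- data.frame(id = seq_len(data$n))
  if (!is.null(data$group)) df$group <- data$group
  resp <- as.data.frame(data$responses)
  names(resp) <- paste0("item", seq_len(data$J))
  utils::write.csv(cbind(df, resp), file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_responses
#' @export
read_responses <- function(file, M = NULL) {
  df <- utils::read.csv(file)
  items <- grep("^item[0-9]+$", names(df), value = TRUE)
  if (length(items) == 0L) stop("no 'item*' columns found in ", file)
  X <- as.matrix(df[, items, drop = FALSE])
  dimnames(X) <- NULL
  if (is.null(M)) M <- max(X) + 1L
  response_dataset(X, M = M,
                   group = if ("group" %in% names(df)) df$group else NULL)
}
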