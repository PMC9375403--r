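#' Read a study configuration file
#'
#' The configuration is a small hierarchical YAML file; vector-valued keys
#' are crossed into a scenario grid. Example:
#'
#' ```yaml
#' instrument: {J: [4, 10], M: 3, archetype: 2}
#' calibration: {N: 250, variance: 1}
#' trial: {N: [200, 500], mu: [0, 2], gamma: 0.2}
#' run: {reps: 500, seed: 1}
#' ```
#'
#' @param path Path to the YAML file.
#' @return A scenario grid data.frame suitable for [run_grid()], with the
#'   run-level settings (`alpha`, `n_nodes`) attached as attributes when
#'   present.
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  # YAML 1.1 readers coerce a bare key `N` to boolean FALSE; undo that
  for (section in names(cfg))
    names(cfg[[section]])[names(cfg[[section]]) == "FALSE"] <- "N"
  need <- function(section, key, default = NULL) {
    val <- cfg[[section]][[key]]
    if (is.null(val)) {
      if (is.null(default))
        stop(sprintf("config is missing required key '%s.%s'", section, key))
      val <- default
    }
    if (!is.numeric(val))
      stop(sprintf("config key '%s.%s' must be numeric", section, key))
    val
  }
  for (section in names(cfg)) {
    if (!section %in% c("instrument", "calibration", "trial", "run"))
      stop(sprintf("unknown config section '%s'", section))
  }
  g <- expand.grid(
    J = need("instrument", "J"),
    M = need("instrument", "M"),
    archetype = need("instrument", "archetype", 2),
    n_calibration = need("calibration", "N"),
    calibration_variance = need("calibration", "variance", 1),
    n_trial = need("trial", "N"),
    mu = need("trial", "mu", 0),
    gamma = need("trial", "gamma"),
    KEEP.OUT.ATTRS = FALSE
  )
  g$n_replications <- need("run", "reps", 500)[1]
  seed <- need("run", "seed", 1)[1]
  g$seed <- seed + seq_len(nrow(g)) - 1L
  attr(g, "alpha") <- need("run", "alpha", 0.05)[1]
  attr(g, "n_nodes") <- need("run", "nodes", 21)[1]
  g
}
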