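#' Simulation configuration
#'
#' Assembles and validates the full description of an experiment: the
#' population, the initial and noise distributions, the interaction
#' algorithm and its parameters, the meeting pattern, and the schedule.
#' The seed fully determines the output of [run_simulation()].
#'
#' Meeting patterns:
#' \describe{
#'   \item{`well_mixed`}{each observer draws a uniformly random partner
#'     other than itself, every round.}
#'   \item{`oracle_independent`}{each observer draws a random partner
#'     index, but the partner's state is supplied as a fresh unbiased
#'     draw with that partner's current exact variance, so the
#'     independence assumption of the analysis holds by construction.
#'     Supported for `conf` and `opt_gaussian`.}
#'   \item{`round_robin_pairs`}{a fresh random perfect matching every
#'     round; both members of a pair observe each other (the synchronous
#'     round model behind the doubling bound). With an odd number of
#'     agents one agent sits out per round.}
#'   \item{`hypercube`}{deterministic complementary matching: in round
#'     `t` agent `i` is paired with `i XOR 2^(t mod log2 n)`. Requires
#'     the total number of agents to be a power of 2. Partners met under
#'     this schedule carry information over disjoint halves of the
#'     population, which is what lets the correlation-corrected rule
#'     disseminate all initial information exactly.}
#' }
#'
#' Algorithms: `"conf"` (confidence sharing), `"opt_gaussian"`
#' (closed-form Gaussian Bayes update; identical arithmetic to `conf`
#' under `w = 1/var`), `"opt_grid"` (full gridded-pdf Bayes update),
#' `"linear"` (constant combination weight `alpha`), `"conf_dynamic"`
#' (confidence sharing with the obsolescence bit), `"conf_corrected"`
#' (correlation-corrected fusion with exact provenance-tracked
#' correlations; forces provenance tracking).
#'
#' @param n_agents Number of mobile agents (>= 2).
#' @param initial_specs A single [make_distribution()] spec (recycled)
#'   or a list of one spec per agent.
#' @param noise_spec Measurement-noise [make_distribution()] spec
#'   (`point_mass` for a noiseless channel).
#' @param algorithm One of the algorithm names above.
#' @param meeting_pattern One of the meeting patterns above.
#' @param rounds Number of interaction rounds (>= 0).
#' @param replicates Number of independent replicate populations.
#' @param seed Integer seed; fully determines the run.
#' @param n_environment Number of immobile environment agents appended
#'   after the mobile ones; they never move or update memory and are
#'   positioned at the current target plus an offset drawn once from
#'   `env_spec`.
#' @param env_spec Distribution of environment-agent offsets (default: a
#'   point mass, i.e. environment agents sit exactly on the target with
#'   infinite confidence).
#' @param alpha Combination weight for `algorithm = "linear"`.
#' @param confidence_noise_sd Standard deviation of the multiplicative
#'   noise applied to every transmitted confidence (see
#'   [transmit_confidence()]).
#' @param obsolescence_tau Obsolescence horizon (rounds) for the
#'   freshness bit of `conf_dynamic`.
#' @param bias Multiplicative perception bias, scalar or one per agent.
#' @param target_theta Target value the agents estimate.
#' @param theta_schedule Optional data.frame with columns `round`,
#'   `theta`: the target moves to `theta` at the start of that round
#'   (dynamic environment).
#' @param record_every Record metrics every this many rounds (round 0
#'   and the final round are always recorded).
#' @param track_provenance Track exact affine coefficients of every
#'   position over the initial positions and noise draws, enabling
#'   [audit_provenance()] and [capacity_audit()]. Limited to linear
#'   update rules and moderate problem sizes.
#' @param grid_points,grid_half_width_sigmas Grid resolution for
#'   `algorithm = "opt_grid"`.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_agents,
                       initial_specs,
                       noise_spec,
                       algorithm = c("conf", "opt_gaussian", "opt_grid",
                                     "linear", "conf_dynamic",
                                     "conf_corrected"),
                       meeting_pattern = c("well_mixed",
                                           "oracle_independent",
                                           "round_robin_pairs",
                                           "hypercube"),
                       rounds = 10,
                       replicates = 1,
                       seed = 1,
                       n_environment = 0,
                       env_spec = NULL,
                       alpha = 0.5,
                       confidence_noise_sd = 0,
                       obsolescence_tau = Inf,
                       bias = 1,
                       target_theta = 0,
                       theta_schedule = NULL,
                       record_every = 1,
                       track_provenance = FALSE,
                       grid_points = 1024,
                       grid_half_width_sigmas = 8) {
  algorithm <- match.arg(algorithm)
  meeting_pattern <- match.arg(meeting_pattern)
  if (!is.numeric(n_agents) || n_agents < 2 || n_agents != round(n_agents)) {
    stop("'n_agents' must be an integer >= 2", call. = FALSE)
  }
  n_agents <- as.integer(n_agents)
  n_environment <- as.integer(n_environment)
  if (n_environment < 0) stop("'n_environment' must be >= 0", call. = FALSE)
  if (is_dist_spec(initial_specs)) {
    initial_specs <- rep(list(initial_specs), n_agents)
  }
  if (!is.list(initial_specs) || length(initial_specs) != n_agents ||
      !all(vapply(initial_specs, is_dist_spec, logical(1)))) {
    stop("'initial_specs' must be one dist_spec or a list of one per agent",
         call. = FALSE)
  }
  if (any(vapply(initial_specs, function(s) s$variance, numeric(1)) <= 0)) {
    stop("initial distributions must have positive variance", call. = FALSE)
  }
  stopifnot_spec(noise_spec)
  if (is.null(env_spec)) env_spec <- make_distribution("point_mass")
  stopifnot_spec(env_spec)
  if (rounds < 0 || rounds != round(rounds)) {
    stop("'rounds' must be a non-negative integer", call. = FALSE)
  }
  if (replicates < 1) stop("'replicates' must be >= 1", call. = FALSE)
  n_total <- n_agents + n_environment
  if (meeting_pattern == "hypercube" &&
      (n_total < 2 || bitwAnd(n_total, n_total - 1L) != 0L)) {
    stop("the hypercube pattern requires the total number of agents to be ",
         "a power of 2", call. = FALSE)
  }
  if (length(bias) == 1L) bias <- rep(bias, n_agents)
  if (length(bias) != n_agents || any(bias <= 0)) {
    stop("'bias' must be positive, scalar or one value per agent",
         call. = FALSE)
  }
  if (algorithm == "conf_corrected") track_provenance <- TRUE
  if (algorithm == "linear" && (alpha < 0 || alpha > 1)) {
    stop("'alpha' must lie in [0, 1]", call. = FALSE)
  }
  if (meeting_pattern == "oracle_independent" &&
      !algorithm %in% c("conf", "opt_gaussian", "conf_dynamic")) {
    stop("'oracle_independent' is only supported for conf/opt_gaussian",
         call. = FALSE)
  }
  if (track_provenance) {
    if (algorithm == "opt_grid") {
      stop("provenance tracking requires a linear update rule ",
           "(conf, opt_gaussian, linear, conf_corrected)", call. = FALSE)
    }
    if (replicates > 200 || n_total > 128) {
      stop("provenance tracking is limited to <= 200 replicates and ",
           "<= 128 agents", call. = FALSE)
    }
  }
  if (!is.null(theta_schedule)) {
    if (!is.data.frame(theta_schedule) ||
        !all(c("round", "theta") %in% names(theta_schedule))) {
      stop("'theta_schedule' must be a data.frame with columns ",
           "'round' and 'theta'", call. = FALSE)
    }
    theta_schedule <- theta_schedule[order(theta_schedule$round), ]
  }
  structure(list(
    n_agents = n_agents, n_environment = n_environment,
    initial_specs = initial_specs, noise_spec = noise_spec,
    env_spec = env_spec, algorithm = algorithm,
    meeting_pattern = meeting_pattern, rounds = as.integer(rounds),
    replicates = as.integer(replicates), seed = as.integer(seed),
    alpha = alpha, confidence_noise_sd = confidence_noise_sd,
    obsolescence_tau = obsolescence_tau, bias = bias,
    target_theta = target_theta, theta_schedule = theta_schedule,
    record_every = as.integer(record_every),
    track_provenance = isTRUE(track_provenance),
    grid_points = as.integer(grid_points),
    grid_half_width_sigmas = grid_half_width_sigmas
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$algorithm, " | ", x$meeting_pattern,
      " | n = ", x$n_agents,
      if (x$n_environment > 0) paste0(" (+", x$n_environment, " env)"),
      " | rounds = ", x$rounds, " x ", x$replicates,
      " replicates | seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

spec_to_list <- function(s) list(kind = s$kind, params = s$params)

list_to_spec <- function(l) {
  if (is.null(l$kind)) stop("config error: distribution entry lacks 'kind'",
                            call. = FALSE)
  do.call(make_distribution, c(list(kind = l$kind), l$params))
}

#' Serialise a simulation configuration to a plain list
#'
#' The inverse of [config_from_list()]; distribution specs become
#' `{kind, params}` entries, suitable for JSON or YAML.
#'
#' @param cfg A [sim_config()] object.
#' @return A plain named list.
#' @export
config_to_list <- function(cfg) {
  out <- unclass(cfg)
  out$initial_specs <- lapply(cfg$initial_specs, spec_to_list)
  out$noise_spec <- spec_to_list(cfg$noise_spec)
  out$env_spec <- spec_to_list(cfg$env_spec)
  if (!is.null(cfg$theta_schedule)) {
    out$theta_schedule <- as.list(cfg$theta_schedule)
  }
  out
}

#' Build a simulation configuration from a plain list
#'
#' @param l A named list as produced by [config_to_list()] or read from
#'   a JSON/YAML config file.
#' @return A [sim_config()] object.
#' @export
config_from_list <- function(l) {
  known <- names(formals(sim_config))
  bad <- setdiff(names(l), known)
  if (length(bad)) {
    stop("config error: unknown key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(l$initial_specs)) {
    stop("config error: 'initial_specs' is required", call. = FALSE)
  }
  specs <- l$initial_specs
  if (!is.null(specs$kind)) {
    l$initial_specs <- list_to_spec(specs)
  } else {
    l$initial_specs <- lapply(specs, list_to_spec)
  }
  if (is.null(l$noise_spec)) {
    stop("config error: 'noise_spec' is required", call. = FALSE)
  }
  l$noise_spec <- list_to_spec(l$noise_spec)
  if (!is.null(l$env_spec)) l$env_spec <- list_to_spec(l$env_spec)
  if (!is.null(l$theta_schedule)) {
    l$theta_schedule <- as.data.frame(lapply(l$theta_schedule, unlist))
  }
  if (!is.null(l$bias)) l$bias <- unlist(l$bias)
  do.call(sim_config, l)
}

#' Read / write simulation configurations
#'
#' JSON (`.json`) and YAML (`.yaml`/`.yml`) are supported, chosen by
#' file extension.
#'
#' @param path File path.
#' @return `read_sim_config` returns a [sim_config()] object;
#'   `write_sim_config` returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  l <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                       simplifyMatrix = FALSE)
  }
  config_from_list(l)
}

#' @rdname read_sim_config
#' @param cfg A [sim_config()] object.
#' @export
write_sim_config <- function(cfg, path) {
  ext <- tolower(tools::file_ext(path))
  l <- config_to_list(cfg)
  ## drop non-scalar defaults that round-trip poorly
  if (is.null(l$theta_schedule)) l$theta_schedule <- NULL
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(l, path)
  } else {
    jsonlite::write_json(l, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  }
  invisible(path)
}
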