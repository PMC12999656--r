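# Structured experiment configuration: YAML files with strict schemas
# (unknown keys are rejected so a misspelled parameter can never silently
# skew a result), preset expansion, and default filling from the reference
# parameter values.

THERMAL_KEYS <- c("tau0", "m", "omega", "sigma_eps", "seed")
GROWTH_KEYS <- c("r0", "c", "r1")
CAPACITY_KEYS <- c("k0", "tau_m", "sigma_k")
SHAPE_KEYS <- c("mu", "s")
INVASION_KEYS <- c("horizon_L", "burn_in", "fd_step", "noise_seed",
                   "ensemble_reps", "N0")
CANONICAL_KEYS <- c("E", "step_eta", "max_iters", "grad_tol")
SWEEP_KEYS <- c("sigma_eps_grid", "omega_grid", "m", "tau0",
                "continuation", "master_seed")
TOP_KEYS <- c("preset", "thermal", "growth", "capacity", "resident",
              "mutant", "invasion", "canonical", "sweep", "output_dir",
              "log_level")

check_keys <- function(x, allowed, where) {
  if (is.null(x)) return(invisible())
  extra <- setdiff(names(x), allowed)
  if (length(extra) > 0)
    stop("unknown key(s) in ", where, ": ",
         paste(extra, collapse = ", "),
         " (allowed: ", paste(allowed, collapse = ", "), ")",
         call. = FALSE)
  invisible()
}

merge_defaults <- function(user, defaults) {
  out <- defaults
  for (k in names(user)) out[[k]] <- user[[k]]
  out
}

#' Load and validate an experiment configuration
#'
#' Reads a YAML experiment file, expands an optional `preset` reference,
#' fills unspecified parameters with the reference defaults, and validates
#' every sub-record through the corresponding constructor. The schema is
#' strict: unknown keys raise an error naming the key. `omega` may be
#' written as a float or as a string multiple of pi (`"13pi/20"`).
#' Loading, saving and re-loading is idempotent.
#'
#' @param path Path to a YAML configuration file.
#' @return An object of class `"experiment_config"`: list with validated
#'   `thermal` ([thermal_regime()]), `growth`, `capacity` (merged into a
#'   [demography_params()] accessible via the `params` element),
#'   optional `resident`/`mutant` ([tpc_shape()]), `invasion`
#'   ([invasion_config()]), `canonical` ([canonical_config()]), optional
#'   `sweep` ([sweep_spec()]), `output_dir` and `log_level`.
#' @seealso [save_config()], [preset()]
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config must be a YAML mapping", call. = FALSE)
  check_keys(raw, TOP_KEYS, "config")
  base <- if (!is.null(raw$preset)) preset(raw$preset)
    else list(growth = list(r0 = 0.1, c = 0.1, r1 = 0.1),
              capacity = list(k0 = 2, tau_m = 0.5, sigma_k = 0.05))
  check_keys(raw$thermal, THERMAL_KEYS, "thermal")
  check_keys(raw$growth, GROWTH_KEYS, "growth")
  check_keys(raw$capacity, CAPACITY_KEYS, "capacity")
  check_keys(raw$resident, SHAPE_KEYS, "resident")
  check_keys(raw$mutant, SHAPE_KEYS, "mutant")
  check_keys(raw$invasion, INVASION_KEYS, "invasion")
  check_keys(raw$canonical, CANONICAL_KEYS, "canonical")
  check_keys(raw$sweep, SWEEP_KEYS, "sweep")

  th_def <- if (!is.null(base$thermal))
    base$thermal[c("tau0", "m", "omega", "sigma_eps", "seed")]
  else list(tau0 = 0.5, m = 0.25, omega = 13 * pi / 20, sigma_eps = 0.5,
            seed = 1L)
  th <- merge_defaults(raw$thermal, th_def)
  thermal <- thermal_regime(th$tau0, th$m, th$omega, th$sigma_eps, th$seed)

  growth <- merge_defaults(raw$growth, base$growth)
  capacity <- merge_defaults(raw$capacity, base$capacity)
  params <- demography_params(r0 = growth$r0, c = growth$c, r1 = growth$r1,
                              k0 = capacity$k0, tau_m = capacity$tau_m,
                              sigma_k = capacity$sigma_k)

  inv_def <- if (!is.null(base$invasion)) unclass(base$invasion)
    else unclass(invasion_config())
  iv <- merge_defaults(raw$invasion, inv_def)
  invasion <- invasion_config(iv$horizon_L, iv$burn_in, iv$fd_step,
                              iv$noise_seed, iv$ensemble_reps, iv$N0)

  can_def <- if (!is.null(base$canonical)) unclass(base$canonical)
    else unclass(canonical_config())
  cv <- merge_defaults(raw$canonical, can_def)
  E <- cv$E
  if (is.list(E)) E <- do.call(rbind, E)
  canonical <- canonical_config(E, cv$step_eta, cv$max_iters, cv$grad_tol)

  resident <- if (!is.null(raw$resident))
    tpc_shape(raw$resident$mu, raw$resident$s) else NULL
  mutant <- if (!is.null(raw$mutant))
    tpc_shape(raw$mutant$mu, raw$mutant$s) else NULL

  sweep <- NULL
  sw_raw <- raw$sweep
  if (!is.null(sw_raw) || !is.null(base$sweep)) {
    sw_def <- if (!is.null(base$sweep)) base$sweep else sweep_spec()
    sw <- merge_defaults(sw_raw, unclass(sw_def))
    sweep <- sweep_spec(sigma_eps_grid = as.numeric(sw$sigma_eps_grid),
                        omega_grid =
                          vapply(sw$omega_grid, parse_omega, numeric(1)),
                        m = sw$m, tau0 = sw$tau0, params = params,
                        inv_cfg = invasion, can_cfg = canonical,
                        master_seed = sw$master_seed,
                        continuation = sw$continuation)
  }

  structure(list(preset = raw$preset, thermal = thermal,
                 growth = growth, capacity = capacity, params = params,
                 resident = resident, mutant = mutant,
                 invasion = invasion, canonical = canonical,
                 sweep = sweep,
                 output_dir = if (is.null(raw$output_dir)) "."
                              else raw$output_dir,
                 log_level = if (is.null(raw$log_level)) "info"
                             else raw$log_level),
            class = "experiment_config")
}

#' Save an experiment configuration as YAML
#'
#' Writes the canonical serialisation of a configuration; re-loading the
#' written file reproduces the configuration (round-trip identity).
#'
#' @param config An `"experiment_config"` (from [load_config()] or
#'   [preset()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  th <- config$thermal
  out <- list()
  if (!is.null(config$preset)) out$preset <- config$preset
  out$thermal <- list(tau0 = th$tau0, m = th$m, omega = th$omega,
                      sigma_eps = th$sigma_eps, seed = th$seed)
  out$growth <- config$growth[GROWTH_KEYS]
  out$capacity <- config$capacity[CAPACITY_KEYS]
  if (!is.null(config$resident))
    out$resident <- list(mu = config$resident$mu, s = config$resident$s)
  if (!is.null(config$mutant))
    out$mutant <- list(mu = config$mutant$mu, s = config$mutant$s)
  iv <- config$invasion
  out$invasion <- list(horizon_L = iv$horizon_L, burn_in = iv$burn_in,
                       fd_step = iv$fd_step, ensemble_reps =
                         iv$ensemble_reps, N0 = iv$N0)
  if (!is.null(iv$noise_seed)) out$invasion$noise_seed <- iv$noise_seed
  cv <- config$canonical
  out$canonical <- list(E = lapply(seq_len(nrow(cv$E)),
                                   function(i) as.numeric(cv$E[i, ])),
                        step_eta = cv$step_eta, max_iters = cv$max_iters,
                        grad_tol = cv$grad_tol)
  if (!is.null(config$sweep)) {
    sw <- config$sweep
    out$sweep <- list(sigma_eps_grid = as.numeric(sw$sigma_eps_grid),
                      omega_grid = as.numeric(sw$omega_grid),
                      m = sw$m, tau0 = sw$tau0,
                      continuation = sw$continuation,
                      master_seed = sw$master_seed)
  }
  out$output_dir <- config$output_dir
  out$log_level <- config$log_level
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' @export
print.experiment_config <- function(x, ...) {
  cat("Experiment configuration",
      if (!is.null(x$preset)) paste0("(preset '", x$preset, "')"), "\n")
  print(x$thermal)
  if (!is.null(x$params)) print(x$params)
  if (!is.null(x$sweep))
    cat("Sweep:", length(x$sweep$sigma_eps_grid), "x",
        length(x$sweep$omega_grid), "grid, m =", x$sweep$m, "\n")
  invisible(x)
}
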