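#' Load and validate a run configuration
#'
#' Reads a YAML configuration describing one run: the strain parameters
#' (`s`, `a`, `Nth`), the environment (`Kplus`, `Kminus`, `nu`, `delta`),
#' and optional run settings (`n_reps`, `seed`, `horizon`, `init`,
#' `stop_at_absorption`, grid specs `nu_values`/`delta_values`). Missing
#' run settings are filled with package defaults and echoed back in the
#' returned object, so a saved config reproduces the run exactly. All
#' parameter invariants are validated before anything runs; violations are
#' reported with the offending field.
#'
#' @param path Path to a YAML file.
#' @return Object of class `"amr_config"`: list with `model`
#'   ([model_params()]), `env` ([env_params()]), `run` (filled defaults)
#'   and `raw` (the parsed file).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  need <- c("s", "a", "Nth", "Kplus", "Kminus", "nu", "delta")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("config missing required field(s): ", paste(missing, collapse = ", "))
  model <- tryCatch(model_params(raw$s, raw$a, raw$Nth),
                    error = function(e) stop("invalid model parameters: ",
                                             conditionMessage(e)))
  env <- tryCatch(env_params(raw$Kplus, raw$Kminus, raw$nu, raw$delta),
                  error = function(e) stop("invalid environment parameters: ",
                                           conditionMessage(e)))
  run <- list(
    n_reps = if (!is.null(raw$n_reps)) as.integer(raw$n_reps) else 500L,
    seed = if (!is.null(raw$seed)) as.integer(raw$seed) else 1L,
    horizon = if (!is.null(raw$horizon)) as.numeric(raw$horizon)
              else default_horizon(env),
    stop_at_absorption = if (!is.null(raw$stop_at_absorption))
      isTRUE(raw$stop_at_absorption) else TRUE,
    init = raw$init,                      # NULL = coexistence-equilibrium rule
    nu_values = raw$nu_values,
    delta_values = raw$delta_values)
  if (run$n_reps < 1) stop("config field 'n_reps' must be >= 1")
  if (run$horizon <= 0) stop("config field 'horizon' must be positive")
  structure(list(model = model, env = env, run = run, raw = raw),
            class = "amr_config")
}

#' Save a run configuration
#'
#' Writes the fully resolved configuration (including filled defaults) back
#' to YAML, so that `load_config(save_config(cfg, f))` round-trips.
#'
#' @param config An `"amr_config"` object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "amr_config"))
  out <- list(s = config$model$s, a = config$model$a, Nth = config$model$Nth,
              Kplus = config$env$Kplus, Kminus = config$env$Kminus,
              nu = config$env$nu, delta = config$env$delta,
              n_reps = config$run$n_reps, seed = config$run$seed,
              horizon = config$run$horizon,
              stop_at_absorption = config$run$stop_at_absorption)
  for (f in c("init", "nu_values", "delta_values"))
    if (!is.null(config$run[[f]])) out[[f]] <- config$run[[f]]
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.amr_config <- function(x, ...) {
  cat("Run configuration\n")
  print(x$model)
  print(x$env)
  cat(sprintf("  n_reps = %d, seed = %d, horizon = %.4g, stop_at_absorption = %s\n",
              x$run$n_reps, x$run$seed, x$run$horizon,
              x$run$stop_at_absorption))
  invisible(x)
}

#' Write a trajectory as TSV with a JSON metadata sidecar
#'
#' The trajectory table (`time`, `NR`, `NS`, `xi`, `K`) goes to `file`; the
#' run metadata (parameters, seed, initial condition, outcome, event count)
#' goes to `<file>.json`, so the artefact is reproducible from its sidecar
#' alone.
#'
#' @param sim An `"amr_sim"` object with a recorded trajectory.
#' @param file Output TSV path.
#' @return The TSV path, invisibly.
#' @export
write_trajectory <- function(sim, file) {
  stopifnot(inherits(sim, "amr_sim"))
  if (is.null(sim$trajectory))
    stop("simulation was run with record = \"none\"; nothing to write")
  utils::write.table(sim$trajectory[, c("time", "NR", "NS", "xi", "K")],
                     file = file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- list(model = unclass(sim$model), env = unclass(sim$env),
               init = sim$init, horizon = sim$horizon, seed = sim$seed,
               outcome = sim$outcome$label, t_abs = sim$t_abs,
               n_events = sim$n_events, truncated = sim$truncated,
               package_version = as.character(utils::packageVersion("amrswitch")))
  jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(file)
}

#' Read a trajectory TSV back
#'
#' @param file TSV path written by [write_trajectory()].
#' @return List with `trajectory` (data frame) and `meta` (parsed sidecar,
#'   or `NULL` when absent).
#' @export
read_trajectory <- function(file) {
  traj <- utils::read.table(file, header = TRUE, sep = "\t")
  side <- paste0(file, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side) else NULL
  list(trajectory = traj, meta = meta)
}

#' Write an ensemble or phase-diagram summary as CSV
#'
#' @param x An `"amr_ensemble"` or `"amr_phase"` object.
#' @param file Output CSV path.
#' @return The path, invisibly.
#' @export
write_summary_csv <- function(x, file) {
  tab <- if (inherits(x, "amr_phase")) x$grid
         else if (inherits(x, "amr_ensemble")) x$summary
         else stop("unsupported object of class ", paste(class(x), collapse = "/"))
  utils::write.csv(tab, file, row.names = FALSE)
  invisible(file)
}
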