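#' Default coexistence-equilibrium initial condition
#'
#' For phase-diagram ensembles the run starts at the deterministic
#' coexistence equilibrium of the environment it finds itself in: the
#' environmental state is drawn from the stationary law `(1 +- delta)/2`
#' (or fixed via `xi0`), the total population starts at the corresponding
#' carrying capacity `N0 = K(xi0)`, and the resistant strain at
#' `NR0 = min(Nth, N0 - 1)` so that both strains are initially present.
#'
#' @param model An [model_params()] object.
#' @param env An [env_params()] object.
#' @param xi0 Optional fixed initial environmental state (`+1`/`-1`);
#'   default draws from the stationary distribution (consumes one RNG draw).
#' @return List with `NR`, `NS`, `xi`.
#' @export
coexistence_init <- function(model, env, xi0 = NULL) {
  if (is.null(xi0)) {
    p <- stationary_env_probability(env$delta)
    xi0 <- if (stats::runif(1) < p[["plus"]]) 1L else -1L
  }
  stopifnot(xi0 %in% c(-1, 1))
  N0 <- round(carrying_capacity(xi0, env))
  NR0 <- min(model$Nth, N0 - 1)
  list(NR = NR0, NS = N0 - NR0, xi = as.integer(xi0))
}

#' Default simulation horizon
#'
#' Twice the arithmetic stationary mean carrying capacity, `2 <K>`: runs
#' that reach this time without compositional absorption are classified as
#' long-lived coexistence. `<K>` bounds the stationary mean population size
#' from above, which makes the rule computable before any simulation.
#'
#' @param env An [env_params()] object.
#' @return Horizon in time units.
#' @export
default_horizon <- function(env) {
  2 * effective_carrying_capacities(env)$Kmean
}

#' Exact stochastic simulation of one trajectory
#'
#' Samples the master equation of the coupled demographic-environmental
#' process exactly via the Gillespie algorithm with five reaction channels
#' (R birth, R death, S birth, S death, environmental switch). Identical
#' seed and inputs give a bit-identical trajectory.
#'
#' @param model An [model_params()] object.
#' @param env An [env_params()] object.
#' @param init Initial condition: list with `NR`, `NS`, `xi`, or `NULL` for
#'   the [coexistence_init()] default.
#' @param horizon Simulation horizon in time units; default
#'   [default_horizon()].
#' @param seed Optional integer seed (`set.seed` is called when given).
#' @param stop_at_absorption Stop once the composition is absorbed (one
#'   strain extinct)? Set `FALSE` to keep sampling the surviving strain's
#'   population-size fluctuations up to the horizon. Total extinction always
#'   stops the run.
#' @param record `"none"` (final state only), `"grid"` (snapshots every
#'   `grid_dt` plus all switching events), or `"full"` (every event).
#' @param grid_dt Snapshot spacing for `record = "grid"`.
#' @param max_events Event-count guard; exceeding it sets the `truncated`
#'   flag on the result (never silent).
#' @return An object of class `"amr_sim"`: list with `final` (NR, NS, xi,
#'   N, t_end), `outcome` (see [classify_outcome()]), `t_abs`, `n_events`,
#'   `truncated`, `trajectory` (data frame or `NULL`), and the inputs as
#'   metadata (`model`, `env`, `init`, `horizon`, `seed`).
#' @examples
#' m <- model_params(0.1, 0.25, 80)
#' e <- env_params(1000, 120, nu = 0.1, delta = 0)
#' sim <- simulate_population(m, e, horizon = 50, seed = 1, record = "grid")
#' sim$outcome
#' @export
simulate_population <- function(model, env, init = NULL,
                                horizon = default_horizon(env),
                                seed = NULL,
                                stop_at_absorption = TRUE,
                                record = c("none", "grid", "full"),
                                grid_dt = 1,
                                max_events = 2e9) {
  stopifnot(inherits(model, "amr_model"), inherits(env, "amr_env"),
            horizon > 0)
  record <- match.arg(record)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(init)) init <- coexistence_init(model, env)
  stopifnot(init$NR >= 0, init$NS >= 0, init$xi %in% c(-1, 1))
  mode <- match(record, c("none", "grid", "full")) - 1L
  res <- ssa_simulate_cpp(init$NR, init$NS, as.integer(init$xi),
                          model$s, model$a, model$Nth,
                          env$Kplus, env$Kminus, env$nu, env$delta,
                          horizon, stop_at_absorption, mode, grid_dt,
                          max_events)
  traj <- NULL
  if (!is.null(res$record) && length(res$record) > 0) {
    traj <- data.frame(res$record)
    traj$N <- traj$NR + traj$NS
    traj$K <- carrying_capacity(traj$xi, env)
  }
  out <- list(final = list(NR = res$NR, NS = res$NS, xi = res$xi,
                           N = res$NR + res$NS, t_end = res$t_end),
              t_abs = res$t_abs,
              n_events = res$n_events,
              truncated = res$truncated,
              trajectory = traj,
              model = model, env = env, init = init,
              horizon = horizon, seed = seed)
  out$outcome <- classify_outcome(out, horizon)
  class(out) <- "amr_sim"
  out
}

#' Classify the terminal state of a trajectory
#'
#' Applies the long-lived-coexistence rule: a run in which both strains are
#' still present at the horizon is `"coexistence"`; otherwise the label is
#' the compositional absorption reached (`"R_fixed"`, `"S_fixed"`) or
#' `"extinct"` if the whole population died out. Extinction is reported as
#' its own label, never folded into a fixation count.
#'
#' @param sim An `"amr_sim"` object (or a list with `final` and `t_abs`).
#' @param horizon Horizon used for the coexistence rule.
#' @return List with `label`, `t_abs` (NA if none), `final`, `horizon`.
#' @export
classify_outcome <- function(sim, horizon = sim$horizon) {
  f <- sim$final
  lab <- is_absorbing(f$NR, f$NS)
  if (lab == "none") lab <- "coexistence"
  list(label = lab, t_abs = sim$t_abs, final = f, horizon = horizon)
}

#' @export
print.amr_sim <- function(x, ...) {
  cat(sprintf("SSA trajectory: %s at t = %.4g (events: %.0f%s)\n",
              x$outcome$label, x$final$t_end, x$n_events,
              if (x$truncated) ", TRUNCATED at event guard" else ""))
  cat(sprintf("  final state: NR = %g, NS = %g, xi = %+d\n",
              x$final$NR, x$final$NS, x$final$xi))
  if (!is.na(x$t_abs))
    cat(sprintf("  compositional absorption at t = %.4g\n", x$t_abs))
  invisible(x)
}

#' Replicate ensemble at one parameter point
#'
#' Runs `n_reps` independent trajectories and summarises the outcome
#' fractions: R fixation probability `phi_R`, S fixation `phi_S`,
#' long-lived coexistence `P_coex`, and total extinction, each with an
#' exact binomial 95% confidence interval. Per-replicate seeds are derived
#' reproducibly from `seed`, so the ensemble is deterministic given the
#' same inputs.
#'
#' @inheritParams simulate_population
#' @param n_reps Number of replicates (>= 1).
#' @param seed Base seed; per-replicate seeds are drawn from it.
#' @param init Fixed initial condition list, a function
#'   `function(model, env)` returning one, or `NULL` for
#'   [coexistence_init()] (stationary initial environment).
#' @return An object of class `"amr_ensemble"`: list with `summary` (one
#'   row per outcome label: count, estimate, CI), `runs` (per-replicate
#'   data frame with outcome, absorption time, final state, seed), and the
#'   inputs as metadata.
#' @export
run_ensemble <- function(model, env, n_reps, seed,
                         init = NULL,
                         horizon = default_horizon(env),
                         stop_at_absorption = TRUE,
                         max_events = 2e9) {
  stopifnot(n_reps >= 1)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
  labels <- character(n_reps)
  t_abs <- numeric(n_reps)
  NRf <- numeric(n_reps); NSf <- numeric(n_reps); xif <- integer(n_reps)
  trunc <- logical(n_reps)
  for (i in seq_len(n_reps)) {
    ini <- if (is.function(init)) init(model, env) else init
    sim <- simulate_population(model, env, init = ini, horizon = horizon,
                               seed = rep_seeds[i],
                               stop_at_absorption = stop_at_absorption,
                               record = "none", max_events = max_events)
    labels[i] <- sim$outcome$label
    t_abs[i] <- if (is.na(sim$t_abs)) NA_real_ else sim$t_abs
    NRf[i] <- sim$final$NR; NSf[i] <- sim$final$NS; xif[i] <- sim$final$xi
    trunc[i] <- sim$truncated
  }
  lev <- c("R_fixed", "S_fixed", "coexistence", "extinct")
  counts <- table(factor(labels, levels = lev))
  ci <- t(vapply(as.integer(counts), function(k) {
    stats::binom.test(k, n_reps)$conf.int
  }, numeric(2)))
  summary <- data.frame(outcome = lev,
                        count = as.integer(counts),
                        estimate = as.numeric(counts) / n_reps,
                        ci_lo = ci[, 1], ci_hi = ci[, 2])
  runs <- data.frame(rep = seq_len(n_reps), seed = rep_seeds,
                     outcome = labels, t_abs = t_abs,
                     NR = NRf, NS = NSf, N = NRf + NSf, xi = xif,
                     truncated = trunc)
  structure(list(summary = summary, runs = runs,
                 model = model, env = env, n_reps = n_reps, seed = seed,
                 horizon = horizon,
                 stop_at_absorption = stop_at_absorption),
            class = "amr_ensemble")
}

#' @export
print.amr_ensemble <- function(x, ...) {
  cat(sprintf("Ensemble of %d replicates (horizon %.4g, seed %d)\n",
              x$n_reps, x$horizon, x$seed))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Outcome fraction accessor
#'
#' @param ens An `"amr_ensemble"` object.
#' @param label Outcome label, e.g. `"S_fixed"`.
#' @return The estimated fraction for that label.
#' @export
outcome_fraction <- function(ens, label) {
  stopifnot(inherits(ens, "amr_ensemble"))
  s <- ens$summary
  s$estimate[match(label, s$outcome)]
}
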