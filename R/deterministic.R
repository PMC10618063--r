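# Right-hand side of the mean-field dynamics in (N, x):
#   dN/dt = N (1 - N/K)
#   dx/dt = (a*theta - s) x (1 - x) / ((1 - a*theta) + (a*theta - s) x)
# with theta = 1 iff NR = x*N < Nth (Heaviside with theta(0) = 0, so
# cooperation is active at exactly NR = Nth). The rhs is discontinuous at
# the threshold; integration is adaptive and restarted at environment
# switches, with a root function available at the threshold crossing.
meanfield_rhs <- function(t, y, parms) {
  N <- y[1]; x <- y[2]
  ath <- if (x * N < parms$Nth) parms$a else 0
  dN <- N * (1 - N / parms$K)
  dx <- (ath - parms$s) * x * (1 - x) / ((1 - ath) + (ath - parms$s) * x)
  list(c(dN, dx))
}

threshold_root <- function(t, y, parms) y[1] * y[2] - parms$Nth

# one-sided composition velocities dx/dt at a given (N, x): theta active
# (drug on, NR "below" threshold) vs inactive
xdot_below <- function(x, s, a) (a - s) * x * (1 - x) / ((1 - a) + (a - s) * x)
xdot_above <- function(x, s) -s * x * (1 - x) / (1 - s * x)

# one-sided velocities of NR = x N on the threshold surface x = Nth/N
surface_fields <- function(N, parms) {
  N <- unname(N)
  x <- parms$Nth / N
  Ndot <- N * (1 - N / parms$K)
  c(below = N * xdot_below(x, parms$s, parms$a) + x * Ndot,
    above = N * xdot_above(x, parms$s) + x * Ndot)
}

# While both one-sided fields push NR toward the threshold the trajectory
# slides along NR = Nth (the Filippov solution: the coexistence equilibrium
# tracking x_th = Nth/N as N relaxes). Only N is integrated; sliding ends
# when either field stops bracketing the surface.
sliding_rhs <- function(t, y, parms) list(y[1] * (1 - y[1] / parms$K))
sliding_exit_root <- function(t, y, parms) {
  f <- surface_fields(y[1], parms)
  c(f[["below"]], f[["above"]], y[1] - parms$Nth * (1 + 1e-9))
}

# integrate one smooth-environment piece with event handling at the
# discontinuity surface NR = Nth (branch switching and Filippov sliding)
integrate_piece <- function(model, K, N0, x0, t0, t1, n_out, rtol, atol) {
  parms <- list(s = model$s, a = model$a, Nth = model$Nth, K = K)
  times <- seq(t0, t1, length.out = max(2L, n_out))
  eps <- 1e-9
  seg <- list()
  N <- N0; x <- x0
  t_cur <- t0
  mode <- "regular"
  # if starting exactly on the surface, decide the branch/sliding first
  guard <- 0L
  while (t_cur < t1 - 1e-12) {
    guard <- guard + 1L
    if (guard > 10000L) stop("threshold event handling failed to advance")
    on_surface <- abs(x * N - parms$Nth) <= eps * max(1, parms$Nth)
    if (mode == "regular" && on_surface && N > parms$Nth) {
      f <- surface_fields(N, parms)
      if (f[["below"]] > 0 && f[["above"]] < 0) {
        mode <- "sliding"
      } else if (f[["below"]] <= 0) {            # both push down: drug-on side
        x <- (parms$Nth * (1 - 10 * eps)) / N
      } else {                                   # both push up: drug-off side
        x <- (parms$Nth * (1 + 10 * eps)) / N
      }
    }
    tt <- unique(c(t_cur, times[times > t_cur + 1e-12 & times < t1], t1))
    if (mode == "sliding") {
      sol <- deSolve::lsodar(y = c(N = N), times = tt, func = sliding_rhs,
                             parms = parms, rootfunc = sliding_exit_root,
                             rtol = rtol, atol = atol)
      block <- cbind(sol[, 1], sol[, 2], parms$Nth / sol[, 2])
      N <- sol[nrow(sol), 2]
      x <- parms$Nth / N
      mode <- "regular"      # surface re-entry re-detected at next loop turn
      # leave the surface on the side the winning field points to
      f <- surface_fields(N, parms)
      if (!(f[["below"]] > 0 && f[["above"]] < 0)) {
        side <- if (f[["above"]] >= 0) 1 + 10 * eps else 1 - 10 * eps
        x <- (parms$Nth * side) / N
      }
    } else {
      sol <- deSolve::lsodar(y = c(N = N, x = x), times = tt,
                             func = meanfield_rhs, parms = parms,
                             rootfunc = threshold_root,
                             rtol = rtol, atol = atol)
      block <- sol[, 1:3, drop = FALSE]
      N <- sol[nrow(sol), 2]
      x <- sol[nrow(sol), 3]
    }
    seg[[length(seg) + 1L]] <- block
    t_cur <- sol[nrow(sol), 1]
  }
  out <- do.call(rbind, seg)
  out <- out[!duplicated(out[, 1]), , drop = FALSE]
  colnames(out) <- c("time", "N", "x")
  as.data.frame(out)
}

#' Mean-field dynamics at constant carrying capacity
#'
#' Integrates the deterministic limit of the model: the total population
#' follows logistic growth toward `K0` on a time scale of order 1, while
#' the resistant fraction `x` relaxes toward the coexistence equilibrium
#' `x_th = Nth/N` on the slower scale `1/s` (from above) or `1/(a - s)`
#' (from below). The fitness step at `NR = Nth` is handled with the
#' `theta(0) = 0` convention and root-detected restarts.
#'
#' @param model An [model_params()] object.
#' @param K0 Constant carrying capacity, cells.
#' @param init List with `N` (> 0) and `x` (in `[0, 1]`).
#' @param t_end Integration time.
#' @param n_out Number of output points.
#' @param rtol,atol Integrator tolerances.
#' @return Data frame with columns `time`, `N`, `x`, `NR`, `NS`.
#' @examples
#' m <- model_params(0.1, 0.25, 80)
#' path <- integrate_mean_field(m, K0 = 120, init = list(N = 1000, x = 0.08),
#'                              t_end = 10)
#' @export
integrate_mean_field <- function(model, K0, init, t_end, n_out = 400L,
                                 rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(model, "amr_model"), K0 > 0, t_end > 0,
            init$N > 0, init$x >= 0, init$x <= 1)
  out <- integrate_piece(model, K0, init$N, init$x, 0, t_end, n_out,
                         rtol, atol)
  out$NR <- out$N * out$x
  out$NS <- out$N * (1 - out$x)
  out
}

#' Piecewise-deterministic (PDMP) dynamics in a switching environment
#'
#' The infinite-population limit of the model: between environmental
#' switches the dynamics is the deterministic mean-field flow with the
#' current capacity `K(t)`, and `K` jumps at each switch. With a supplied
#' environment path the output is fully deterministic; alternatively a
#' telegraph path is drawn from `env` (and `seed`).
#'
#' @param model An [model_params()] object.
#' @param env An [env_params()] object (used to map states to capacities,
#'   and to draw a path when `env_path` is missing).
#' @param init List with `N`, `x`.
#' @param t_end Integration time.
#' @param env_path Optional data frame `(time, xi)` from [simulate_dmn()].
#' @param seed Optional seed for the drawn path.
#' @param xi0 Optional fixed initial environment when drawing the path.
#' @param n_out Output points per unit segment length (minimum 10 per
#'   segment).
#' @param rtol,atol Integrator tolerances.
#' @return Data frame with columns `time`, `N`, `x`, `NR`, `xi`; the
#'   environment path used is attached as attribute `"env_path"`.
#' @export
integrate_pdmp <- function(model, env, init, t_end, env_path = NULL,
                           seed = NULL, xi0 = NULL, n_out = 200L,
                           rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(model, "amr_model"), inherits(env, "amr_env"))
  if (is.null(env_path))
    env_path <- simulate_dmn(env, t_end, xi0 = xi0, seed = seed)
  starts <- env_path$time[env_path$time < t_end]
  states <- env_path$xi[env_path$time < t_end]
  ends <- c(starts[-1], t_end)
  N <- init$N; x <- init$x
  pieces <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    K <- carrying_capacity(states[i], env)
    len <- ends[i] - starts[i]
    np <- max(10L, ceiling(n_out * len / t_end))
    p <- integrate_piece(model, K, N, x, starts[i], ends[i], np, rtol, atol)
    p$xi <- states[i]
    pieces[[i]] <- p
    N <- p$N[nrow(p)]; x <- p$x[nrow(p)]
  }
  out <- do.call(rbind, pieces)
  out$NR <- out$N * out$x
  attr(out, "env_path") <- env_path
  out
}

#' Time to the bottom of the transient resistant-abundance dip
#'
#' After a switch from abundance to scarcity (`K+ -> K-`) the population
#' crashes toward `K-` faster than the composition can respond, dragging
#' the resistant abundance through a transient dip. Starting from
#' `N(0) ~ K+`, the dip bottom is reached after
#' `t_dip = ln[ (1-s)/(a-s) * (1 - K-/K+) ]`.
#'
#' @param model An [model_params()] object with `a > s` strictly.
#' @param env An [env_params()] object with `Kminus < Kplus`.
#' @return Dip time in time units.
#' @examples
#' dip_time(model_params(0.1, 0.25, 80), env_params(1000, 120, 0.1, 0))
#' @export
dip_time <- function(model, env) {
  stopifnot(inherits(model, "amr_model"), inherits(env, "amr_env"))
  if (model$a <= model$s) stop("dip analytics require a > s")
  if (env$Kminus >= env$Kplus)
    stop("no transient dip: requires Kminus < Kplus")
  arg <- (1 - model$s) / (model$a - model$s) * (1 - env$Kminus / env$Kplus)
  if (arg <= 1) stop("invalid regime: dip-time argument <= 1 (no dip forms)")
  log(arg)
}

#' Resistant abundance at the bottom of the transient dip
#'
#' Ignoring demographic noise and starting from the coexistence equilibrium
#' `NR(0) = Nth` at the switch, the dip bottom is
#' `NR_dip = Nth (K-/K+) (1-s)/(1-a) ((1-s)/(a-s))^{(a-s)/(1-a)}`,
#' bounded below by `Nth K-/K+`. The population size at the bottom is
#' `N(t_dip) ~ K- (1-s)/(1-a)`. Fluctuation-driven eradication of the
#' resistant strain is feasible when the dip bottom is of order one
#' (operationally `NR_dip <= feasibility_threshold`, default 10), so that
#' demographic fluctuations of order `sqrt(NR_dip)` can reach zero.
#'
#' @inheritParams dip_time
#' @param feasibility_threshold Dip-bottom size below which eradication by
#'   demographic noise is deemed feasible (cells).
#' @return List of class `"amr_dip"` with `t_dip`, `NR_dip`, `lower_bound`
#'   (`Nth K-/K+`), `N_at_dip`, and logical `eradication_feasible`.
#' @export
dip_minimum <- function(model, env, feasibility_threshold = 10) {
  td <- dip_time(model, env)
  s <- model$s; a <- model$a
  ratio <- env$Kminus / env$Kplus
  NR_dip <- model$Nth * ratio * (1 - s) / (1 - a) *
    ((1 - s) / (a - s))^((a - s) / (1 - a))
  structure(list(t_dip = td,
                 NR_dip = NR_dip,
                 lower_bound = model$Nth * ratio,
                 N_at_dip = env$Kminus * (1 - s) / (1 - a),
                 eradication_feasible = NR_dip <= feasibility_threshold),
            class = "amr_dip")
}

#' @export
print.amr_dip <- function(x, ...) {
  cat(sprintf("Transient dip: t_dip = %.4g, NR_dip = %.4g (lower bound %.4g)\n",
              x$t_dip, x$NR_dip, x$lower_bound))
  cat(sprintf("  N at dip bottom ~ %.4g; eradication feasible: %s\n",
              x$N_at_dip, x$eradication_feasible))
  invisible(x)
}

#' Optimal environmental region for resistant-strain eradication
#'
#' The four timing conditions for fluctuation-driven eradication translate
#' into interval constraints on the products `nu (1 - delta)` (mild-state
#' exit rate) and `nu (1 + delta)` (harsh-state exit rate):
#' `s / (2 ln(K+/K-)) <= nu (1 - delta) <= s` and
#' `(a - s) / (2 ln(K+/K-)) <= nu (1 + delta) <= 1 / t_dip`.
#' Environments inside both intervals allow repeated transient dips deep
#' enough for demographic noise to eradicate the resistant strain.
#'
#' @inheritParams dip_time
#' @return List of class `"amr_region"` with `nu_plus_bounds`,
#'   `nu_minus_bounds` (each `c(lower, upper)`), logical `nonempty`, and
#'   `membership`, a predicate `function(nu, delta)`.
#' @examples
#' reg <- optimal_eradication_region(model_params(0.1, 0.25, 80),
#'                                   env_params(1000, 120, 0.1, 0))
#' reg$membership(0.05, 0)
#' @export
optimal_eradication_region <- function(model, env) {
  td <- dip_time(model, env)
  lnK <- log(env$Kplus / env$Kminus)
  npb <- c(lower = model$s / (2 * lnK), upper = model$s)
  nmb <- c(lower = (model$a - model$s) / (2 * lnK), upper = 1 / td)
  nonempty <- npb[["lower"]] < npb[["upper"]] && nmb[["lower"]] < nmb[["upper"]]
  membership <- function(nu, delta) {
    np <- nu * (1 - delta)
    nm <- nu * (1 + delta)
    np >= npb[["lower"]] & np <= npb[["upper"]] &
      nm >= nmb[["lower"]] & nm <= nmb[["upper"]]
  }
  structure(list(nu_plus_bounds = npb, nu_minus_bounds = nmb,
                 nonempty = nonempty, membership = membership,
                 t_dip = td),
            class = "amr_region")
}

#' @export
print.amr_region <- function(x, ...) {
  cat("Optimal eradication region (interval constraints)\n")
  cat(sprintf("  nu (1 - delta) in [%.5g, %.5g]\n",
              x$nu_plus_bounds[["lower"]], x$nu_plus_bounds[["upper"]]))
  cat(sprintf("  nu (1 + delta) in [%.5g, %.5g]\n",
              x$nu_minus_bounds[["lower"]], x$nu_minus_bounds[["upper"]]))
  cat(sprintf("  nonempty: %s\n", x$nonempty))
  invisible(x)
}

#' Large-population transferability criterion
#'
#' The fluctuation-driven eradication mechanism carries over to arbitrarily
#' large populations as long as the dip-bottom scale `Nth K-/K+` stays of
#' order 10 or below, regardless of the absolute magnitudes of the
#' capacities and threshold.
#'
#' @param model An [model_params()] object.
#' @param env An [env_params()] object.
#' @param threshold Cut-off for the criterion (default 10 cells).
#' @return List with `value` (`Nth K-/K+`) and logical `transferable`.
#' @export
large_population_criterion <- function(model, env, threshold = 10) {
  v <- model$Nth * env$Kminus / env$Kplus
  list(value = v, transferable = v <= threshold)
}
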