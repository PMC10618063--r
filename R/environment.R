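#' Carrying capacity in a given environmental state
#'
#' `K = (Kplus + Kminus + xi * (Kplus - Kminus)) / 2`, i.e. `Kplus` when
#' `xi = +1` and `Kminus` when `xi = -1`.
#'
#' @param xi Environmental state, `+1` or `-1` (vectorised).
#' @param env An [env_params()] object.
#' @return Carrying capacity in cells.
#' @export
carrying_capacity <- function(xi, env) {
  stopifnot(inherits(env, "amr_env"), all(xi %in% c(-1, 1)))
  (env$Kplus + env$Kminus + xi * (env$Kplus - env$Kminus)) / 2
}

#' Environmental switching rate
#'
#' The telegraph noise flips `xi -> -xi` at rate `nu * (1 - delta * xi)`:
#' `nu_plus = nu (1 - delta)` out of the abundant state and
#' `nu_minus = nu (1 + delta)` out of the scarce one.
#'
#' @param xi Environmental state, `+1` or `-1` (vectorised).
#' @param env An [env_params()] object.
#' @return Switching rate per unit time.
#' @examples
#' e <- env_params(250, 50, nu = 0.2, delta = 0.6)
#' switching_rate(+1, e)  # 0.08
#' switching_rate(-1, e)  # 0.32
#' @export
switching_rate <- function(xi, env) {
  stopifnot(inherits(env, "amr_env"))
  if (!all(xi %in% c(-1, 1))) stop("'xi' must be +1 or -1")
  env$nu * (1 - env$delta * xi)
}

#' Stationary distribution of the environmental state
#'
#' At stationarity the telegraph noise occupies `xi = +1` with probability
#' `(1 + delta) / 2` and `xi = -1` with probability `(1 - delta) / 2`,
#' so its stationary mean is `delta`.
#'
#' @param delta Switching bias in `(-1, 1)`.
#' @return Named numeric vector `c(plus = , minus = )`, summing to 1.
#' @export
stationary_env_probability <- function(delta) {
  stopifnot(is.numeric(delta), length(delta) == 1L, delta > -1, delta < 1)
  c(plus = (1 + delta) / 2, minus = (1 - delta) / 2)
}

#' Effective carrying capacities of the switching environment
#'
#' In the fast-switching limit the population cannot track `K(t)` and
#' experiences the self-averaged harmonic-type capacity
#' `Kbar = 1 / <1/K> = 2 K+ K- / ((1 - delta) K+ + (1 + delta) K-)`.
#' The arithmetic stationary mean is
#' `<K> = ((1 + delta) K+ + (1 - delta) K-) / 2`. Always
#' `Kminus <= Kbar <= <K> <= Kplus`, with all collapsing to `K+-` as
#' `delta -> +-1`.
#'
#' @param env An [env_params()] object.
#' @return List with elements `Kbar` and `Kmean`.
#' @examples
#' effective_carrying_capacities(env_params(1000, 120, 1, 0))
#' @export
effective_carrying_capacities <- function(env) {
  stopifnot(inherits(env, "amr_env"))
  d <- env$delta
  Kbar <- 2 * env$Kplus * env$Kminus /
    ((1 - d) * env$Kplus + (1 + d) * env$Kminus)
  Kmean <- ((1 + d) * env$Kplus + (1 - d) * env$Kminus) / 2
  list(Kbar = Kbar, Kmean = Kmean)
}

#' Simulate a telegraph-noise sample path
#'
#' Draws the continuous-time two-state Markov chain driving the environment.
#' Waiting times in state `xi` are exponential with rate
#' `nu * (1 - delta * xi)`. By default the initial state is drawn from the
#' stationary law `(1 +- delta) / 2`; a fixed `xi0` may be supplied to
#' reproduce particular sample paths.
#'
#' @param env An [env_params()] object.
#' @param t_end Path duration in time units.
#' @param xi0 Optional initial state (`+1` or `-1`); default stationary draw.
#' @param seed Optional integer seed.
#' @return A data frame with columns `time` and `xi`: the state entered at
#'   each `time` (first row is the initial state at time 0), plus attribute
#'   `t_end`.
#' @export
simulate_dmn <- function(env, t_end, xi0 = NULL, seed = NULL) {
  stopifnot(inherits(env, "amr_env"), t_end > 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(xi0)) {
    p <- stationary_env_probability(env$delta)
    xi0 <- if (stats::runif(1) < p[["plus"]]) 1L else -1L
  }
  stopifnot(xi0 %in% c(-1, 1))
  cap <- max(64L, ceiling(2 * env$nu * t_end + 10 * sqrt(env$nu * t_end)))
  times <- numeric(cap)
  states <- integer(cap)
  times[1] <- 0
  states[1] <- as.integer(xi0)
  n <- 1L
  t <- 0
  xi <- as.integer(xi0)
  repeat {
    t <- t + stats::rexp(1, rate = switching_rate(xi, env))
    if (t >= t_end) break
    xi <- -xi
    n <- n + 1L
    if (n > cap) {            # grow geometrically; keeps appends linear
      cap <- cap * 2L
      length(times) <- cap
      length(states) <- cap
    }
    times[n] <- t
    states[n] <- xi
    if (n > 5e7) stop("telegraph path exceeded event guard")
  }
  out <- data.frame(time = times[seq_len(n)], xi = states[seq_len(n)])
  attr(out, "t_end") <- t_end
  out
}

#' Resample a telegraph path on a uniform grid
#'
#' Piecewise-constant interpolation of a switch-event path at evenly spaced
#' times, used to estimate stationary statistics without event-time bias.
#'
#' @param path Data frame from [simulate_dmn()].
#' @param dt Grid step in time units.
#' @param t_end Duration; defaults to the path's recorded duration.
#' @return Data frame with columns `time`, `xi` on the uniform grid.
#' @export
resample_dmn <- function(path, dt = 0.1, t_end = attr(path, "t_end")) {
  stopifnot(is.data.frame(path), all(c("time", "xi") %in% names(path)),
            dt > 0, !is.null(t_end))
  grid <- seq(0, t_end, by = dt)
  idx <- findInterval(grid, path$time)
  data.frame(time = grid, xi = path$xi[pmax(idx, 1L)])
}

#' Empirical statistics of a telegraph path
#'
#' Estimates the stationary mean of `xi` and its autocovariance at the
#' requested lags from an evenly resampled path, and fits the exponential
#' decay rate of the autocovariance (theory: `(1 - delta^2) exp(-2 nu |t|)`,
#' so the fitted rate estimates `2 nu`). A path containing fewer than one
#' switch is flagged as low-confidence.
#'
#' @param path Data frame from [simulate_dmn()].
#' @param lags Numeric lags (time units) at which to report autocovariance.
#' @param dt Resampling grid step.
#' @return List with `mean`, `autocov` (named by lag), `decay_rate`,
#'   `n_switches`, and logical `low_confidence`.
#' @export
dmn_statistics <- function(path, lags = c(0, 1, 2, 5), dt = 0.1) {
  stopifnot(all(lags >= 0))
  rs <- resample_dmn(path, dt = dt)
  x <- rs$xi
  n <- length(x)
  m <- mean(x)
  acov <- vapply(lags, function(l) {
    k <- as.integer(round(l / dt))
    if (k >= n) return(NA_real_)
    mean((x[seq_len(n - k)] - m) * (x[seq_len(n - k) + k] - m))
  }, numeric(1))
  names(acov) <- as.character(lags)
  # decay-rate fit on positive lags with positive autocovariance
  pos <- lags > 0 & !is.na(acov) & acov > 0
  decay <- if (sum(pos) >= 2) {
    fit <- stats::lm(log(acov[pos]) ~ lags[pos])
    -unname(stats::coef(fit)[2])
  } else if (sum(pos) == 1 && acov[["0"]] > 0) {
    -log(acov[pos] / acov[["0"]]) / lags[pos]
  } else {
    NA_real_
  }
  list(mean = m, autocov = acov, decay_rate = unname(decay),
       n_switches = nrow(path) - 1L,
       low_confidence = nrow(path) < 2L)
}

#' Write a telegraph path as two-column TSV
#'
#' @param path Data frame from [simulate_dmn()].
#' @param file Output path.
#' @return The file path, invisibly.
#' @export
write_env_path <- function(path, file) {
  utils::write.table(path[, c("time", "xi")], file = file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}
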