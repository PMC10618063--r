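#' Effective Moran transition rates at fixed population size
#'
#' In a static environment the total population relaxes to the constant
#' carrying capacity `K0` much faster than the composition evolves, and the
#' composition then follows an effective Moran process in which each R
#' birth is balanced by an S death and vice versa. The effective rates are
#' `T~R+ = TR+ TS- / N` and `T~R- = TR- TS+ / N` evaluated at `N = K0`.
#' Their ratio `gamma(n) = T~R-(n) / T~R+(n) = f_S(n) / f_R` is piecewise
#' constant: `(1 - a)/(1 - s)` below the cooperation threshold and
#' `1/(1 - s)` at or above it.
#'
#' @param n Resistant count, `0 <= n <= K0` (vectorised).
#' @param K0 Fixed total population size, cells.
#' @param model An [model_params()] object.
#' @return List with numeric vectors `up` (`T~R+`) and `down` (`T~R-`);
#'   both zero at the absorbing states `n = 0` and `n = K0`.
#' @export
effective_moran_rates <- function(n, K0, model) {
  stopifnot(inherits(model, "amr_model"), K0 >= 2)
  if (any(n < 0 | n > K0)) stop("'n' out of range [0, K0]")
  fR <- fitness_R(model)
  fS <- fitness_S(n, model)
  fbar <- (fR * n + fS * (K0 - n)) / K0
  up <- fR * n * (K0 - n) / (fbar * K0)
  down <- fS * (K0 - n) * n / (fbar * K0)
  list(up = up, down = down)
}

#' Hop ratio of the effective Moran chain
#'
#' `gamma(n) = T~R-(n)/T~R+(n) = f_S(n)/f_R`, defined for interior states.
#'
#' @inheritParams effective_moran_rates
#' @return Numeric vector of ratios.
#' @export
moran_gamma <- function(n, K0, model) {
  stopifnot(all(n >= 1 & n <= K0 - 1))
  fitness_S(n, model) / fitness_R(model)
}

# log cumulative products log(rho_m) = sum_{j=1..m} log gamma(j), m = 0..K0-1
moran_log_rho <- function(K0, model) {
  lg <- log(moran_gamma(seq_len(K0 - 1), K0, model))
  c(0, cumsum(lg))
}

# stable log(sum(exp(x)))
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Exact fixation probability of the resistant strain
#'
#' The standard absorption formula of a one-dimensional birth-death chain
#' with absorbing boundaries at `n = 0` and `n = K0`:
#' `phi(n0) = sum_{m=0}^{n0-1} rho_m / sum_{m=0}^{K0-1} rho_m` with
#' `rho_m = prod_{j<=m} gamma(j)`. Products are accumulated in log space,
#' so the evaluation is stable up to `K0 ~ 1e5`.
#'
#' @param n0 Initial resistant count(s), `0 <= n0 <= K0` (vectorised).
#' @param K0 Fixed total population size.
#' @param model An [model_params()] object.
#' @return Fixation probability(ies) of R; `phi(0) = 0`, `phi(K0) = 1`,
#'   strictly increasing in `n0`.
#' @examples
#' m <- model_params(0, 0, 1)          # neutral: phi = n0/K0
#' fixation_probability_exact(3, 10, m)
#' @export
fixation_probability_exact <- function(n0, K0, model) {
  stopifnot(all(n0 >= 0 & n0 <= K0), K0 >= 2)
  lr <- moran_log_rho(K0, model)
  lZ <- logsumexp(lr)
  vapply(n0, function(k) {
    if (k == 0) return(0)
    exp(logsumexp(lr[seq_len(k)]) - lZ)
  }, numeric(1))
}

#' Closed-form approximation of the fixation probability and K0*
#'
#' Approximates the R fixation probability from a start at the coexistence
#' equilibrium `x0 = Nth/K0` by
#' `phi = 1 / (1 + (1 - s)^{-(K0 - K0*)})`, where
#' `K0* = Nth ln(1-a)/ln(1-s) - ln(s(1-a)/(a-s))/ln(1-s)` is the population
#' size at which R and S fixate equiprobably (`phi(K0*) = 1/2` exactly).
#' To leading order `K0*/Nth ~ ln(1-a)/ln(1-s)`, which is about 3 for
#' `s = 0.1`, `a = 0.25`: resistance prevails in populations smaller than
#' roughly three times the cooperation threshold.
#'
#' @param K0 Total population size(s), cells (vectorised); `K0 > Nth`.
#' @param model An [model_params()] object with `0 < s < a < 1` strictly.
#' @return List with `phi` (vector), `K0_star`, and `ratio` =
#'   `ln(1-a)/ln(1-s)` (the leading-order `K0*/Nth`).
#' @export
fixation_probability_approx <- function(K0, model) {
  stopifnot(inherits(model, "amr_model"))
  s <- model$s; a <- model$a
  if (a <= s || s <= 0) stop("approximation requires 0 < s < a < 1")
  K0_star <- model$Nth * log(1 - a) / log(1 - s) -
    log(s * (1 - a) / (a - s)) / log(1 - s)
  phi <- 1 / (1 + (1 - s)^(-(K0 - K0_star)))
  list(phi = phi, K0_star = K0_star, ratio = log(1 - a) / log(1 - s))
}

#' Mean coexistence time of the effective Moran chain
#'
#' The unconditional mean absorption time (time until either strain fixates)
#' of the birth-death chain, from the recurrence
#' `d_n = gamma_n d_{n-1} - 1/lambda_n` for `d_n = tau(n+1) - tau(n)` with
#' `tau(0) = tau(K0) = 0`. All products and sums are telescoped in log
#' space, so the evaluation remains finite-precision-stable for large `K0`
#' (the result itself may overflow to `Inf` when the MCT is astronomically
#' large, which is reported as such).
#'
#' @param n0 Initial resistant count(s), `0 < n0 < K0` (vectorised).
#' @param K0 Fixed total population size.
#' @param model An [model_params()] object.
#' @return Mean time(s) to absorption, in units of the baseline birth rate.
#' @export
mean_coexistence_time <- function(n0, K0, model) {
  stopifnot(all(n0 > 0 & n0 < K0), K0 >= 2)
  lr <- moran_log_rho(K0, model)                      # log rho_m, m=0..K0-1
  lam <- effective_moran_rates(seq_len(K0 - 1), K0, model)$up
  llam <- log(lam)
  # c_m = log sum_{k=1..m} exp(-log rho_k - log lambda_k), cumulative
  inner <- -lr[-1] - llam                             # k = 1..K0-1
  cm <- numeric(K0 - 1)
  run <- -Inf
  for (k in seq_len(K0 - 1)) {
    run <- logsumexp(c(run, inner[k]))
    cm[k] <- run
  }
  term <- lr[-1] + cm                                 # m = 1..K0-1
  lZ <- logsumexp(lr)
  ld0 <- logsumexp(term) - lZ                         # log tau(1)
  vapply(n0, function(j) {
    first <- exp(ld0 + logsumexp(lr[seq_len(j)]))
    second <- if (j >= 2) sum(exp(term[seq_len(j - 1)])) else 0
    first - second
  }, numeric(1))
}

#' Tabulate fixation probability and MCT curves
#'
#' Computes exact and approximate R fixation probabilities and the exact
#' mean coexistence time over a range of static population sizes, starting
#' from the coexistence equilibrium `n0 = round(Nth)` (clamped inside the
#' chain). One row per `(Nth, K0)` pair, suitable for CSV export.
#'
#' @param s,a Strain parameters (see [model_params()]).
#' @param Nth_values Cooperation thresholds to tabulate.
#' @param K0_values Population sizes; entries `<= Nth` are skipped.
#' @return Data frame with columns `Nth`, `K0`, `n0`, `phi_exact`,
#'   `phi_approx`, `K0_star`, `mct`.
#' @export
moran_curves <- function(s, a, Nth_values, K0_values) {
  rows <- list()
  for (Nth in Nth_values) {
    model <- model_params(s, a, Nth)
    app <- NULL
    for (K0 in K0_values) {
      if (K0 <= Nth) next
      n0 <- max(1L, min(K0 - 1L, as.integer(round(Nth))))
      app <- fixation_probability_approx(K0, model)
      rows[[length(rows) + 1L]] <- data.frame(
        Nth = Nth, K0 = K0, n0 = n0,
        phi_exact = fixation_probability_exact(n0, K0, model),
        phi_approx = app$phi,
        K0_star = app$K0_star,
        mct = mean_coexistence_time(n0, K0, model))
    }
  }
  do.call(rbind, rows)
}
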