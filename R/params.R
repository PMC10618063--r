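#' Strain-level model parameters
#'
#' Bundles the constants describing the two competing strains: the extra
#' metabolic cost `s` paid by the resistant strain R for constitutively
#' producing the drug-inactivating enzyme, the growth-rate reduction `a`
#' suffered by the sensitive strain S when the drug is active, and the
#' cooperation threshold `Nth`, the number of R cells above which enough
#' enzyme is present to protect the whole community (public good).
#'
#' Fitnesses are `f_R = 1 - s` always, and `f_S = 1 - a` below the threshold
#' (`NR < Nth`) or `f_S = 1` at or above it. The biologically interesting
#' regime has `0 < s < a < 1`; the constructor also admits the neutral edge
#' cases `s = 0` and `s = a` used for calibration against classical results.
#' Operations whose formulas require `s < a` strictly (the closed-form
#' fixation approximation, the dip analytics) reject `a <= s` themselves.
#'
#' @param s Extra metabolic cost of resistance, dimensionless, in `[0, 1)`.
#' @param a Drug-induced growth reduction of S, dimensionless, in `[0, 1)`,
#'   with `a >= s`.
#' @param Nth Cooperation threshold in cells; positive integer.
#' @return An object of class `"amr_model"`: a list with elements
#'   `s`, `a`, `Nth`.
#' @examples
#' model_params(s = 0.1, a = 0.25, Nth = 80)
#' @export
model_params <- function(s, a, Nth) {
  stopifnot(is.numeric(s), length(s) == 1L, is.finite(s),
            is.numeric(a), length(a) == 1L, is.finite(a),
            is.numeric(Nth), length(Nth) == 1L, is.finite(Nth))
  if (s < 0 || s >= 1) stop("'s' must lie in [0, 1)")
  if (a < 0 || a >= 1) stop("'a' must lie in [0, 1)")
  if (a < s) stop("drug impact 'a' must be >= resistance cost 's' (model constraint 0 <= s <= a < 1)")
  if (Nth < 1 || Nth != round(Nth)) stop("'Nth' must be a positive integer")
  structure(list(s = s, a = a, Nth = as.integer(Nth)), class = "amr_model")
}

#' @export
print.amr_model <- function(x, ...) {
  cat("Two-strain AMR model parameters\n")
  cat(sprintf("  resistance cost      s   = %g   (f_R = %g)\n", x$s, 1 - x$s))
  cat(sprintf("  drug impact on S     a   = %g   (f_S = %g below threshold)\n",
              x$a, 1 - x$a))
  cat(sprintf("  cooperation threshold Nth = %d cells\n", x$Nth))
  invisible(x)
}

#' Switching-environment parameters
#'
#' The carrying capacity is driven by dichotomous Markov (telegraph) noise
#' `xi(t)` on `{-1, +1}`: `K = Kplus` when `xi = +1` (abundant resources)
#' and `K = Kminus` when `xi = -1` (scarce resources). The environment
#' flips at rate `nu * (1 - delta * xi)`, so that `nu_plus = nu * (1 - delta)`
#' is the rate of leaving the abundant state and `nu_minus = nu * (1 + delta)`
#' the rate of leaving the scarce one. `nu` is the mean switching rate and
#' `delta` the bias: for `delta > 0` the environment spends more time in
#' the abundant state.
#'
#' The degenerate case `Kplus == Kminus` is allowed and represents a static
#' environment with constant carrying capacity (switching events then have
#' no effect on the dynamics).
#'
#' @param Kplus Carrying capacity in the abundant state, cells.
#' @param Kminus Carrying capacity in the scarce state, cells;
#'   `Kplus >= Kminus >= 1`.
#' @param nu Mean switching rate, per unit time; positive.
#' @param delta Switching bias, in `(-1, 1)`.
#' @return An object of class `"amr_env"`: a list with elements `Kplus`,
#'   `Kminus`, `nu`, `delta` and the derived rates `nu_plus`, `nu_minus`.
#' @examples
#' env_params(Kplus = 1000, Kminus = 120, nu = 0.1, delta = 0)
#' @export
env_params <- function(Kplus, Kminus, nu, delta) {
  stopifnot(is.numeric(Kplus), length(Kplus) == 1L, is.finite(Kplus),
            is.numeric(Kminus), length(Kminus) == 1L, is.finite(Kminus),
            is.numeric(nu), length(nu) == 1L, is.finite(nu),
            is.numeric(delta), length(delta) == 1L, is.finite(delta))
  if (Kminus < 1) stop("'Kminus' must be >= 1")
  if (Kplus < Kminus) stop("'Kplus' must be >= 'Kminus'")
  if (nu <= 0) stop("'nu' must be positive")
  if (delta <= -1 || delta >= 1) stop("'delta' must lie in (-1, 1)")
  structure(list(Kplus = Kplus, Kminus = Kminus, nu = nu, delta = delta,
                 nu_plus = nu * (1 - delta), nu_minus = nu * (1 + delta)),
            class = "amr_env")
}

#' Static-environment shorthand
#'
#' Convenience constructor for a constant carrying capacity `K0`: both
#' environmental states carry the same capacity, so the (still present)
#' switching channel has no effect on the population. A negligible switching
#' rate keeps the event overhead at zero for all practical horizons.
#'
#' @param K0 Constant carrying capacity, cells.
#' @param nu Switching rate; defaults to a negligible value.
#' @return An `"amr_env"` object with `Kplus == Kminus == K0`.
#' @export
static_env <- function(K0, nu = 1e-9) {
  env_params(Kplus = K0, Kminus = K0, nu = nu, delta = 0)
}

#' @export
print.amr_env <- function(x, ...) {
  cat("Switching-environment parameters\n")
  cat(sprintf("  K+ = %g, K- = %g cells\n", x$Kplus, x$Kminus))
  cat(sprintf("  mean switching rate nu = %g, bias delta = %g\n", x$nu, x$delta))
  cat(sprintf("  nu+ (K+ -> K-) = %g, nu- (K- -> K+) = %g\n",
              x$nu_plus, x$nu_minus))
  invisible(x)
}
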