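#' Sensitive-strain fitness under the public-good threshold
#'
#' The sensitive strain S grows at fitness `1 - a` while the drug is active
#' and at the baseline fitness 1 once the resistant abundance reaches the
#' cooperation threshold and the drug is inactivated community-wide:
#' `f_S = 1 - a * theta(Nth - NR)` with the Heaviside convention
#' `theta(z) = 1` iff `z > 0` and `theta(0) = 0`. Cooperation is therefore
#' already active at exactly `NR = Nth`.
#'
#' @param NR Resistant abundance, cells (vectorised, non-negative).
#' @param model An [model_params()] object.
#' @return Numeric vector of fitness values (`1 - a` or `1`).
#' @examples
#' m <- model_params(0.1, 0.5, 30)
#' fitness_S(c(29, 30, 31), m)   # 0.5 1.0 1.0
#' @export
fitness_S <- function(NR, model) {
  stopifnot(inherits(model, "amr_model"), all(NR >= 0))
  ifelse(NR < model$Nth, 1 - model$a, 1)
}

#' Resistant-strain fitness
#'
#' Constant fitness `f_R = 1 - s`: the resistant strain pays the metabolic
#' cost of enzyme production regardless of the drug state.
#'
#' @inheritParams fitness_S
#' @return The scalar `1 - s`.
#' @export
fitness_R <- function(model) {
  stopifnot(inherits(model, "amr_model"))
  1 - model$s
}

#' Abundance-weighted mean population fitness
#'
#' `fbar = f_R * NR / N + f_S * NS / N` with `N = NR + NS`. Birth rates are
#' normalised by this quantity, which links the model to the classical Moran
#' process at fixed `N`.
#'
#' @param NR,NS Strain abundances, cells (non-negative scalars).
#' @param model An [model_params()] object.
#' @return Mean fitness; lies between `min(f_R, f_S)` and `max(f_R, f_S)`.
#' @export
mean_fitness <- function(NR, NS, model) {
  stopifnot(inherits(model, "amr_model"), NR >= 0, NS >= 0)
  N <- NR + NS
  if (N == 0) stop("mean fitness undefined for an empty population (N = 0)")
  (fitness_R(model) * NR + fitness_S(NR, model) * NS) / N
}

#' Demographic transition rates
#'
#' The four propensities of the multivariate birth-death process: births
#' at rate `f_strain / fbar` per capita (fitness relative to the population
#' mean) and deaths at the logistic rate `N / K` per capita, so that the
#' total population follows logistic dynamics with carrying capacity `K`
#' in the mean-field limit. Two exact identities hold for every state:
#' `TR_plus + TS_plus = N` (birth normalisation) and
#' `TR_minus + TS_minus = N^2 / K`.
#'
#' @param NR,NS Strain abundances, cells (non-negative scalars).
#' @param K Current carrying capacity, cells; positive.
#' @param model An [model_params()] object.
#' @return An object of class `"amr_rates"`: named list with `TR_plus`,
#'   `TR_minus`, `TS_plus`, `TS_minus` and their sum `total`. All zero when
#'   `N = 0` (the empty population is absorbing).
#' @examples
#' m <- model_params(0.1, 0.25, 150)
#' transition_rates(100, 100, K = 1000, m)
#' @export
transition_rates <- function(NR, NS, K, model) {
  stopifnot(inherits(model, "amr_model"),
            is.finite(NR), is.finite(NS), is.finite(K),
            NR >= 0, NS >= 0, K > 0)
  N <- NR + NS
  if (N == 0) {
    r <- list(TR_plus = 0, TR_minus = 0, TS_plus = 0, TS_minus = 0, total = 0)
    class(r) <- "amr_rates"
    return(r)
  }
  fbar <- mean_fitness(NR, NS, model)
  r <- list(TR_plus  = fitness_R(model) * NR / fbar,
            TR_minus = N / K * NR,
            TS_plus  = fitness_S(NR, model) * NS / fbar,
            TS_minus = N / K * NS)
  r$total <- r$TR_plus + r$TR_minus + r$TS_plus + r$TS_minus
  class(r) <- "amr_rates"
  r
}

#' @export
print.amr_rates <- function(x, ...) {
  cat(sprintf("birth: R %.6g, S %.6g | death: R %.6g, S %.6g | total %.6g\n",
              x$TR_plus, x$TS_plus, x$TR_minus, x$TS_minus, x$total))
  invisible(x)
}

#' Compositional absorption test
#'
#' The composition is absorbed once either strain is extinct: the birth and
#' death rates of an absent strain vanish, so only the surviving strain's
#' population size keeps fluctuating. Total extinction (`N = 0`) is its own
#' label and is never folded into a fixation count.
#'
#' @param NR,NS Strain abundances, cells.
#' @return One of `"none"`, `"R_fixed"`, `"S_fixed"`, `"extinct"`.
#' @export
is_absorbing <- function(NR, NS) {
  stopifnot(NR >= 0, NS >= 0)
  if (NR == 0 && NS == 0) return("extinct")
  if (NS == 0) return("R_fixed")
  if (NR == 0) return("S_fixed")
  "none"
}
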