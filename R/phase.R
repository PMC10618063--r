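#' Gaussian smoothing of a histogram over cell counts
#'
#' Convolves a mass vector with a discrete Gaussian kernel of width `sigma`
#' (in cells), truncated at `4 sigma` and renormalised at the edges so that
#' the total mass is preserved exactly. `sigma = 0` returns the input
#' unchanged.
#'
#' @param mass Non-negative numeric vector of histogram masses (bin width
#'   one cell).
#' @param sigma Kernel standard deviation in cells.
#' @return Smoothed vector of the same length and total mass.
#' @export
gaussian_smooth <- function(mass, sigma = 10) {
  stopifnot(all(mass >= 0), sigma >= 0)
  if (sigma == 0 || length(mass) < 2L) return(mass)
  half <- ceiling(4 * sigma)
  kern <- stats::dnorm(seq(-half, half), sd = sigma)
  kern <- kern / sum(kern)
  n <- length(mass)
  out <- numeric(n)
  wsum <- numeric(n)
  for (j in seq(-half, half)) {
    w <- kern[j + half + 1L]
    src <- seq_len(n) - j
    ok <- src >= 1L & src <= n
    out[ok] <- out[ok] + w * mass[src[ok]]
    wsum[src[ok]] <- wsum[src[ok]] + w
  }
  # edge renormalisation: mass near the boundary is not lost to truncation
  redistrib <- mass / ifelse(wsum > 0, wsum, 1)
  out <- numeric(n)
  for (j in seq(-half, half)) {
    w <- kern[j + half + 1L]
    src <- seq_len(n) - j
    ok <- src >= 1L & src <= n
    out[ok] <- out[ok] + w * redistrib[src[ok]]
  }
  out
}

#' Count modes of a smoothed histogram
#'
#' Local maxima whose prominence (height above the deepest valley separating
#' them from a higher maximum) exceeds `min_prominence` times the global
#' maximum.
#'
#' @param mass Numeric vector (e.g. from [gaussian_smooth()]).
#' @param min_prominence Relative prominence threshold in `(0, 1)`.
#' @return Integer mode count; the mode positions (indices) are attached as
#'   attribute `"positions"`.
#' @export
count_modes <- function(mass, min_prominence = 0.1) {
  n <- length(mass)
  if (n < 3L) return(structure(as.integer(any(mass > 0)), positions = which.max(mass)))
  is_max <- c(FALSE, mass[2:(n - 1)] > mass[1:(n - 2)] &
                mass[2:(n - 1)] >= mass[3:n], FALSE)
  # include boundary maxima
  if (mass[1] > mass[2]) is_max[1] <- TRUE
  if (mass[n] > mass[n - 1]) is_max[n] <- TRUE
  peaks <- which(is_max)
  if (length(peaks) == 0L) return(structure(0L, positions = integer(0)))
  gmax <- max(mass)
  keep <- logical(length(peaks))
  for (i in seq_along(peaks)) {
    p <- peaks[i]
    h <- mass[p]
    # highest saddle on the way to a higher peak, on each side
    saddle <- -Inf
    left <- peaks[peaks < p & mass[peaks] >= h]
    if (length(left)) saddle <- max(saddle, min(mass[max(left):p]))
    right <- peaks[peaks > p & mass[peaks] >= h]
    if (length(right)) saddle <- max(saddle, min(mass[p:min(right)]))
    prom <- if (is.finite(saddle)) h - saddle else h
    keep[i] <- prom >= min_prominence * gmax
  }
  structure(sum(keep), positions = peaks[keep])
}

#' Stationary abundance distributions
#'
#' Runs an ensemble with absorption *not* stopping the clock (the surviving
#' strain's population size keeps fluctuating), samples the state of every
#' replicate at `sampling_time` (default `2 <K>`, by when the size dynamics
#' has reached quasi-stationarity), and returns smoothed histograms of `N`,
#' `NR` and `NS` over cell counts, with modality diagnostics.
#'
#' @inheritParams run_ensemble
#' @param sampling_time Sampling time; default `2 <K>`.
#' @param sigma Gaussian smoothing width in cells (default 10).
#' @param min_prominence Mode-counting prominence threshold.
#' @return List of class `"amr_abund"` with `samples` (data frame of final
#'   `N`, `NR`, `NS`), `dist` (list of data frames `count`, `mass`,
#'   `smoothed` for `N`, `NR`, `NS`), `modes` (named mode counts), `means`
#'   (named means), and metadata.
#' @export
abundance_distributions <- function(model, env, n_reps, seed,
                                    sampling_time = default_horizon(env),
                                    init = NULL, sigma = 10,
                                    min_prominence = 0.1,
                                    max_events = 2e9) {
  ens <- run_ensemble(model, env, n_reps = n_reps, seed = seed, init = init,
                      horizon = sampling_time, stop_at_absorption = FALSE,
                      max_events = max_events)
  samples <- ens$runs[, c("N", "NR", "NS")]
  top <- max(samples$N, 1)
  dist <- lapply(samples, function(v) {
    mass <- tabulate(pmin(v, top) + 1L, nbins = top + 1L) / length(v)
    data.frame(count = 0:top, mass = mass,
               smoothed = gaussian_smooth(mass, sigma))
  })
  modes <- vapply(dist, function(d) as.integer(count_modes(d$smoothed,
                                                           min_prominence)),
                  integer(1))
  structure(list(samples = samples, dist = dist, modes = modes,
                 means = vapply(samples, mean, numeric(1)),
                 sampling_time = sampling_time, sigma = sigma,
                 model = model, env = env, n_reps = n_reps, seed = seed),
            class = "amr_abund")
}

#' @export
print.amr_abund <- function(x, ...) {
  cat(sprintf("Abundance distributions at t = %.4g (%d replicates)\n",
              x$sampling_time, x$n_reps))
  cat(sprintf("  means: N = %.1f, NR = %.1f, NS = %.1f\n",
              x$means[["N"]], x$means[["NR"]], x$means[["NS"]]))
  cat(sprintf("  modes (sigma = %g): N %d, NR %d, NS %d\n", x$sigma,
              x$modes[["N"]], x$modes[["NR"]], x$modes[["NS"]]))
  invisible(x)
}

#' Fixation/coexistence phase diagram over an environment grid
#'
#' Runs [run_ensemble()] at every `(nu, delta)` grid point and collects the
#' outcome fractions with binomial intervals, the mean final abundances,
#' and (optionally) whether the point lies inside the analytic optimal
#' eradication region. Per-point failures are caught, flagged and skipped
#' so a long scan always completes.
#'
#' @param model An [model_params()] object.
#' @param base_env An [env_params()] object supplying `Kplus`/`Kminus`.
#' @param nu_values,delta_values Grid axes (strictly monotone).
#' @param n_reps Replicates per grid point.
#' @param seed Base seed; per-point seeds are derived reproducibly.
#' @param overlay_region Add the analytic eradication-region membership?
#' @param ... Further arguments passed to [run_ensemble()].
#' @return Object of class `"amr_phase"`: list with `grid` (long-format
#'   data frame, one row per point) and metadata.
#' @export
scan_phase_diagram <- function(model, base_env, nu_values, delta_values,
                               n_reps, seed, overlay_region = TRUE, ...) {
  stopifnot(all(diff(nu_values) > 0) || length(nu_values) == 1L,
            all(diff(delta_values) > 0) || length(delta_values) == 1L)
  region <- if (overlay_region)
    tryCatch(optimal_eradication_region(model, base_env),
             error = function(e) NULL)
  pts <- expand.grid(nu = nu_values, delta = delta_values,
                     KEEP.OUT.ATTRS = FALSE)
  set.seed(seed)
  pt_seeds <- sample.int(.Machine$integer.max - 1L, nrow(pts))
  rows <- vector("list", nrow(pts))
  for (i in seq_len(nrow(pts))) {
    env_i <- env_params(base_env$Kplus, base_env$Kminus,
                        nu = pts$nu[i], delta = pts$delta[i])
    row <- data.frame(nu = pts$nu[i], delta = pts$delta[i],
                      seed = pt_seeds[i], n_reps = n_reps,
                      phi_R = NA_real_, phi_S = NA_real_,
                      p_coex = NA_real_, p_extinct = NA_real_,
                      phi_R_lo = NA_real_, phi_R_hi = NA_real_,
                      phi_S_lo = NA_real_, phi_S_hi = NA_real_,
                      mean_N = NA_real_, mean_NR = NA_real_,
                      mean_NS = NA_real_,
                      in_region = NA, failed = FALSE)
    ens <- tryCatch(
      run_ensemble(model, env_i, n_reps = n_reps, seed = pt_seeds[i], ...),
      error = function(e) {
        warning(sprintf("grid point (nu = %g, delta = %g) failed: %s",
                        pts$nu[i], pts$delta[i], conditionMessage(e)))
        NULL
      })
    if (is.null(ens)) {
      row$failed <- TRUE
    } else {
      s <- ens$summary
      g <- function(lab, col) s[[col]][match(lab, s$outcome)]
      row$phi_R <- g("R_fixed", "estimate")
      row$phi_S <- g("S_fixed", "estimate")
      row$p_coex <- g("coexistence", "estimate")
      row$p_extinct <- g("extinct", "estimate")
      row$phi_R_lo <- g("R_fixed", "ci_lo"); row$phi_R_hi <- g("R_fixed", "ci_hi")
      row$phi_S_lo <- g("S_fixed", "ci_lo"); row$phi_S_hi <- g("S_fixed", "ci_hi")
      row$mean_N <- mean(ens$runs$N)
      row$mean_NR <- mean(ens$runs$NR)
      row$mean_NS <- mean(ens$runs$NS)
    }
    if (!is.null(region))
      row$in_region <- region$membership(pts$nu[i], pts$delta[i])
    rows[[i]] <- row
  }
  structure(list(grid = do.call(rbind, rows), model = model,
                 base_env = base_env, n_reps = n_reps, seed = seed),
            class = "amr_phase")
}

#' @export
print.amr_phase <- function(x, ...) {
  cat(sprintf("Phase diagram scan: %d grid points, %d replicates each\n",
              nrow(x$grid), x$n_reps))
  print(utils::head(x$grid[, c("nu", "delta", "phi_R", "phi_S", "p_coex",
                               "p_extinct", "in_region")], 10),
        row.names = FALSE)
  invisible(x)
}

#' Mean abundances along environmental axes
#'
#' Samples the quasi-stationary state (at `2 <K>`, continuing past
#' compositional fixation) along a sweep of `nu` at fixed `delta` and/or a
#' sweep of `delta` at fixed `nu`, returning mean `N`, `NR`, `NS` per
#' point. The stationary mean population decreases with the switching rate
#' at fixed bias, increases with the bias at fixed rate, and approaches
#' `K+-` as `delta -> +-1`.
#'
#' @inheritParams scan_phase_diagram
#' @param nu_values Switching rates for the `nu` sweep (fixed `delta0`).
#' @param delta_values Biases for the `delta` sweep (fixed `nu0`).
#' @param delta0,nu0 Fixed values for the respective sweeps.
#' @param n_reps Replicates per point.
#' @return List with data frames `vs_nu` and `vs_delta` (columns: axis
#'   value, `mean_N`, `mean_NR`, `mean_NS`, `n_reps`).
#' @export
mean_abundances_vs_environment <- function(model, base_env, n_reps, seed,
                                           nu_values = NULL,
                                           delta_values = NULL,
                                           delta0 = 0, nu0 = base_env$nu,
                                           max_events = 2e9) {
  sweep_one <- function(nu, delta, sd) {
    env_i <- env_params(base_env$Kplus, base_env$Kminus, nu = nu,
                        delta = delta)
    ens <- run_ensemble(model, env_i, n_reps = n_reps, seed = sd,
                        horizon = default_horizon(env_i),
                        stop_at_absorption = FALSE, max_events = max_events)
    c(mean_N = mean(ens$runs$N), mean_NR = mean(ens$runs$NR),
      mean_NS = mean(ens$runs$NS))
  }
  set.seed(seed)
  out <- list(vs_nu = NULL, vs_delta = NULL)
  if (!is.null(nu_values)) {
    sds <- sample.int(.Machine$integer.max - 1L, length(nu_values))
    m <- t(vapply(seq_along(nu_values),
                  function(i) sweep_one(nu_values[i], delta0, sds[i]),
                  numeric(3)))
    out$vs_nu <- data.frame(nu = nu_values, delta = delta0, m,
                            n_reps = n_reps)
  }
  if (!is.null(delta_values)) {
    sds <- sample.int(.Machine$integer.max - 1L, length(delta_values))
    m <- t(vapply(seq_along(delta_values),
                  function(i) sweep_one(nu0, delta_values[i], sds[i]),
                  numeric(3)))
    out$vs_delta <- data.frame(nu = nu0, delta = delta_values, m,
                               n_reps = n_reps)
  }
  out
}

#' Composition of coexisting communities
#'
#' For each grid point, the mean resistant fraction `x = NR/N` computed
#' only over the replicates classified as long-lived coexistence, together
#' with the coexistence probability and the number of contributing runs.
#' Points where no replicate coexisted are flagged (`NA` mean), never
#' interpolated.
#'
#' @inheritParams scan_phase_diagram
#' @return Data frame with one row per grid point: `nu`, `delta`,
#'   `p_coex`, `n_coex`, `mean_x_coex`, `mean_NR_coex`, `mean_NS_coex`.
#' @export
coexistence_composition <- function(model, base_env, nu_values, delta_values,
                                    n_reps, seed, ...) {
  pts <- expand.grid(nu = nu_values, delta = delta_values,
                     KEEP.OUT.ATTRS = FALSE)
  set.seed(seed)
  pt_seeds <- sample.int(.Machine$integer.max - 1L, nrow(pts))
  rows <- vector("list", nrow(pts))
  for (i in seq_len(nrow(pts))) {
    env_i <- env_params(base_env$Kplus, base_env$Kminus,
                        nu = pts$nu[i], delta = pts$delta[i])
    ens <- run_ensemble(model, env_i, n_reps = n_reps, seed = pt_seeds[i],
                        ...)
    co <- ens$runs[ens$runs$outcome == "coexistence" & ens$runs$N > 0, ]
    rows[[i]] <- data.frame(
      nu = pts$nu[i], delta = pts$delta[i],
      p_coex = outcome_fraction(ens, "coexistence"),
      n_coex = nrow(co),
      mean_x_coex = if (nrow(co)) mean(co$NR / co$N) else NA_real_,
      mean_NR_coex = if (nrow(co)) mean(co$NR) else NA_real_,
      mean_NS_coex = if (nrow(co)) mean(co$NS) else NA_real_)
  }
  do.call(rbind, rows)
}
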