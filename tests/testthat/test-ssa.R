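test_that("identical seed and inputs give a bit-identical trajectory", {
  m <- bench_model()
  e <- bench_env(nu = 0.5)
  a <- simulate_population(m, e, horizon = 30, seed = 77, record = "full")
  b <- simulate_population(m, e, horizon = 30, seed = 77, record = "full")
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$final, b$final)
  c2 <- simulate_population(m, e, horizon = 30, seed = 78, record = "full")
  expect_false(identical(a$trajectory, c2$trajectory))
})

test_that("trajectories are event-valid: increasing times, single-step moves", {
  m <- bench_model(Nth = 10)
  e <- env_params(60, 20, nu = 0.5, delta = 0.2)
  sim <- simulate_population(m, e, init = list(NR = 10, NS = 20, xi = 1),
                             horizon = 20, seed = 5, record = "full")
  tr <- sim$trajectory
  expect_true(all(diff(tr$time) > 0))
  dNR <- diff(tr$NR); dNS <- diff(tr$NS); dxi <- diff(tr$xi)
  one_step <- (abs(dNR) + abs(dNS) == 1 & dxi == 0) |
    (dNR == 0 & dNS == 0 & abs(dxi) == 2)
  expect_true(all(one_step))
  expect_true(all(tr$NR >= 0 & tr$NS >= 0))
  expect_true(all(tr$K == carrying_capacity(tr$xi, e)))
})

test_that("an initially absorbed composition is classified at time zero", {
  m <- bench_model()
  e <- bench_env()
  sim <- simulate_population(m, e, init = list(NR = 0, NS = 50, xi = 1),
                             horizon = 10, seed = 1)
  expect_identical(sim$outcome$label, "S_fixed")
  expect_identical(sim$t_abs, 0)
  ext <- simulate_population(m, e, init = list(NR = 0, NS = 0, xi = 1),
                             horizon = 10, seed = 1)
  expect_identical(ext$outcome$label, "extinct")
})

test_that("the event guard reports truncation explicitly", {
  m <- bench_model()
  e <- bench_env()
  sim <- simulate_population(m, e, horizon = 1000, seed = 3,
                             max_events = 50)
  expect_true(sim$truncated)
})

test_that("small-system distribution matches direct master-equation integration", {
  # truncated ME on (NR, NS) in 0..cap, static K0; the SSA must sample it
  # exactly. Oracle: dense generator integrated with deSolve.
  m <- model_params(0.1, 0.25, 5)
  K0 <- 15; cap <- 40L
  idx <- function(nr, ns) nr * (cap + 1L) + ns + 1L
  nstate <- (cap + 1L)^2
  Q <- matrix(0, nstate, nstate)
  for (nr in 0:cap) for (ns in 0:cap) {
    if (nr + ns == 0) next
    r <- transition_rates(nr, ns, K0, m)
    i <- idx(nr, ns)
    if (nr < cap && r$TR_plus > 0) Q[idx(nr + 1L, ns), i] <- Q[idx(nr + 1L, ns), i] + r$TR_plus
    if (ns < cap && r$TS_plus > 0) Q[idx(nr, ns + 1L), i] <- Q[idx(nr, ns + 1L), i] + r$TS_plus
    if (nr > 0) Q[idx(nr - 1L, ns), i] <- Q[idx(nr - 1L, ns), i] + r$TR_minus
    if (ns > 0) Q[idx(nr, ns - 1L), i] <- Q[idx(nr, ns - 1L), i] + r$TS_minus
    out <- r$TR_plus * (nr < cap) + r$TS_plus * (ns < cap) + r$TR_minus + r$TS_minus
    Q[i, i] <- Q[i, i] - out
  }
  p0 <- numeric(nstate); p0[idx(5L, 5L)] <- 1
  sol <- deSolve::ode(y = p0, times = c(0, 1), parms = NULL,
                      func = function(t, y, p) list(as.vector(Q %*% y)))
  p1 <- pmax(sol[2, -1], 0)
  grid <- expand.grid(ns = 0:cap, nr = 0:cap)   # column-major over idx
  me_mean_NR <- sum(grid$nr * p1)
  me_mean_NS <- sum(grid$ns * p1)
  me_var_NR <- sum(grid$nr^2 * p1) - me_mean_NR^2

  n_reps <- 4000
  set.seed(88)
  seeds <- sample.int(1e6, n_reps)
  fin <- t(vapply(seeds, function(sd) {
    s <- simulate_population(m, static_env(K0),
                             init = list(NR = 5, NS = 5, xi = 1),
                             horizon = 1, seed = sd,
                             stop_at_absorption = FALSE)
    c(s$final$NR, s$final$NS)
  }, numeric(2)))
  se_NR <- sqrt(me_var_NR / n_reps)
  expect_lt(abs(mean(fin[, 1]) - me_mean_NR), 3 * se_NR)
  expect_lt(abs(mean(fin[, 2]) - me_mean_NS), 4 * sqrt(me_var_NR / n_reps))
  # pointwise marginal check at a few abundances
  for (k in c(3, 5, 8)) {
    pk <- sum(p1[grid$nr == k])
    phat <- mean(fin[, 1] == k)
    expect_lt(abs(phat - pk), 3 * sqrt(pk * (1 - pk) / n_reps) + 1e-3)
  }
})

test_that("neutral dynamics fixates in proportion to the initial count", {
  m <- model_params(0, 0, 1)
  ens <- run_ensemble(m, static_env(30), n_reps = 600, seed = 21,
                      init = list(NR = 10, NS = 20, xi = 1), horizon = 1e5)
  p0 <- 10 / 30
  se <- sqrt(p0 * (1 - p0) / 600)
  expect_lt(abs(outcome_fraction(ens, "R_fixed") - p0), 3 * se)
})

test_that("constant-K fixation fraction matches the exact Moran probability", {
  m <- model_params(0.1, 0.25, 13)
  K0 <- 40
  phi <- fixation_probability_exact(13, K0, m)
  ens <- run_ensemble(m, static_env(K0), n_reps = 400, seed = 15,
                      init = list(NR = 13, NS = K0 - 13, xi = 1),
                      horizon = 1e6)
  se <- sqrt(phi * (1 - phi) / 400)
  expect_lt(abs(outcome_fraction(ens, "R_fixed") - phi), 3 * se)
  expect_identical(outcome_fraction(ens, "coexistence"), 0)
})

test_that("population size keeps tracking K after compositional fixation", {
  m <- bench_model(Nth = 10)
  e <- env_params(250, 50, nu = 0.5, delta = 0)
  sim <- simulate_population(m, e, init = list(NR = 0, NS = 150, xi = 1),
                             horizon = 400, seed = 33,
                             stop_at_absorption = FALSE, record = "grid")
  tr <- sim$trajectory
  late <- tr[tr$time > 20, ]
  expect_true(all(late$NR == 0))                      # composition stays absorbed
  expect_gt(mean(late$N), e$Kminus)
  expect_lt(mean(late$N), e$Kplus)
  # size correlates with the driving capacity
  expect_gt(mean(late$N[late$xi == 1]), mean(late$N[late$xi == -1]))
})

test_that("ensemble fractions partition unity and trivial cases behave", {
  m <- bench_model()
  e <- bench_env(nu = 0.1)
  ens <- run_ensemble(m, e, n_reps = 40, seed = 2, horizon = 30)
  expect_equal(sum(ens$summary$estimate), 1)
  expect_identical(sum(ens$summary$count), 40L)
  one <- run_ensemble(m, e, n_reps = 1, seed = 5,
                      init = list(NR = 10, NS = 0, xi = 1), horizon = 5)
  expect_identical(outcome_fraction(one, "R_fixed"), 1)
  # reproducible given the same base seed
  ens2 <- run_ensemble(m, e, n_reps = 40, seed = 2, horizon = 30)
  expect_identical(ens$runs, ens2$runs)
})

test_that("classification separates coexistence at horizon from absorption", {
  m <- bench_model(Nth = 10)
  sim_fix <- list(final = list(NR = 30, NS = 0, t_end = 12), t_abs = 12)
  expect_identical(classify_outcome(sim_fix, horizon = 100)$label, "R_fixed")
  sim_co <- list(final = list(NR = 10, NS = 20, t_end = 100), t_abs = NA_real_)
  expect_identical(classify_outcome(sim_co, horizon = 100)$label, "coexistence")
  sim_ext <- list(final = list(NR = 0, NS = 0, t_end = 40), t_abs = 40)
  expect_identical(classify_outcome(sim_ext, horizon = 100)$label, "extinct")
})
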