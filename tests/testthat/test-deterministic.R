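test_that("total population follows the closed-form logistic solution", {
  m <- bench_model()
  K0 <- 500; N0 <- 20
  path <- integrate_mean_field(m, K0, init = list(N = N0, x = 0.5),
                               t_end = 15, n_out = 200)
  closed <- K0 * N0 * exp(path$time) / (K0 + N0 * (exp(path$time) - 1))
  expect_equal(path$N, closed, tolerance = 1e-6)
  # fixed point: starting at K0 stays at K0
  flat <- integrate_mean_field(m, K0, init = list(N = K0, x = 0.5), t_end = 5)
  expect_equal(flat$N, rep(K0, nrow(flat)), tolerance = 1e-6)
})

test_that("resistant fraction moves toward the coexistence equilibrium", {
  m <- bench_model(Nth = 50)
  K0 <- 200
  up <- integrate_mean_field(m, K0, init = list(N = K0, x = 0.1), t_end = 2)
  expect_true(all(diff(up$x) > 0))        # NR = 20 < Nth: x increases
  dn <- integrate_mean_field(m, K0, init = list(N = K0, x = 0.5), t_end = 2)
  expect_true(all(diff(dn$x) < 0))        # NR = 100 > Nth: x decreases
  # long-run convergence to x_th = Nth/K0
  lng <- integrate_mean_field(m, K0, init = list(N = K0, x = 0.1), t_end = 200)
  expect_equal(lng$x[nrow(lng)], 50 / 200, tolerance = 0.02)
})

test_that("size relaxes on a faster time scale than composition", {
  m <- model_params(0.05, 0.12, 50)
  K0 <- 200
  path <- integrate_mean_field(m, K0, init = list(N = 0.5 * K0, x = 0.1),
                               t_end = 120, n_out = 2000)
  t_N <- path$time[which(abs(path$N - K0) / K0 < 0.05)[1]]
  xeq <- 50 / 200
  t_x <- path$time[which(abs(path$x - xeq) / xeq < 0.05)[1]]
  expect_lt(t_N, t_x / 3)
})

test_that("PDMP with no switches reduces to the mean-field flow", {
  m <- bench_model(Nth = 30)
  e <- env_params(300, 100, nu = 1e-8, delta = 0)
  path0 <- data.frame(time = 0, xi = 1)
  attr(path0, "t_end") <- 10
  pd <- integrate_pdmp(m, e, init = list(N = 50, x = 0.3), t_end = 10,
                       env_path = path0, n_out = 100)
  mf <- integrate_mean_field(m, K0 = 300, init = list(N = 50, x = 0.3),
                             t_end = 10, n_out = 100)
  merged <- merge(pd, mf, by = "time", suffixes = c("_pd", "_mf"))
  expect_gt(nrow(merged), 50)
  expect_equal(merged$N_pd, merged$N_mf, tolerance = 1e-6)
  expect_equal(merged$x_pd, merged$x_mf, tolerance = 1e-6)
})

test_that("PDMP tracks the switching capacity and is deterministic given a path", {
  m <- model_params(0.2, 0.5, 30)
  e <- env_params(250, 50, nu = 0.2, delta = 0.6)
  path <- simulate_dmn(e, t_end = 120, seed = 19)
  pd <- integrate_pdmp(m, e, init = list(N = 250, x = 30 / 250),
                       t_end = 120, env_path = path)
  pd2 <- integrate_pdmp(m, e, init = list(N = 250, x = 30 / 250),
                        t_end = 120, env_path = path)
  expect_identical(pd, pd2)
  # N stays within the capacity band after initial relaxation
  late <- pd[pd$time > 5, ]
  expect_true(all(late$N > 45 & late$N < 255))
  # long stretches in one environment approach the current capacity
  durs <- diff(c(path$time, 120))
  long_idx <- which(durs > 10 & path$time + durs <= 120)
  for (i in long_idx) {
    t_close <- path$time[i] + durs[i] - 0.01
    K_i <- carrying_capacity(path$xi[i], e)
    N_close <- late$N[which.min(abs(late$time - t_close))]
    expect_equal(N_close, K_i, tolerance = 0.05)
  }
})

test_that("fast-switching mean field with the harmonic capacity is stationary at Kbar", {
  m <- bench_model()
  e <- bench_env()
  Kbar <- effective_carrying_capacities(e)$Kbar
  mf <- integrate_mean_field(m, K0 = Kbar, init = list(N = 600, x = 0.2),
                             t_end = 30)
  expect_equal(mf$N[nrow(mf)], Kbar, tolerance = 1e-4)
})

test_that("dip time and dip minimum match the closed forms and their bounds", {
  m <- bench_model()
  e <- bench_env()
  expect_equal(dip_time(m, e), log(5.28), tolerance = 1e-12)    # 1.6639
  d <- dip_minimum(m, e)
  expect_equal(d$NR_dip, 16.485, tolerance = 1e-3)
  expect_equal(d$lower_bound, 9.6)
  expect_equal(d$N_at_dip, 120 * 0.9 / 0.75)                    # 144
  expect_false(d$eradication_feasible)                          # 16.5 > 10
  expect_gte(d$NR_dip, d$lower_bound)
  # extreme bottleneck limit: t_dip -> ln((1-s)/(a-s))
  e_deep <- env_params(1e9, 120, nu = 0.1, delta = 0)
  expect_equal(dip_time(m, e_deep), log(0.9 / 0.15), tolerance = 1e-6)
  # dip bottom decreases with capacity contrast
  dips <- vapply(c(500, 1000, 5000), function(Kp)
    dip_minimum(m, env_params(Kp, 120, 0.1, 0))$NR_dip, numeric(1))
  expect_true(all(diff(dips) < 0))
  # invalid regimes are rejected
  expect_error(dip_time(m, static_env(120)), "Kminus < Kplus")
  expect_error(dip_time(model_params(0.2, 0.2, 10), e), "a > s")
})

test_that("numeric dip from the deterministic flow matches the analytics", {
  # switch K+ -> K- from the coexistence equilibrium: integrate at K- from
  # N(0) = K+, NR(0) = Nth and locate the resistant-abundance minimum
  m <- bench_model()
  e <- bench_env()
  mf <- integrate_mean_field(m, K0 = e$Kminus,
                             init = list(N = e$Kplus, x = m$Nth / e$Kplus),
                             t_end = 12, n_out = 6000)
  i <- which.min(mf$NR)
  d <- dip_minimum(m, e)
  expect_equal(mf$time[i], d$t_dip, tolerance = 0.10)
  expect_equal(mf$NR[i], d$NR_dip, tolerance = 0.15)
  # population size at the dip bottom ~ K- (1-s)/(1-a)
  expect_equal(mf$N[i], d$N_at_dip, tolerance = 0.10)
})

test_that("eradication region bounds, membership and degenerate limits", {
  m <- bench_model()
  e <- bench_env()
  reg <- optimal_eradication_region(m, e)
  expect_equal(unname(reg$nu_plus_bounds), c(0.1 / (2 * log(1000 / 120)), 0.1),
               tolerance = 1e-10)
  expect_equal(unname(reg$nu_minus_bounds),
               c(0.15 / (2 * log(1000 / 120)), 1 / log(5.28)),
               tolerance = 1e-10)
  expect_true(reg$nonempty)
  expect_true(reg$membership(0.05, 0))       # 0.05 sits in both intervals
  expect_false(reg$membership(0.05, 0.999))  # nu(1-delta) -> 0 below lower bound
  expect_false(reg$membership(1e-4, 0))
  expect_false(reg$membership(100, 0))
})

test_that("large-population transferability criterion", {
  e <- bench_env()
  lp <- large_population_criterion(bench_model(Nth = 80), e)
  expect_equal(lp$value, 9.6)
  expect_true(lp$transferable)
  lp2 <- large_population_criterion(bench_model(Nth = 100), e)
  expect_equal(lp2$value, 12)
  expect_false(lp2$transferable)
})
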