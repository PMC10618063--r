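# Shared fixtures: the benchmark parameter set used throughout (moderate
# cost/impact, harsh-mild capacity contrast) and a first-step-analysis
# oracle for the effective Moran chain, independent of the closed-form
# implementation it validates.

bench_model <- function(Nth = 80) model_params(s = 0.1, a = 0.25, Nth = Nth)

bench_env <- function(nu = 0.1, delta = 0) {
  env_params(Kplus = 1000, Kminus = 120, nu = nu, delta = delta)
}

# Exact absorption quantities by first-step analysis: a tridiagonal linear
# solve (Thomas algorithm) on the interior states 1..K0-1 of the effective
# Moran chain. Absorption times can reach ~1e9 x the event scale, making the
# system condition number ~1e12; a plain double-precision solve then only
# delivers ~1e-5 relative accuracy. The elimination is therefore carried out
# in compensated double-double arithmetic (~31 significant digits), which
# keeps the oracle's own error far below the 1e-8/1e-10 comparison levels.

# double-double primitives (Dekker/Knuth); numbers are c(hi, lo)
dd_two_sum <- function(a, b) {
  s <- a + b
  bb <- s - a
  c(s, (a - (s - bb)) + (b - bb))
}
dd_split <- function(a) {
  t <- 134217729 * a           # 2^27 + 1
  hi <- t - (t - a)
  c(hi, a - hi)
}
dd_two_prod <- function(a, b) {
  p <- a * b
  as_ <- dd_split(a); bs <- dd_split(b)
  err <- ((as_[1] * bs[1] - p) + as_[1] * bs[2] + as_[2] * bs[1]) +
    as_[2] * bs[2]
  c(p, err)
}
dd_norm <- function(hi, lo) {
  s <- hi + lo
  c(s, lo - (s - hi))
}
dd_add <- function(x, y) {
  s <- dd_two_sum(x[1], y[1])
  dd_norm(s[1], s[2] + x[2] + y[2])
}
dd_neg <- function(x) -x
dd_mul <- function(x, y) {
  p <- dd_two_prod(x[1], y[1])
  dd_norm(p[1], p[2] + x[1] * y[2] + x[2] * y[1])
}
dd_div <- function(x, y) {
  q1 <- x[1] / y[1]
  r <- dd_add(x, dd_neg(dd_mul(c(q1, 0), y)))
  q2 <- r[1] / y[1]
  r <- dd_add(r, dd_neg(dd_mul(c(q2, 0), y)))
  q3 <- r[1] / y[1]
  dd_norm(q1, q2 + q3)
}

# Thomas solve of  sub[i] x[i-1] + diag[i] x[i] + sup[i] x[i+1] = b[i].
# The diagonal is supplied as a list of dd pairs: the absorption systems have
# exact zero row sums (-diag = sub + sup), and rounding that sum to a single
# double perturbs the solution by cond(A) * u, which the huge absorption
# times amplify to ~1e-5. Keeping diag = -(up + down) unrounded avoids it.
dd_thomas <- function(sub, diag_dd, sup, b) {
  m <- length(sup)
  if (m == 1L) return(b[1] / (diag_dd[[1]][1] + diag_dd[[1]][2]))
  cp <- vector("list", m)
  dp <- vector("list", m)
  cp[[1]] <- dd_div(c(sup[1], 0), diag_dd[[1]])
  dp[[1]] <- dd_div(c(b[1], 0), diag_dd[[1]])
  for (i in 2:m) {
    den <- dd_add(diag_dd[[i]], dd_neg(dd_mul(c(sub[i], 0), cp[[i - 1]])))
    cp[[i]] <- dd_div(c(sup[i], 0), den)
    dp[[i]] <- dd_div(dd_add(c(b[i], 0),
                             dd_neg(dd_mul(c(sub[i], 0), dp[[i - 1]]))), den)
  }
  x <- vector("list", m)
  x[[m]] <- dp[[m]]
  for (i in (m - 1):1)
    x[[i]] <- dd_add(dp[[i]], dd_neg(dd_mul(cp[[i]], x[[i + 1]])))
  vapply(x, function(v) v[1] + v[2], numeric(1))
}

moran_oracle <- function(K0, model) {
  n <- seq_len(K0 - 1)
  r <- effective_moran_rates(n, K0, model)
  sub <- c(0, r$down[-1])
  dg <- lapply(n, function(i) dd_two_sum(-r$up[i], -r$down[i]))
  sup <- c(r$up[-(K0 - 1)], 0)
  bphi <- -ifelse(n == K0 - 1, r$up, 0)
  list(phi = dd_thomas(sub, dg, sup, bphi),
       tau = dd_thomas(sub, dg, sup, rep(-1, K0 - 1)))
}
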