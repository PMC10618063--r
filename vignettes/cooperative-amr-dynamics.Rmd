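---
title: "Eco-evolutionary dynamics of cooperative antimicrobial resistance under switching environments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eco-evolutionary dynamics of cooperative antimicrobial resistance under switching environments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amrswitch)
```

## The model

`amrswitch` simulates and analyses a well-mixed microbial community of two
strains under a constant input of a biostatic (growth-inhibiting) drug. The
resistant strain R constitutively produces a drug-inactivating enzyme at a
metabolic cost; the sensitive strain S does not. Enzyme concentration is
proxied by the resistant abundance $N_R$, and resistance acts as a
*thresholded public good*: once $N_R \ge N_{\mathrm{th}}$ there is enough
enzyme to push the drug below its minimum inhibitory concentration for the
whole community.

Fitnesses are

$$f_R = 1 - s, \qquad
  f_S = 1 - a\,\theta[N_{\mathrm{th}} - N_R],$$

with $0 \le s \le a < 1$; $s$ is the cost of resistance, $a$ the
growth-rate reduction the drug inflicts on unprotected S cells, and
$\theta$ the Heaviside step with the convention $\theta[0] = 0$, so
cooperation is already active at exactly $N_R = N_{\mathrm{th}}$. Below the
threshold R outgrows S; at or above it the ordering reverses, which creates
a stable coexistence equilibrium at $N_R = N_{\mathrm{th}}$.

Each strain is born at per-capita rate $f_{R/S}/\bar f$ (fitness relative
to the population mean $\bar f$) and dies at the logistic rate $N/K$. Two
identities pin the process down exactly: total birth rate $= N$ and total
death rate $= N^2/K$, so the population size follows logistic dynamics
toward the carrying capacity $K$ in the mean-field limit, decoupled from
the composition. The mean-fitness normalisation also maps the
fixed-$N$ composition dynamics onto a classical Moran process, which is
what makes the static-environment theory exact.

Environmental variability enters through the carrying capacity:
$K(t) \in \{K_-, K_+\}$ is driven by dichotomous Markov (telegraph) noise
$\xi(t) \in \{-1, +1\}$ that flips at rate $\nu(1 - \delta\xi)$. The mean
switching rate is $\nu$ and the bias $\delta$; at stationarity
$\xi = \pm 1$ with probability $(1 \pm \delta)/2$, and the autocovariance
decays as $(1 - \delta^2)e^{-2\nu|t - t'|}$. Sudden $K_+ \to K_-$ switches
are population bottlenecks: they couple environmental variability to
demographic noise, which is the mechanism of interest.

## Units and time scale

Time is measured in units of the baseline birth rate (the fitness-1
strain's generation scale); all rates — $\nu$, the dip time, mean
coexistence times — are in these units. A rough laboratory translation is
one unit $\approx$ one replication cycle ($\sim$ 1 h for fast-growing
bacteria), so the interesting switching regime $\nu \sim s \sim 0.1$
corresponds to environmental phases of order ten generations.

## What the simulator does

`simulate_population()` runs the Gillespie algorithm over five reaction
channels: R birth, R death, S birth, S death, and the environmental flip.
Because all rates are constant between events, adding the switch as a fifth
channel keeps the composite simulation a statistically exact sample of the
joint master equation; the test suite checks the sampled distribution of a
small system against direct numerical integration of the truncated master
equation. The core loop is implemented in C++ (Rcpp) with R's RNG, so a
seed gives a bit-identical trajectory and ensembles are reproducible from a
single base seed.

Compositional absorption ($N_R = 0$ or $N_S = 0$) stops a run by default.
The population *size* keeps fluctuating after fixation, so analyses of
abundance distributions pass `stop_at_absorption = FALSE` and sample the
surviving strain at the quasi-stationary horizon. Total extinction
($N = 0$) is always its own outcome label, never folded into fixation
counts. An event-count guard marks truncated runs explicitly.

### Ensemble conditions

Phase-diagram ensembles start from the coexistence equilibrium of the
environment the run finds itself in: $\xi_0$ drawn from the stationary law,
$N_0 = K(\xi_0)$, $N_R(0) = \min(N_{\mathrm{th}}, N_0 - 1)$. This extends
the static-environment convention (start at the coexistence composition
$x_{\mathrm{th}} = N_{\mathrm{th}}/K_0$) to the fluctuating case; it is the
package's declared default, configurable through `init`.

The default horizon is $2\langle K\rangle$, twice the arithmetic stationary
mean capacity. Runs with both strains alive at the horizon count as
*long-lived coexistence*. $\langle K\rangle$ bounds the stationary mean
population size from above, so the rule is computable before any
simulation.

The benchmark parameter set used throughout the tests and the acceptance
script is $s = 0.1$, $a = 0.25$, $K_- = 120$, $K_+ = 1000$,
$N_{\mathrm{th}} = 80$ — plausible magnitudes for enzymatic resistance
costs and sub-MIC drug impact, with a capacity contrast large enough for
bottleneck-driven dips yet small enough that demographic noise does not
swamp the dynamics.

## Static-environment theory

At constant $K_0$ the size relaxes in $O(1)$ time while the composition
evolves on the slower scales $1/s$ and $1/(a - s)$, so the composition is
well described by a Moran chain at fixed $N = K_0$ with effective exchange
rates $\tilde T_R^\pm = T_R^\pm T_S^\mp / N$. The hop ratio
$\gamma(n) = \tilde T_R^-/\tilde T_R^+ = f_S(n)/f_R$ is piecewise constant,
and the R fixation probability and mean coexistence time (MCT) follow from
the standard absorption formulas of a birth–death chain:

$$\phi(n_0) = \frac{\sum_{m=0}^{n_0-1}\rho_m}{\sum_{m=0}^{K_0-1}\rho_m},
  \qquad \rho_m = \prod_{j \le m}\gamma(j),$$

with the analogous telescoped sums for the MCT. All products and sums are
accumulated in log space, so the formulas remain stable for $K_0$ up to
$10^5$ (the MCT itself may overflow to `Inf` for astronomically long
coexistence, which is reported as such).

Starting at the coexistence equilibrium, the fixation probability admits
the closed approximation

$$\phi \simeq \frac{1}{1 + (1-s)^{-(K_0 - K_0^*)}}, \qquad
  K_0^* = N_{\mathrm{th}}\frac{\ln(1-a)}{\ln(1-s)}
        - \frac{\ln\!\big(s(1-a)/(a-s)\big)}{\ln(1-s)},$$

where $K_0^*$ is the population size at which R and S fixate equiprobably
($\phi(K_0^*) = \tfrac12$ exactly). For $s = 0.1$, $a = 0.25$ the leading
ratio $\ln(1-a)/\ln(1-s) \approx 2.73$, i.e. $K_0^* \approx 3
N_{\mathrm{th}}$: resistance prevails in populations up to roughly three
times the threshold.

```{r moran}
m <- model_params(s = 0.1, a = 0.25, Nth = 20)
fixation_probability_approx(120, m)$K0_star
fixation_probability_exact(20, 120, m)
```

### Validation strategy, and what the Moran reduction does not capture

The closed-form $\phi$ and MCT are validated against an independent
first-step-analysis oracle: a tridiagonal (Thomas) solve of the absorption
equations, run in compensated double-double arithmetic because absorption
times of order $10^9$ make the linear system's condition number
$\sim 10^{12}$ — a plain double solve is then itself only accurate to
$\sim 10^{-5}$ and would dominate the comparison. With the high-precision
oracle the implementations agree to better than $10^{-8}$ relative over
all tested chains (sizes up to 200). The oracle keeps the diagonal
$-(\tilde T^+ + \tilde T^-)$ as an unrounded two-term sum: absorption
systems have exact zero row sums, and rounding that structure away is
precisely what the large absorption times amplify.

The full two-variable simulation at constant $K$ reproduces the Moran
$\phi$ within binomial error (the hop *ratios* are preserved exactly), but
its mean absorption time runs $\sim 30\%$ below the one-dimensional MCT at
the benchmark size $K_0 = 120$: population-size fluctuations contribute
compositional noise that the fixed-$N$ reduction discards, so the reduction
preserves where the chain is absorbed much more faithfully than how long
absorption takes. Tests therefore assert tight agreement for $\phi$ and
order-of-magnitude agreement for the time scale.

## Deterministic limits and the transient dip

With demographic noise switched off the model becomes a
piecewise-deterministic Markov process (PDMP): logistic flow of $N$ toward
the current $K(t)$, coupled to the composition equation, with $K$ jumping
at the telegraph switch times. `integrate_mean_field()` and
`integrate_pdmp()` integrate these flows with `deSolve` (adaptive `lsodar`,
default relative tolerance $10^{-8}$).

The right-hand side is discontinuous at $N_R = N_{\mathrm{th}}$. The
integrator detects the crossing with a root function and restarts on the
appropriate branch; when the one-sided fields *bracket* the surface (below
pushes up, above pushes down) the trajectory follows the Filippov sliding
solution — $N_R$ pinned at $N_{\mathrm{th}}$, equivalently
$x = N_{\mathrm{th}}/N$, while only $N$ is integrated — until the fields
stop bracketing. This is exactly the coexistence equilibrium tracking
$x_{\mathrm{th}}(t) = N_{\mathrm{th}}/N(t)$; without it, event-detected
integration chatters at the equilibrium and stalls.

After a bottleneck ($K_+ \to K_-$) the size crashes faster than the
composition responds and drags $N_R$ through a transient dip. From a start
at $N(0) \approx K_+$, $N_R(0) = N_{\mathrm{th}}$:

$$t_{\mathrm{dip}} = \ln\!\Big[\frac{1-s}{a-s}\Big(1 -
  \frac{K_-}{K_+}\Big)\Big], \qquad
  N_R^{\mathrm{dip}} = N_{\mathrm{th}}\,\frac{K_-}{K_+}\,
  \frac{1-s}{1-a}\Big(\frac{1-s}{a-s}\Big)^{(a-s)/(1-a)}
  \;\gtrsim\; N_{\mathrm{th}}\frac{K_-}{K_+}.$$

```{r dip}
m80 <- model_params(0.1, 0.25, 80)
e <- env_params(Kplus = 1000, Kminus = 120, nu = 0.1, delta = 0)
dip_minimum(m80, e)
```

These closed forms are themselves approximations (they assume
$K_+ \gg K_- \gg 1$ and neglect the drift of $x$ during the crash); the
numeric PDMP minimum sits within about 7% of the formulas at the benchmark
parameters, and the tests allow 10–15%.

Demographic fluctuations at the dip bottom are of order
$\sqrt{N_R^{\mathrm{dip}}}$, so eradication of R by noise requires a dip
bottom of order one; the package operationalises this as
$N_R^{\mathrm{dip}} \le 10$ (configurable). Four timing conditions — long
enough mild phases for recovery, harsh phases long enough to reach the dip
but short enough to spare S, cycles as fast as possible — bound the
products $\nu(1-\delta)$ and $\nu(1+\delta)$ and give the analytic
*optimal eradication region* returned by `optimal_eradication_region()`.
The same dip scale $N_{\mathrm{th}} K_-/K_+$ controls transferability to
large populations: as long as it stays $\lesssim 10$ the mechanism
survives arbitrary absolute sizes (`large_population_criterion()`).

## Phase diagrams and abundance structure

`scan_phase_diagram()` estimates $\hat\phi_R$, $\hat\phi_S$,
$\hat P_{\mathrm{coex}}$ and the extinction fraction over a $(\nu, \delta)$
grid with exact binomial intervals; the fractions partition unity at every
point, failed points are flagged and skipped, and the analytic eradication
region can be overlaid per point. The qualitative picture reproduced by
the tests: sensitive-strain fixation (eradication of resistance) peaks at
intermediate switching $\nu \sim s$, while very slow and very fast
environments favour resistant fixation or long-lived coexistence.

`abundance_distributions()` samples every replicate at the horizon
(continuing past compositional fixation) and smooths the cell-count
histograms with a Gaussian kernel of width $\sigma = 10$ cells, truncated
at $4\sigma$ and renormalised at the edges so mass is preserved exactly.
Modes are counted with a prominence rule (default 10% of the global
maximum) to avoid counting smoothing ripples. Fast switching
($\nu \gg s$) self-averages the environment: the size distribution is
unimodal around the harmonic-type effective capacity
$\bar K = 2K_+K_-/[(1-\delta)K_+ + (1+\delta)K_-]$; slow switching splits
it into modes near $K_-$ and $K_+$.

```{r kbar}
effective_carrying_capacities(env_params(1000, 120, nu = 100, delta = 0))
```

## Problem sizes and reproducibility

The test suite and the acceptance script run at desk scale, chosen so the
full suite completes in minutes on one core: 2000 replicates for the
constant-capacity fixation comparison, 500 replicates per switching rate
for the eradication ordering, 300 for abundance distributions, telegraph
paths of $10^5$ time units, and Moran chains up to $K_0 = 200$ against the
oracle (the closed forms themselves are exercised up to $10^5$). These are
about an order of magnitude below the replicate counts one would use for
publication-quality phase diagrams; the binomial intervals reported with
every estimate make the Monte-Carlo resolution explicit. All randomness
flows from user-supplied seeds; per-replicate and per-grid-point seeds are
derived reproducibly and stored in the outputs.

## What the in-silico conditions do and do not emulate

The simulator *is* the model: a well-mixed community, a sharp public-good
threshold in R abundance (constant-volume chemostat logic), biostatic drug
action at constant influx, and binary environmental switching at
stationarity. Real systems add structure the model deliberately omits:
spatial organisation and local enzyme gradients, smooth or
concentration-dependent (quorum-sensing) regulation of enzyme production,
biocidal drug action at high concentration, threshold set by the resistant
*fraction* rather than abundance, and periodic rather than random
environments. Passing tests therefore establish the internal consistency
of model, theory and simulation — not that any particular laboratory
community obeys the threshold rule. The fitness normalisation by $\bar f$
is a modelling convenience (it exactly decouples size from composition);
results are expected to be robust to it, but only the normalised form is
implemented.

## Known limitations

- The MCT of the one-dimensional Moran reduction overestimates the
  two-variable absorption time by tens of percent at moderate $K_0$ (see
  above); use it for scaling and ordering, not as a precise clock.
- The dip formulas degrade as $K_+/K_-$ approaches 1 (the dip disappears;
  the functions reject the invalid regime explicitly).
- `mean_coexistence_time()` returns `Inf` when the absorption time
  overflows double precision; the fixation probabilities remain finite and
  accurate.
- Ensemble estimates are exact-binomial per outcome but outcomes are
  correlated across labels (they partition the same runs); joint inference
  across labels should resample instead.
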