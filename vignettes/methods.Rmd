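---
title: "Methods: coupled demography and thermal-optimum evolution in a predator–prey system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupled demography and thermal-optimum evolution in a predator-prey system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`evorescue` couples daily predator–prey demography to the evolution of a
single quantitative trait — the thermal optimum of each species'
performance curve — under a seasonally varying, gradually warming
climate. This vignette records the model's assumptions, the numerical
design, the parameter defaults and why they were chosen, and what the
package's tests do and do not establish.

## The model in brief

### Climate

Daily temperature is the deterministic three-parameter series
$T(t) = -s\cos(2\pi t/365) + \bar T + kt/36500$ on a 365-day calendar
(day 1 = Jan 1, 2000; no leap days). This *smoothed* series is what the
simulator consumes: it captures seasonality and the secular warming
trend while deliberately omitting day-to-day weather noise, which is
equivalent to assuming organisms buffer short-term variability
physiologically. Consequences of that idealization: phenological dates
(emergence, the sexual switch) are sharp rather than distributed, and
the model cannot express extreme-event mortality (heat waves, late
frosts). `fit_climate_params()` recovers $(\bar T, s, k)$ from any
observed daily series by ordinary least squares on the regressors
$[1, t, \cos(2\pi t/365), \sin(2\pi t/365)]$, with $s$ the amplitude of
the harmonic pair, so a series whose seasonal minimum is not anchored at
Jan 1 still yields its amplitude. $\bar T$ is defined as the intercept —
the generator's year-2000 reference parameter — noting that the realized
calendar-year-2000 mean of a trended series differs from it by
$k \cdot \approx 0.5/100$ °C, which is below every tolerance used here.

### Thermal performance

All vital rates derive from one normalized shape $g_0(u)$ of the
mismatch $u = T - z$ between the environmental temperature and an
individual's thermal optimum $z$: an asymmetric double-Gaussian with
flank scales tied to the critical-limit offsets
($\sigma_\text{side} = \delta_\text{side}/2.5$), shifted and rescaled to
equal 1 at $u = 0$ and exactly 0 at $u = -\delta_{\min}$ and
$u = +\delta_{\max}$. The long cold flank and short steep hot flank give
the warm-skewed curve typical of insect vital rates: performance decays
gently below the optimum and collapses within a few degrees above it.
Both species share the functional shape (differing only in parameters),
and the whole curve shifts horizontally as $z$ evolves — formally, every
rate satisfies $r(z + c, T + c) = r(z, T)$. Birth is
$f = f_{\max} g_0$, intrinsic mortality is $m_0 + m_1 (1 - g_0)$
(minimal at the optimum), and the predator's capture rate is modulated
by $g_0$ inside a Holling type-II response
$\beta = g_0\, a/(1 + ahA)$.

We considered the Briere-type form $r \propto (T - CT_{\min})
(CT_{\max} - T)^{1/m}$ first; anchoring its peak at the optimum forces
the exponent $1/m = \delta_{\max}/\delta_{\min}$, which makes the hot
flank *flatter* as the hot-side offset shrinks — the opposite of the
intended biology — so the double-Gaussian was adopted as the default
form. Both forms satisfy the same contracts (unimodality, boundary
zeros, shift equivariance, asymmetry).

### Demography and selection

With phenotype $z = z_g + z_e$ (breeding value plus environmental
effect, $z_e \sim N(0, V_e)$), the population means driving

$$A' = A\,[1 + (\bar F_A - \bar B_L)\,\Delta t], \qquad
  L' = L\,[1 + \bar w_L\,\Delta t]$$

are double integrals of the rates over the breeding-value density and
the environmental distribution. The aphid's breeding-value density is
tracked explicitly on a uniform grid and reweighted by lineage growth
each day,

$$\rho'(z_g) \propto \rho(z_g)\,
  [1 + \Delta t\,\bar F(z_g) - \Delta t\,\bar B_L],$$

so it may (and does) become non-Gaussian through the asexual season.
Predation enters that reweighting as a phenotype-independent constant;
note this still perturbs moments at $O(\Delta t^2)$ — the constant
shifts the relative weight of the baseline against the
phenotype-dependent part — which the tests quantify rather than assume
away. The ladybird density is reweighted by its own lineage growth and
then, every step, reset to the normal distribution implied by its
updated mean and variance: the infinitesimal-model assumption of
continuous random mating.

### Genetic variance dynamics

Ladybirds follow the per-step Bulmer recursion: after selection and
mutational input $V_\tau \Delta t$, the deviation of additive variance
from the segregation variance updates as $d' = d/2 + \Delta V_g$ and
variance resets to $V_{g0} + d'$. Aphids have no segregation during the
asexual phase; variance erodes (or occasionally inflates) with
selection, mutation enters by explicit convolution each day, and the
single annual sexual generation restores
$V_{g,l} = (1-f)V_{g0} + d_l + V_\tau$ with
$d_l = \tfrac{1-f}{2} d_{l-1} + \Delta V_{g,\text{year}}$, the
inbreeding coefficient $f$ discounting restored variance. The
parenthesization $(1-f)V_{g0} + d_l$ versus $(1-f)(V_{g0} + d_l)$ is
genuinely ambiguous in the source material; the former is the default
and the latter is available behind the config flag `vg_reset_nested`.
With both segregation variances at zero the entire genetic machinery is
inert and trait means are exactly constant — the no-evolution reduction
used by Models 1 and 2.

### Phenology

Aphids emerge on the first day their mean growth rate (at the carryover
abundance, frozen genetics) exceeds `growth_threshold` (default 0, i.e.
any positive growth; the alternative reading "rate > 1" is available);
ladybirds emerge on the first later day their criterion holds. The
sexual switch fires on the first day after the summer solstice with
$DL < -0.05\,T + 15.67$ and $T < \bar z_A$. Restricting the test to
declining photoperiod is a deliberate design choice: the same numeric
condition also holds on cool short spring days, where it would
otherwise terminate the season on its opening day; sexual induction in
holocyclic aphids is a short-day *autumn* response. The switch day
triggers the aphid sexual reset and sends both species into
overwintering with survival 0.8; trait means, variances and densities
are frozen over winter. A season still open at calendar year end (or one
that never opened) closes there so the annual overwintering mortality is
paid exactly once per year.

## Numerical design

* **Time step.** Forward Euler with $\Delta t$ = 1 day — the discrete
  expectation updates *are* the model, not an approximation of a
  continuous system. Halving the step changes first-year annual aphid
  pressure by well under 1% (tested).
* **Breeding-value grid.** 601 points spanning the mean ± 8 sd (spacing
  ≈ sd/37), recentred by whole cells when the mean drifts more than one
  cell (exactly moment-preserving) and zero-padded when edge density
  exceeds 1e-10. Grids are rebuilt fresh only where the model itself
  prescribes a reset to normality.
* **Environmental integral.** The environmentally averaged shape
  $S(u) = E_{z_e}[g_0(u - z_e)]$ is an exact Gaussian convolution,
  precomputed once per (V_e, TPC) on a 2.5×10⁻⁴ °C mismatch grid by FFT
  and interpolated cubically thereafter. Gauss–Hermite quadrature was
  rejected after measurement: the TPC's critical-limit cusps violate its
  smoothness assumption and 21-node GH oscillates by O(10⁻²) as the cusp
  crosses nodes, while the tabulated convolution agrees with adaptive
  quadrature to ≲1.5×10⁻⁶ pointwise and ~10⁻⁷ after integration over a
  breeding-value density.
* **Mutation kernel.** Convolution with $N(0, V_\tau \Delta t)$ uses a
  column-normalized dense Gaussian kernel when the kernel sd spans at
  least two grid cells, and an equivalent mass-conserving explicit
  diffusion step (with stability substepping) when narrower — the usual
  case for the small daily mutational input. Both paths preserve the
  mean to 10⁻¹⁰ and add the prescribed variance to 10⁻⁸.
* **Degenerate inputs.** Zero-variance populations are exact point
  masses; every operation treats them as the delta-function limit, so
  no-evolution scenarios are exactly — not approximately — constant.
* **Collapse and extinction.** A growth multiplier ≤ 0 wipes the
  population within the step (abundances floor at 0). Ladybird
  extinction latches when abundance falls below 1 individual:
  deterministic densities never reach exact zero, and re-colonization is
  out of scope. Variance floors at 0 with a warning if $V_{g0} + d$ ever
  goes negative.

## Parameter defaults and calibration

Genetic parameters follow published estimates for these taxa:
$V_{g0} = 0.3$ °C², $V_e = 0.7$ °C² for both species, aphid inbreeding
$f = 0.1$, mutational heritability $h_m^2 = 10^{-3}$ with
$\eta = 1/7$ generations/day so the daily mutational input is
$V_\tau = 10^{-4}$ °C². Ecological and TPC defaults — offsets 18/6 °C,
aphid peak birth 0.3/day, mortality baselines/slopes 0.02/0.2 (aphid)
and 0.01/0.1 (ladybird), searching rate $a = 10^{-7}$, handling time
$h = 0.02$ day, conversion $Q_p = 50$ prey per egg, $K = 5\times10^7$ —
were calibrated once against the package's own structural targets and
then frozen: stable coexistence of both species at all nine reference
locations under the stable climate (the baseline annual cycle converges
to machine precision), predator extinction at all nine under warming
without evolution, and prey persistence everywhere under the full model.
Two considerations fixed the ecological scale: the predator's
recruitment term must dominate its thermal mortality (otherwise
persistence demands near-perfect thermal matching), and the functional
response must remain far from saturation at equilibrium — strongly
saturating variants put the equilibrium below the type-II "hump" and
destabilize the annual cycle into multi-year oscillations
(Rosenzweig–MacArthur enrichment instability), violating the stable
baseline.

Two qualitative patterns reported for the original study system do
**not** emerge under these defaults, and the acceptance tests record
them as failures rather than papering over them: predator extinction
under the full eco-evolutionary model at the harshest northern location,
and final predator abundance declining with the warming trend. The
structural reason is documented here deliberately: the model is
asymptotically shift-equivariant (all rates depend only on $T - z$ and
the warming increment is uniform within a year), the only
calendar-anchored process — the photoperiod switch — *lengthens* the
season as autumns warm, and with $V_{g0} = 0.3$ °C² the evolutionary lag
at realistic trends (≤ 0.12 °C/year) is only ~0.5–1 °C, far inside any
plausible thermal tolerance. Under those conditions rescue succeeds
wherever the stable baseline coexists, and predator abundance is weakly
*increasing* in the trend. Breaking the prey-compensation buffer (so a
maladapted predator could actually starve) requires the strongly
saturating response that destabilizes the baseline; stability was
prioritized. The variance-sensitivity direction is unaffected: with
$V_{g0,L} = 0$ the predator goes extinct wherever the climate warms, and
larger $V_{g0,L}$ improves its final abundance.

## Locally adapted optima

Initial trait means are the *locally adapted optima* — the pair at which
the coupled dynamics are stationary under the location's zero-trend
climate. `find_local_optima()` obtains them by evolutionary relaxation:
run the full dynamics with the trend off (extinction latch disabled, so
transients may pass through low abundance; candidate starts near the
seasonal peak with cooler fallbacks) until the year-over-year trait
displacement falls below 0.01 °C. Relaxation replaced a 2-D grid search
over candidate pairs because it is self-consistent (the returned pair is
by construction a fixed point of the same dynamics the scenarios run),
cheaper by an order of magnitude, and satisfies the same contracts
(stationarity, shift equivariance, warm-above-cool ordering). The nine
reference-location optima under the frozen defaults ship in
`local_optima()`; regenerate them after changing parameters.

Scenario runs flush initial conditions for 21 years under the full
dynamics before the scenario toggles apply. Model 1's flush also uses
the zero-trend climate: flushing under warming and then reverting the
climate would freeze warming-adapted trait values into the stable
baseline — a pure initialization artifact. For the same reason the
seasonality–trend sweep derives locally adapted optima per seasonality
value (the stable-climate optimum is independent of the trend, so one
relaxation serves a whole row of the grid).

## The stochastic oracle

The individual-based implementation draws a fresh environmental effect
per individual per day, applies Bernoulli birth/death at probability
rate × Δt, inherits breeding values clonally (aphids) or as midparent
plus a $N(0, V_{g0}/2)$ segregation deviate (ladybirds), and — matching
the deterministic pipeline's assumption of random mating within every
time step — re-mates the whole surviving predator pool each day
(mean-preserving, variance-restoring). Large abundances are represented
by up to 10⁵ particles with a scaling factor, uniformly subsampled
(unbiased). The acceptance suite compares one full growing season at the
northernmost reference location against the deterministic pipeline: 20
seeded replicates, trajectories sampled at one-third, two-thirds and the
end of the season, agreement required within 3 Monte Carlo standard
errors for both species' mean breeding values and log-abundances. A
convergence test verifies the stochastic–deterministic gap shrinks as
1/√N over 10³–10⁵ particles.

The oracle validates the *integral updates*, not the biology of the
infinitesimal reset itself: without the per-step re-mating the oracle's
predator responds measurably more slowly than the deterministic model,
which quantifies the cost of assuming daily random mating for an insect
whose real generation time is weeks.

## Problem sizes

The shipped tests and the acceptance script use: 601-point
breeding-value grids; nine locations × three scenarios × 151 simulated
years for the pattern checks; a 2×3 seasonality–trend sweep; one
season × 20 replicates × 10⁵ particles for the oracle comparison; and
10³–10⁵ particles for the convergence slope. These sizes were chosen so
the entire suite exercises every code path at full model resolution
while remaining comfortable on a single CPU.

## Known limitations

* No dispersal, spatial structure, stage structure, phenotypic
  plasticity, or vertical/width evolution of the TPC; a single
  univariate trait per species.
* Deterministic infinite-population densities: no demographic
  stochasticity or drift in the main loop (the extinction latch at one
  individual is the only concession to finiteness).
* The smoothed climate omits weather variance and extreme events; the
  trend is purely linear and seasonality is held constant over time.
* The daily random-mating reset overstates how quickly a predator with
  multi-week generations re-normalizes its breeding-value distribution.
* The calibrated defaults stand in for unavailable species-specific
  TPC measurements; they are internally consistent (stable baseline,
  calibrated extinction patterns) but not fitted to data, and the two
  unreproduced geographic patterns discussed above should be read in
  that light.
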