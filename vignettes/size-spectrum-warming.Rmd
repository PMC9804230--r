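---
title: "Temperature-dependent multi-species size-spectrum modelling with thermspectrum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temperature-dependent multi-species size-spectrum modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermspectrum)
```

## The model

`thermspectrum` simulates a size-structured food web: three fish species
whose individuals are tracked by body weight $w$, feeding on each other
and on two background resource spectra (a pelagic, plankton-like one and
a benthic, invertebrate-like one).  The state of each species is its
number density $N_i(w)$ (individuals per gram per unit habitat), which
evolves by the transport (McKendrick–von Foerster) equation

$$\frac{\partial N_i}{\partial t}
  + \frac{\partial\, (g_i N_i)}{\partial w} = -\mu_i N_i ,$$

with food-dependent somatic growth $g_i(w)$ and total mortality
$\mu_i(w)$.  At the egg weight $w_0$ the influx of individuals equals the
recruitment flux, $N_i(w_0) = R_i / g_i(w_0)$.

All individual-level rates follow standard size-spectrum bioenergetics:

* **Encounter and satiation.**  A predator of weight $w$ scans a volume
  $\gamma_i w^q$; suitable prey biomass is weighted by a log-normal
  preference in the predator/prey weight ratio, centred on $\beta_i$ with
  width $\sigma_i$.  Intake saturates through a Holling type-II response,
  giving a feeding level $f_i(w)\in[0,1]$ relative to the maximum
  consumption rate $h_i w^n$.
* **Energy budget.**  Assimilated intake $\alpha f h w^n$ pays metabolism
  $k_s w^p$ first; the non-negative remainder is split between somatic
  growth and reproduction by a smooth allocation $\psi_i(w)$ that rises
  around the maturation weight $w_{mat}$ and reaches 1 at the asymptotic
  weight $W_i$, so growth approximates a von Bertalanffy curve at constant
  feeding level.
* **Mortality.**  The sum of predation (emergent from the encounter
  machinery of all predators), a constant allometric background rate
  $\mu_0 W_i^{n-1}$, starvation (energy deficit divided by $\xi w$, with
  reserve fraction $\xi = 0.1$), and knife-edge fishing: the full rate
  $F_i$ at and above $w_{mat}$, nothing below.
* **Recruitment.**  Egg production (half the population is female, with
  efficiency $\epsilon$) passes through a Beverton–Holt cap:
  $R = R_{max} R_{phy} / (R_{phy} + R_{max})$.  The ratio
  $R_{phy}/R = 1 + R_{phy}/R_{max}$ is reported as the density-dependence
  diagnostic.

Resources regrow toward a power-law carrying capacity
$\kappa w^{-\lambda}$ (with $\lambda = 2 - n + q$) at the size-dependent
semi-chemostat rate $r_0 w^{p-1}$, and are depleted by the same predation
machinery.

## Temperature

Temperature enters through the Arrhenius correction factor

$$r_T = \exp\!\left(\frac{E\,(T - T_{ref})}{k\,T\,T_{ref}}\right),$$

equal to 1 at the reference temperature $T_{ref} = 283.15$ K.  Under the
`physiology` scenario the coefficients of maximum consumption, search
volume, metabolism and background mortality are multiplied by their
respective factors each step (recomputed from reference values, never
compounded); growth itself is untouched, so its thermal response is
emergent.  Under the `resources` scenario the regeneration coefficient
$r_0$ scales with $+E$ and the carrying-capacity coefficient $\kappa$
with $-E$, leaving the spectrum slope unchanged — warmer water cycles
resources faster but holds less standing biomass.  `both` combines the
two; `none` disconnects temperature entirely (trajectories are then
bitwise independent of the temperature series, which is tested).

Activation energies are uncertain, so projections run as ensembles: each
draw samples the six energies independently from configured normal
distributions.  Defaults are $E$ = 0.59(8) eV for metabolism and
mortality, 0.69(10) eV for consumption and search, and 0.63(10) eV for
both resource parameters.  The resource mean is anchored so that a +1 °C
rise shrinks the resource spectrum's elevation by 8.7%.  The physiology
means are placeholder literature-scale values, configurable in the
thermal section of the JSON config.

## The synthetic world

Real applications would force the model with assessment fishing
mortalities, assessment SSB for calibration, and a regional climate
temperature series.  The `synthetic_spec()` generators stand in for all
three so the full pipeline is testable offline:

* an accelerating warming trend with AR(1) interannual noise (coefficient
  0.6, innovation sd 0.15 K), re-centred so its 1992–2002 mean equals
  $T_{ref}$ and reaching $T_{ref} + 2$ K in 2050;
* piecewise-constant fishing histories per species (a rise-and-fall
  piscivore fishery, steadier forage-fish fisheries), optionally with
  lognormal noise, clamped non-negative;
* SSB calibration targets generated from the model itself at known
  "true" $R_{max}$, perturbed with 5% lognormal noise — which is what
  makes parameter-recovery testing meaningful;
* closed-form von Bertalanffy weight-at-age growth targets.

The default species are *archetypes* — a small forage fish, a medium
forage fish and a large piscivore with sprat-, herring- and cod-like
life-history scales — **not** fitted stock parameters.  They were chosen
once, before any acceptance measurement, for three properties: all three
coexist, the community reaches a steady state well before 200 years, and
growth curves are life-history plausible (the piscivore passes ~1 kg
within a few years, the small forage fish approaches its ~25 g asymptote
by age 4–6).  Two choices deserve comment:

* the two planktivores are niche-separated (the small one grows faster
  and feeds purely pelagically; the medium one splits 0.7/0.3 across
  resources), because two identical filter feeders competitively exclude
  one another in this model family;
* forage-fish $R_{max}$ values were set low enough that Beverton–Holt
  density dependence damps predator–prey limit cycles; with weaker
  damping the web cycles persistently at sub-percent amplitude and never
  meets the steady-state tolerance.

A green test on this world establishes that the machinery reproduces the
mechanisms (directions, identities, recoveries) — not that any real
stock would show these magnitudes.  Real assessment data, hindcast skill
and real climate fields are out of scope.

## Calibration

`calibrate_rmax()` fits $\log_{10} R_{max}$ per species by minimising the
residual sum of squares between log steady-state SSB (at $T_{ref}$ and
window-mean $F$) and log targets.  It works in two stages: a
multiplicative fixed-point pre-conditioning
($R_{max} \leftarrow R_{max}\,\cdot$ target/SSB, three iterations), which
exploits the near-proportionality of steady SSB to $R_{max}$, followed by
a bounded quasi-Newton (`L-BFGS-B`) polish with numerical gradients on
the steady-state map.  Two details matter for robustness:

* every polish evaluation warm-starts from the *same* base steady state,
  making the objective a deterministic function of the parameters — a
  mutable warm start lets line searches compare inconsistent values and
  can walk the optimiser uphill;
* the objective uses window-averaged SSB, so residual limit-cycle phase
  does not alias into the fit.

`tune_h_to_growth()` then adjusts the maximum-consumption coefficients by
a deterministic multiplicative coordinate search against weight-at-age
targets (the `ks` coefficient follows `h` to keep the critical feeding
level fixed); the pair of steps can be iterated, two passes sufficing in
practice.

## Scenario pipeline

`run_warming_projection()` performs, per ensemble draw, a burn-in under
the first year's forcing, a projection through the historical fishing
series and warming temperatures (switching to `f_future` after the
historical window), and an identical baseline whose temperature is frozen
at its 1997 value.  Size-at-age is evaluated by integrating a cohort
through the final year's quasi-steady growth field (fixed-step RK4 on a
log-linear interpolation of $g$), a deliberate design choice: the
projection horizon is reported as 2050 growth trajectories, and a
quasi-steady cohort avoids mixing the transient into the growth curve.

`fmsy_search()` grid-searches steady-state yield over $F$ for one species
at a time, holding the others fixed; `run_constant_grid()` sweeps the
full factorial of constant temperature and fishing proportions
(0.75–1.25 of $T_{ref}$ in steps of 0.01 × 0.1–2.0 of reference
$F_{MSY}$ in steps of 0.05 = 1989 cells, the unique uniform-step
reconstruction of that cell count).  Temperature proportions are applied
on the Kelvin scale, since $T_{ref}$ is defined in Kelvin; this is an
interpretation and is flagged as such.

## Numerical choices

* **Grid.**  One shared log grid; 100 bins span the fish range (smallest
  egg to largest $W_i$), and the resource range extends four decades
  further down at the same spacing.  Species and resource ranges live on
  index spans of this grid.
* **Fish step.**  Implicit first-order upwind in weight, swept by forward
  substitution (the system is bidiagonal), unconditionally stable.  The
  per-cell mortality uses *exponential fitting*: the plain implicit
  factor $1/(1+\mu\,\Delta w/g)$ misrepresents survival where
  $\mu\,\Delta w / g$ is order one (exactly where mature biomass sits),
  so the effective mortality is $(g/\Delta w)\,(e^{x}-1)$ with $x$ the
  trapezoidal estimate of $\int \mu/g\,dw$ across the cell.  The discrete
  steady flux ratio then matches the analytic exponential per cell.
* **Sharp edges.**  Knife-edge selectivity and resource range cutoffs are
  discretised as partial-bin overlap fractions, so fished biomass and
  total resource capacity do not jump as exact thresholds move between
  grid points under refinement.  The species' top bin passes its outflux
  out of the resolved range instead of accumulating a grid-dependent
  boundary spike.
* **Resource step.**  Semi-implicit relaxation with exact fixed point
  $r\,\kappa w^{-\lambda}/(r+\mu_{pre})$.
* **Steady detection.**  Converged when every species' SSB varies
  relatively by less than $10^{-4}$ over a 10-year window, *or* when the
  means of consecutive 10-year windows differ by less than the same
  tolerance (accepting a persistent sub-tolerance limit cycle whose
  cycle-average has stopped drifting).  Window-averaged SSB is exposed
  alongside the final state.
* **Convergence in practice.**  Halving `dt` changes steady SSB by less
  than 0.1%.  Doubling the weight resolution moves the planktivores' SSB
  by ~1–3% but the piscivore's by ~15–20%: its mature biomass sits at the
  top of the community grid where log cells are widest (~1.7 kg at 10 kg)
  while growth tends to zero, and its recruitment is hard-capped, so
  survival discretisation passes straight into SSB with no compensating
  feedback.  The refinement test asserts these measured orders; treat
  absolute piscivore biomass levels as resolution-dependent and compare
  like with like (same grid) across scenarios, which is what every
  pipeline function does.

## Worked example

```{r example, eval = FALSE}
model <- spectrum_model()           # archetype food web at Tref
state <- run_to_steady(model)
ssb(state, model)                   # steady spawning-stock biomass
attr(state, "rates")$R_phy / attr(state, "rates")$R  # density dependence

# +2 K steady state with temperature acting on resources only
m_hot <- model
m_hot$thermal <- thermal_config(scenario = "resources")
hot <- run_to_steady(m_hot, state = state, T = 285.15)
yield(hot, m_hot) / yield(state, model)   # forage yields decline
```

## Known limitations

* No length-based outputs, spatial structure, multiple gears, or
  non-knife-edge selectivities.
* Exponential thermal scaling only — no unimodal performance curves, so
  do not push the model near or beyond physiological optima.
* The archetype parameters are stand-ins; all of them, including the
  thermal means and standard deviations, are overridable through the
  JSON configuration, and any quantitative application must supply its
  own.
* Absolute piscivore biomass carries a resolution dependence (above);
  within-grid comparisons and directional responses are robust to it.
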