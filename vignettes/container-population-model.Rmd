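---
title: "A container-resolution model of Aedes aegypti populations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A container-resolution model of Aedes aegypti populations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aedespop)
```

`aedespop` simulates *Aedes aegypti* populations at the resolution of
individual water-holding containers within houses on a rectangular grid,
and provides the calibration and spatial-analysis machinery needed to
confront such a simulation with household-survey and ovitrap data.  This
vignette is the package's own account of the model, the choices behind
it, and what the test suite does and does not establish.

## The population model

### Spatial structure

The unit of space is a grid cell holding one house; each house holds a
fixed inventory of containers.  Containers are described by one of 14
categories (`plastic`, `medium storage`, `large tanks`, `tires`,
`non-traditional`, `cooking`, `miscellaneous`, `flower pots`, `cans`,
`bath`, `bottles`, `natural`, `wells`, `pet`), an inside/outside
location, a sun-exposure fraction, a lid flag, a fill method (`manual`,
`passive-rain`, `assisted-rain`) and a volume in liters.

Evaluation grids are built by tiling several copies of one surveyed
block (`build_replicated_grid()`).  Within each copy the assignment of
houses to cells is an independent uniform permutation, so every house
appears once per copy with different neighbours, while its container
inventory travels with it verbatim.  For four copies the default tiling
is a 2 x 2 arrangement of blocks — the most compact rectangle, which
minimises the perimeter and hence boundary effects; a `"strip"` (1 x k)
layout is available as an option because the tiling arrangement is a
genuinely open choice.  Distances are Manhattan grid steps (horizontal
or vertical moves); translating steps into meters (roughly 5–10 m per
step in a dense urban block) is reporting-only metadata that the model
itself never uses.

### Food input and larval density dependence

The daily food input into a container of type $i$ at location $j$ with
volume $V$ is the multiplicative model

$$F = F_0 \, \alpha_i \, \beta_j \, V,$$

with $F_0$ a baseline rate in liver-powder-equivalent mg per liter per
day, $\alpha_i$ a container-type coefficient and $\beta_j$ an
inside/outside coefficient.  Because the three factors multiply, only
relative values of $\alpha$ and $\beta$ are identifiable; the package
enforces the conventional normalization $\alpha_{\text{large tanks}} =
1$ and $\beta_{\text{outside}} = 1$, letting $F_0$ carry the overall
scale.

Each container tracks a food pool (mg) updated daily in a fixed order:
input, proportional decay, consumption by larvae, and return of a
fraction of dead immature biomass as food.  Larval cohorts demand food
up to an intake ceiling (`larval_intake_rate`, mg food per mg larva per
day); when the pool cannot meet total demand, intake is allocated
proportionally to cohort demand (no priority rule is imposed — the
model gives no reason to feed one cohort first).  A cohort fed below a
quarter of its ceiling (`starvation_intake_fraction`) counts that day as
starving: its daily mortality is multiplied by
`starvation_mortality_multiplier`, and once its run of starving days
exceeds `starvation_reserve_days` the cohort's reserves are exhausted
and it dies.  This food pathway is the model's only density dependence:
crowding depletes food, which raises mortality and delays development,
which in turn relieves crowding.  The test suite verifies the direction
of this feedback (doubling initial larvae lowers per-capita pupation
and raises mean development time) rather than any particular functional
form.

### Simplified cohort biology

The full enzyme-kinetic development and weight-gain formulations used by
detailed container-mosquito simulators are replaced here by a compact
cohort model with the same contract — food-mediated density dependence
with starvation — because that contract is what calibration and
evaluation exercise:

* **Development** is linear in degree-days: a larval cohort accrues
  `dev_rate_coeff` of its stage per degree-day of water temperature
  above `dev_temp_threshold` (default 1/110 per degree-day above
  13.4 °C, i.e. roughly nine days at 27 °C).
* **Growth**: weight gain is `growth_efficiency` times food ingested;
  pupation requires both completed development and a minimum weight
  (`pupation_weight`), so underfed cohorts pupate late.
* **Eggs** embryonate for `egg_maturation_days`, then hatch on the
  first day their container is wet *and* its water is at or above
  `min_hatch_water_temp` (default 22 °C).  That hatching threshold is
  appropriate for warm climates and is plausibly too high for temperate
  ones — a known limitation that shows up as conservative late-season
  predictions in temperate runs.  Mature eggs stranded dry persist with
  reduced daily survival (`dry_egg_survival`); no deeper dormancy
  physiology is modelled.
* **Adults**: only females are tracked (assumed mated; the model has no
  mating structure for males to affect).  Emerging adults are female
  with probability `female_fraction`.  A female becomes gravid
  `gonotrophic_cycle_days` after emergence or her last oviposition,
  lays `eggs_per_batch` eggs into a single wet container of her house,
  and reverts to the start of the cycle.  Site choice among the wet
  containers of a house is multinomial with probability proportional to
  $V^{2/3}$, a water-surface proxy; the model source gives no selection
  rule, and this choice avoids the degenerate all-eggs-in-one-container
  behaviour of volume-proportional or uniform rules while preferring
  larger surfaces.
* **Dispersal**: each female independently moves with probability
  `dispersal_prob` per day to a uniformly chosen Manhattan-adjacent
  house, so one day moves at most one step.

### Water dynamics

Water temperature is the daily mean air temperature plus
`water_sun_warming` x sun-exposure for outside containers and a fixed
`water_inside_offset` (default −1 °C) inside; this is the simplest rule
that is monotone in exposure and cooler indoors.  Manually filled
containers are held full.  Rain-filled containers gain a fraction of
their volume per mm of rain (assisted-rain catchments four times more
efficient than passive ones), lose a fixed evaporative fraction daily,
are capped at their volume, and a lid halves both gain and loss.  These
are qualitative roles for the surveyed covariates, not hydrology.

### Stochasticity and determinism

Every random event — survival, hatching, sex at emergence, oviposition
site choice, dispersal — is a binomial or multinomial draw from one
seeded generator, and the order of events within a day is fixed as
listed above.  A run is therefore an exact function of (grid, weather,
parameters, seed); the suite asserts bitwise reproducibility.  Functions
that consume randomness save and restore the caller's RNG state.

An audit mode (`run_simulation(..., ledger = TRUE)`) records, for every
container-day, the four food-balance terms and the per-stage inflows and
outflows, and the tests require these ledgers to balance exactly —
integer-exactly for counts, to floating-point rounding for food.

## Weather: ingestion and synthesis

`read_weather()` ingests comma-delimited daily records (`date, tmin,
tmax, rain, rh`) and enforces a gap-free calendar, `tmin <= tmax`,
non-negative rain and humidity in [0, 100].  `generate_weather()`
synthesizes series from a regime: sinusoidal seasonal means (period 365
days) plus Gaussian daily noise for temperatures; rain as a Bernoulli
wet-day indicator times an exponential depth whose mean is solved so
the expected annual total matches the regime; humidity as bounded noise
around a (possibly seasonal) mean.  Humidity is generated as a single
daily value — the simplified biology only needs a coarse moisture
signal, and no min/max humidity pair is used anywhere downstream.

Two presets encode the study conditions: an `equatorial` regime (mean
daily maximum 32.2 °C with a 5–95 % range of about 29–35 °C, mean daily
minimum 21.4 °C, 2,878 mm of rain per year falling on about 60 % of
days, mean humidity 85 %) and a Southern-hemisphere `temperate` regime
(seasonal amplitudes of 6.5–7.5 °C around means of 22.4/12.8 °C,
1,200 mm of rain per year, humidity 55–75 % peaking in winter), phased
so the coldest weeks fall at mid-year and a July-to-June reporting year
starts in winter.

## Synthetic inputs

No field survey, productivity table or ovitrap series ships with the
package; `generate_survey_subset()`, `generate_target_productivity()`
and `generate_positivity_series()` produce inputs with the structure
the pipeline assumes.  The default survey block is 17 x 9 houses
holding exactly 871 containers (the density scales with block area for
other dimensions).  Container counts per house are equal-rate Poisson
conditioned on the exact total — realized directly as a multinomial
draw, which *is* that conditional law, after guaranteeing each house at
least one container.  Per-type frequencies and log-normal volume
parameters are order-of-magnitude plausibility choices (cans common and
small, large tanks and wells rare and big); they are configuration, not
claims about any real survey, and nothing in the tests depends on their
particular values.  Productivity targets are Dirichlet draws,
optionally sorted so productivity decreases along the canonical type
order.  Positivity series follow a seasonal signal that is exactly zero
through the cold weeks of a temperate winter and high year-round in the
equatorial regime.

Because all inputs are synthetic, passing tests establish that the
machinery is self-consistent — the simulator produces the spatial
randomness it should, calibration recovers coefficients the simulator
itself generated, the statistics detect constructed structure — and
not that the model reproduces any particular real population.

## Calibration

### Per-type coefficients

`calibrate_type_coefficients()` adjusts $\alpha_i$ (and optionally
$\beta_j$ and $F_0$) so simulated per-type shares of cumulative pupal
production match a target table.  No closed-form estimator exists for a
stochastic simulator, so the scheme is a damped multiplicative
fixed-point iteration: each round runs a few replicate simulations,
forms shares, and applies
$\alpha_i \leftarrow \alpha_i (t_i / s_i)^\eta$ with $\eta = 0.5$,
re-normalizing $\alpha_{\text{large tanks}} = 1$ afterwards.  Full
($\eta = 1$) steps oscillate on a stochastic objective; halving the
exponent damps them.  Ratios are clamped to a multiplicative trust
region of 4 per iteration so a type that stochastically produced zero
pupae (but has positive target) moves up at a bounded rate instead of
dividing by zero.  A discrepancy that keeps rising over five
consecutive iterations halves the step.  Convergence is
$\max_i |s_i - t_i| \le$ `tol`.  Because the product $F_0 \alpha_i
\beta_j$ confounds scale and shape, $F_0$ is only ever fitted against a
*level* target (total pupae), never against shares.

The calibration contract is honoured by construction elsewhere: the
pipeline fits coefficients on a calibration grid whose houses are
disjoint from the evaluation grid, and the tests verify that
calibration changes nothing but the three food coefficients.

### Baseline-only calibration

`calibrate_overall_F0()` is the data-poor mode: with $\alpha, \beta$
frozen at donor values, it finds the scalar $F_0$ at which the mean of
the simulated ovitrap-positivity proxy matches the mean of a target
weekly series.  Mean positivity is monotone in $F_0$ over any sensible
bracket, so the search is a bracketed bisection — geometric in the
multiplier, since food acts multiplicatively — with geometric widening
(capped) if the initial bracket does not straddle the target.

The positivity proxy itself (`ovitrap_positivity()`) is, per day, the
fraction of containers with at least one oviposition in the trailing
7 days, aggregated to weeks by averaging.

## Spatial statistics

All three statistics consume per-house counts on grid positions with
inverse-Manhattan-distance weights and integer-shell neighbourhoods
($\Omega_d(i)$ = houses within distance $d$ of $i$, excluding $i$;
increments are taken between consecutive integer distances).

* **Moran's I**: $I = \frac{N}{W}\frac{\sum_{ij} w_{ij}(x_i - \bar
  x)(x_j - \bar x)}{\sum_i (x_i - \bar x)^2}$, expectation $-1/(N-1)$
  under random allocation.  Significance uses a permutation null
  (counts shuffled over cells, weights fixed; default 999 draws) rather
  than the normal-theory variance, because a permutation test makes no
  distributional assumption the grid doesn't satisfy; the analytic
  expectation is reported alongside.
* **Weighted L**: $K_w(d) = N \sum_i \sum_{j \in \Omega_d(i)} x_i x_j /
  \sum_i \sum_{j \ne i} x_i x_j$ and $L_w = \sqrt{K_w/\pi}$, with the
  unweighted $L(d)$ obtained by setting every count to one.  This
  normalization is pinned by two requirements: dummy counts must reduce
  $L_w$ to the classic point-pattern $L$ of the house lattice, and
  constant counts must give $L_w \equiv L$ exactly (the tests assert
  exact equality, which survives floating point because the constant
  factors out of the ratio).  The reported contrast is the increment
  difference $(L_w(d) - L_w(d-1)) - (L(d) - L(d-1))$; positive values
  mean counts cluster beyond what the house pattern imposes.  No
  geometric edge correction is applied: the unweighted $L(d)$ of the
  house pattern already absorbs the lattice's own edge structure, which
  is the reason for computing it at all.  This is a documented
  limitation for comparisons with edge-corrected K-function software.
* **Local G**: for each house, the neighbourhood sum is standardized
  against its exact permutation moments,
  $$G_i(d) = \frac{\sum_{j \in \Omega_d(i)} x_j - W_i \bar x_{(i)}}
  {s_{(i)} \sqrt{W_i (N - 1 - W_i)/(N-2)}},$$
  where $\bar x_{(i)}$ and $s_{(i)}$ are the mean and standard
  deviation of the counts excluding house $i$ and $W_i = |\Omega_d(i)|$.
  Excluding $i$ from the moments makes the expectation exactly zero
  under random allocation, which is the property the statistic's use
  rests on.  Houses with $|G_i|$ above a threshold (default 2.575, the
  two-sided 0.01 standard-normal critical value as conventionally
  printed; `critical_z()` computes it exactly) are labelled
  positive- or negative-cluster members.  $W_i \in \{0, N-1\}$ makes
  the denominator degenerate; such houses are reported as unlabelled
  with a flag rather than as a number.

Degenerate inputs are errors, not NaNs: constant counts make Moran's I
and $G_i$ undefined (zero variance), all-zero counts make $L_w$
undefined, and the functions say so.  The one deliberate exception is
`cluster_size_profile()` on constant counts, which returns zero members
at every distance — no house can deviate from a constant field, and the
profile is the natural summary to keep total.

Every statistic is verified against an independent naive $O(N^2)$ loop
implementation on batches of random small grids (agreement to 1e−10),
and Moran's I additionally against an external library implementation
on a row-standardized weight matrix.

## Problem sizes and numerical choices

Simulation-based tests run at deliberately reduced sizes chosen to
exercise every code path with comfortable statistical margins: the
calibration-recovery experiment uses a single 9 x 9 block (about 460
containers), two simulated years and five replicates per iteration;
conservation audits use a 5 x 5 block over one year; regime-behaviour
checks use 6 x 6 blocks with a one-year burn-in and one-year horizon
over five seeds.  The full 17 x 9 x 4 construction is exercised
structurally (house/container accounting, Moran null on 612 cells)
rather than dynamically.  Default burn-in for reported output is one
year, letting the population equilibrate from its inoculum (10 mature
eggs and 5 larvae per container).

Other numerical conventions: food pools are clipped at zero after
consumption (consumption is capped at availability, so the clip only
guards rounding); egg maturation uses an absorbing mature pool; cohort
bookkeeping is by hatch-day cohort, not individual, for all immature
stages, while adults are per-house counts with an age-within-cycle
register; seeds passed to replicate runs are derived arithmetically
from the caller's seed and kept below 2^31.

## Known limitations

* The biology is a deliberate simplification; rate parameters are
  plausible defaults, not a fitted life table.  Calibration absorbs
  much — but not all — of this into the food coefficients.
* The 22 °C hatching threshold is likely conservative for temperate
  populations (see above).
* Containers of a house are independent except through shared weather
  and the house's adults; no micro-siting, shading interactions or
  container turnover.
* The grid is a rectangular lattice with unit steps; no real
  geo-referencing, street topology or irregular spacing.
* The L statistics use lattice-pattern correction only (no geometric
  edge correction), and the synthetic survey's type frequencies are
  not estimates of any real container distribution.
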