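---
title: "pelagibm: model structure, parameterisation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pelagibm: model structure, parameterisation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pelagibm)
```

## Scope

`pelagibm` is a one-dimensional (water-column), full life cycle,
super-individual model of co-occurring European anchovy (*Engraulis
encrasicolus*) and European sardine (*Sardina pilchardus*) populations in
a temperate, seasonally stratified shelf sea of the kind found in the
northern Aegean.  It couples four pieces:

1. a **Wisconsin-type bioenergetics** budget driving individual growth;
2. an **energy allocation / egg production algorithm** with a
   reproductive buffer, which lets each species express any breeding
   strategy between pure *capital* (eggs paid from stored energy) and
   pure *income* (eggs paid from concurrent intake);
3. a **super-individual population module** with stage structure,
   natural/fishing/starvation mortality and diel vertical migration
   (DVM); and
4. a **synthetic water-column environment** — a parametric temperature
   and zooplankton climatology with linear relaxation and a grazing
   sink, making the fish–plankton coupling two-way.

A genetic algorithm calibrates the stage-specific half-saturation
coefficients of consumption against size-at-age references, a bisection
calibrates juvenile natural mortality against reference biomasses, and a
scenario engine runs exploitation-rate sweeps and fishing-closure timing
experiments.

## Bioenergetics

Weight-specific rates (all in g prey · g fish⁻¹ · d⁻¹) follow the
Wisconsin scheme.  Relative growth is

$$\frac{1}{W}\frac{dW}{dt} = \bigl[C - (R + EG + SDA + EX +
E_{buffer})\bigr]\cdot \frac{CAL_z}{CAL_f},$$

with consumption $C$, respiration $R$, egestion $EG = a_f C$, specific
dynamic action $SDA = a_{sda}(C-EG)$, excretion $EX = a_e(C-EG)+b_e$, the
specific flux into (or out of) the reproductive buffer $E_{buffer}$, and
the zooplankton/fish caloric equivalents $CAL_z, CAL_f$.

Maximum consumption is $C_{max} = a_c W^{b_c} f_C(T)$ with the
Thornton–Lesem temperature scalar $f_C(T)=V^X e^{X(1-V)}$,
$V=(T_{max}-T)/(T_{max}-T_{opt})$, $X = S^2(1+\sqrt{1+40/Y})^2/400$,
$S=\ln Q_c (T_{max}-T_{opt})$, $Y=\ln Q_c(T_{max}-T_{opt}+2)$.  Realised
consumption over the two prey types (microzooplankton $i=1$,
mesozooplankton $i=2$) uses a multispecies functional response with
vulnerabilities $v_{j,i}$ and half-saturation coefficients $k_{j,i}$ per
stage $j$:

$$C_i = C_{max}\,\frac{PD_i v_i / k_i}{1 + \sum_j PD_j v_j / k_j}.$$

Early larvae eat only microzooplankton ($v=1$), late larvae both at
$v=0.5$, juveniles and adults only mesozooplankton.  Respiration is
$R = a_r W^{b_r} f_R(T) A$ with $f_R = Q_{10}^{(T-T_m)/10}$ and a
swimming-activity multiplier $A = e^{d_r U}$,
$U = a_A W^{b_A} e^{c_A T}$, whose $(a_A, c_A)$ pair switches at 12 °C;
juveniles use a reduced $a_A$ during the low-food season (column-mean
mesozooplankton below half its annual peak — the `lowfeed_frac`
parameter).

Two conventions deserve comment:

* **Allometric signs.** The package uses $b_c = -0.31$ and
  $b_r = -0.34$: weight-*specific* maximum consumption and respiration
  decline with size, as throughout the Wisconsin model family.  First
  feeding larvae of ~10⁻⁴ g then have $C_{max}$ of several g/g/d and
  adults about 0.2 g/g/d; with positive exponents larval growth through
  the observed stage windows would be impossible at any prey density.
* **Caloric equivalents.** Only the ratio $CAL_z/CAL_f$ enters the
  budget.  Defaults are $CAL_z = 2580$, $CAL_f = 5400$ J g⁻¹ wet — a
  zooplankton-to-fish energy density ratio of ≈ 0.48, in the range used
  by bioenergetics models of small pelagic fish.  Both are explicit,
  required configuration parameters.

Weight–length conversion uses a piecewise log₁₀–log₁₀ relation with two
slope changes, continuous and strictly increasing, hence analytically
invertible (`weight_from_length()` / `length_from_weight()`).  Base-10
logarithms, length in mm and weight in g are the assumed convention: the
first inflexion point of the anchovy fit, $d_1 = 1.5798$, corresponds to
$10^{1.5798} \approx 38$ mm, which falls at the late-larva/juvenile
boundary as it should.  Length is **ratcheted**: it is updated from
weight only when it would increase, so weight loss reduces condition,
not length.  This keeps the 35 % starvation rule meaningful (a shrinking
fish must actually lose body mass relative to its maximum, not renegotiate
its length).

## DVM and the integration of the daily budget

Late larvae, juveniles and adults occupy the surface layer (0–30 m) at
night and the sub-thermocline layer by day; eggs and early larvae stay
in the surface layer.  The daily step evaluates **consumption with the
night (surface) layer's prey field and temperature** — feeding happens
where and when the fish are in the food — and **respiration at the
day/night residence-time-weighted temperature** (`day_fraction`, default
0.5).  The behaviour itself is fixed; only this integration rule is a
package choice.

## Energy allocation, spawning and the capital index

Surplus after maintenance, $A = C - (R+EG+SDA+EX)$:

* $A \ge 0$, immature ($L < L_m$): all of $A$ goes to growth (immature
  fish do not store fat).
* $A \ge 0$, mature: a fraction $k = 0.5$ goes to growth and $(1-k)A$ is
  banked in the reproductive buffer (all year round).
* $A < 0$: the deficit is paid **from the buffer first**, the remainder
  from soma as negative growth.  Buffer withdrawals for maintenance are
  logged in the season's emergency-maintenance accumulator ($AR$).

A super-individual spawns daily whenever its species' SST gate holds
(anchovy: SST > 15 °C, sardine: SST < 16 °C), $L > L_m$, and the buffer
can pay one batch ($E_{buffer} \ge E_{egg} W$).  The batch releases
$DSF \times W$ eggs per individual (anchovy 46, sardine 20.1 eggs g⁻¹)
and debits $E_{egg} W$ ($E_{egg}$ is per gram of spawner, so the debit
scales with individual weight).  The season also ends when the SST gate
closes.  A season *starts* on the day the gate first turns true
(buffer-at-start recorded, accumulators cleared); an individual
maturing mid-season joins at its promotion day, with the spawning-onset
diagnostic measured from the population's gate opening.

**Atresia.**  Nine consecutive days on which food is insufficient to
meet metabolic requirements end the individual's spawning season.  Two
interpretation choices matter and are made as follows.  First, under
the buffer-first allocation a fish whose intake falls short but whose
buffer still bridges the gap *is* meeting its metabolic requirements,
so a deficit day is counted only when the soma actually shrinks
(intake plus buffer fail maintenance).  This makes the end of the
anchovy season what it should be: exhaustion of reserves followed by
the nine-day rule, rather than an automatic stop nine days after the
first lean day.  Second, atresia is the resorption of developing eggs,
so the rule can only terminate a season in which spawning has begun
(`egg_cum > 0`); without this, a winter spawner whose season opens
during the lean late-autumn weeks would lose its entire season before
laying a single batch.  The hunger counter resets on any sufficient
day.

The capital index per season,

$$CI = \frac{\Delta E_{buffer} - \sum AR}{\sum E_{egg}},$$

is 1 when all egg energy came from the pre-season store and 0 when the
buffer merely passed concurrent intake through.  It is reported per
age class, abundance-weighted, and is undefined (missing, not zero) for
seasons without egg release.

The buffer is held in absolute units (g prey per individual); the
specific flux $E_{buffer}$ in the growth equation is the absolute flux
divided by weight, so the whole bracketed budget stays in
g prey g⁻¹ d⁻¹ and a single $CAL_z/CAL_f$ conversion applies.

## Population module

Populations are fixed pools of super-individuals: at most 150 SIs in
each early stage (embryos, early larvae, late larvae) and 10 in the
juvenile stage and in each adult age class (anchovy: ages 1–3, sardine:
1–4).  Design choices where the scheme is underdetermined:

* **Cap policy.** When a stage is full, the incumbent with the smallest
  abundance merges into its nearest neighbour by weight
  (abundance-weighted means of weight, length, age and reproductive
  stores).  Merging conserves abundance and biomass exactly, which is a
  tested invariant.
* **Egg SIs.** All batches a species releases on one day are identical
  (age 0, hatchling weight), so they are pooled into a single egg SI
  per species per day before admission.
* **Abundance is continuous** and decays deterministically as
  $dN/dt = -(M+F)N$; fishing mortality applies to adults only and is
  zeroed inside a closure window.  SIs below 10⁻³ individuals are
  culled.
* **Stage transitions** are one-way, at the species' length boundaries
  (anchovy 4–11–42–100 mm, sardine 5–13–50–105 mm); embryos hatch after
  a temperature-dependent duration integrated as a development fraction
  (default $D(T) = 22.3 e^{-0.0875 T}$ days, an adopted exponential
  form; configurable).  Adults advance age class on 365-day age
  anniversaries, not calendar dates, and are removed on leaving their
  terminal class (senescence).
* **Starvation**: an SI dies when weight falls below 65 % of its
  reference weight.  The reference is a rolling maximum that relaxes
  toward the current weight with a ~90-day timescale, so the 35 %
  criterion measures *acute* loss: with a lifetime maximum, a
  long-lived adult whose weight cycles seasonally by ±20–25 % would
  eventually starve "on paper" while in perfectly ordinary condition.
* **Initial state**: one SI per adult age class at a representative
  class length, abundances scaled to the reference biomass, with a
  starting buffer of 30 egg batches; the 10-year spin-up erases this.

## Synthetic environment

The built-in forcing replaces an ocean/biogeochemical model with the
emergent patterns such a model produces in the Thracian Sea setting:

* **SST** interpolates twelve mid-month anchors (13.2 °C in February to
  25.5 °C in August).  With the defaults, SST crosses 15 °C upward in
  mid-April and 16 °C downward in mid-November, so the anchovy season
  runs from spring into autumn and the sardine season from November to
  late April.
* **Temperature profile**: a sigmoid thermocline at 30 m over
  near-constant 14.5 °C deep water; in winter the column is mixed.
* **Mesozooplankton** column mean rises steadily (linearly) from
  mid-December (day 350) to an early-June peak (8 → 45 mgC m⁻³),
  crashes sharply (cosine ramp) to the autumn low by mid-August, then
  stays flat until mid-December — a steady winter-to-summer increase
  followed by a sharp early-summer decline.  During stratification its
  vertical profile is a Gaussian deep maximum at 40 m; in the mixed
  season it is surface-concentrated.  Microzooplankton follows an
  earlier, flatter spring cycle (18–35 mgC m⁻³) and is always
  surface-weighted.
* **Nocturnal ascent**: a fraction (`night_ascent`, default 0.15) of
  the sub-thermocline mesozooplankton migrates into the surface layer
  at night, where all feeding takes place; grazing removal is weighted
  by this exposure.  The fraction controls how much of the summer deep
  maximum the fish can reach: with a small default, the food
  *accessible* to anchovy collapses when stratification develops, which
  is what forces its egg production onto stored reserves (the capital
  pattern); larger values hand the deep biomass to the fish at night
  and flatten the seasonal contrast.
* **Two-way coupling**: pools relax linearly toward the day's
  climatology at 0.1 d⁻¹ (exact exponential integration) and fish
  demand is removed from the surface pools, capped at availability, the
  cap feeding back into realised consumption.  Mass bookkeeping
  (production − removal = net pool change) closes to 10⁻⁸ relative and
  is tested.
* **Scales**: the column represents a habitat area of 5 × 10¹⁰ m²
  (≈ 50,000 km², the combined shelf and adjacent habitat the two stocks
  occupy in the northern Aegean) and zooplankton
  carbon converts to wet prey mass at 12.5 g wet (g C)⁻¹.  These two
  constants link population consumption (grams) to concentrations
  (mgC m⁻³) and set how strongly the fish deplete their prey — the only
  stabilising feedback in the model.

What the synthetic forcing does **not** emulate: interannual
variability, nutrient dynamics, lateral inputs, weather-scale noise, and
any fate for egested/excreted material (these fluxes are tracked as
diagnostics only).  Model results are therefore climatological averages;
passing tests show the mechanisms work under a repeating mean year, not
that the model reproduces any particular observed year.

## Calibration

**Half-saturation coefficients.** The GA is real-coded with tournament
selection (size 2), uniform crossover (rate 0.9), annealed Gaussian
mutation (per-gene rate 0.25, initial scale 15 % of the gene range,
decaying by 0.93–0.98 per generation) and elitism 1.  Termination: 1000
generations, or mean population fitness unchanged (relative tolerance
10⁻⁹) for 150 consecutive generations — the annealing is what allows the
population to converge far enough for the stagnation rule to be
operative.  Fitness is $1/(\sum(\text{pred}-\text{ref})^2+\varepsilon)$
with $\varepsilon = 10^{-12}$ so an exact fit is finite.  Tuning is
**sequential** (early larvae → late larvae → juveniles → each adult age
class) with earlier stages frozen, each stage evaluated by a
single-super-individual forward run (no mortality, no spawning debits,
allocation split still active) from the frozen entry state.  A
simultaneous mode exists for comparison; on recovery experiments the
sequential mode achieves an equal or smaller final squared deviation at
the same budget, consistent with each stage's growth depending on its
predecessors.

Because the two late-larva coefficients govern two prey whose seasonal
densities co-vary, a single growth trajectory leaves them on a shallow
fitness valley (many micro/meso combinations produce nearly the same
total intake).  The reference table therefore includes a second,
late-season larval cohort, whose different prey mix makes the pair
jointly identifiable; the late stage additionally uses a larger,
slower-annealed GA population (see `ga_cfg_late`).

The *shipped* default coefficients were set with this machinery against
a package-defined reference growth schedule for the two species in the
region (anchovy reaching ~100 mm around age 9–10 months and ~140 mm at
age 3+; sardine ~105 mm around its first winter and ~145–160 mm at age
4), followed by manual adjustment where population-level constraints
bind (larval stage durations versus stage-specific mortality, the
timing of sardine maturity relative to its spawning gate, and
identifiability of the late-larva pair).  They are model constructs,
not field estimates.

**Juvenile natural mortality** is the stock-scaling knob: alternating
per-species bracketing bisections (geometric midpoints over
[5 × 10⁻⁴, 0.03] d⁻¹) on the coupled model's years-11–30 mean biomass
against the species' reference biomass (anchovy 40,000 t, sardine
25,000 t), to 5 % relative tolerance, evaluated on the same 30-year
protocol that is reported.  The coupled dynamics are deterministic but
sensitively dependent on parameters (a knife-edge typical of
quasi-neutral two-species coexistence), so each bisection returns the
best point visited rather than the last midpoint, two alternating
rounds are used so each species is calibrated against the other's
calibrated biomass, and a final narrow polish is accepted only if it
reduces the worst relative error of the confirming run
(`calibrate_reference_state()`).  The anchovy value so obtained is of
the same order as the 0.012 d⁻¹ juvenile mortality adopted for the
stock in the literature this model builds on.

## Management scenarios

Paterson's exploitation rate E.R. = F/(M+F) uses the adult rates only.
The sweep back-solves F from target E.R.s per species
(F = E.R.·M/(1−E.R.)), runs each grid cell and records post-spin-up
mean biomasses, annual population fecundity and mean mesozooplankton.
The closure experiment moves a 2.5-month ban (day 15 of month *m*
through the end of month *m*+2, wrapping at the year end) through all
twelve offsets and additionally records the mean individual weight of
the exploitable stock inside the window — its minimum marks the
recruitment period.  The baseline configuration applies F year-round;
the existing December–February ban corresponds to offset *m* = 12.

## Numerical choices and problem sizes

* Daily time stepping of per-day rates (the package's native desk-scale
  mode); a 1200-s sub-step would only re-discretise the same per-day
  rates, and all processes in the model (feeding, spawning decisions,
  mortality) are defined per day.
* Deterministic forward dynamics; the only RNG users are the GA and
  optional fixture noise, always behind an explicit seed.
* 365-day calendar (no leap days), appropriate for climatological
  forcing.
* Analyses in the package's tests use 30-year runs with 10-year
  spin-up for the calibrated baseline, shorter (10–20 year) runs for
  the bisection evaluations and scenario grids, and 2–6 year runs for
  structural checks — sizes chosen so the full suite documents the
  model's behaviour at desk scale.
* Ties in the merge policy resolve to the lowest slot index
  (`which.min`); embryo development carries fractional progress across
  days; weights are floored at 10⁻⁹ g (starvation removes such SIs
  first).

## Known limitations

* One spatial column: no horizontal movement or migration; thresholds
  hit all SIs simultaneously, so spawning seasons start and end
  abruptly.
* The plankton model has no explicit production dynamics — relaxation
  toward a fixed climatology bounds how strongly fish can reshape the
  seasonal cycle.
* Fixed climatological year: no interannual variability or regime
  shifts; capital/income diagnostics are long-run means.
* Mortalities are constant within a stage; no predation feedback or
  intraguild egg predation.
* The capital index is sensitive to the seasonal phasing of food
  against each species' spawning window; under a different forcing
  climatology the breeding-pattern diagnosis can legitimately differ.
  In particular, first-season sardine matures into the rich spring and
  banks whatever surplus exceeds one daily batch, which pushes its
  seasonal index slightly negative rather than to zero.
* In the closure-timing experiment the two species interact: offsets
  that strongly benefit anchovy (winter–spring) depress sardine through
  shared-prey competition, and sardine's own response is nearly flat
  from late spring to autumn.  Single-species conclusions about optimal
  closure timing should therefore be read from the anchovy response
  (which shows a clear spring optimum) with the interaction in mind.
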