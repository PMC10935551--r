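---
title: "Modelling mercury bioaccumulation and seafood exposure with hgtrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling mercury bioaccumulation and seafood exposure with hgtrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`hgtrace` models the fate of mercury in a shelf-sea food web and the human
dietary exposure that follows from eating its commercial species. It was
built for the question raised by North Sea oil-and-gas decommissioning —
what does leaving cleaned subsea pipelines *in situ* do to mercury levels in
seafood and to consumer health metrics — but every stage is generic: any
mass-balanced trophic network with a diet matrix can be run through the
same chain.

This vignette explains the model, its assumptions, the tunable parameters,
the numerical choices, and what the synthetic test data do and do not
demonstrate.

## 1. The static food web

The skeleton is an Ecopath-style mass balance. Each functional group $i$
carries a biomass $B_i$ (t km$^{-2}$ wet weight), a production rate $P/B_i$
(yr$^{-1}$), a consumption rate $Q/B_i$ (yr$^{-1}$, zero for producers and
detritus) and an ecotrophic efficiency $EE_i \in [0,1]$. The diet matrix
$DC_{ij}$ gives the fraction of predator $i$'s consumption taken from prey
$j$; consumer rows sum to one. The master-equation residual

$$ B_i \, (P/B)_i \, EE_i \;-\; \sum_j B_j \, (Q/B)_j \, DC_{ji} \;-\; Y_i $$

is zero for every group of a balanced web ($Y_i$ are fishery removals).
Biomass accumulation and net migration are fixed at zero: the model
environment is closed, with no migration of biota. Flows *into* detritus are
not part of the static balance; the contaminant layer tracks the detrital
mercury pool explicitly instead. Fractional trophic levels solve
$TL_i = 1 + \sum_j DC_{ij} TL_j$, so producers and detritus sit at 1.

Biomasses are held at their balanced values throughout: there are no
temporal biomass dynamics, no fishing-effort dynamics and no multi-stanza
groups.

## 2. The contaminant dynamic

Mercury is tracked as total mercury, with uptake and retention chosen to
emulate methylmercury behaviour. Writing $A_i$ for the total pool of group
$i$ (µg over the model area), $W$ for the water-column pool and
$C_w = W/V$ for its concentration ($V$ = area × depth),

$$ \frac{dA_i}{dt} = u_i C_w K_i
   + \alpha \sum_j \frac{Q_{ij}}{B_j} A_j
   - \sum_k \frac{Q_{ki}}{B_i} A_i
   - e A_i - d_i A_i $$

where $K_i$ is the group's biomass in kg, $Q$ the consumption matrix,
$\alpha$ the dietary assimilation fraction, $e$ the excretion rate and
$d_i = (P/B)_i (1 - EE_i)$ the non-predation mortality rate. The water pool
receives the external influx, all excreted mass and any unassimilated
dietary fraction, and funds all direct uptake; the $d_i$ flows accumulate
in the detritus pool. Total system mass therefore changes exactly by the
external forcing — the conservation property the test suite checks to
$10^{-9}$ relative at every output step.

Key calibration conventions:

* **Direct uptake from water** ($u_i$, l kg$^{-1}$ yr$^{-1}$) is nonzero
  only for the photosynthetic plankton groups and the grazing crustaceans
  (copepods, euphausiids). For all other marine groups, uptake is
  diet-borne; direct uptake from seawater is negligible by comparison.
* **Excretion** defaults to $e = 0.10$ yr$^{-1}$. The source figure is a
  "10 %" elimination with no stated time base; we read it as a first-order
  annual rate, document that reading prominently, and leave it
  configurable. It stands in for uptake of non-accumulating mercury
  species and limited demethylation.
* **Assimilation** defaults to $\alpha = 1$: the 10 % loss is carried
  entirely by $e$. Values below 1 return the unassimilated share to the
  water column, preserving conservation.
* **Mortality routing**: without the $d_i$ term, an apex group's only loss
  would be excretion, and its equilibrium concentration would be
  $Q/B \cdot \bar c_{prey}/e$ — a biologically absurd magnification of
  10–100× per trophic step at $e = 0.1$. Routing non-predation mortality
  to detritus makes the total specific loss $e + P/B$, so the step
  magnification becomes $\alpha \, (Q/B)/(P/B + e) \approx 1/GE$, i.e.
  roughly 3–7× per trophic level — the observed range for methylmercury.
  It also gives detritus the nonzero burden it carries in real webs. The
  flow can be switched off.
* **No sediment compartment, no export, no speciation kinetics.** All
  released mercury mixes instantaneously into the single water volume.
  These simplifications are deliberate and conservative; they bound the
  exposure from above rather than predicting a real release.

### Numerical scheme

Between release events the system is linear and time-invariant,
$\dot x = F x + f$. Rather than an adaptive ODE stepper, the engine
propagates with the matrix exponential of the augmented system
$\begin{pmatrix} F & f \\ 0 & 0 \end{pmatrix}$ acting on $(x, 1)$: one
`Matrix::expm()` call per distinct step length, cached and reapplied. The
result is exact for the model (to matrix-exponential accuracy, near machine
precision at these dimensions), unconditionally stable, and independent of
any step-size choice — the output grid spacing (default 1 yr) is purely a
sampling decision. Because $F$ has nonnegative off-diagonal entries, the
propagator is a nonnegative matrix and pools can never go negative under
nonnegative forcing. Pulse releases are applied between propagation
segments, raising $W$ by exactly the released mass. The test suite
cross-checks this route against an independent small-step Euler oracle
(step $2\times 10^{-5}$ yr) to $10^{-4}$ relative at $t = 100$ yr.

### Equilibration

The validation baseline is the system "allowed to reach equilibrium" at the
background concentration of 0.57 µg l$^{-1}$. A closed system with a
sustained influx has no steady state — total mass grows linearly — so
equilibration treats the water column as an infinite reservoir: $C_w$ is
held fixed and the biota subsystem, which is strictly dissipative for
$e > 0$, is solved directly (`solve(M, -s)`); an iterative mode integrates
instead until the maximum relative pool change drops below $10^{-8}$
yr$^{-1}$, with a 10 000-yr cap and an explicit error carrying the last
state on failure. At that fixed point the fully coupled zero-influx system
is also stationary, which is why release-free scenario runs started from it
do not drift.

### Calibration

Field uptake rates are not measurable directly; what the literature offers
is body burdens. `calibrate_uptake()` therefore solves the inverse problem:
given target equilibrium whole-body concentrations for the flagged groups,
it exploits linearity to build the response matrix of equilibrium
concentration per unit uptake rate and solves for $u$. A target below what
dietary inflow alone already delivers would need $u_i < 0$; that is
reported per group as an unreachable target rather than clipped.

## 3. Release scenarios

Scenario A is the status quo: 0.57 µg l$^{-1}$ initial concentration and a
0.01 t yr$^{-1}$ anthropogenic background influx, over 570 000 km² at a
mean depth of 95 m. Scenarios B–D add a single pulse at year 50: 0.07 t
(the 317.12 km of currently abandoned pipeline, cleaned), 9.9 t (all
45 000 km, cleaned) and 72.93 t (45 000 km cleaned only to the 2 mg kg$^{-1}$
smelting threshold). Two source inconsistencies are handled explicitly
rather than resolved:

* The printed release masses cannot be reproduced from the stated pipe
  geometry (schedule 60, 10″: OD 27.31 cm, wall 12.7 mm). Annulus
  arithmetic gives ≈ 81.6 t of steel per km, hence ≈ 0.0067 t for the
  317.12 km case at 260 µg kg$^{-1}$ — about a tenth of the printed 0.07 t.
  The presets therefore carry the printed masses verbatim, and the
  geometry helpers (`steel_mass_per_km()`, `pipeline_release_mass()`)
  exist for custom inventories and sensitivity work.
* The post-release background is quoted both as 0.01 t yr$^{-1}$ and as
  0.000004 t yr$^{-1}$ in different scenario descriptions. The presets keep
  the constant 0.01; any other value can be set on a custom scenario.

A pulse is a single release because setwise release was reported to make no
difference to final accumulation; `spread_release()` distributes a pulse
over $N$ years for sensitivity analyses (in a linear system the final
accumulation is insensitive once all mass is in).

## 4. Validation statistics

Whole-body concentrations convert to muscle concentrations by the
allocation fractions 0.5 (fish), 0.15 (shrimp) and 1.0
(benthos/plankton/detritus). We implement the conversion as a pure
multiplier on the whole-body concentration; a divisor convention (reading
the fraction as muscle's share of body mass with all mercury in muscle) is
available as an option since the source wording does not disambiguate.

Agreement with observations uses the model/observed ratio $M/\bar O$ and
the normalized mean bias $\mathrm{NMB} = \sum (M - O) / \sum O$. The
interpretive factor follows the published worked examples: $\mathrm{NMB}
\ge 0$ is overprediction by $\mathrm{NMB} + 1$; negative values are
underprediction by $|\mathrm{NMB}| + 1$ (the worked example pairs −0.2 with
a factor 1.2, which matches $|\mathrm{NMB}|+1$ rather than
$1/(\mathrm{NMB}+1) = 1.25$; we follow the published convention).

Food standards are 0.5 mg kg$^{-1}$ muscle for low and 1.0 mg kg$^{-1}$ for
high trophic level species. The source text states this assignment once in
each direction; we follow the methods-section reading (low = 0.5,
high = 1.0), and both limits are configurable through `food_standard()`.
Groups are classed high at $TL \ge 4$ by default. The standards govern
marketed seafood, so exceedance counts in the report summary cover the
commercially landed groups.

## 5. Dietary exposure

The weekly intake equation is applied per species as

$$ EWI = \frac{AC \cdot F \cdot WI \cdot AB \cdot Frac}{W} $$

with $AC$ the muscle methylmercury concentration (µg kg$^{-1}$), $F$ the
bioaccessible fraction (default 1, the conservative choice when no
species value is known), $WI$ the weekly intake (kg), $AB = 0.79$ the
stomach epithelial absorption rate, $Frac$ the sourcing fraction and $W$
the body weight (kg). The published rendering of this equation is
typographically ambiguous ("AB W" merged); the grouping above is the only
dimensionally consistent reading (µg per kg body weight per week) and is
what we implement. Methylmercury is taken as 95 % of muscle total mercury
for fish and higher organisms (30 %/15 % for zoo-/phytoplankton-class
items), configurable per class.

Food groups are fixed to three — oily fish, white fish, shellfish — and a
group's weekly intake is split evenly across its species (the published
food-group formula is garbled; the even-split-then-sum reading follows the
surrounding sentence, and weighting by landings is left to the caller via
custom mappings). Each species mixes two sources: the North Sea share
(21 % for fish, 23 % for shellfish) carries the scenario concentration,
the imported share carries the baseline (scenario A) concentration, since
no data exist for imported stock. Totals are compared with the TWI of
1.3 µg kg$^{-1}$ bw week$^{-1}$; the hazard quotient divides the weekly dose
by the EPA reference of 0.0001 mg kg$^{-1}$ d$^{-1}$ = 0.0007 mg kg$^{-1}$
week$^{-1}$.

## 6. The synthetic generator

The actual 29-group North Sea parameterization is not redistributable, so
the package ships a generator that reproduces its *shape*: 29 groups with
the named guilds (three phytoplankton producers, copepods and euphausiids
as strict herbivores, gelatinous and carnivorous zooplankton, seven benthic
guilds including shrimp, eleven named fish, three warm-blooded top
predators, one detritus pool), the direct-uptake flags, muscle fractions
and commercial status of the real composition — with invented parameter
values. Conventions, chosen once for realism and documented here:

* biomass log-uniform on [0.01, 50] t km$^{-2}$ with the upper bound
  shrinking with trophic rank; the detrital pool at 100–500 t km$^{-2}$,
  far larger than any living compartment (a small detrital biomass would
  concentrate the whole web's mortality flow into an implausible hotspot);
* producer $P/B$ 10–100 yr$^{-1}$, consumer $P/B$ falling log-linearly
  with rank to ~0.03–0.16 yr$^{-1}$ for apex groups; $Q/B = P/B / GE$ with
  gross efficiency $GE \sim U(0.15, 0.3)$;
* diets drawn over lower-ranked groups at the spec'd connectance,
  availability-weighted by $\sqrt{B_{prey}}$ so abundant prey dominate and
  the web stays omnivorous rather than chain-like (fish land at
  $TL \approx 3.3$–5, matching shelf-sea webs);
* $EE$ back-solved from realized predation demand, working from apex
  groups downward and raising a prey's $P/B$ where demand would push
  $EE$ past 0.95 — so `mass_balance_residuals()` is identically zero on
  every emitted web;
* one explicit integer seed threads through all draws and the caller's
  RNG state is restored afterwards.

Default calibration targets are 0.5 µg kg$^{-1}$ whole-body for
phytoplankton and 4 µg kg$^{-1}$ for the grazers — literature-plausible
background burdens that leave the commercial fish of the default web a
factor ≳ 2 below the 0.5 mg kg$^{-1}$ standard at baseline, as the
validated real model is.

The generator also produces observation sets (modelled value divided by
$1 + b$ times unit-mean lognormal noise at a stated CV, so the NMB
machinery can be checked against a constructed truth) and consumer
profiles (men, women, children, pregnant women; NHS-recommendation intakes
dominating NDNS reported intakes component-wise by construction).

**What passing tests do and do not show.** The synthetic webs exercise
every invariant the analysis relies on — balance, conservation, linearity,
monotonicity in release mass, regime ordering — under realistic magnitudes.
They do not reproduce the real model's species parameters, diet data or
observed concentration tables, so numerical outputs (muscle
concentrations, EWIs, HQs) characterize the method, not the North Sea.

## 7. Problem sizes and tolerances used in the tests

The suite runs the full 29-group chain at a 100-yr horizon; conservation is
checked on one hundred 8-group webs over 20 yr with a mid-horizon pulse;
the Euler cross-check uses a 3-group web at $dt = 2 \times 10^{-5}$ yr over
100 yr (computed exactly via binary exponentiation of the Euler step);
calibration round-trips use 5-group webs with targets generated by forward
runs, closing within 1 %; bias recovery averages 20 seeds at 100 studies
per group. All are seconds-scale choices that still probe each property at
meaningful size.

## 8. Known limitations

* Total mercury is a proxy; there is no methylation/speciation kinetics and
  no sediment compartment, so re-mobilization pathways are out of scope.
* Static biomasses mean no growth dilution dynamics and no trophic cascade
  responses to a release.
* The exposure layer is deterministic (no Monte Carlo over intake or
  concentration distributions) and ignores cooking losses.
* The economic (revenue-loss) dimension of decommissioning is not
  implemented: no method is specified for it.
* Release is fully mixed instantaneously; near-field plumes and local
  sediment contamination are not represented.
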