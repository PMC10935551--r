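# hgtrace

Mercury food-web bioaccumulation and seafood exposure modelling for shelf
seas, motivated by North Sea oil-and-gas decommissioning: if cleaned subsea
pipelines are abandoned *in situ*, residual mercury enters the water
column, biomagnifies up the food web, and reaches people through seafood.
`hgtrace` implements that whole chain as composable, tested R functions —
for ecotoxicologists and risk assessors who want the method on their own
food-web parameterizations rather than inside a GUI modelling suite.

## What it computes

**Static mass balance (Ecopath-style).** Functional groups with biomass
`B` (t km⁻²), production `P/B` and consumption `Q/B` (yr⁻¹), ecotrophic
efficiency `EE` and a diet matrix `DC`. A balanced web satisfies, per
group,

    B·(P/B)·EE − Σⱼ Bⱼ·(Q/B)ⱼ·DCⱼᵢ − Yᵢ = 0

and fractional trophic levels solve `TL = 1 + DC·TL`.

**Contaminant dynamics (Ecotracer-style).** Per-group mercury pools `Aᵢ`
and a water pool `W` evolve by

    dAᵢ/dt = uᵢ·C_w·Kᵢ + α·Σⱼ (Qᵢⱼ/Bⱼ)·Aⱼ − Σₖ (Qₖᵢ/Bᵢ)·Aᵢ − e·Aᵢ − dᵢ·Aᵢ

with direct water uptake `uᵢ` restricted to phytoplankton, copepods and
euphausiids, excretion `e = 0.10 yr⁻¹`, dietary assimilation `α`, and
non-predation mortality `dᵢ = (P/B)(1−EE)` routed to detritus. The closed
system conserves mass exactly up to external influx; being linear, it is
propagated with matrix exponentials (no step-size error). Release
scenarios A–D reproduce the published decommissioning cases: background
0.57 µg l⁻¹ and 0.01 t yr⁻¹ influx, plus a year-50 pulse of 0 / 0.07 /
9.9 / 72.93 t mixed into 570 000 km² × 95 m.

**Validation and risk.** Whole-body burdens convert to muscle
concentrations (×0.5 fish, ×0.15 shrimp, ×1 otherwise) and are compared to
observations by the M/O ratio and the normalized mean bias
`NMB = Σ(M−O)/ΣO` with its interpretive factor (NMB 1.2 → overprediction
×2.2; NMB −0.2 → underprediction ×1.2), and to the food standards (0.5 /
1.0 mg kg⁻¹ muscle for low / high trophic level species). The estimated
weekly methylmercury intake per consumer group is

    EWI = AC·F·WI·AB·Frac / W   (µg kg⁻¹ bw week⁻¹)

checked against the TWI of 1.3 µg kg⁻¹ bw week⁻¹, and the hazard quotient
divides the weekly dose by the EPA reference (0.0007 mg kg⁻¹ week⁻¹).

**Synthetic data.** Because the real 29-group parameterization is not
redistributable, `generate_foodweb()` emits mass-balanced webs of the same
shape (named guilds, direct-uptake flags, muscle fractions), plus
calibration helpers, synthetic observation sets with controlled bias, and
consumer profiles — so the entire pipeline runs and is testable from a
seed.

## Worked example

```r
library(hgtrace)

web    <- generate_foodweb(web_gen_spec(seed = 1))   # 29-group synthetic web
params <- calibrate_uptake(web, default_uptake_targets(web))
report <- run_full_analysis(web, params = params, horizon = 100, seed = 1)
report$summary
#>   scenario fs_exceedances_low fs_exceedances_high max_muscle_mg_per_kg
#> 1        A                  0                   0            0.2429547
#> 2        B                  0                   0            0.2429552
#> 3        C                  0                   0            0.2430305
#> 4        D                  0                   0            0.2435134
#>   max_muscle_group twi_exceedances    max_hq
#> 1 harbour_porpoise               0 0.4963806
#> 2 harbour_porpoise               0 0.4963808
#> 3 harbour_porpoise               0 0.4964138
#> 4 harbour_porpoise               0 0.4966255
```

Reading it: muscle concentrations rise monotonically from scenario A
(status quo) to D (72.93 t release), but even the worst case lifts the most
contaminated group by well under a percent — a 72.93 t pulse into a
5.4 × 10¹⁶ l basin raises the water concentration by only ~1.3 × 10⁻³
µg l⁻¹ against a 0.57 µg l⁻¹ background — so no commercial group crosses a
food standard, no consumer group crosses the TWI, and every hazard
quotient stays below 1 at this calibrated baseline. Per-profile detail:

```r
subset(report$risk, scenario == "D" & consumer == "pregnant women")
#>    scenario       consumer regime ... ewi_total_ug_per_kg_bw_wk twi_exceeded        hq
#> 31        D pregnant women    NHS ...                0.23175859        FALSE 0.3310837
#> 32        D pregnant women   NDNS ...                0.08659998        FALSE 0.1237143
```

The NHS-recommendation regime always yields a higher weekly intake than
the NDNS reported-consumption regime, here 0.232 vs 0.087 µg kg⁻¹ bw
week⁻¹ for pregnant women under scenario D.

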