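# erwsim

Coupled ecosystem simulation of enhanced rock weathering (ERW) in a
vertically lumped, biogeochemically active soil layer.

ERW amends soils with crushed Ca- and Mg-rich silicate rock (basalt,
olivine, wollastonite). Dissolution consumes CO₂-derived acidity and
generates alkalinity, converting soil CO₂ into dissolved inorganic carbon
(mostly HCO₃⁻) that can be leached toward groundwater and, eventually, the
ocean — a carbon dioxide removal (CDR) pathway. How much CO₂ is actually
removed depends on tightly coupled ecosystem processes: soil moisture
controls both dissolution (wetted mineral surfaces) and leaching;
respiration sets the soil CO₂ pressure and hence porewater pH; plants take
up the released cations (an alkalinity sink) and feed the soil carbon
cycle; the exchange complex buffers everything. `erwsim` simulates this
whole loop for users who want process-based, mass-conserving estimates of
potential and effective CDR under arbitrary climates, soils, feedstocks
and cropping systems — without any external data dependencies, thanks to a
built-in synthetic weather generator.

## Model core

* **Mineral dissolution** (10-min step): Palandri–Kharaka kinetics per
  mineral and mechanism *m* ∈ {acid, neutral, base},

  r = F_D · s_eff · (1 − min(Ω, 1)) · Σₘ k₂₅,ₘ ·
  exp[−Eₐ,ₘ/R · (1/T − 1/298.15)] · (10^−pH)^{n_m}   (mol m⁻² s⁻¹)

  with shrinking-particle surface area A = A₀ (m/m₀)^{2/3} per
  application cohort. A packaged library ships constants for albite,
  ferroactinolite, epidote, chlorite, quartz, calcite, forsterite,
  anorthite and diopside.
* **Carbonate system** (10-min step): alkalinity as the solute charge
  balance ALK = 2[Ca²⁺] + 2[Mg²⁺] + [K⁺] + [Na⁺] + [NH₄⁺] − [NO₃⁻] −
  [Anᵣ] − [TPO₄]; open-system pH solve against the soil-air CO₂
  reservoir; Millington–Quirk CO₂ efflux; pedogenic carbonate
  (first-order in 10^SI − 1); Gaines–Thomas cation exchange.
* **Soil biology** (daily): microbially explicit MEND-style organic
  carbon decomposition (POC/MAOC/DOC, microbes, enzymes, earthworms,
  eight litter pools) plus complete N, P, K/Ca/Mg, Si, Na, Al and
  residual-anion budgets.
* **Vegetation** (daily): single-canopy light-use-efficiency
  photosynthesis, maintenance + growth respiration, stoichiometry-limited
  nutrient uptake with an 80→100 % reserve-saturation ramp, litterfall
  and crop harvest.
* **Hydrology** (hourly): bucket water balance with saturation-excess
  runoff, Priestley–Taylor ET and unit-gradient drainage.

Accounting: **potential CDR** = 2 mol CO₂ per mol of weathered Ca²⁺ + Mg²⁺
(g CO₂ m⁻²; 1 g m⁻² = 0.01 t ha⁻¹); **effective CDR** = DIC leached below
the active layer, as CO₂. Every element (C, N, P, K, Ca, Mg, Na, Si, Al,
anions) carries a conservation ledger that the test suite requires to
close within 10⁻⁶ relative over multi-year runs.

## Worked example

Five kilograms of basalt per square metre (the Blue-Ridge-type
characterisation: 19.6 % albite, 11.6 % ferroactinolite, 25.6 % epidote,
36.3 % chlorite, 5.2 % quartz) applied on day 30 of a one-year simulation
under synthetic humid-temperate forcing:

```r
library(erwsim)

basalt <- list(albite = 0.196, ferroactinolite = 0.116, epidote = 0.256,
               chlorite = 0.363, quartz = 0.052)
cfg <- validate_config(list(
  feedstock = list(events = list(
    list(day = 30, rate = 5, ssa = 300, fractions = basalt)))))
forcing <- generate_synthetic_forcing(
  mean_temp = 12, seasonal_amp = 10, diurnal_amp = 6,
  annual_rain_mm = 900, storm_freq = 0.4, seed = 1, n_years = 1)

out <- run_simulation(cfg, forcing, seed = 1)
print(out)
#> <erw_output> 365 days
#>   potential CDR 0.035 t CO2/ha (total), effective 0.037 t CO2/ha
#>   max |element ledger residual| 2.01e-14

ctrl <- run_simulation(validate_config(), forcing, seed = 1)
round(c(treated = tail(out$daily_state$ph, 1),
        control = tail(ctrl$daily_state$ph, 1)), 3)
#> treated control
#>   6.020   5.976
```

Reading the numbers: in its first year this application weathers a few
per cent of its fast minerals, releasing enough Ca + Mg to bind
~0.035 t CO₂ ha⁻¹ as alkalinity (potential CDR). Effective CDR is the
*gross* DIC export below the active layer — it includes the background
respiration-derived bicarbonate that an untreated soil also leaches, so
the ERW contribution is the treatment-minus-control difference. The
porewater pH ends slightly above the untreated control (most of the
first-year alkalinity is buffered onto the exchange complex — base
saturation 76.1 % vs 75.9 % — before pH responds, the lag ERW field
trials also show). The ledger residual line confirms element mass
conservation at rounding error. Absolute magnitudes depend on the
uncalibrated default parameters (see the methods vignette); the
conservation, monotonicity and feedback properties hold by construction.

Packaged scenarios: `scenario_config("mesocosm_sorghum")` (121-day
column experiment, F_D = 0.5) and
`scenario_config("illinois_maize_soy")` /
`"illinois_maize_soy_basaltB"` (4-year maize–soy rotation, four annual
5 kg m⁻² basalt applications under two feedstock characterisations; bring
your own forcing). A thin command-line driver lives at
`inst/cli/erwsim` (`gen-forcing`, `validate`, `spinup`, `run`).

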