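---
title: "Model description and numerical choices"
author: "erwsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model description and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erwsim)
```

# What erwsim simulates

`erwsim` simulates enhanced rock weathering (ERW) — amending a soil with
crushed silicate rock so that mineral dissolution consumes CO~2~-derived
acidity and generates alkalinity — inside a vertically lumped,
biogeochemically active soil layer (default 30 cm). The model couples five
interacting components on a nested clock:

* an **hourly bucket water balance** (infiltration, saturation-excess
  runoff, Priestley–Taylor evapotranspiration, unit-gradient drainage, a
  trivial degree-day snow store) that supplies effective saturation,
  transpiration and bottom leakage to everything else;
* **10-minute feedstock dissolution** using Palandri–Kharaka rate laws
  (acid / neutral / base mechanisms, Arrhenius temperature correction,
  proton-activity power laws) modified by a linear soil-moisture term, a
  thermodynamic factor $1-\min(\Omega,1)$ and a dimensionless dissolution
  factor $F_D$ that absorbs uncharacterised field effects;
* **10-minute carbonate-system chemistry**: porewater alkalinity as the
  charge balance $ALK = 2[\mathrm{Ca}^{2+}] + 2[\mathrm{Mg}^{2+}] +
  [\mathrm{K}^+] + [\mathrm{Na}^+] + [\mathrm{NH_4}^+] -
  [\mathrm{NO_3}^-] - [\mathrm{An}_r] - [\mathrm{TPO_4}]$, an open-system
  pH solve against the soil-air CO~2~ reservoir, Millington–Quirk gas
  efflux, pedogenic carbonate precipitation/dissolution, and Gaines–Thomas
  cation exchange;
* **daily microbially explicit soil organic carbon** decomposition
  (MEND-style POC/MAOC/DOC pools, bacteria, saprotrophic fungi,
  mycorrhizae, a shared enzyme pool, earthworms, eight litter pools) and
  full N, P, base-cation, Si, Na, Al and residual-anion budgets;
* a **daily single-canopy vegetation component** with light-use-efficiency
  photosynthesis, maintenance/growth respiration, stoichiometry-limited
  nutrient uptake and litterfall/harvest.

The model reports *potential CDR* (the CO~2~ equivalent of Ca + Mg released
by weathering, 2 mol CO~2~ per mol of divalent cation) and *effective CDR*
(dissolved inorganic carbon actually leached below the layer, expressed as
CO~2~). Monovalent (K + Na) alkalinity is reported separately as a
diagnostic and excluded from the headline number.

# Time stepping and operator splitting

Each day: the soil biology and vegetation advance one daily step using the
*previous* day's aggregated chemistry (time-mean pH, end-of-day solute
masses, summed leaching rate). Each hour within the day: the bucket water
balance advances, then six 10-minute chemistry sub-steps run in the fixed
order *weathering release → cation exchange → alkalinity/pH + CO~2~
transport → pedogenic carbonate*. The pH used by the dissolution law is the
previous sub-step's pH (explicit coupling). This is a deliberate
operator-splitting scheme with an $O(\Delta t)$ splitting error at the
10-minute scale; it avoids any inner iteration between weathering and the
carbonate solve and keeps every sub-step's mass bookkeeping exact.

All calendars use 365-day years (leap days dropped) so the hourly,
10-minute and daily clocks always align.

# Numerical methods

**pH and gas–aqueous partitioning.** Given alkalinity and the total
inorganic carbon mass (soil-air CO~2~ + DIC), the carbonate alkalinity
$B = ALK - [\mathrm{OH}^-] + [\mathrm{H}^+]$ fixes
$[\mathrm{H_2CO_3}^*]$ at each trial pH, so the partitioning reduces to a
single monotone scalar equation in pH. It is solved by safeguarded Newton
iteration (bisection fallback, bracket pH 1–13) warm-started from the
previous sub-step. The standalone `solve_carbonate_system()` brackets pH in
[2, 12] and refines the charge balance below 10^-10^ mol m^-3^.
Equilibrium constants are van 't Hoff corrected from their 25 °C values.
Activity coefficients are unity (dilute porewater); a Davies-equation hook
exists in the configuration but is off by default.

**Cation exchange.** Gaines–Thomas selectivity implies
$E_i = k_i a_i \lambda^{z_i}$ for a single site-balance multiplier
$\lambda$; combined with the per-cation mass balance each equivalent
fraction is an explicit rational function of $\lambda$, leaving one
monotone scalar equation solved by safeguarded Newton in $\log\lambda$.
Per-element mass (solution + exchangeable) is conserved exactly by
construction. Exchangeable acidity is not an equilibrium species:
treating protons as an unbuffered equilibrium reservoir is structurally
unstable whenever base cations are scarce relative to the CEC (the site
balance then drives either the acidity or the solution concentrations to
extremes). Instead, acidity relaxes kinetically toward a titration
equilibrium $1/(1+10^{\,\mathrm{pH}-\mathrm{pH}_{50}})$
(default pH~50~ = 5.5) with a configurable e-folding time (default 60 d):
acidification displaces base cations into solution conservatively;
de-acidification frees sites that the next sub-step equilibrium refills
from solution, rate-limited by the base charge available in solution.
This gives base saturation a realistic, smoothly buffered pH response.

**Feedstock surface area.** Each application event creates one cohort per
mineral; cohort reactive area follows the shrinking-particle rule
$A = A_0 (m/m_0)^{2/3}$. Dissolved moles per sub-step are capped at the
cohort's remaining moles; at the 10-minute step the cap binds only in
pathological configurations. Calcite is the only phase with a saturation
ratio ($\Omega$ from the ion activity product over $K_{sp}$); silicates
dissolve far from equilibrium by default. Application events whose X-ray
mineralogy closes to slightly less than 100 % (down to 95 %) are accepted,
with the unresolved remainder treated as inert residue.

**Mass conservation.** Every transfer in the model is double-booked:
`run_simulation()` accumulates per-element inputs and exports and compares
initial + inputs − exports with final stocks over ten ledgers
(C, N, P, K, Ca, Mg, Na, Si, Al, residual anions). The test suite requires
closure within 10^-6^ relative on a four-year amended run; in practice the
residuals sit at rounding error (~10^-12^). Daily pool updates use explicit
Euler steps with all outfluxes jointly capped so no pool goes negative;
the SOC step additionally halves its internal time step (up to four times)
if a pool would still be driven negative.

# Key parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `site$z_active` | 0.30 | m | depth of the lumped active layer |
| `site$cec` | 40 | mol~c~ m^-2^ | cation exchange capacity of the layer |
| `weathering$F_D` | 1 | – | dissolution factor (>1 enhancement, <1 inhibition) |
| `weathering$k_precip` | 10^-8^ | mol m^-2^ s^-1^ | pedogenic-carbonate rate constant |
| `chemistry$dic_rain` | 0.2 | g C m^-3^ | DIC concentration of rainwater |
| `chemistry$selectivity` | Ca 1, Mg 1, K 0.2, Na 0.05 | – | Gaines–Thomas affinities (Ca reference) |
| `chemistry$acid_ph50`, `acid_tau` | 5.5, 60 | pH, d | exchangeable-acidity titration midpoint and relaxation time |
| `hydrology$damping_days` | 10 | d | soil-temperature e-folding time |
| `biogeochem$q10` | 2 (ref. 20 °C) | – | temperature response of biology |
| `biogeochem$fw_opt` | 0.6 | – | moisture optimum of decomposition |
| `biogeochem$fph_mu`, `fph_sigma` | 6.5, 1.5 | pH | Gaussian pH response |

The environmental modifiers ($Q_{10}$ form, quadratic moisture optimum,
Gaussian pH response), the Michaelis–Menten constants of the decomposition
fluxes, the litter-routing fractions, the C:element ratios of soil organic
matter, and the plant stoichiometric targets for Ca, Mg and Si are
**calibration placeholders**: plausible magnitudes for a temperate
agricultural soil, shipped as defaults so the coupled system runs and
conserves mass, not site-calibrated values. The pedogenic-carbonate rate
constant `k_precip` and the rainwater DIC concentration `dic_rain` are
likewise free parameters — the published lineage of this model family
names both terms without printing field values, so the defaults here are
deliberately conservative and fully configurable.

# The synthetic forcing generator

`generate_synthetic_forcing()` makes the entire system testable offline.
It emulates: a sinusoidal annual temperature cycle (minimum in
mid-January) plus a diurnal sinusoid (minimum ~03:00) plus bounded AR(1)
noise; rainfall as a marked Poisson process (storm arrivals at a
configurable daily frequency, exponentially distributed depths whose mean
is set so the expected annual total matches the configured rainfall); a
day-length-modulated clear-sky shortwave curve attenuated on rainy hours;
humidity anticorrelated with the temperature anomaly and saturated during
rain; constant pressure and CO~2~.

What it does **not** emulate: storm clustering and frontal systems,
autocorrelated dry spells, seasonal rainfall regimes (monsoons),
co-variation of wind with storms, longwave radiation, weather
extremes with realistic return periods. Passing conservation and
monotonicity tests under this generator demonstrates internal consistency
of the model, not skill against field observations — reproducing observed
fluxes additionally requires reanalysis forcing and site calibration.

The default test conditions (mean 12 °C, seasonal amplitude 10 °C, diurnal
6 °C, 900 mm yr^-1^, 0.4 storms d^-1^) describe a generic humid temperate
agricultural climate.

# Design choices made where the design was open

* **Bucket hydrology instead of a Richards column.** The ERW chemistry is
  vertically lumped, so a single bucket of the active-layer depth
  preserves the moisture statistics that drive dissolution at a fraction
  of the cost; the aggregation question a multi-layer solution would raise
  (how to collapse a moisture profile into the lumped layer) disappears.
* **Moisture term.** The dissolution law multiplies by effective
  saturation directly (pure proportionality): dry soil weathers nothing,
  saturated soil weathers at the full wetted-surface rate.
* **$F_D$ placement.** $F_D$ multiplies the mechanism-summed rate;
  algebraically equivalent to scaling each mechanism. Note that
  *cumulative* release is sub-linear in $F_D$ even at frozen pH, because
  the shrinking-particle rule depletes cohorts faster at higher $F_D$;
  exact factor-two scaling holds only in the depletion-free limit.
* **Exchange solved exactly.** The Gaines–Thomas system is reduced to one
  scalar equation instead of a damped fixed-point iteration over all
  cations — the same equilibrium with exact elemental conservation and
  fewer iterations.
* **TPO~4~ charge −1 in alkalinity.** The undifferentiated orthophosphate
  pool enters the charge balance with a single negative charge despite its
  mixed speciation; this follows the model family's stated balance and is
  flagged here because it slightly understates the acid contribution of
  HPO~4~^2-^ at high pH.
* **Al outside the charge balance.** Aluminium is tracked as a
  conservative mobile pool (input + weathering − leaching, no plant
  uptake) and excluded from alkalinity, consistent with its minor role
  above pH 5.
* **NH~4~^+^ and PO~4~^3-^ do not exchange with clays** — deliberately
  omitted, as the processes are poorly constrained; base saturation will
  therefore run slightly high where ammonium loads are large.
* **Daily nutrient chemistry.** NH~4~, NO~3~ and TPO~4~ update on the
  daily biology clock and are held constant within a day's 10-minute
  sub-steps; base cations, Si, Al and DIC update at the sub-step.
* **80 → 100 % uptake suppression.** Plant nutrient uptake is multiplied
  by a factor falling linearly from 1 to 0 as an element's reserve fills
  from 80 % to 100 % of capacity — a continuous, monotone reading of
  reserve-saturation regulation.
* **Seed carbon.** Annual crops are planted as a small seed pool (15 g C
  m^-2^ plus starter reserves) booked as an external input, so the plant
  carbon ledger closes across planting and harvest. A harvested (dead)
  stand takes up no nutrients until replanting.
* **Photosynthesis water stress** is fully relieved at 60 % of the
  plant-available water range (an FAO-56-style depletion fraction), while
  the evapotranspiration limit in the hydrology step keeps the full
  wilting-point-to-field-capacity ramp. Without this split the canopy is
  chronically stressed at typical mid-range soil moisture.
* **Trait calibration.** Light-use efficiencies, allocation fractions and
  turnover/maintenance rates were set once so that the default grass
  canopy persists under the default climate (GPP ≈ 700–800 g C m^-2^
  yr^-1^ under repeating forcing) and crop canopies develop within their
  phenology windows; perennial grass allocates little to reproductive
  tissue and sheds it continuously, where crops accumulate it for
  harvest.

# Spin-up behaviour

`spin_up()` recycles a forcing record with no feedstock, carries the state
across cycles, and reports the relative drift of the solution and
exchangeable pools over the final cycle, warning above 1 % (this
package's convention for "not converged"). Two caveats are documented
deliberately: (i) the primary-mineral pools release on a multi-decade
timescale and are excluded from the convergence metric; (ii) the
exchangeable **Ca** pool is so strongly buffered by the exchange complex
that its per-cycle drift can *rise* for several cycles before decaying —
settling is monotone for the faster pools (Mg, Na) once the initial
transient has passed, and the test suite asserts exactly that.

# Problem sizes used by the packaged checks

The conservation audit runs four years of hourly hydrology with 10-minute
chemistry (two 5 kg m^-2^ applications); the rate-monotonicity experiment
runs five 3-year simulations at application rates 0–10 kg m^-2^; the
$F_D$-feedback experiment runs four 121-day bare-soil simulations; the
chemistry oracles scan a 20-point alkalinity × pCO~2~ grid against a
10^-5^-resolution brute-force search. These sizes keep the full suite
within a desktop coffee break while exercising every coupled pathway.

# Known limitations

* No vertical structure: concentration gradients, horizon-specific pH and
  deep-root uptake are outside scope; field users should treat the lumped
  pH as a porewater proxy, not a bulk-soil measurement.
* Silicate saturation states are not computed; secondary clay formation is
  a first-order sink, so Si (and to a lesser degree Al) release is
  overestimated where smectite-type sinks matter.
* The light-use-efficiency canopy cannot reproduce leaf-level responses
  (CO~2~ fertilisation, VPD effects); crop GPP magnitudes are set by the
  trait defaults.
* Effective CDR is accounted at the bottom of the active layer; riverine
  transport, degassing en route and ocean storage efficiency are not
  modelled.
* Biogeochemical parameter defaults are uncalibrated placeholders (see
  above); absolute CDR magnitudes from the defaults are indicative only,
  while the conservation, monotonicity and feedback properties hold by
  construction.
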