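# Physical and chemical constants used across modules.
# All equilibrium constants are 25 degC values on the mol/L scale; van 't Hoff
# temperature correction is applied where a reaction enthalpy is given.

#' @keywords internal
.const <- list(
  R_gas      = 8.314462,     # J mol-1 K-1
  R_Lat      = 0.08205736,   # L atm mol-1 K-1
  T_ref      = 298.15,       # K
  sec_hour   = 3600,
  sec_substep = 600,         # ERW chemistry sub-step, s
  substeps_per_hour = 6L,
  hours_year = 8760L,        # 365-day calendar, leap days dropped
  M_CO2      = 44.01,        # g mol-1
  # atomic masses, g mol-1
  M = c(Ca = 40.078, Mg = 24.305, K = 39.0983, Na = 22.98977,
        Si = 28.0855, Al = 26.98154, P = 30.97376, C = 12.011,
        N = 14.0067),
  # carbonate system at 25 degC (mol/L scale) and reaction enthalpies (J/mol)
  logK_H  = -1.47,  dH_KH = -19983,   # CO2(g) <-> H2CO3*, exothermic
  logK_1  = -6.35,  dH_K1 =   7646,   # H2CO3* <-> H+ + HCO3-
  logK_2  = -10.33, dH_K2 =  14850,   # HCO3- <-> H+ + CO3 2-
  logK_w  = -14.0,  dH_Kw =  55836,   # water autoionisation
  logK_sp_calcite = -8.48, dH_Ksp = -9610,  # CaCO3 solubility product
  D0_CO2_air = 1.39e-5      # free-air CO2 diffusivity, m2 s-1
)

# van 't Hoff correction of an equilibrium constant from 25 degC to temp_K
.vant_hoff <- function(K25, dH, temp_K) {
  K25 * exp(-dH / .const$R_gas * (1 / temp_K - 1 / .const$T_ref))
}
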