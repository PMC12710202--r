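# shared fixtures for the test suite; everything is generated in code

basalt_lewis <- list(albite = 0.196, ferroactinolite = 0.116,
                     epidote = 0.256, chlorite = 0.363, quartz = 0.052)

# one-mechanism synthetic mineral library for kinetics oracles
toy_lib <- function() {
  data.frame(
    mineral = c("fo_neutral", "acidmin", "acidmin"),
    mechanism = c("neutral", "acid", "neutral"),
    log_k25 = c(-10.64, -6.0, -11.0),
    Ea_kJmol = c(79.0, 50.0, 50.0),
    n_H = c(0, 0.8, 0),
    molar_mass_g = c(140.69, 100.0, 100.0),
    stoich_Ca = c(0, 1, 1), stoich_Mg = c(2, 0, 0),
    stoich_K = 0, stoich_Na = 0,
    stoich_Si = c(1, 0, 0), stoich_Al = 0, stoich_P = 0, stoich_C = 0,
    log_Keq = NA_real_, source = "synthetic",
    stringsAsFactors = FALSE)
}

short_forcing <- function(n_years = 1, seed = 1) {
  generate_synthetic_forcing(mean_temp = 12, seasonal_amp = 10,
                             diurnal_amp = 6, annual_rain_mm = 900,
                             storm_freq = 0.4, seed = seed,
                             n_years = n_years)
}

short_config <- function(n_days = 90, ...) {
  over <- list(...)
  raw <- utils::modifyList(list(schedule = list(n_days = n_days)), over)
  validate_config(raw)
}
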