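#' Hourly bucket water balance for the active soil layer
#'
#' Single-bucket simplification over the biogeochemically active layer of
#' depth `z_active`: saturation-excess runoff, unit-gradient drainage
#' `Ks * s_eff^c` with the Clapp-Hornberger exponent `c = 2b + 3`,
#' Priestley-Taylor potential evapotranspiration partitioned to transpiration
#' by a Beer-law canopy fraction `1 - exp(-0.5 * lai)` and limited by a
#' linear soil-moisture stress between wilting point and field capacity.
#' Sub-zero precipitation accumulates in a snow store melting with a
#' degree-day factor.
#'
#' @param state named numeric: `s_eff` (effective saturation, 0..1) and
#'   `snow` (snow water equivalent, mm)
#' @param hour one-row list/data frame with `air_temp` (degC), `precip`
#'   (mm h-1) and `sw_down` (W m-2)
#' @param lai leaf area index, m2 m-2
#' @param params hydraulic parameter list from [hydro_params()]
#' @return list with `state` (updated) and `fluxes` (named numeric, mm h-1:
#'   `infiltration`, `runoff`, `evaporation`, `transpiration`, `leakage`,
#'   `snowfall`, `melt`)
#' @export
step_soil_water <- function(state, hour, lai, params) {
  ta <- hour$air_temp; pr <- hour$precip; sw <- hour$sw_down
  if (!is.finite(ta) || !is.finite(pr) || !is.finite(sw))
    stop("NaN forcing at ", if (!is.null(hour$timestamp)) hour$timestamp
         else "unknown hour")
  if (lai < 0) stop("lai must be >= 0")
  s <- state[["s_eff"]]; snow <- state[["snow"]]

  # snow partition and degree-day melt
  snowfall <- if (ta <= 0) pr else 0
  rain <- pr - snowfall
  melt <- if (ta > 0) min(snow, params$snow_ddf * ta / 24) else 0
  snow <- snow + snowfall - melt
  input <- rain + melt

  # Priestley-Taylor potential ET (mm h-1) on net shortwave
  delta <- 4098 * (0.6108 * exp(17.27 * ta / (ta + 237.3))) /
    (ta + 237.3)^2
  gamma <- 0.066
  rn <- (1 - params$albedo) * sw                    # W m-2
  pet <- max(0, params$pt_alpha * delta / (delta + gamma) * rn /
               2.45e6 * 3600)                       # mm h-1
  beta <- min(1, max(0, (s - params$s_wp) / (params$s_fc - params$s_wp)))
  f_t <- 1 - exp(-0.5 * lai)
  transp <- pet * f_t * beta
  evap <- pet * (1 - f_t) * beta
  leak <- params$ks_mm_h * s^params$c_exp

  cap <- params$capacity_mm                         # porosity * Za * 1000
  storage <- s * cap
  avail <- storage + input
  out <- evap + transp + leak
  if (out > avail && out > 0) {                     # cannot dry below empty
    sc <- avail / out
    evap <- evap * sc; transp <- transp * sc; leak <- leak * sc
    out <- avail
  }
  new_storage <- storage + input - out
  runoff <- 0
  if (new_storage > cap) {                          # saturation excess
    runoff <- new_storage - cap
    new_storage <- cap
  }
  infiltration <- input - runoff
  state[["s_eff"]] <- new_storage / cap
  state[["snow"]] <- snow
  list(state = state,
       fluxes = c(infiltration = infiltration, runoff = runoff,
                  evaporation = evap, transpiration = transp,
                  leakage = leak, snowfall = snowfall, melt = melt))
}

#' Assemble hydraulic parameters from a validated configuration
#'
#' @param config a `sim_config`
#' @return list used by [step_soil_water()]
#' @export
hydro_params <- function(config) {
  s <- config$site; h <- config$hydrology
  list(z_active = s$z_active, porosity = s$porosity,
       capacity_mm = s$porosity * s$z_active * 1000,
       s_fc = s$field_capacity / s$porosity,
       s_wp = s$wilting_point / s$porosity,
       ks_mm_h = s$ks_mm_h, c_exp = 2 * s$b + 3,
       pt_alpha = h$pt_alpha, albedo = h$albedo, snow_ddf = h$snow_ddf)
}

#' Soil temperature as a damped response to air temperature
#'
#' First-order exponential filter of hourly air temperature with e-folding
#' time `damping_days`; a stand-in for ground heat flux in the lumped layer.
#'
#' @param air_temp hourly air temperature series, degC
#' @param damping_days e-folding time, days (> 0)
#' @param init initial soil temperature (default: first air temperature)
#' @param floor0 if `TRUE`, floor the result at 0 degC
#' @return numeric series of the same length
#' @export
soil_temperature <- function(air_temp, damping_days, init = air_temp[1],
                             floor0 = FALSE) {
  if (damping_days <= 0) stop("damping_days must be > 0")
  k <- min(1, 1 / (damping_days * 24))
  out <- stats::filter(k * air_temp, 1 - k, method = "recursive",
                       init = init)
  out <- as.numeric(out)
  if (floor0) out <- pmax(out, 0)
  out
}
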