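#' Temperature-corrected carbonate-system constants
#'
#' Henry's constant, the two carbonic-acid dissociation constants, the water
#' ion product and the calcite solubility product, van 't Hoff corrected
#' from their 25 degC values. All on the mol/L scale.
#'
#' @param temp_c temperature, degC
#' @return named list `KH`, `K1`, `K2`, `Kw`, `Ksp`
#' @export
carbonate_constants <- function(temp_c) {
  tk <- temp_c + 273.15
  list(KH  = .vant_hoff(10^.const$logK_H, .const$dH_KH, tk),
       K1  = .vant_hoff(10^.const$logK_1, .const$dH_K1, tk),
       K2  = .vant_hoff(10^.const$logK_2, .const$dH_K2, tk),
       Kw  = .vant_hoff(10^.const$logK_w, .const$dH_Kw, tk),
       Ksp = .vant_hoff(10^.const$logK_sp_calcite, .const$dH_Ksp, tk))
}

#' Porewater alkalinity from solute pools
#'
#' Charge-balance alkalinity of the porewater: proton donors minus
#' acceptors among the tracked conservative ions,
#' \deqn{ALK = 2[Ca^{2+}] + 2[Mg^{2+}] + [K^+] + [Na^+] + [NH_4^+]
#'   - [NO_3^-] - [An_r] - [TPO_4]}
#' with all concentrations in mol m-3 of pore water. Al is deliberately
#' excluded; TPO4 enters with charge -1 (see vignette). A negative result is
#' a valid acidic state.
#'
#' @param solutes named numeric, g element m-2: `Ca`, `Mg`, `K`, `Na`,
#'   `NH4` (as g N), `NO3` (as g N), `TPO4` (as g P)
#' @param an_r residual anion pool, mol charge m-2
#' @param water_volume porewater volume, m3 m-2 (> 0)
#' @return alkalinity, mol_c m-3
#' @export
alkalinity <- function(solutes, an_r, water_volume) {
  if (water_volume <= 0) stop("water_volume must be > 0")
  M <- .const$M
  (2 * solutes[["Ca"]] / M[["Ca"]] + 2 * solutes[["Mg"]] / M[["Mg"]] +
     solutes[["K"]] / M[["K"]] + solutes[["Na"]] / M[["Na"]] +
     solutes[["NH4"]] / M[["N"]] - solutes[["NO3"]] / M[["N"]] -
     solutes[["TPO4"]] / M[["P"]] - an_r) / water_volume
}

#' Open-system carbonate equilibrium: pH and DIC speciation
#'
#' Solves the porewater charge balance
#' `ALK = [HCO3-] + 2[CO3 2-] + [OH-] - [H+]` for pH at fixed CO2 partial
#' pressure (open system against the soil-air reservoir), with temperature
#' corrected constants. The root is bracketed in pH 2..12 and refined by
#' safeguarded Newton iteration to a charge-balance residual below
#' 1e-10 mol m-3.
#'
#' @param alk alkalinity, mol_c m-3
#' @param pco2 CO2 partial pressure, atm (> 0)
#' @param temp_c temperature, degC
#' @return list `pH`, `h2co3` (CO2(aq) + H2CO3), `hco3`, `co3` (mol m-3)
#' @export
solve_carbonate_system <- function(alk, pco2, temp_c = 25) {
  if (pco2 <= 0) stop("pco2 must be > 0")
  K <- carbonate_constants(temp_c)
  a <- K$KH * pco2                         # [H2CO3*], mol/L
  alk_l <- alk / 1000
  f <- function(h) K$K1 * a / h * (1 + 2 * K$K2 / h) + K$Kw / h - h - alk_l
  lo <- 2; hi <- 12
  flo <- f(10^-lo); fhi <- f(10^-hi)
  if (flo > 0 && fhi > 0 || flo < 0 && fhi < 0)
    stop(sprintf(
      "no charge-balance root in pH [2,12] (alk=%g mol m-3, pCO2=%g atm)",
      alk, pco2))
  ph <- .solve_ph(alk_l, a, K, 0.5 * (lo + hi), lo, hi)
  h <- 10^-ph
  list(pH = ph,
       h2co3 = a * 1000,
       hco3 = K$K1 * a / h * 1000,
       co3 = K$K1 * K$K2 * a / h^2 * 1000)
}

# safeguarded Newton (on pH) for the open-system charge balance; mol/L units
.solve_ph <- function(alk_l, a, K, ph0, lo = 2, hi = 12) {
  ln10 <- log(10)
  ph <- min(max(ph0, lo), hi)
  for (it in 1:100) {
    h <- 10^-ph
    fv <- K$K1 * a / h + 2 * K$K1 * K$K2 * a / h^2 + K$Kw / h - h - alk_l
    if (abs(fv) < 1e-16) break
    dfdx <- ln10 * (K$K1 * a / h + 4 * K$K1 * K$K2 * a / h^2 +
                      K$Kw / h + h)
    step <- fv / dfdx
    ph_new <- ph - step
    if (!is.finite(ph_new) || ph_new <= lo || ph_new >= hi) {
      # bisection fallback keeps the bracket
      if (fv > 0) hi2 <- ph else lo2 <- ph
      ph_new <- if (fv > 0) 0.5 * (lo + ph) else 0.5 * (ph + hi)
    }
    if (fv > 0) hi <- ph else lo <- ph
    ph <- min(max(ph_new, lo + 1e-12), hi - 1e-12)
    if (abs(step) < 1e-13) break
  }
  ph
}

# Partition total inorganic carbon between soil-air CO2 and DIC at
# equilibrium with the porewater alkalinity. Single 1D solve in pH:
# carbonate alkalinity B = ALK - OH + H fixes [H2CO3*] at each pH, hence
# gas (ideal gas in the air-filled pore space) and aqueous C.
# Returns pH, pCO2 (atm), gas and aqueous C (g C m-2).
.equilibrate_ic <- function(ic_tot, alk, temp_c, water_volume, air_volume,
                            ph_hint = NA, K = NULL) {
  if (is.null(K)) K <- carbonate_constants(temp_c)
  tk <- temp_c + 273.15
  alk_l <- alk / 1000
  # moles gas per m2 at partial pressure p (atm): p * air_volume / (R T) * 1000
  gas_coef <- air_volume * 1000 / (.const$R_Lat * tk) * .const$M[["C"]]
  aq_coef <- water_volume * 1000 * .const$M[["C"]]  # g C per (mol/L DIC)
  if (ic_tot <= 0)
    return(list(pH = .solve_ph(alk_l, 1e-12 * K$KH, K, 7),
                pco2 = 1e-12, gas = 0, aq = 0))
  f <- function(ph) {
    h <- 10^-ph
    b <- alk_l - K$Kw / h + h                 # HCO3 + 2CO3, mol/L
    a <- b * h / (K$K1 * (1 + 2 * K$K2 / h))  # H2CO3*, mol/L
    if (a < 0) a <- 0
    dic <- a * (1 + K$K1 / h + K$K1 * K$K2 / h^2)
    p <- a / K$KH
    gas_coef * p + aq_coef * dic - ic_tot
  }
  lo <- 1; hi <- 13
  ph <- NA
  if (is.finite(ph_hint)) {
    # safeguarded Newton (numeric derivative) from the previous sub-step
    x <- min(max(ph_hint, lo + 0.01), hi - 0.01)
    for (it in 1:30) {
      fx <- f(x)
      if (abs(fx) < 1e-11 * max(ic_tot, 1e-3)) { ph <- x; break }
      if (fx > 0) lo <- max(lo, x) else hi <- min(hi, x)
      dfx <- (f(x + 1e-7) - fx) / 1e-7
      xn <- if (is.finite(dfx) && dfx < 0) x - fx / dfx else NA
      if (!is.finite(xn) || xn <= lo || xn >= hi) xn <- 0.5 * (lo + hi)
      if (abs(xn - x) < 1e-12) { ph <- xn; break }
      x <- xn
    }
    if (is.na(ph)) ph <- x
  } else {
    flo <- f(lo)
    if (flo < 0) { # extremely little C even at acid end; keep acid bound
      ph <- lo
    } else if (f(hi) > 0) ph <- hi
    else {
      for (it in 1:60) {                     # f is decreasing in pH
        mid <- 0.5 * (lo + hi)
        if (f(mid) > 0) lo <- mid else hi <- mid
        if (hi - lo < 1e-11) break
      }
      ph <- 0.5 * (lo + hi)
    }
  }
  h <- 10^-ph
  b <- alk_l - K$Kw / h + h
  a <- max(0, b * h / (K$K1 * (1 + 2 * K$K2 / h)))
  dic <- a * (1 + K$K1 / h + K$K1 * K$K2 / h^2)
  p <- max(a / K$KH, 1e-12)
  gas <- gas_coef * p
  aq <- aq_coef * dic
  # distribute any residual rounding so that gas + aq == ic_tot exactly
  tot <- gas + aq
  if (tot > 0) { gas <- gas * ic_tot / tot; aq <- aq * ic_tot / tot }
  list(pH = ph, pco2 = p, gas = gas, aq = aq)
}

#' Advance the inorganic-carbon pools over one sub-step
#'
#' Total inorganic carbon (soil-air CO2 + DIC) gains respiration and
#' rain-borne DIC, loses DIC leaching (proportional rule) and gaseous CO2
#' efflux through a Millington-Quirk effective diffusivity over half the
#' active-layer depth (advection folded into the same conductance). Gas and
#' aqueous phases are re-equilibrated against the solved pH each sub-step.
#'
#' @param carb list with `ic_tot` (g C m-2, gas + DIC); other entries of the
#'   carbonate state (`pH`, `pco2`, `gas`, `dic`) are recomputed
#' @param r_het,r_aut respiration inputs over the sub-step, g C m-2 (>= 0)
#' @param infil_m infiltration over the sub-step, m
#' @param leach_rate dimensionless leaching rate for the sub-step
#' @param atm_co2 atmospheric CO2, ppm
#' @param dt sub-step, s
#' @param alk porewater alkalinity, mol_c m-3
#' @param env list: `temp_c`, `s_eff`, `porosity`, `z_active`, `dic_rain`
#' @return list `carb` (with `ic_tot`, `gas`, `dic`, `pH`, `pco2`) and
#'   `fluxes` (`efflux`, `leach`, `rain_dic`, all g C m-2 per sub-step;
#'   efflux positive upward)
#' @export
step_inorganic_carbon <- function(carb, r_het, r_aut, infil_m, leach_rate,
                                  atm_co2, dt, alk, env) {
  if (r_het < 0 || r_aut < 0) stop("respiration inputs must be >= 0")
  por <- env$porosity
  vw <- max(env$s_eff * por * env$z_active, 1e-6)
  va <- max((1 - env$s_eff) * por * env$z_active, 1e-6)
  rain_dic <- infil_m * env$dic_rain
  ic <- carb$ic_tot + r_het + r_aut + rain_dic

  eq <- .equilibrate_ic(ic, alk, env$temp_c, vw, va,
                        ph_hint = if (!is.null(carb$pH)) carb$pH else NA,
                        K = env$K)

  # DIC leaching (capped at the aqueous pool)
  leach <- min(eq$aq * leach_rate, eq$aq)

  # gas-phase ventilation toward the atmospheric concentration
  tk <- env$temp_c + 273.15
  theta_a <- (1 - env$s_eff) * por
  d_eff <- .const$D0_CO2_air * theta_a^(10 / 3) / por^2
  cond <- d_eff / (env$z_active / 2)              # m s-1
  c_soil <- eq$gas / va                           # g C m-3 air
  c_atm <- atm_co2 * 1e-6 * 1000 / (.const$R_Lat * tk) * .const$M[["C"]]
  relax <- 1 - exp(-cond * dt / va)
  efflux <- (c_soil - c_atm) * va * relax         # g C m-2, signed
  # never extract more than the gas reservoir holds
  if (efflux > eq$gas) efflux <- eq$gas

  ic_new <- ic - leach - efflux
  eq2 <- .equilibrate_ic(ic_new, alk, env$temp_c, vw, va,
                         ph_hint = eq$pH, K = env$K)
  carb$ic_tot <- ic_new
  carb$gas <- eq2$gas
  carb$dic <- eq2$aq
  carb$pH <- eq2$pH
  carb$pco2 <- eq2$pco2
  list(carb = carb,
       fluxes = c(efflux = efflux, leach = leach, rain_dic = rain_dic))
}

#' Pedogenic carbonate precipitation / dissolution over one sub-step
#'
#' First-order kinetics in the calcite saturation state: with saturation
#' index `SI = log10([Ca2+][CO3 2-]/Ksp)`, precipitation (`W < 0`) removes C
#' at rate `k_p * (10^SI - 1)` when SI > 0; dissolution (`W > 0`) of
#' existing mineral proceeds at `k_p * (1 - 10^SI)` when SI < 0, capped by
#' the available mineral. Ca is removed or returned 1:1 with C; the caller
#' applies the Ca and inorganic-carbon updates.
#'
#' @param mineral_c pedogenic carbonate pool, g C m-2
#' @param ca_conc Ca2+ concentration, mol m-3
#' @param co3_conc CO3 2- concentration, mol m-3
#' @param temp_c temperature, degC
#' @param k_p rate constant, mol m-2 s-1
#' @param dt sub-step, s
#' @param ca_avail solution Ca available for precipitation, g Ca m-2
#' @return `W_CaMgCO3`, g C m-2 per sub-step (signed; > 0 dissolution)
#' @export
carbonate_mineral_step <- function(mineral_c, ca_conc, co3_conc, temp_c,
                                   k_p, dt, ca_avail = Inf, K = NULL) {
  if (is.null(K)) K <- carbonate_constants(temp_c)
  iap <- (ca_conc / 1000) * (co3_conc / 1000)
  if (iap <= 0) si <- -Inf else si <- log10(iap / K$Ksp)
  if (!is.finite(si) && si < 0 && mineral_c <= 0) return(0)
  omega <- 10^si
  if (omega > 1) {
    w <- -k_p * (omega - 1) * dt * .const$M[["C"]]   # g C m-2, precipitation
    max_prec <- ca_avail / .const$M[["Ca"]] * .const$M[["C"]]
    if (-w > max_prec) w <- -max_prec
  } else if (omega < 1 && mineral_c > 0) {
    w <- k_p * (1 - omega) * dt * .const$M[["C"]]    # dissolution
    if (w > mineral_c) w <- mineral_c
  } else w <- 0
  w
}

#' Calcite saturation ratio of the current porewater
#' @param ca_conc Ca2+ concentration, mol m-3
#' @param co3_conc CO3 2- concentration, mol m-3
#' @param temp_c temperature, degC
#' @return saturation ratio Omega (>= 0)
#' @export
calcite_omega <- function(ca_conc, co3_conc, temp_c = 25, K = NULL) {
  if (is.null(K)) K <- carbonate_constants(temp_c)
  max(0, (ca_conc / 1000) * (co3_conc / 1000) / K$Ksp)
}

#' Gaines-Thomas cation-exchange equilibrium
#'
#' Equilibrates solution Ca, Mg, K, Na with the exchange complex under
#' Gaines-Thomas selectivity: equivalent fractions satisfy
#' `E_i = k_i * a_i * lambda^(z_i)` for a scalar `lambda` fixed by the site
#' balance, where `k_i` is the per-cation affinity (Ca = 1 reference) and
#' `a_i` the solution activity. Combined with the per-cation mass balance
#' this reduces to one monotone scalar equation in `lambda`, solved by
#' bisection + Newton polish; per-element mass (solution + exchangeable) is
#' conserved exactly by construction. When `pH` is supplied, protons compete
#' for sites with affinity `h_affinity` (an unbuffered proton reservoir),
#' so exchangeable acidity responds to acidification; otherwise the acidity
#' fraction is held fixed.
#'
#' @param solutes named numeric g m-2 with at least `Ca`, `Mg`, `K`, `Na`
#' @param exchanger list: `cec` (mol_c m-2), `frac` (named equivalent
#'   fractions of Ca, Mg, K, Na), `acidity` (residual fraction)
#' @param water_volume porewater volume, m3 m-2
#' @param selectivity named affinities, default `Ca=1, Mg=1, K=0.2, Na=0.05`
#' @param pH porewater pH for proton competition, or `NA` to freeze acidity
#' @param h_affinity proton affinity on the exchanger
#' @return list `solutes` (updated), `exchanger` (updated)
#' @export
exchange_equilibrium <- function(solutes, exchanger, water_volume,
                                 selectivity = c(Ca = 1, Mg = 1, K = 0.2,
                                                 Na = 0.05),
                                 pH = NA, h_affinity = 4, lam0 = NULL) {
  if (exchanger$cec <= 0) stop("CEC must be > 0")
  ions <- c("Ca", "Mg", "K", "Na")
  z <- c(Ca = 2, Mg = 2, K = 1, Na = 1)
  cec <- exchanger$cec
  M <- .const$M[ions]
  tot <- solutes[ions] / M + exchanger$frac[ions] * cec / z  # mol m-2
  liters <- water_volume * 1000
  kaff <- selectivity[ions]
  with_h <- is.finite(pH)
  target <- if (with_h) 1 else 1 - exchanger$acidity
  if (target <= 0) {
    # exchanger fully acid and frozen: everything to solution
    exchanger$frac[ions] <- 0
    solutes[ions] <- tot * M
    return(list(solutes = solutes, exchanger = exchanger))
  }

  # E_i(lambda) = alpha_i tot_i / (1 + alpha_i cec / z_i),
  # alpha_i = k_i lambda^z_i / liters ; E_H = k_H [H+] lambda
  a_h <- if (with_h) 10^(-pH) else 0
  zv <- c(2, 2, 1, 1)
  kv <- as.numeric(kaff) / liters
  tv <- as.numeric(tot)
  czv <- cec / zv
  hk <- h_affinity * a_h
  # max attainable from finite cations
  emax <- sum(tv * zv) / cec
  if (!with_h && emax <= target) {
    e <- as.numeric(tot * z / cec)
    names(e) <- ions
    exchanger$frac[ions] <- e
    exchanger$acidity <- 1 - sum(e)
    solutes[ions] <- 0
    return(list(solutes = solutes, exchanger = exchanger))
  }
  # site balance is smooth and increasing in lambda: Newton in log-lambda
  # with a global bisection safeguard
  lo <- 1e-30; hi <- 1e30
  lam <- if (!is.null(lam0) && is.finite(lam0) && lam0 > 0) lam0 else 1
  for (it in 1:100) {
    al <- kv * lam^zv
    den <- 1 + al * czv
    ev <- al * tv / den
    fv <- sum(ev) - target                 # site-balance residual
    dv <- sum(al * tv * zv / den^2)        # d/d log(lam)
    if (with_h) { eh <- hk * lam; fv <- fv + eh; dv <- dv + eh }
    if (abs(fv) < 1e-12 * target) break
    if (fv < 0) lo <- max(lo, lam) else hi <- min(hi, lam)
    ln <- if (dv > 0) lam * exp(-fv / dv) else NA
    if (!is.finite(ln) || ln <= lo || ln >= hi) ln <- sqrt(lo * hi)
    if (abs(log(ln / lam)) < 1e-14) { lam <- ln; break }
    lam <- ln
  }
  al <- kv * lam^zv
  e <- stats::setNames(al * tv / (1 + al * czv), ions)
  e_h <- if (with_h) hk * lam else 0
  # normalise the residual bisection error onto the fractions
  sc <- target / (sum(e) + e_h)
  e <- e * sc
  exchanger$frac <- stats::setNames(as.numeric(e), ions)
  exchanger$acidity <- 1 - sum(e)   # with H competing: proton occupancy
  sol_mol <- tot - e * cec / z
  sol_mol[sol_mol < 0] <- 0
  solutes[ions] <- as.numeric(sol_mol * M)
  out <- list(solutes = solutes, exchanger = exchanger)
  attr(out, "lambda") <- lam
  out
}

#' Base saturation of the exchange complex
#'
#' @param exchanger list with `frac` (equivalent fractions of Ca, Mg, K, Na)
#' @return percentage of exchange sites occupied by base cations
#' @export
base_saturation <- function(exchanger) {
  100 * sum(exchanger$frac[c("Ca", "Mg", "K", "Na")])
}
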