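#' Environmental modifiers on biological rates
#'
#' Dimensionless multipliers in \[0, 1\]: a Q10 temperature response
#' referenced at `t_ref` (capped at 1), a quadratic soil-moisture optimum at
#' `fw_opt`, and a Gaussian pH response centred on `fph_mu`.
#'
#' @param soil_temp soil temperature, degC
#' @param s_eff effective saturation, 0..1
#' @param pH porewater pH
#' @param params biogeochemical parameter list (see [default_config()])
#' @return named numeric `f_T`, `f_W`, `f_pH`
#' @export
env_modifiers <- function(soil_temp, s_eff, pH, params) {
  soil_temp <- unname(soil_temp); s_eff <- unname(s_eff); pH <- unname(pH)
  f_t <- min(1, params$q10^((soil_temp - params$t_ref) / 10))
  f_w <- max(0, 1 - ((s_eff - params$fw_opt) / params$fw_opt)^2)
  f_ph <- exp(-0.5 * ((pH - params$fph_mu) / params$fph_sigma)^2)
  c(f_T = f_t, f_W = min(1, f_w), f_pH = f_ph)
}

#' Proportional leaching flux
#'
#' Leaching is proportional to the dissolved pool and the per-step leaching
#' rate (bottom leakage / water volume), capped at the pool mass.
#'
#' @param pool_mass dissolved pool, g m-2 (>= 0)
#' @param leach_rate dimensionless per-step rate (>= 0)
#' @return leached mass, g m-2 per step
#' @export
leach_flux <- function(pool_mass, leach_rate) {
  stopifnot(pool_mass >= 0, leach_rate >= 0)
  min(pool_mass * leach_rate, pool_mass)
}

# scale a set of outfluxes so their sum never exceeds the source pool
.cap_out <- function(pool, ...) {
  fl <- c(...)
  s <- sum(fl)
  if (s > pool && s > 0) fl <- fl * (pool / s)
  fl
}

#' Daily microbially explicit SOC decomposition step
#'
#' MEND-style pool structure: particulate (lignin- and cellulose-like),
#' mineral-associated and dissolved organic C; bacteria, saprotrophic fungi,
#' arbuscular and ectomycorrhiza, a shared extracellular enzyme pool and
#' earthworms; eight first-order litter pools. Depolymerisation fluxes are
#' Michaelis-Menten in substrate and linear in enzymes, all scaled by
#' `f_T * f_W * f_pH`. A saturating (Langmuir-style) fraction of decomposed
#' POC routes to MAOC. Microbes take up DOC with fixed growth yield, produce
#' enzymes and respire maintenance; earthworms graze POC. Carbon use
#' efficiency is reported as an emergent diagnostic. If any pool would go
#' negative the step halves its internal time step up to 4 times before
#' raising an error.
#'
#' @param pools list with `soc` and `litter` named vectors (g C m-2)
#' @param env modifiers from [env_modifiers()]
#' @param litter_in named additions to the litter pools, g C m-2 d-1
#' @param params biogeochemical parameters
#' @param myc_in plant carbon supplied to mycorrhizae, g C m-2 d-1
#' @param dt days (default 1)
#' @return list `pools`, `r_het` (components and total, g C m-2 d-1),
#'   `fluxes` (decomposition fluxes F2l, F2c, F3, SOM C decomposition,
#'   litter C decomposition), `cue`
#' @export
step_soc <- function(pools, env, litter_in = NULL, params, myc_in = 0,
                     dt = 1) {
  for (halving in 0:4) {
    n_sub <- 2^halving
    res <- try(.step_soc_once(pools, env, litter_in, params, myc_in,
                              dt, n_sub), silent = TRUE)
    if (!inherits(res, "try-error")) return(res)
    if (halving == 4) stop(attr(res, "condition")$message)
  }
}

.step_soc_once <- function(pools, env, litter_in, params, myc_in, dt,
                           n_sub) {
  soc <- pools$soc; lit <- pools$litter
  f <- env[["f_T"]] * env[["f_W"]] * env[["f_pH"]]
  ftw <- env[["f_T"]] * env[["f_W"]]
  h <- dt / n_sub
  r_mic <- r_lit <- r_ew <- growth_cum <- 0
  f2l_cum <- f2c_cum <- f3_cum <- som_dec <- lit_dec <- 0
  if (!is.null(litter_in)) {
    lit[names(litter_in)] <- lit[names(litter_in)] +
      unlist(litter_in) * dt
  }
  for (s in seq_len(n_sub)) {
    # litter decomposition, linear kinetics
    kl <- params$lit_k[c("leaf_ag", "wood_ag", "root_bg", "fine_bg")]
    kl8 <- c(kl, kl)[c(1, 2, 3, 4, 1, 2, 3, 4)]
    names(kl8) <- names(lit)
    d_lit <- kl8 * lit * ftw * h
    lit_resp <- sum(d_lit) * params$lit_resp_frac
    to_doc_l <- sum(d_lit) * params$lit_doc_frac
    rest <- sum(d_lit) - lit_resp - to_doc_l
    to_pocl <- rest * params$lit_lig_frac
    to_pocc <- rest - to_pocl

    mb <- soc[["bact"]] + soc[["fungi"]]
    enz <- soc[["enz"]]
    f2l <- params$v_lig * enz * soc[["poc_l"]] /
      (params$k_lig + soc[["poc_l"]]) * f * h
    f2c <- params$v_cel * enz * soc[["poc_c"]] /
      (params$k_cel + soc[["poc_c"]]) * f * h
    f3 <- params$v_mao * enz * soc[["maoc"]] /
      (params$k_mao + soc[["maoc"]]) * f * h
    f2l <- min(f2l, soc[["poc_l"]]); f2c <- min(f2c, soc[["poc_c"]])
    f3 <- min(f3, soc[["maoc"]])
    # POC-derived C routes to MAOC with reactive-surface saturation
    sat <- max(0, 1 - soc[["maoc"]] / params$maoc_max)
    to_maoc <- (f2l + f2c) * params$f_mao * sat
    to_doc <- (f2l + f2c) - to_maoc + f3

    upt <- params$v_upt * mb * soc[["doc"]] /
      (params$k_doc + soc[["doc"]]) * f * h
    upt <- min(upt, soc[["doc"]] + to_doc + to_doc_l)
    growth <- params$yield * upt
    r_growth <- (1 - params$yield) * upt
    enz_prod <- params$enz_frac * growth
    maint <- params$mic_maint * mb * ftw * h
    maint <- min(maint, mb * 0.5)
    mort <- params$mic_mort * mb * h
    myc <- soc[["am"]] + soc[["em"]]
    myc_maint <- params$mic_maint * myc * ftw * h
    myc_mort <- params$mic_mort * myc * h
    enz_turn <- params$enz_turn * enz * h

    gr <- params$ew_graze * (soc[["poc_l"]] + soc[["poc_c"]]) * ftw * h
    assim <- params$ew_assim * gr
    casts <- gr - assim                      # returned to cellulose POC
    ew_growth <- params$ew_cue * assim
    r_worm <- assim - ew_growth
    ew_mort <- params$ew_mort * soc[["worm"]] * h

    frac_l <- soc[["poc_l"]] / max(soc[["poc_l"]] + soc[["poc_c"]], 1e-12)
    soc[["poc_l"]] <- soc[["poc_l"]] + to_pocl - f2l - gr * frac_l
    soc[["poc_c"]] <- soc[["poc_c"]] + to_pocc - f2c - gr * (1 - frac_l) +
      casts + 0.25 * mort + ew_mort
    soc[["maoc"]] <- soc[["maoc"]] + to_maoc + 0.25 * mort - f3
    soc[["doc"]] <- soc[["doc"]] + to_doc + to_doc_l + 0.5 * mort +
      enz_turn + myc_mort - upt
    net_mb <- growth - enz_prod - maint - mort
    soc[["bact"]] <- soc[["bact"]] +
      net_mb * soc[["bact"]] / max(mb, 1e-12)
    soc[["fungi"]] <- soc[["fungi"]] +
      net_mb * soc[["fungi"]] / max(mb, 1e-12)
    myc_add <- myc_in * h                    # g C over the sub-interval
    if (myc > 0) {
      d_myc <- myc_add - myc_maint - myc_mort
      soc[["am"]] <- soc[["am"]] + d_myc * soc[["am"]] / myc
      soc[["em"]] <- soc[["em"]] + d_myc * soc[["em"]] / myc
    } else soc[["am"]] <- soc[["am"]] + myc_add
    soc[["enz"]] <- soc[["enz"]] + enz_prod - enz_turn
    soc[["worm"]] <- soc[["worm"]] + ew_growth - ew_mort
    lit <- lit - d_lit

    if (any(soc < -1e-12) || any(lit < -1e-12))
      stop("SOC pool driven negative")
    soc[soc < 0] <- 0; lit[lit < 0] <- 0

    r_mic <- r_mic + r_growth + maint + myc_maint
    r_lit <- r_lit + lit_resp
    r_ew <- r_ew + r_worm
    growth_cum <- growth_cum + growth
    f2l_cum <- f2l_cum + f2l; f2c_cum <- f2c_cum + f2c
    f3_cum <- f3_cum + f3
    som_dec <- som_dec + f2l + f2c + f3
    lit_dec <- lit_dec + sum(d_lit)
  }
  r_het <- r_mic + r_lit + r_ew
  cue <- if (growth_cum + r_mic > 0) growth_cum / (growth_cum + r_mic)
         else NA_real_
  list(pools = list(soc = soc, litter = lit),
       r_het = c(microbe = r_mic, litter = r_lit, earthworm = r_ew,
                 total = r_het),
       fluxes = c(F2l = f2l_cum, F2c = f2c_cum, F3 = f3_cum,
                  som_decomp = som_dec, litter_decomp = lit_dec),
       cue = cue)
}

#' Daily mineral nitrogen step
#'
#' NH4 and NO3 balances: SOM-decay mineral input, net microbial
#' immobilisation/mineralisation closing microbial stoichiometry,
#' nitrification, NH3 volatilisation (increasing with pH), denitrification
#' under wet (near-anaerobic) conditions, proportional leaching, plant
#' uptake, and external inputs. Organic leaching exports a fixed fraction
#' of decomposed organic N.
#'
#' @param pools list: `org_n`, `nh4`, `no3` (g N m-2)
#' @param env modifiers plus `pH` and `s_eff` entries in `ctx`
#' @param ctx list: `pH`, `s_eff`, `som_n_flux` (organic N released by SOM +
#'   litter decomposition, g N m-2 d-1), `mic_n_demand` (g N m-2 d-1),
#'   `leach_rate` (d-1)
#' @param uptake named `nh4`, `no3` plant uptake, g N m-2 d-1 (already
#'   demand-limited; capped here at availability)
#' @param ext_n external N input (deposition + fertiliser), g N m-2 d-1
#' @param params biogeochemical parameters
#' @param dt days
#' @return list `pools`, `fluxes`
#' @export
step_nitrogen <- function(pools, env, ctx, uptake = c(nh4 = 0, no3 = 0),
                          ext_n = 0, params, dt = 1) {
  nh4 <- pools$nh4; no3 <- pools$no3; org <- pools$org_n
  ftw <- env[["f_T"]] * env[["f_W"]]
  nflux <- min(ctx$som_n_flux * dt, org)
  org_leach <- nflux * params$f_org_lea
  min_in <- (nflux - org_leach) * params$lambda_n
  recycled <- nflux - org_leach - min_in          # stays organic
  org <- org - org_leach - min_in

  # net immobilisation when microbial demand exceeds decomposition supply
  demand <- max(0, ctx$mic_n_demand * dt)
  supply <- min_in
  imm <- 0
  if (demand > supply) imm <- min(0.5 * nh4, demand - supply)
  nh4 <- nh4 + min_in - imm
  org <- org + imm + 0                             # immobilised N to biomass

  nit <- params$k_nit * nh4 * ftw * dt
  f_vol <- 1 / (1 + 10^(9.25 - ctx$pH))            # NH3 fraction rises w/ pH
  vol <- params$k_vol * nh4 * f_vol * dt
  up_nh4 <- uptake[["nh4"]] * dt
  lk_nh4 <- leach_flux(nh4, ctx$leach_rate * dt)
  out <- .cap_out(nh4, nit = nit, vol = vol, up = up_nh4, lk = lk_nh4)
  nh4 <- nh4 - sum(out) + ext_n * dt
  nit <- out[["nit"]]; vol <- out[["vol"]]
  up_nh4 <- out[["up"]]; lk_nh4 <- out[["lk"]]

  f_an <- max(0, (ctx$s_eff - 0.7) / 0.3)^2        # anaerobic ramp
  den <- params$k_den * no3 * f_an * dt
  up_no3 <- uptake[["no3"]] * dt
  lk_no3 <- leach_flux(no3, ctx$leach_rate * dt)
  out3 <- .cap_out(no3, den = den, up = up_no3, lk = lk_no3)
  no3 <- no3 + nit - sum(out3)
  list(pools = list(org_n = org, nh4 = nh4, no3 = no3),
       fluxes = c(mineralisation = min_in, immobilisation = imm,
                  nitrification = nit, volatilisation = vol,
                  denitrification = out3[["den"]],
                  leach_nh4 = lk_nh4, leach_no3 = out3[["lk"]],
                  uptake_nh4 = up_nh4, uptake_no3 = out3[["up"]],
                  org_leach = org_leach, ext_in = ext_n * dt,
                  recycled = recycled))
}

#' Daily mineral phosphorus step
#'
#' TPO4 (undifferentiated orthophosphate species) balance: SOM-decay input,
#' microbial immobilisation, plant uptake, leaching, first-order secondary
#' fixation, slow primary (parent-material) release, feedstock-derived P
#' and external inputs.
#'
#' @param pools list: `org_p`, `tpo4`, `primary`, `secondary` (g P m-2)
#' @param ew_p feedstock P release, g P m-2 d-1 (>= 0)
#' @param env modifiers
#' @param ctx list: `som_p_flux`, `mic_p_demand`, `leach_rate`
#' @param uptake plant TPO4 uptake, g P m-2 d-1
#' @param ext_p external P input, g P m-2 d-1
#' @param params biogeochemical parameters
#' @param dt days
#' @return list `pools`, `fluxes`
#' @export
step_phosphorus <- function(pools, ew_p = 0, env, ctx, uptake = 0,
                            ext_p = 0, params, dt = 1) {
  stopifnot(ew_p >= 0)
  tp <- pools$tpo4; org <- pools$org_p
  pflux <- min(ctx$som_p_flux * dt, org)
  org_leach <- pflux * params$f_org_lea
  min_in <- (pflux - org_leach) * params$lambda_p
  org <- org - org_leach - min_in
  demand <- max(0, ctx$mic_p_demand * dt)
  imm <- if (demand > min_in) min(0.5 * tp, demand - min_in) else 0
  org <- org + imm
  pri <- params$k_pri * pools$primary * dt
  sec <- params$k_sec_p * tp * dt
  up <- uptake * dt
  lk <- leach_flux(tp, ctx$leach_rate * dt)
  out <- .cap_out(tp + min_in - imm, sec = sec, up = up, lk = lk)
  tp <- tp + min_in - imm + pri + ew_p * dt + ext_p * dt - sum(out)
  list(pools = list(org_p = org, tpo4 = tp,
                    primary = pools$primary - pri,
                    secondary = pools$secondary + out[["sec"]]),
       fluxes = c(mineralisation = min_in, immobilisation = imm,
                  primary_release = pri, secondary_fix = out[["sec"]],
                  uptake = out[["up"]], leach = out[["lk"]],
                  org_leach = org_leach, ew_p = ew_p * dt,
                  ext_in = ext_p * dt))
}

#' Daily base-cation solution step (K, Ca, Mg)
#'
#' Solution pools gain the litter-decay release, the DOC-route SOM release
#' scaled by the C:X ratio of SOM, slow primary (parent material) release,
#' feedstock weathering and external inputs; they lose first-order secondary
#' fixation, plant uptake and proportional leaching. Transfers to the
#' exchange complex are handled by [exchange_equilibrium()] at the chemistry
#' sub-step and are not part of this daily balance.
#'
#' @param pools list of named vectors over `c("Ca","Mg","K")`: `solution`,
#'   `org`, `primary`, `secondary` (g X m-2)
#' @param ew_x named feedstock release, g X m-2 d-1 (>= 0)
#' @param ctx list: `som_c_decomp` (SOM C decomposition flux, g C m-2 d-1),
#'   `doc_fluxes` (F2l+F2c+F3 sum), `leach_rate`
#' @param uptake named plant uptake, g X m-2 d-1
#' @param ext_x named external inputs, g X m-2 d-1
#' @param params biogeochemical parameters (`cx_som`, `k_fix`, `k_pri`,
#'   `lambda_x`, `f_d`)
#' @param dt days
#' @return list `pools`, `fluxes` (matrices element x flux)
#' @export
step_cations <- function(pools, ew_x = c(Ca = 0, Mg = 0, K = 0), ctx,
                         uptake = c(Ca = 0, Mg = 0, K = 0),
                         ext_x = c(Ca = 0, Mg = 0, K = 0), params, dt = 1) {
  stopifnot(all(ew_x >= 0))
  el <- c("Ca", "Mg", "K")
  cx <- params$cx_som[el]
  if (any(cx <= 0)) stop("C:X ratio of SOM must be > 0")
  fl <- matrix(0, length(el), 7,
               dimnames = list(el, c("som_release", "doc_release",
                                     "primary_release", "secondary_fix",
                                     "uptake", "leach", "ext_in")))
  sol <- pools$solution[el]; org <- pools$org[el]
  pri <- pools$primary[el]; sec <- pools$secondary[el]
  for (x in el) {
    som_rel <- min(params$lambda_x * ctx$som_c_decomp / cx[[x]] * dt,
                   org[[x]])
    doc_rel <- min(params$f_d * ctx$doc_fluxes / cx[[x]] * dt,
                   org[[x]] - som_rel)
    p_rel <- params$k_pri * pri[[x]] * dt
    fix <- params$k_fix[[x]] * sol[[x]] * dt
    up <- uptake[[x]] * dt
    lk <- leach_flux(sol[[x]], ctx$leach_rate * dt)
    out <- .cap_out(sol[[x]], fix = fix, up = up, lk = lk)
    sol[[x]] <- sol[[x]] + som_rel + doc_rel + p_rel + ew_x[[x]] * dt +
      ext_x[[x]] * dt - sum(out)
    org[[x]] <- org[[x]] - som_rel - doc_rel
    pri[[x]] <- pri[[x]] - p_rel
    sec[[x]] <- sec[[x]] + out[["fix"]]
    fl[x, ] <- c(som_rel, doc_rel, p_rel, out[["fix"]], out[["up"]],
                 out[["lk"]], ext_x[[x]] * dt)
  }
  list(pools = list(solution = sol, org = org, primary = pri,
                    secondary = sec),
       fluxes = fl)
}

#' Daily Si, Na, Al and residual-anion step
#'
#' Si follows the cation template without an exchangeable pool; Na has
#' passive uptake only; Al has no uptake; the residual anion pool (mol
#' charge m-2) is input - leaching - passive uptake.
#'
#' @param pools list: `si` (solution, org, primary, secondary), `na`, `al`
#'   (g m-2), `an_r` (mol_c m-2)
#' @param ew named `Si`, `Na`, `Al` feedstock release, g m-2 d-1
#' @param ctx list: `som_c_decomp`, `doc_fluxes`, `leach_rate`
#' @param passive named passive uptake: `Si`, `Na` (g m-2 d-1), `An`
#'   (mol_c m-2 d-1)
#' @param ext named external inputs `Si`, `Na`, `Al` (g m-2 d-1), `An`
#'   (mol_c m-2 d-1)
#' @param params biogeochemical parameters
#' @param dt days
#' @return list `pools`, `fluxes`
#' @export
step_si_na_al_anions <- function(pools, ew = c(Si = 0, Na = 0, Al = 0),
                                 ctx, passive = c(Si = 0, Na = 0, An = 0),
                                 ext = c(Si = 0, Na = 0, Al = 0, An = 0),
                                 params, dt = 1) {
  stopifnot(all(ew >= 0))
  si <- pools$si
  som_rel <- min(params$lambda_x * ctx$som_c_decomp /
                   params$cx_som[["Si"]] * dt, si$org)
  doc_rel <- min(params$f_d * ctx$doc_fluxes / params$cx_som[["Si"]] * dt,
                 si$org - som_rel)
  p_rel <- params$k_pri * si$primary * dt
  fix <- params$k_fix[["Si"]] * si$solution * dt
  up_si <- passive[["Si"]] * dt
  lk_si <- leach_flux(si$solution, ctx$leach_rate * dt)
  out <- .cap_out(si$solution, fix = fix, up = up_si, lk = lk_si)
  si$solution <- si$solution + som_rel + doc_rel + p_rel +
    ew[["Si"]] * dt + ext[["Si"]] * dt - sum(out)
  si$org <- si$org - som_rel - doc_rel
  si$primary <- si$primary - p_rel
  si$secondary <- si$secondary + out[["fix"]]

  na <- pools$na
  lk_na <- leach_flux(na, ctx$leach_rate * dt)
  up_na <- passive[["Na"]] * dt
  out_na <- .cap_out(na, lk = lk_na, up = up_na)
  na <- na + ew[["Na"]] * dt + ext[["Na"]] * dt - sum(out_na)

  al <- pools$al
  lk_al <- leach_flux(al, ctx$leach_rate * dt)
  al <- al + ew[["Al"]] * dt + ext[["Al"]] * dt - lk_al

  an <- pools$an_r
  lk_an <- leach_flux(an, ctx$leach_rate * dt)
  up_an <- passive[["An"]] * dt
  out_an <- .cap_out(an, lk = lk_an, up = up_an)
  an <- an + ext[["An"]] * dt - sum(out_an)

  list(pools = list(si = si, na = na, al = al, an_r = an),
       fluxes = c(si_som = som_rel, si_doc = doc_rel, si_primary = p_rel,
                  si_fix = out[["fix"]], si_uptake = out[["up"]],
                  si_leach = out[["lk"]],
                  na_leach = out_na[["lk"]], na_uptake = out_na[["up"]],
                  al_leach = lk_al,
                  an_leach = out_an[["lk"]], an_uptake = out_an[["up"]]))
}
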