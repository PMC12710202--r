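.plant_elements <- c("N", "P", "K", "Ca", "Mg", "Si", "Na")

#' Create a plant state
#'
#' Seven carbon pools (living leaves, dead standing leaves, sapwood,
#' heartwood, fine roots, non-structural carbohydrates, reproductive
#' tissues) plus per-element structural and reserve contents.
#'
#' @param c_pools named numeric g C m-2 (leaf, dead_leaf, sapwood,
#'   heartwood, root, nsc, repro)
#' @param traits trait list from [pft_traits()]
#' @param reserve_fill initial reserves as a fraction of capacity
#' @return a `plant_state` list
#' @export
new_plant_state <- function(c_pools, traits, reserve_fill = 0.5) {
  struct_c <- sum(c_pools) - c_pools[["nsc"]]
  st <- list(
    c = c_pools,
    struct = traits$target_stoich * struct_c,
    reserve = traits$max_reserve * reserve_fill,
    alive = TRUE, starved = FALSE)
  class(st) <- "plant_state"
  st
}

#' Daily gross primary production (light-use-efficiency surrogate)
#'
#' `GPP = LUE * APAR * f_T * water_stress * nutrient_stress` with
#' `APAR = 0.45 * SW * (1 - exp(-0.5 * lai))` (MJ m-2 d-1 of absorbed PAR).
#' Zero outside the crop phenology window.
#'
#' @param sw_mj daily shortwave total, MJ m-2 d-1
#' @param temp_c daily mean air temperature, degC
#' @param lai leaf area index (>= 0)
#' @param water_stress,nutrient_stress multipliers in \[0, 1\]
#' @param traits trait list
#' @param doy day of year (1..365)
#' @return GPP, g C m-2 d-1
#' @export
daily_photosynthesis <- function(sw_mj, temp_c, lai, water_stress,
                                 nutrient_stress, traits, doy = 180) {
  stopifnot(lai >= 0, water_stress >= 0, water_stress <= 1,
            nutrient_stress >= 0, nutrient_stress <= 1)
  if (is.finite(traits$plant_doy) &&
      (doy < traits$plant_doy || doy > traits$harvest_doy))
    return(0)
  apar <- 0.45 * sw_mj * (1 - exp(-0.5 * lai))
  f_t <- min(1, max(0, (temp_c - 2) / 16))       # ramp 2..18 degC
  max(0, traits$lue * apar * f_t * water_stress * nutrient_stress)
}

#' Allocate assimilate and compute autotrophic respiration
#'
#' Maintenance respiration per live tissue (`coeff * mass * f_T`, Q10 = 2
#' referenced at 20 degC) is paid from current assimilation, then from the
#' NSC pool; when NSC is exhausted growth stops, unpaid maintenance is
#' forgone and a starvation flag is set. Remaining assimilate is allocated
#' by the trait fractions, with a growth-respiration fraction charged on
#' structural growth. `r_aut` is maintenance paid plus growth respiration.
#'
#' @param plant a `plant_state`
#' @param gpp g C m-2 d-1
#' @param soil_temp degC (drives root maintenance; canopy uses the same
#'   temperature in this lumped scheme)
#' @param traits trait list
#' @param dt days
#' @return list `plant`, `r_aut` (named: total, root, canopy, growth),
#'   `growth` (structural growth per tissue, g C m-2)
#' @export
allocate_respire <- function(plant, gpp, soil_temp, traits, dt = 1) {
  f_t <- 2^((soil_temp - 20) / 10)
  cp <- plant$c
  rm <- c(leaf = traits$maint_resp[["leaf"]] * cp[["leaf"]],
          sapwood = traits$maint_resp[["sapwood"]] * cp[["sapwood"]],
          root = traits$maint_resp[["root"]] * cp[["root"]]) * f_t * dt
  avail <- gpp * dt
  rm_due <- sum(rm)
  paid_gpp <- min(avail, rm_due)
  deficit <- rm_due - paid_gpp
  paid_nsc <- min(cp[["nsc"]], deficit)
  cp[["nsc"]] <- cp[["nsc"]] - paid_nsc
  rm_paid <- paid_gpp + paid_nsc
  plant$starved <- rm_paid < rm_due - 1e-12
  # unpaid maintenance scales down each tissue's share
  scale_rm <- if (rm_due > 0) rm_paid / rm_due else 0
  remaining <- avail - paid_gpp

  al <- traits$alloc
  growth <- c(leaf = 0, sapwood = 0, root = 0, repro = 0)
  g_resp <- 0
  if (remaining > 0 && !plant$starved) {
    to_nsc <- remaining * al[["nsc"]]
    cp[["nsc"]] <- cp[["nsc"]] + to_nsc
    struct_alloc <- remaining - to_nsc
    gf <- traits$growth_resp_frac
    g_resp <- struct_alloc * gf
    net <- struct_alloc * (1 - gf)
    w <- al[c("leaf", "sapwood", "root", "repro")]
    w <- w / sum(w)
    growth <- net * w
    names(growth) <- c("leaf", "sapwood", "root", "repro")
    cp[["leaf"]] <- cp[["leaf"]] + growth[["leaf"]]
    cp[["sapwood"]] <- cp[["sapwood"]] + growth[["sapwood"]]
    cp[["root"]] <- cp[["root"]] + growth[["root"]]
    cp[["repro"]] <- cp[["repro"]] + growth[["repro"]]
  }
  plant$c <- cp
  root_share <- rm[["root"]] * scale_rm +
    g_resp * if (sum(traits$alloc[c("leaf", "sapwood", "root",
                                    "repro")]) > 0)
      traits$alloc[["root"]] / sum(traits$alloc[c("leaf", "sapwood",
                                                  "root", "repro")])
    else 0
  r_aut <- rm_paid + g_resp
  list(plant = plant,
       r_aut = c(total = r_aut, root = root_share,
                 canopy = r_aut - root_share, growth = g_resp),
       growth = growth)
}

#' Stoichiometry-limited plant nutrient uptake
#'
#' Passive uptake follows the transpiration stream at the solution
#' concentration; active uptake is Michaelis-Menten in concentration,
#' scaled by fine-root mass and relative reserve deficit. Total uptake per
#' element is multiplied by a suppression factor that falls linearly from 1
#' to 0 as the reserve fills from 80\% to 100\% of capacity, and is capped
#' by both the available solution mass and the remaining reserve capacity.
#' Na is passive-only; Al is never taken up; N draws on NH4 and NO3 in
#' proportion to availability. N fixers top up to half of the unmet N
#' demand (counted as an external input by the caller).
#'
#' @param plant a `plant_state`
#' @param solutes named g m-2 (Ca, Mg, K, Na, NH4, NO3, TPO4, Si)
#' @param transp_m transpiration over the step, m (>= 0)
#' @param water_volume porewater volume, m3 m-2
#' @param traits trait list
#' @param dt days
#' @return list `plant`, `uptake` (named g element m-2: N, P, K, Ca, Mg,
#'   Si, Na), `uptake_nh4`, `uptake_no3`, `fixation`
#' @export
nutrient_uptake <- function(plant, solutes, transp_m, water_volume, traits,
                            dt = 1) {
  stopifnot(transp_m >= 0)
  res <- plant$reserve
  mx <- traits$max_reserve
  root <- plant$c[["root"]]
  vw <- max(water_volume, 1e-9)
  up <- stats::setNames(numeric(length(.plant_elements)), .plant_elements)
  M <- .const$M
  avail <- c(N = solutes[["NH4"]] + solutes[["NO3"]], P = solutes[["TPO4"]],
             K = solutes[["K"]], Ca = solutes[["Ca"]], Mg = solutes[["Mg"]],
             Si = solutes[["Si"]], Na = solutes[["Na"]])
  molm <- c(N = M[["N"]], P = M[["P"]], K = M[["K"]], Ca = M[["Ca"]],
            Mg = M[["Mg"]], Si = M[["Si"]], Na = M[["Na"]])
  for (e in .plant_elements) {
    fill <- if (mx[[e]] > 0) res[[e]] / mx[[e]] else 1
    supp <- if (fill >= 1) 0 else if (fill <= 0.8) 1 else (1 - fill) / 0.2
    conc_g <- avail[[e]] / vw                       # g m-3
    pas <- transp_m * conc_g
    act <- 0
    if (e != "Na" && traits$uptake_vmax > 0) {
      cmol <- conc_g / molm[[e]]                    # mol m-3
      demand <- max(0, 1 - fill)
      act <- traits$uptake_vmax * root * cmol / (traits$uptake_km + cmol) *
        demand * dt
    }
    u <- (pas + act) * supp
    u <- min(u, avail[[e]], max(0, mx[[e]] - res[[e]]))
    up[[e]] <- u
    res[[e]] <- res[[e]] + u
  }
  # N split between NH4 and NO3 by availability
  nh4 <- solutes[["NH4"]]; no3 <- solutes[["NO3"]]
  wn <- if (nh4 + no3 > 0) nh4 / (nh4 + no3) else 0
  fix <- 0
  if (isTRUE(traits$n_fixer)) {
    deficit <- max(0, 0.8 * mx[["N"]] - res[["N"]])
    fix <- 0.5 * deficit * min(1, root / 50) * dt
    fix <- min(fix, mx[["N"]] - res[["N"]])
    res[["N"]] <- res[["N"]] + fix
  }
  plant$reserve <- res
  list(plant = plant, uptake = up,
       uptake_nh4 = up[["N"]] * wn, uptake_no3 = up[["N"]] * (1 - wn),
       fixation = fix)
}

#' Tissue turnover, litter production and harvest
#'
#' First-order turnover routes living leaves to standing dead, standing
#' dead and sapwood to above-ground litter, fine roots to below-ground
#' litter; the lignin-like share of each flux goes to the structural
#' partner pool. On `harvest = TRUE`, the export fraction of above-ground
#' carbon (and its elements, proportional to C) leaves the system, the
#' residue falls to above-ground litter, roots and NSC go to below-ground
#' litter, and the same fraction of the reserves is exported.
#'
#' @param plant a `plant_state`
#' @param traits trait list
#' @param dt days
#' @param harvest logical: apply the harvest event this step
#' @return list `plant`, `litter_c` (named 8-pool litter C input),
#'   `litter_el` (named element content of the litter), `export_c`,
#'   `export_el`
#' @export
litterfall <- function(plant, traits, dt = 1, harvest = FALSE) {
  hf <- traits$harvest_export_frac
  if (harvest && (hf < 0 || hf > 1))
    stop("harvest export fraction must be in [0, 1]")
  cp <- plant$c
  tv <- traits$turnover
  lit <- c(leaf_ag = 0, wood_ag = 0, root_bg = 0, fine_bg = 0,
           leaf_ag2 = 0, wood_ag2 = 0, root_bg2 = 0, fine_bg2 = 0)
  lig <- 0.3

  struct_c0 <- sum(cp) - cp[["nsc"]]
  to_dead <- tv[["leaf"]] * cp[["leaf"]] * dt
  dead_fall <- tv[["dead_leaf"]] * cp[["dead_leaf"]] * dt
  wood_fall <- tv[["sapwood"]] * cp[["sapwood"]] * dt
  root_fall <- tv[["root"]] * cp[["root"]] * dt
  repro_fall <- tv[["repro"]] * cp[["repro"]] * dt
  cp[["leaf"]] <- cp[["leaf"]] - to_dead
  cp[["dead_leaf"]] <- cp[["dead_leaf"]] + to_dead - dead_fall
  cp[["sapwood"]] <- cp[["sapwood"]] - wood_fall
  cp[["root"]] <- cp[["root"]] - root_fall
  cp[["repro"]] <- cp[["repro"]] - repro_fall
  lit[["leaf_ag"]] <- (dead_fall + repro_fall) * (1 - lig)
  lit[["leaf_ag2"]] <- (dead_fall + repro_fall) * lig
  lit[["wood_ag"]] <- wood_fall * (1 - lig)
  lit[["wood_ag2"]] <- wood_fall * lig
  lit[["fine_bg"]] <- root_fall * (1 - lig)
  lit[["fine_bg2"]] <- root_fall * lig
  lit_c <- dead_fall + wood_fall + root_fall + repro_fall
  export_c <- 0

  if (harvest) {
    ag <- cp[["leaf"]] + cp[["dead_leaf"]] + cp[["sapwood"]] +
      cp[["repro"]] + cp[["heartwood"]]
    export_c <- ag * hf
    residue <- ag * (1 - hf)
    lit[["leaf_ag"]] <- lit[["leaf_ag"]] + residue * (1 - lig)
    lit[["leaf_ag2"]] <- lit[["leaf_ag2"]] + residue * lig
    bg <- cp[["root"]] + cp[["nsc"]]
    lit[["root_bg"]] <- lit[["root_bg"]] + bg * (1 - lig)
    lit[["root_bg2"]] <- lit[["root_bg2"]] + bg * lig
    lit_c <- lit_c + residue + bg
    cp[c("leaf", "dead_leaf", "sapwood", "heartwood", "root", "nsc",
         "repro")] <- 0
    plant$alive <- FALSE
  }

  # elements follow the structural C proportionally
  frac_out <- if (struct_c0 > 0) (lit_c + export_c) / struct_c0 else 0
  frac_out <- min(frac_out, 1)
  el_out <- plant$struct * frac_out
  share_exp <- if (lit_c + export_c > 0) export_c / (lit_c + export_c)
               else 0
  export_el <- el_out * share_exp
  litter_el <- el_out - export_el
  plant$struct <- plant$struct - el_out
  if (harvest) {
    export_el <- export_el + plant$reserve * hf
    litter_el <- litter_el + plant$reserve * (1 - hf)
    plant$reserve[] <- 0
  }
  plant$c <- cp
  list(plant = plant, litter_c = lit, litter_el = litter_el,
       export_c = export_c, export_el = export_el)
}

#' @export
print.plant_state <- function(x, ...) {
  cat("<plant_state> total C", sprintf("%.1f", sum(x$c)), "g m-2; leaf",
      sprintf("%.1f", x$c[["leaf"]]), "| root",
      sprintf("%.1f", x$c[["root"]]), "| NSC",
      sprintf("%.1f", x$c[["nsc"]]), "\n")
  invisible(x)
}
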