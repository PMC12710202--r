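.erwsim_env <- new.env(parent = emptyenv())

.release_elements <- c("Ca", "Mg", "K", "Na", "Si", "Al", "P", "C")

#' Packaged mineral dissolution-kinetics library
#'
#' One row per mineral-mechanism (acid / neutral / base), with the log10 rate
#' constant at 25 degC (mol m-2 s-1), Arrhenius activation energy (kJ mol-1),
#' proton reaction order, molar mass, element stoichiometry and (for
#' carbonates) the solubility log K. Values are transcribed from the public
#' Palandri & Kharaka (2004, USGS OFR 2004-1068) compilation; entries using a
#' proxy mineral carry it in the `source` tag. Chlorite uses clinochlore
#' kinetics; ferroactinolite uses tremolite-group amphibole kinetics. Iron
#' and structural O/H are not tracked.
#'
#' @param path optional path to an alternative library file in the same
#'   tab-separated dialect
#' @return data frame of mineral-mechanism entries
#' @export
mineral_library <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.erwsim_env$mineral_lib)) return(.erwsim_env$mineral_lib)
    path <- system.file("extdata", "mineral_kinetics.tsv",
                        package = "erwsim", mustWork = TRUE)
    lib <- utils::read.delim(path, stringsAsFactors = FALSE)
    .erwsim_env$mineral_lib <- lib
    return(lib)
  }
  utils::read.delim(path, stringsAsFactors = FALSE)
}

# compact per-mineral kinetics used in the hot loop
.prep_kinetics <- function(minerals, lib = mineral_library()) {
  out <- lapply(minerals, function(m) {
    rows <- lib[lib$mineral == m, , drop = FALSE]
    if (nrow(rows) == 0) stop("mineral not in kinetics library: ", m)
    list(name = m,
         k25 = 10^rows$log_k25,
         ea = rows$Ea_kJmol * 1000,
         n_h = rows$n_H,
         molar_mass = rows$molar_mass_g[1],
         stoich = as.numeric(rows[1, paste0("stoich_", .release_elements)]),
         is_carbonate = is.finite(rows$log_Keq[1]))
  })
  names(out) <- minerals
  out
}

#' Palandri-Kharaka dissolution rate with soil-moisture and F_D factors
#'
#' Surface-normalised dissolution rate summed over the acid, neutral and
#' base mechanisms, each Arrhenius-corrected from 25 degC and scaled by the
#' proton activity to its reaction order, then multiplied by the effective
#' saturation (linear soil-moisture term), the thermodynamic factor
#' `1 - min(omega, 1)` and the dimensionless dissolution factor `F_D`:
#' \deqn{r = F_D\, s_{eff}\, (1-\min(\Omega,1)) \sum_m k_m(25)\,
#'   e^{-E_a/R (1/T - 1/298.15)}\, (10^{-pH})^{n_m}}
#'
#' @param mineral mineral name present in [mineral_library()]
#' @param pH porewater pH (0..14)
#' @param soil_temp soil temperature, degC
#' @param s_eff effective saturation (0..1)
#' @param omega mineral saturation ratio (>= 0); silicates are treated as
#'   far from equilibrium (omega = 0) unless stated
#' @param F_D dimensionless dissolution factor (>= 0)
#' @param lib optional alternative kinetics library
#' @return dissolution rate, mol m-2 s-1
#' @export
dissolution_rate <- function(mineral, pH, soil_temp, s_eff, omega = 0,
                             F_D = 1, lib = mineral_library()) {
  stopifnot(pH >= 0, pH <= 14, s_eff >= 0, s_eff <= 1, omega >= 0, F_D >= 0)
  kin <- .prep_kinetics(mineral, lib)[[1]]
  .kin_rate(kin, pH, soil_temp, s_eff, omega, F_D)
}

.kin_rate <- function(kin, pH, soil_temp, s_eff, omega, F_D) {
  temp_K <- soil_temp + 273.15
  arr <- exp(-kin$ea / .const$R_gas * (1 / temp_K - 1 / .const$T_ref))
  mech <- kin$k25 * arr * 10^(-pH * kin$n_h)
  F_D * s_eff * (1 - min(omega, 1)) * sum(mech)
}

#' Create an empty feedstock state
#'
#' Tracks per-application-cohort remaining mineral mass and reactive surface
#' area, plus cumulative dissolved moles per element.
#'
#' @return a `feedstock_state`
#' @export
new_feedstock_state <- function() {
  st <- list(
    cohorts = data.frame(mineral = character(0), mass0 = numeric(0),
                         mass = numeric(0), area0 = numeric(0),
                         stringsAsFactors = FALSE),
    cum_moles = stats::setNames(numeric(length(.release_elements)),
                                .release_elements))
  class(st) <- "feedstock_state"
  st
}

#' Apply a feedstock application event
#'
#' Adds one cohort per mineral with mass `rate * fraction` and initial
#' reactive surface area `rate * fraction * ssa`. Minerals with zero
#' fraction are skipped. Fractions may sum to slightly less than 1 (down to
#' 0.95): X-ray-diffraction mineralogies rarely close exactly, and the
#' unresolved remainder is treated as inert residue that never dissolves.
#'
#' @param state a `feedstock_state`
#' @param event list with `rate` (kg rock m-2), `ssa` (specific surface
#'   area, m2 kg-1) and `fractions` (named mass fractions summing to 1)
#' @param lib optional kinetics library (used to reject unknown minerals)
#' @return updated `feedstock_state`
#' @export
apply_feedstock_event <- function(state, event, lib = mineral_library()) {
  fr <- unlist(event$fractions)
  if (sum(fr) > 1 + 1e-9 || sum(fr) < 0.95)
    stop("mineral fractions must sum to 1 (up to 5% inert residue)")
  if (event$rate < 0) stop("application rate must be >= 0")
  unknown <- setdiff(names(fr), unique(lib$mineral))
  if (length(unknown))
    stop("minerals absent from kinetics library: ",
         paste(unknown, collapse = ", "))
  fr <- fr[fr > 0]
  if (event$rate == 0 || length(fr) == 0) return(state)
  add <- data.frame(mineral = names(fr),
                    mass0 = event$rate * as.numeric(fr),
                    mass = event$rate * as.numeric(fr),
                    area0 = event$rate * as.numeric(fr) * event$ssa,
                    stringsAsFactors = FALSE)
  state$cohorts <- rbind(state$cohorts, add)
  state
}

#' Dissolve the feedstock assemblage over one sub-step
#'
#' For each cohort: moles dissolved = rate * area * dt, capped at the
#' remaining moles; surface area follows the shrinking-particle rule
#' `A = A0 * (m / m0)^(2/3)`. Element release is the stoichiometric sum over
#' minerals in g element m-2. The calcite saturation ratio enters through
#' `chem$omega_calcite`; silicates dissolve far from equilibrium.
#'
#' @param state a `feedstock_state`
#' @param chem list with `pH`, `soil_temp` (degC), `s_eff` and
#'   `omega_calcite`
#' @param F_D dimensionless dissolution factor
#' @param dt sub-step length, s (the ERW clock uses 600 s)
#' @param kin prepared kinetics (internal fast path); defaults to lookup
#' @return list with updated `state` and `release` (named g m-2, elements
#'   Ca, Mg, K, Na, Si, Al, P, C)
#' @export
step_feedstock <- function(state, chem, F_D, dt = 600, kin = NULL) {
  if (dt <= 0) stop("dt must be positive")
  release <- stats::setNames(numeric(length(.release_elements)),
                             .release_elements)
  co <- state$cohorts
  if (nrow(co) == 0) return(list(state = state, release = release))
  if (is.null(kin)) kin <- .prep_kinetics(unique(co$mineral))
  rel_mol <- release
  for (i in seq_len(nrow(co))) {
    m <- co$mass[i]
    if (m <= 0) next
    k <- kin[[co$mineral[i]]]
    omega <- if (k$is_carbonate) chem$omega_calcite else 0
    rate <- .kin_rate(k, chem$pH, chem$soil_temp, chem$s_eff, omega, F_D)
    area <- co$area0[i] * (m / co$mass0[i])^(2 / 3)
    mol <- rate * area * dt                      # mol mineral
    mol_max <- m * 1000 / k$molar_mass           # kg -> g -> mol
    if (mol > mol_max) mol <- mol_max
    co$mass[i] <- m - mol * k$molar_mass / 1000
    if (co$mass[i] < 0) co$mass[i] <- 0
    rel_mol <- rel_mol + mol * k$stoich
  }
  state$cohorts <- co
  release <- rel_mol * .const$M[.release_elements]
  state$cum_moles <- state$cum_moles + rel_mol
  list(state = state, release = release)
}

#' Stoichiometric element content of the remaining feedstock
#'
#' @param state a `feedstock_state`
#' @param lib optional alternative kinetics library
#' @return named numeric, g element m-2 remaining in the solid assemblage
#' @export
feedstock_element_content <- function(state, lib = mineral_library()) {
  out <- stats::setNames(numeric(length(.release_elements)),
                         .release_elements)
  co <- state$cohorts
  if (nrow(co) == 0) return(out)
  kin <- .prep_kinetics(unique(co$mineral), lib)
  for (i in seq_len(nrow(co))) {
    k <- kin[[co$mineral[i]]]
    mol <- co$mass[i] * 1000 / k$molar_mass
    out <- out + mol * k$stoich * .const$M[.release_elements]
  }
  out
}

#' @export
print.feedstock_state <- function(x, ...) {
  cat("<feedstock_state> ", nrow(x$cohorts), " cohort rows, total mass ",
      sprintf("%.4g", sum(x$cohorts$mass)), " kg m-2\n", sep = "")
  invisible(x)
}
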