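#' Built-in soil texture hydraulic defaults
#'
#' Clapp-Hornberger-style parameters per texture class: saturated
#' conductivity `ks_mm_h`, retention exponent `b` (the drainage exponent is
#' `2b + 3`), porosity and volumetric field capacity / wilting point. Values
#' are representative class means from the standard pedotransfer literature
#' and can be overridden per site in the configuration.
#'
#' @return data frame keyed by `texture`
#' @export
texture_defaults <- function() {
  data.frame(
    texture  = c("sand", "loamy_sand", "sandy_loam", "loam", "silt_loam",
                 "clay_loam", "clay"),
    ks_mm_h  = c(210, 150, 35, 13, 7, 2.5, 1.3),
    b        = c(4.05, 4.38, 4.90, 5.39, 5.30, 8.52, 11.40),
    porosity = c(0.395, 0.410, 0.435, 0.451, 0.485, 0.476, 0.482),
    field_capacity = c(0.12, 0.15, 0.21, 0.27, 0.33, 0.36, 0.40),
    wilting_point  = c(0.03, 0.05, 0.09, 0.12, 0.13, 0.19, 0.27),
    stringsAsFactors = FALSE)
}

#' Built-in plant functional type trait sets
#'
#' Trait defaults for the packaged plant functional types. Light-use
#' efficiency (`lue`, g C per MJ absorbed PAR), specific leaf area (`sla`,
#' m2 per g leaf C), allocation fractions (sum to 1), first-order tissue
#' turnover rates (d-1), maintenance respiration coefficients (fraction of
#' tissue C per day at 20 degC), growth respiration fraction, crop phenology
#' (day-of-year; NA = perennial), harvest export fraction, tissue
#' stoichiometric targets (g element per g C) and maximum reserve capacities
#' (g element m-2). Stoichiometric targets for Ca, Mg, Si are calibration
#' parameters, not literature constants.
#'
#' @param pft one of `"maize"`, `"soybean"`, `"sorghum"`, `"grass"`
#' @return a named list of traits
#' @export
pft_traits <- function(pft = c("maize", "soybean", "sorghum", "grass")) {
  pft <- match.arg(pft)
  base <- list(
    lue = 2.0, sla = 0.018,
    alloc = c(leaf = 0.30, sapwood = 0.25, root = 0.20, nsc = 0.10,
              repro = 0.15),
    turnover = c(leaf = 0.010, sapwood = 0.003, root = 0.008, repro = 0,
                 dead_leaf = 0.05),
    maint_resp = c(leaf = 0.010, sapwood = 0.002, root = 0.008),
    growth_resp_frac = 0.25,
    plant_doy = NA_integer_, harvest_doy = NA_integer_,
    harvest_export_frac = 0.45,
    target_stoich = c(N = 0.030, P = 0.0030, K = 0.020, Ca = 0.008,
                      Mg = 0.003, Si = 0.010, Na = 5e-4),
    max_reserve = c(N = 6, P = 0.8, K = 5, Ca = 2.5, Mg = 1.0, Si = 3,
                    Na = 0.2),
    uptake_vmax = 0.05,   # g element per g root C per day at unit conc
    uptake_km = 0.5,      # mol m-3 half-saturation
    n_fixer = FALSE)
  tweak <- switch(pft,
    maize   = list(lue = 3.0, plant_doy = 120L, harvest_doy = 280L),
    soybean = list(lue = 2.0, plant_doy = 150L, harvest_doy = 273L,
                   n_fixer = TRUE,
                   target_stoich = c(N = 0.045, P = 0.0035, K = 0.022,
                                     Ca = 0.016, Mg = 0.0030, Si = 0.004,
                                     Na = 5e-4),
                   max_reserve = c(N = 9, P = 0.9, K = 5, Ca = 4.0,
                                   Mg = 0.9, Si = 1.2, Na = 0.2)),
    sorghum = list(lue = 2.8, plant_doy = 130L, harvest_doy = 251L),
    grass   = list(lue = 2.0,
                   alloc = c(leaf = 0.35, sapwood = 0.10, root = 0.30,
                             nsc = 0.20, repro = 0.05),
                   turnover = c(leaf = 0.010, sapwood = 0.003,
                                root = 0.008, repro = 0.010,
                                dead_leaf = 0.05)))
  out <- utils::modifyList(base, tweak)
  out$pft <- pft
  out
}

#' Full default simulation configuration
#'
#' Every tunable parameter of the simulator with its default. User
#' configurations (YAML or R lists) are merged over these defaults by
#' [validate_config()]. Units are given in the vignette; initial pools are
#' generic temperate-agricultural values intended as spin-up starting points.
#'
#' @return nested named list
#' @export
default_config <- function() {
  list(
    site = list(
      latitude = 40,
      z_active = 0.30,            # biogeochemically active layer depth, m
      texture = "silt_loam",
      porosity = NULL,            # NULL = from texture class
      field_capacity = NULL,
      wilting_point = NULL,
      ks_mm_h = NULL,
      b = NULL,
      cec = 40                    # mol_c m-2 over the active layer
    ),
    schedule = list(n_years = 1L, n_days = NULL, spinup_years = 0L,
                    year0 = 2001L),
    feedstock = list(events = list()),   # each: day, rate, ssa, fractions
    weathering = list(
      F_D = 1,                    # dimensionless dissolution factor
      k_precip = 1e-8,            # carbonate precip rate, mol m-2 s-1
      substep_s = 600,
      fixed_ph = NULL             # freeze the pH seen by dissolution
    ),
    chemistry = list(
      dic_rain = 0.2,             # DIC in rainwater, g C m-3
      selectivity = c(Ca = 1, Mg = 1, K = 0.2, Na = 0.05),
      # exchangeable acidity relaxes toward a titration equilibrium
      # 1/(1 + 10^(pH - acid_ph50)) with e-folding time acid_tau (days)
      acid_ph50 = 5.5,
      acid_tau = 60,
      davies = FALSE              # activity-correction hook, default off
    ),
    hydrology = list(
      damping_days = 10,          # soil-temperature e-folding time, d
      snow_ddf = 3,               # degree-day melt factor, mm degC-1 d-1
      pt_alpha = 1.26, albedo = 0.15,
      soil_temp_floor = FALSE
    ),
    vegetation = list(
      pft = "grass",
      traits = NULL,              # overrides merged over pft_traits(pft)
      rotation = NULL,            # named list year_index -> pft
      lai_max = 6
    ),
    biogeochem = .default_bgc_params(),
    initial = .default_initial_pools(),
    external = list(
      # exogenous inputs, g element m-2 yr-1 (deposition etc.)
      deposition = c(N = 0.8, P = 0.05, K = 0.3, Ca = 0.4, Mg = 0.1,
                     Na = 0.3, Si = 0.1, Al = 0.02, An = 0.01),
      fert_events = list()        # each: day, element ("N"/"P"), amount g m-2
    )
  )
}

# microbially explicit decomposition and nutrient-cycle parameters; defaults
# are plausible placeholders pending calibration (see vignette)
.default_bgc_params <- function() {
  list(
    q10 = 2, t_ref = 20,
    fw_opt = 0.6,
    fph_mu = 6.5, fph_sigma = 1.5,
    v_lig = 1.0,  k_lig = 500,    # lignin-like POC -> DOC, fungal enzymes
    v_cel = 2.0,  k_cel = 500,    # cellulose-like POC -> DOC
    v_mao = 0.25, k_mao = 3000,   # MAOC -> DOC
    v_upt = 0.20, k_doc = 10,     # microbial DOC uptake
    yield = 0.45,                 # microbial growth yield on DOC
    enz_frac = 0.04,              # fraction of growth to enzyme production
    enz_turn = 0.05,              # enzyme turnover to DOC, d-1
    mic_mort = 0.008,             # microbial mortality, d-1
    mic_maint = 0.002,            # microbial maintenance respiration, d-1
    myc_nsc_frac = 0.002,         # plant NSC fraction to mycorrhizae, d-1
    ew_graze = 3e-4,              # earthworm POC grazing, d-1
    ew_assim = 0.3, ew_cue = 0.25, ew_mort = 0.005,
    f_mao = 0.30, maoc_max = 6000, # POC->MAOC routing, Langmuir saturation
    lit_k = c(leaf_ag = 0.010, wood_ag = 0.002, root_bg = 0.008,
              fine_bg = 0.020),
    lit_resp_frac = 0.3,          # respired share of litter decomposition
    lit_lig_frac = 0.25,          # lignin-like share of litter to POC
    lit_doc_frac = 0.05,          # direct litter -> DOC share
    cn_som = 12, cp_som = 110, cn_mic = 8, cp_mic = 50,
    lambda_n = 0.3, lambda_p = 0.3, lambda_x = 0.9,
    f_org_lea = 0.10, f_d = 0.10,
    cx_som = c(Ca = 150, Mg = 400, K = 200, Na = 2000, Si = 50),
    k_nit = 0.05, k_vol = 0.01, k_den = 0.02,
    k_sec_p = 0.002,              # secondary P fixation, d-1
    k_fix = c(Ca = 1e-4, Mg = 1e-4, K = 1e-4, Si = 5e-4),
    k_pri = 1e-5                  # primary (parent material) release, d-1
  )
}

.default_initial_pools <- function() {
  list(
    s_eff = 0.5, soil_temp = 10, snow = 0,
    soc = c(poc_l = 300, poc_c = 700, maoc = 3000, doc = 20,
            bact = 50, fungi = 50, am = 10, em = 10, enz = 2, worm = 5),
    litter = c(leaf_ag = 30, wood_ag = 10, root_bg = 20, fine_bg = 20,
               leaf_ag2 = 10, wood_ag2 = 5, root_bg2 = 10, fine_bg2 = 10),
    org_n = 330, org_p = 36,
    # a moderately acid agricultural porewater (pH ~6-6.5 under soil CO2)
    solutes = c(Ca = 2, Mg = 0.8, K = 1.2, Na = 0.6, NH4 = 0.3,
                NO3 = 0.6, TPO4 = 0.3, Si = 3, Al = 0.05),
    an_r = 0.02,                  # residual anions, mol_c m-2
    exch_frac = c(Ca = 0.55, Mg = 0.15, K = 0.04, Na = 0.01),  # rest acidity
    primary = c(Ca = 500, Mg = 300, K = 800, Si = 5000, P = 100),
    secondary = c(Ca = 0, Mg = 0, K = 0, Si = 0, P = 0),
    carbonate_mineral = 0,        # pedogenic carbonate, g C m-2
    plant = c(leaf = 30, dead_leaf = 0, sapwood = 30, heartwood = 0,
              root = 40, nsc = 50, repro = 0),
    reserve_fill = 0.5            # initial reserves as fraction of max
  )
}

#' Validate and complete a simulation configuration
#'
#' Merges a raw (possibly partial) configuration over [default_config()],
#' resolves texture-class hydraulic defaults, and checks every invariant.
#' All violations are reported together, not only the first. Defaults that
#' were filled in are recorded in the `filled_defaults` attribute.
#'
#' @param raw nested list (e.g. from [read_config()]), or `NULL` for pure
#'   defaults
#' @return a validated `sim_config` list
#' @export
validate_config <- function(raw = NULL) {
  cfg <- default_config()
  filled <- character(0)
  if (!is.null(raw)) {
    stopifnot(is.list(raw))
    filled <- .unset_leaves(cfg, raw)
    cfg <- utils::modifyList(cfg, raw)
    # modifyList merges by name and drops unnamed elements: carry the
    # event/rotation lists over wholesale
    if (!is.null(raw$feedstock$events))
      cfg$feedstock$events <- raw$feedstock$events
    if (!is.null(raw$external$fert_events))
      cfg$external$fert_events <- raw$external$fert_events
    if (!is.null(raw$vegetation$rotation))
      cfg$vegetation$rotation <- raw$vegetation$rotation
  } else filled <- .unset_leaves(cfg, list())

  errs <- character(0)
  push <- function(msg) errs <<- c(errs, msg)

  tex <- texture_defaults()
  if (!cfg$site$texture %in% tex$texture)
    push(paste0("unknown texture class '", cfg$site$texture, "'"))
  else {
    row <- tex[tex$texture == cfg$site$texture, ]
    for (f in c("porosity", "field_capacity", "wilting_point", "ks_mm_h",
                "b"))
      if (is.null(cfg$site[[f]])) cfg$site[[f]] <- row[[f]]
  }
  s <- cfg$site
  if (!is.null(s$porosity)) {
    if (s$z_active <= 0) push("site$z_active must be > 0")
    if (s$porosity <= 0 || s$porosity >= 1)
      push("site$porosity must be in (0, 1)")
    if (!(s$wilting_point < s$field_capacity &&
          s$field_capacity < s$porosity))
      push("require wilting_point < field_capacity < porosity")
    if (s$cec <= 0) push("site$cec must be > 0")
  }
  if (cfg$weathering$F_D < 0) push("weathering$F_D must be >= 0")
  if (cfg$schedule$n_years < 1) push("schedule$n_years must be >= 1")
  if (cfg$schedule$spinup_years < 0)
    push("schedule$spinup_years must be >= 0")
  if (!is.null(cfg$schedule$n_days) && cfg$schedule$n_days < 1)
    push("schedule$n_days must be >= 1 when given")

  lib_minerals <- unique(mineral_library()$mineral)
  n_days <- if (!is.null(cfg$schedule$n_days)) cfg$schedule$n_days
            else cfg$schedule$n_years * 365
  for (i in seq_along(cfg$feedstock$events)) {
    ev <- cfg$feedstock$events[[i]]
    lab <- paste0("feedstock event ", i, ": ")
    if (is.null(ev$day) || ev$day < 1 || ev$day > n_days)
      push(paste0(lab, "day outside simulation window [1, ", n_days, "]"))
    if (is.null(ev$rate) || ev$rate < 0)
      push(paste0(lab, "rate must be >= 0"))
    if (is.null(ev$ssa) || ev$ssa <= 0)
      push(paste0(lab, "specific surface area must be > 0"))
    fr <- unlist(ev$fractions)
    # XRD mineralogies rarely close exactly: up to 5% unresolved mass is
    # treated as inert residue
    if (is.null(fr) || sum(fr) > 1 + 1e-9 || sum(fr) < 0.95)
      push(paste0(lab, "mineral fractions must sum to 1 ",
                  "(within 5% inert residue; got ", format(sum(fr)), ")"))
    if (any(fr < 0 | fr > 1)) push(paste0(lab, "fractions must be in [0,1]"))
    unknown <- setdiff(names(fr), lib_minerals)
    if (length(unknown))
      push(paste0(lab, "minerals absent from kinetics library: ",
                  paste(unknown, collapse = ", ")))
  }
  for (i in seq_along(cfg$external$fert_events)) {
    ev <- cfg$external$fert_events[[i]]
    if (is.null(ev$day) || ev$day < 1 || ev$day > n_days)
      push(paste0("fertiliser event ", i, " outside simulation window"))
    if (!ev$element %in% c("N", "P"))
      push(paste0("fertiliser event ", i, " element must be 'N' or 'P'"))
  }
  ef <- cfg$initial$exch_frac
  if (any(ef < 0 | ef > 1) || sum(ef) > 1 + 1e-9)
    push("initial$exch_frac must be in [0,1] and sum to <= 1")
  if (!cfg$vegetation$pft %in% c("maize", "soybean", "sorghum", "grass"))
    push(paste0("unknown pft '", cfg$vegetation$pft, "'"))
  if (cfg$chemistry$dic_rain < 0) push("chemistry$dic_rain must be >= 0")
  if (cfg$hydrology$damping_days <= 0)
    push("hydrology$damping_days must be > 0")

  if (length(errs))
    stop("configuration invalid:\n  - ", paste(errs, collapse = "\n  - "))

  # resolve traits once
  tr <- pft_traits(cfg$vegetation$pft)
  if (!is.null(cfg$vegetation$traits))
    tr <- utils::modifyList(tr, cfg$vegetation$traits)
  cfg$vegetation$traits <- tr

  attr(cfg, "filled_defaults") <- filled
  class(cfg) <- c("sim_config", "list")
  cfg
}

# names of default leaves not overridden by the user (dotted paths)
.unset_leaves <- function(def, usr, prefix = "") {
  out <- character(0)
  get_usr <- function(u, nm)
    if (is.list(u) && nm %in% names(u)) u[[nm]] else NULL
  for (nm in names(def)) {
    path <- paste0(prefix, nm)
    if (is.list(def[[nm]]) && !is.null(names(def[[nm]]))) {
      out <- c(out, .unset_leaves(def[[nm]], get_usr(usr, nm),
                                  paste0(path, "$")))
    } else if (is.null(get_usr(usr, nm)) &&
               !(!is.list(usr) && !is.null(names(usr)) &&
                 nm %in% names(usr))) {
      out <- c(out, path)
    }
  }
  out
}

#' Read a configuration file
#'
#' Parses a YAML configuration and validates it with [validate_config()].
#'
#' @param path path to a YAML file
#' @return a validated `sim_config`
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  # yaml returns unnamed lists for mappings of numbers; coerce known vectors
  validate_config(.coerce_config_vectors(raw))
}

# yaml maps come back as lists; the config stores several named numeric
# vectors -- coerce those specific keys back to vectors
.vector_keys <- c("selectivity", "deposition", "fractions", "cx_som",
                  "k_fix", "lit_k", "soc", "litter", "solutes",
                  "exch_frac", "primary", "secondary", "plant",
                  "target_stoich", "max_reserve", "alloc", "turnover",
                  "maint_resp")

.coerce_config_vectors <- function(x, key = "") {
  if (!is.list(x)) return(x)
  if (key %in% .vector_keys && length(x) && !is.null(names(x)) &&
      all(vapply(x, function(e) is.numeric(e) && length(e) == 1,
                 logical(1))))
    return(unlist(x))
  out <- lapply(seq_along(x), function(i)
    .coerce_config_vectors(x[[i]], if (is.null(names(x))) "" else
      names(x)[i]))
  names(out) <- names(x)
  out
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$schedule$n_years, " yr, pft=", x$vegetation$pft,
      ", texture=", x$site$texture,
      ", F_D=", x$weathering$F_D,
      ", feedstock events=", length(x$feedstock$events), "\n", sep = "")
  invisible(x)
}

#' Hash of a configuration (for run metadata)
#' @param config a `sim_config`
#' @return character scalar
#' @export
config_hash <- function(config) {
  attr(config, "filled_defaults") <- NULL
  txt <- paste(utils::capture.output(utils::str(config, digits.d = 15,
                                                vec.len = 1e6)),
               collapse = "\n")
  # 31-based rolling hash over the deparsed configuration (not crypto)
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Load a packaged scenario configuration
#'
#' @param name one of `"mesocosm_sorghum"`, `"illinois_maize_soy"`,
#'   `"illinois_maize_soy_basaltB"`
#' @return a validated `sim_config`
#' @export
scenario_config <- function(name = c("mesocosm_sorghum",
                                     "illinois_maize_soy",
                                     "illinois_maize_soy_basaltB")) {
  name <- match.arg(name)
  read_config(system.file("extdata", "scenarios",
                          paste0(name, ".yaml"),
                          package = "erwsim", mustWork = TRUE))
}
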