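bgc <- erwsim:::.default_bgc_params()
env_ref <- env_modifiers(20, 0.6, 6.5, bgc)   # reference conditions
pools0 <- local({
  ini <- erwsim:::.default_initial_pools()
  list(soc = ini$soc, litter = ini$litter)
})

test_that("environmental modifiers are bounded and unity at reference", {
  expect_equal(unname(env_ref), c(1, 1, 1))
  for (t in c(-5, 0, 10, 30)) for (s in c(0, 0.3, 1)) {
    e <- env_modifiers(t, s, 5, bgc)
    expect_true(all(e >= 0 & e <= 1))
  }
  expect_equal(env_modifiers(20, 0, 6.5, bgc)[["f_W"]], 0)
})

test_that("leaching flux is proportional and capped", {
  expect_equal(leach_flux(10, 0), 0)
  expect_equal(leach_flux(10, 0.01), 0.1)
  expect_equal(leach_flux(10, 3), 10)     # capped at the pool
  expect_error(leach_flux(-1, 0.1))
})

test_that("without enzymes only litter decay proceeds", {
  p <- pools0
  p$soc[c("enz")] <- 0
  r <- step_soc(p, env_ref, params = bgc)
  expect_equal(unname(r$fluxes[c("F2l", "F2c", "F3")]), c(0, 0, 0))
  expect_gt(r$fluxes[["litter_decomp"]], 0)
})

test_that("dry soil silences microbial respiration", {
  env_dry <- env_modifiers(20, 0, 6.5, bgc)
  r <- step_soc(pools0, env_dry, params = bgc)
  expect_equal(r$r_het[["microbe"]], 0)
  expect_equal(r$r_het[["earthworm"]], 0)
})

test_that("closed-system carbon closes against cumulative respiration", {
  p <- pools0
  tot0 <- sum(p$soc) + sum(p$litter)
  cum <- 0
  for (d in 1:365) {
    r <- step_soc(p, env_ref, litter_in = NULL, params = bgc)
    p <- r$pools
    cum <- cum + r$r_het[["total"]]
  }
  tot1 <- sum(p$soc) + sum(p$litter)
  expect_equal(tot1 + cum, tot0, tolerance = 1e-8)
  expect_true(r$cue > 0 && r$cue < 1)     # emergent CUE is a fraction
})

test_that("zero nitrogen pools with zero inputs stay zero", {
  r <- step_nitrogen(list(org_n = 0, nh4 = 0, no3 = 0), env_ref,
                     ctx = list(pH = 6.5, s_eff = 0.5, som_n_flux = 0,
                                mic_n_demand = 0, leach_rate = 0),
                     params = bgc)
  expect_true(all(unlist(r$pools) == 0))
  expect_true(all(r$fluxes == 0))
})

test_that("an ammonium pulse nitrifies with the discrete closed form", {
  # all pathways but nitrification off; explicit daily Euler gives
  # NH4_t = NH4_0 (1-k)^t and NO3_t = NH4_0 (1 - (1-k)^t)
  p2 <- bgc; p2$k_vol <- 0
  k <- p2$k_nit
  pool <- list(org_n = 0, nh4 = 2, no3 = 0)
  for (t in 1:40) {
    pool <- step_nitrogen(pool, env_ref,
                          ctx = list(pH = 6.5, s_eff = 0.5,
                                     som_n_flux = 0, mic_n_demand = 0,
                                     leach_rate = 0),
                          params = p2)$pools
  }
  expect_equal(pool$nh4, 2 * (1 - k)^40, tolerance = 1e-10)
  expect_equal(pool$no3, 2 * (1 - (1 - k)^40), tolerance = 1e-10)
})

test_that("the nitrogen ledger closes over a synthetic year", {
  pool <- list(org_n = 300, nh4 = 1, no3 = 1.5)
  exported <- 0; ext_in <- 0; uptaken <- 0
  tot0 <- 300 + 1 + 1.5
  set.seed(9)
  for (d in 1:365) {
    ctx <- list(pH = runif(1, 5.5, 7.5), s_eff = runif(1, 0.2, 0.95),
                som_n_flux = runif(1, 0, 0.3),
                mic_n_demand = runif(1, 0, 0.1),
                leach_rate = runif(1, 0, 0.05))
    upt <- c(nh4 = runif(1, 0, 0.05), no3 = runif(1, 0, 0.05))
    r <- step_nitrogen(pool, env_ref, ctx, uptake = upt, ext_n = 0.01,
                       params = bgc)
    pool <- r$pools
    fx <- r$fluxes
    exported <- exported + fx[["volatilisation"]] +
      fx[["denitrification"]] + fx[["leach_nh4"]] + fx[["leach_no3"]] +
      fx[["org_leach"]]
    uptaken <- uptaken + fx[["uptake_nh4"]] + fx[["uptake_no3"]]
    ext_in <- ext_in + fx[["ext_in"]]
  }
  tot1 <- pool$org_n + pool$nh4 + pool$no3
  expect_equal(tot1 + exported + uptaken - ext_in, tot0,
               tolerance = 1e-8 * tot0)
})

test_that("volatilisation increases with pH", {
  ctx_of <- function(ph) list(pH = ph, s_eff = 0.5, som_n_flux = 0,
                              mic_n_demand = 0, leach_rate = 0)
  v <- vapply(c(5, 7, 9), function(ph)
    step_nitrogen(list(org_n = 0, nh4 = 5, no3 = 0), env_ref,
                  ctx_of(ph), params = bgc)$fluxes[["volatilisation"]],
    0)
  expect_true(all(diff(v) > 0))
})

test_that("phosphorus with only secondary fixation decays geometrically", {
  p2 <- bgc; p2$k_pri <- 0
  pool <- list(org_p = 0, tpo4 = 1, primary = 0, secondary = 0)
  for (t in 1:30)
    pool <- step_phosphorus(pool, 0, env_ref,
                            ctx = list(som_p_flux = 0, mic_p_demand = 0,
                                       leach_rate = 0),
                            params = p2)$pools
  expect_equal(pool$tpo4, (1 - bgc$k_sec_p)^30, tolerance = 1e-10)
  expect_equal(pool$secondary, 1 - (1 - bgc$k_sec_p)^30,
               tolerance = 1e-10)
})

test_that("the phosphorus ledger closes over a synthetic year", {
  pool <- list(org_p = 30, tpo4 = 0.5, primary = 100, secondary = 0)
  tot0 <- 30 + 0.5 + 100
  out <- 0; inn <- 0
  set.seed(10)
  for (d in 1:365) {
    r <- step_phosphorus(pool, ew_p = 0.001, env = env_ref,
                         ctx = list(som_p_flux = runif(1, 0, 0.02),
                                    mic_p_demand = runif(1, 0, 0.01),
                                    leach_rate = runif(1, 0, 0.05)),
                         uptake = runif(1, 0, 0.01), ext_p = 0.0002,
                         params = bgc)
    pool <- r$pools
    out <- out + r$fluxes[["leach"]] + r$fluxes[["org_leach"]] +
      r$fluxes[["uptake"]]
    inn <- inn + r$fluxes[["ew_p"]] + r$fluxes[["ext_in"]]
  }
  tot1 <- pool$org_p + pool$tpo4 + pool$primary + pool$secondary
  expect_equal(tot1 + out - inn, tot0, tolerance = 1e-8 * tot0)
})

test_that("a weathering cation pulse raises solution by exactly the pulse", {
  p2 <- bgc
  p2$k_fix <- c(Ca = 0, Mg = 0, K = 0, Si = 0); p2$k_pri <- 0
  pools <- list(solution = c(Ca = 1, Mg = 1, K = 1),
                org = c(Ca = 0, Mg = 0, K = 0),
                primary = c(Ca = 0, Mg = 0, K = 0),
                secondary = c(Ca = 0, Mg = 0, K = 0))
  r <- step_cations(pools, ew_x = c(Ca = 0.7, Mg = 0, K = 0),
                    ctx = list(som_c_decomp = 0, doc_fluxes = 0,
                               leach_rate = 0),
                    params = p2)
  expect_equal(r$pools$solution[["Ca"]], 1.7)
  expect_equal(r$pools$solution[["Mg"]], 1)
})

test_that("source-free cation solution decays only by uptake + leaching", {
  p2 <- bgc; p2$k_fix <- c(Ca = 0, Mg = 0, K = 0, Si = 0); p2$k_pri <- 0
  pools <- list(solution = c(Ca = 2, Mg = 2, K = 2),
                org = c(Ca = 0, Mg = 0, K = 0),
                primary = c(Ca = 0, Mg = 0, K = 0),
                secondary = c(Ca = 0, Mg = 0, K = 0))
  r <- step_cations(pools, ctx = list(som_c_decomp = 0, doc_fluxes = 0,
                                      leach_rate = 0.1),
                    uptake = c(Ca = 0.2, Mg = 0, K = 0), params = p2)
  expect_equal(r$pools$solution[["Ca"]], 2 - 0.2 - 0.2)
  expect_equal(r$pools$solution[["Mg"]], 2 - 0.2)
})

test_that("each cation ledger closes over a synthetic year", {
  pools <- list(solution = c(Ca = 5, Mg = 2, K = 3),
                org = c(Ca = 20, Mg = 8, K = 15),
                primary = c(Ca = 400, Mg = 250, K = 600),
                secondary = c(Ca = 0, Mg = 0, K = 0))
  tot0 <- vapply(c("Ca", "Mg", "K"), function(e)
    pools$solution[[e]] + pools$org[[e]] + pools$primary[[e]] +
      pools$secondary[[e]], 0)
  out <- inn <- c(Ca = 0, Mg = 0, K = 0)
  set.seed(11)
  for (d in 1:365) {
    r <- step_cations(pools,
                      ew_x = c(Ca = 0.01, Mg = 0.005, K = 0.002),
                      ctx = list(som_c_decomp = runif(1, 0, 5),
                                 doc_fluxes = runif(1, 0, 3),
                                 leach_rate = runif(1, 0, 0.05)),
                      uptake = c(Ca = 0.01, Mg = 0.004, K = 0.008),
                      ext_x = c(Ca = 0.001, Mg = 3e-4, K = 8e-4),
                      params = bgc)
    pools <- r$pools
    for (e in c("Ca", "Mg", "K")) {
      out[[e]] <- out[[e]] + r$fluxes[e, "uptake"] + r$fluxes[e, "leach"]
      inn[[e]] <- inn[[e]] + r$fluxes[e, "ext_in"] +
        c(Ca = 0.01, Mg = 0.005, K = 0.002)[[e]]
    }
  }
  for (e in c("Ca", "Mg", "K")) {
    tot1 <- pools$solution[[e]] + pools$org[[e]] + pools$primary[[e]] +
      pools$secondary[[e]]
    expect_equal(tot1 + out[[e]] - inn[[e]], tot0[[e]],
                 tolerance = 1e-8 * tot0[[e]], label = e)
  }
})

test_that("Si/Na/Al/anion template behaves per balance", {
  p2 <- bgc; p2$k_fix <- c(Ca = 0, Mg = 0, K = 0, Si = 0); p2$k_pri <- 0
  mk <- function(si_sol = 1, na = 1, al = 1, an = 1)
    list(si = list(solution = si_sol, org = 0, primary = 0,
                   secondary = 0), na = na, al = al, an_r = an)
  # pure first-order washout with no inputs
  pools <- mk()
  for (t in 1:20)
    pools <- step_si_na_al_anions(pools,
                                  ctx = list(som_c_decomp = 0,
                                             doc_fluxes = 0,
                                             leach_rate = 0.05),
                                  params = p2)$pools
  expect_equal(pools$na, (1 - 0.05)^20, tolerance = 1e-10)
  expect_equal(pools$al, (1 - 0.05)^20, tolerance = 1e-10)
  expect_equal(pools$an_r, (1 - 0.05)^20, tolerance = 1e-10)

  # aluminium with sealed bottom grows linearly with the constant input
  pools <- mk(al = 0)
  for (t in 1:25)
    pools <- step_si_na_al_anions(pools,
                                  ctx = list(som_c_decomp = 0,
                                             doc_fluxes = 0,
                                             leach_rate = 0),
                                  ext = c(Si = 0, Na = 0, Al = 0.01,
                                          An = 0),
                                  params = p2)$pools
  expect_equal(pools$al, 0.25, tolerance = 1e-12)

  # sodium ledger including passive uptake closes over a year
  pools <- mk()
  out <- inn <- 0
  set.seed(12)
  for (d in 1:365) {
    r <- step_si_na_al_anions(pools,
                              ew = c(Si = 0, Na = 0.002, Al = 0),
                              ctx = list(som_c_decomp = 0,
                                         doc_fluxes = 0,
                                         leach_rate = runif(1, 0, 0.05)),
                              passive = c(Si = 0, Na = runif(1, 0, 0.003),
                                          An = 0),
                              ext = c(Si = 0, Na = 5e-4, Al = 0,
                                      An = 0),
                              params = p2)
    pools <- r$pools
    out <- out + r$fluxes[["na_leach"]] + r$fluxes[["na_uptake"]]
    inn <- inn + 0.002 + 5e-4
  }
  expect_equal(pools$na + out - inn, 1, tolerance = 1e-8)
})
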