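test_that("neutral-mechanism rate reproduces the hand-computed constant", {
  # single neutral mechanism, log k = -10.64 at 25 degC: the rate law
  # collapses to 10^-10.64 mol m-2 s-1 at s_eff = 1, omega = 0, F_D = 1
  r <- dissolution_rate("fo_neutral", pH = 7, soil_temp = 25, s_eff = 1,
                        omega = 0, F_D = 1, lib = toy_lib())
  expect_equal(r, 10^-10.64, tolerance = 1e-12)
})

test_that("multiplicative factors zero the rate as required", {
  lib <- toy_lib()
  expect_equal(dissolution_rate("acidmin", 5, 25, 1, 0, F_D = 0,
                                lib = lib), 0)
  expect_equal(dissolution_rate("acidmin", 5, 25, s_eff = 0, 0, 1,
                                lib = lib), 0)
  expect_equal(dissolution_rate("acidmin", 5, 25, 1, omega = 1, 1,
                                lib = lib), 0)
  expect_equal(dissolution_rate("acidmin", 5, 25, 1, omega = 3, 1,
                                lib = lib), 0)
})

test_that("Arrhenius temperature response is exact", {
  lib <- toy_lib()
  r25 <- dissolution_rate("fo_neutral", 7, 25, 1, 0, 1, lib = lib)
  r35 <- dissolution_rate("fo_neutral", 7, 35, 1, 0, 1, lib = lib)
  expect_equal(r35 / r25,
               exp(-79000 / 8.314462 * (1 / 308.15 - 1 / 298.15)),
               tolerance = 1e-12)
})

test_that("rate is exactly linear in F_D", {
  lib <- toy_lib()
  r1 <- dissolution_rate("acidmin", 5.5, 18, 0.7, 0, 1, lib = lib)
  for (fd in c(0.25, 0.5, 2, 7.5))
    expect_equal(dissolution_rate("acidmin", 5.5, 18, 0.7, 0, fd,
                                  lib = lib), fd * r1)
})

test_that("acid-mechanism minerals weather no faster at higher pH", {
  lib <- toy_lib()
  grid <- seq(3, 10, by = 0.5)
  rates <- vapply(grid, function(p)
    dissolution_rate("acidmin", p, 20, 1, 0, 1, lib = lib), 0)
  expect_true(all(diff(rates) <= 0))
})

test_that("feedstock events add mass and area per the application rule", {
  ev <- list(rate = 5, ssa = 100, fractions = basalt_lewis)
  st <- apply_feedstock_event(new_feedstock_state(), ev)
  co <- st$cohorts
  expect_equal(co$mass[co$mineral == "albite"], 0.98)  # 5 kg x 19.6%
  expect_equal(co$area0[co$mineral == "chlorite"], 5 * 0.363 * 100)

  # rate 0 leaves the state unchanged
  expect_identical(apply_feedstock_event(st, list(rate = 0, ssa = 100,
                                                  fractions = basalt_lewis)),
                   st)
  # two successive identical events exactly double each mineral mass
  st2 <- apply_feedstock_event(st, ev)
  m1 <- tapply(st$cohorts$mass, st$cohorts$mineral, sum)
  m2 <- tapply(st2$cohorts$mass, st2$cohorts$mineral, sum)
  expect_equal(as.numeric(m2), 2 * as.numeric(m1[names(m2)]))
  # unknown minerals are a configuration error
  expect_error(apply_feedstock_event(new_feedstock_state(),
                                     list(rate = 1, ssa = 10,
                                          fractions = list(unobtanium = 1))),
               "unobtanium")
})

test_that("empty feedstock releases nothing and is unchanged", {
  st <- new_feedstock_state()
  r <- step_feedstock(st, list(pH = 6, soil_temp = 15, s_eff = 0.5,
                               omega_calcite = 0), 1, 600)
  expect_identical(r$state, st)
  expect_true(all(r$release == 0))
})

test_that("two-mineral release equals the sum of per-mineral oracles", {
  lib <- toy_lib()
  kin <- erwsim:::.prep_kinetics(c("fo_neutral", "acidmin"), lib)
  chem <- list(pH = 5.2, soil_temp = 17, s_eff = 0.8, omega_calcite = 0)
  one <- function(minerals, fracs) {
    st <- apply_feedstock_event(new_feedstock_state(),
                                list(rate = 2, ssa = 50,
                                     fractions = fracs), lib = lib)
    step_feedstock(st, chem, 1, 600, kin = kin)$release
  }
  both <- one(NULL, list(fo_neutral = 0.5, acidmin = 0.5))
  # independent per-mineral hand evaluation of rate * area * dt * stoich
  hand <- function(m, mass) {
    k <- kin[[m]]
    rate <- sum(k$k25 * exp(-k$ea / 8.314462 *
                              (1 / (17 + 273.15) - 1 / 298.15)) *
                  10^(-5.2 * k$n_h)) * 0.8
    mol <- rate * (mass * 50) * 600
    mol * k$stoich * c(Ca = 40.078, Mg = 24.305, K = 39.0983,
                       Na = 22.98977, Si = 28.0855, Al = 26.98154,
                       P = 30.97376, C = 12.011)
  }
  expect_equal(both, hand("fo_neutral", 1) + hand("acidmin", 1),
               tolerance = 1e-10)
})

test_that("demand beyond remaining mass releases exactly the content", {
  lib <- toy_lib()
  st <- apply_feedstock_event(new_feedstock_state(),
                              list(rate = 1e-6, ssa = 1e6,
                                   fractions = list(acidmin = 1)),
                              lib = lib)
  content <- feedstock_element_content(st, lib = lib)
  # enormous dt so the cap binds
  r <- step_feedstock(st, list(pH = 2, soil_temp = 40, s_eff = 1,
                               omega_calcite = 0), 100, dt = 1e9,
                      kin = erwsim:::.prep_kinetics("acidmin", lib))
  expect_equal(sum(r$state$cohorts$mass), 0)
  expect_equal(r$release, content, tolerance = 1e-12)
  # the exhausted cohort has zero area and releases nothing further
  r2 <- step_feedstock(r$state, list(pH = 2, soil_temp = 40, s_eff = 1,
                                     omega_calcite = 0), 100, dt = 1e9,
                       kin = erwsim:::.prep_kinetics("acidmin", lib))
  expect_true(all(r2$release == 0))
})

test_that("cumulative release never exceeds the stoichiometric content", {
  ev <- list(rate = 0.01, ssa = 5000, fractions = basalt_lewis)
  st <- apply_feedstock_event(new_feedstock_state(), ev)
  content <- feedstock_element_content(st)
  kin <- erwsim:::.prep_kinetics(unique(st$cohorts$mineral))
  released <- content * 0
  for (i in 1:200) {
    r <- step_feedstock(st, list(pH = 3.5, soil_temp = 35, s_eff = 1,
                                 omega_calcite = 0), 50, dt = 6e5,
                        kin = kin)
    st <- r$state
    released <- released + r$release
    expect_true(all(released <= content + 1e-9))
  }
  # non-quartz minerals weather out completely in the long-time limit;
  # released Ca, Mg, Na, Al approach the total content
  for (e in c("Ca", "Mg", "Na", "Al"))
    expect_equal(released[[e]], content[[e]], tolerance = 1e-6)
})

test_that("negative or zero dt is a parameter error", {
  st <- apply_feedstock_event(new_feedstock_state(),
                              list(rate = 1, ssa = 10,
                                   fractions = list(quartz = 1)))
  expect_error(step_feedstock(st, list(pH = 6, soil_temp = 15,
                                       s_eff = 0.5, omega_calcite = 0),
                              1, dt = -600), "dt")
})

test_that("packaged mineral library is complete and well-formed", {
  lib <- mineral_library()
  need <- c("albite", "ferroactinolite", "epidote", "chlorite", "quartz",
            "calcite", "forsterite", "anorthite", "diopside")
  expect_true(all(need %in% lib$mineral))
  expect_true(all(lib$molar_mass_g > 0))
  expect_true(all(lib$n_H[lib$mechanism == "acid"] > 0))
  expect_true(all(lib$n_H[lib$mechanism == "neutral"] == 0))
  expect_true(all(lib$n_H[lib$mechanism == "base"] < 0))
  expect_true(all(nzchar(lib$source)))
})
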