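test_that("mechanism variants set exactly the intended bounds", {
  m <- core_model_cached()
  ra <- apply_mechanism(m, "redox_arm")
  dc <- apply_mechanism(m, "direct_coupling")
  up <- apply_mechanism(m, "uphill")

  # redox arm: ubiquinol-coupled pMMO active, the other silenced
  expect_equal(ra$reactions$pMMO1$upper_bound, 0)
  expect_gt(ra$reactions$pMMO2$upper_bound, 0)
  expect_equal(dc$reactions$pMMO2$upper_bound, 0)
  expect_gt(dc$reactions$pMMO1$upper_bound, 0)
  # uphill opens complex III backwards; the others keep it forward-only
  expect_lt(up$reactions$rxn10113_c0$lower_bound, 0)
  expect_equal(ra$reactions$rxn10113_c0$lower_bound, 0)
  expect_equal(dc$reactions$rxn10113_c0$lower_bound, 0)

  # the two variants differ only in pMMO / complex III bounds
  differing <- names(Filter(function(id) {
    a <- ra$reactions[[id]]; b <- dc$reactions[[id]]
    a$lower_bound != b$lower_bound || a$upper_bound != b$upper_bound
  }, stats::setNames(names(m$reactions), names(m$reactions))))
  expect_setequal(differing, c("pMMO1", "pMMO2"))

  # idempotence
  expect_identical(apply_mechanism(ra, "redox_arm"), ra)

  # missing reaction is named in the error
  bad <- chain_model()
  expect_error(apply_mechanism(bad, "redox_arm"), "pMMO")
})

test_that("the mechanism panel reproduces the measured physiology", {
  m <- core_model_cached()
  panel <- mechanism_panel(m, uptake_ch4 = 14.9, ngam_atp = 3.5)
  expect_true(all(panel$status == "optimal"))
  yields <- stats::setNames(panel$yield_gdw_per_mol, panel$variant)
  # the redox arm matches the measured 7.2 +- 0.4 g-DW per mol methane
  expect_lt(abs(yields[["redox_arm"]] - 7.2), 0.4)
  # electron-economy ordering
  expect_lte(yields[["redox_arm"]], yields[["uphill"]] + 1e-9)
  expect_lte(yields[["uphill"]], yields[["direct_coupling"]] + 1e-9)

  # maintenance beyond the full combustion ATP yield: no variant can pay it
  starved <- mechanism_panel(m, uptake_ch4 = 14.9, ngam_atp = 80)
  expect_true(all(starved$yield_gdw_per_mol == 0))
  expect_true(all(starved$status == "infeasible"))
})

test_that("oxygen/methane ratio matches the redox arm and the burn limit", {
  m <- core_model_cached()
  ra <- apply_mechanism(m, "redox_arm")
  expect_equal(oxygen_methane_ratio(ra, 14.9, 3.5), 1.5, tolerance = 1e-6)

  # fully oxidizing limit: biomass forced to zero and all methane burned
  # gives the combustion stoichiometry CH4 + 2 O2
  burn <- set_bounds(ra, "biomass", 0, 0)
  sol <- pfba(burn, "NGAM", "max",
              extra_bounds = list(EX_ch4_e0 = c(-14.9, -14.9)))
  expect_equal(abs(sol$fluxes[["EX_o2_e0"]]) / 14.9, 2.0, tolerance = 1e-6)

  # the ratio falls monotonically as more carbon is pushed into biomass
  mu_max <- fba(ra, extra_bounds = core_growth_bounds())$objective_value
  ratios <- vapply(c(0, 0.5, 1) * mu_max, function(mu) {
    s <- pfba(set_bounds(ra, "biomass", mu, mu), "NGAM", "max",
              extra_bounds = list(EX_ch4_e0 = c(-14.9, -14.9)))
    abs(s$fluxes[["EX_o2_e0"]]) / 14.9
  }, 0)
  expect_true(all(diff(ratios) < 1e-9))
})

test_that("growth is impossible with every methane-oxidation route closed", {
  m <- core_model_cached()
  off <- set_bounds(set_bounds(m, "pMMO1", 0, 0), "pMMO2", 0, 0)
  sol <- fba(off, extra_bounds = list(EX_ch4_e0 = c(-14.9, 0), NGAM = c(0, 0)))
  expect_lt(abs(sol$objective_value), 1e-9)
})

test_that("each variant's optimum is reproducible across repeated solves", {
  m <- core_model_cached()
  for (v in c("redox_arm", "direct_coupling", "uphill")) {
    mv <- apply_mechanism(m, v)
    a <- fba(mv, extra_bounds = core_growth_bounds())$objective_value
    b <- fba(mv, extra_bounds = core_growth_bounds())$objective_value
    expect_identical(a, b)
  }
})
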