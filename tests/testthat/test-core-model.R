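test_that("the calibrated core model reproduces the anchor physiology", {
  m <- core_model_cached()
  expect_gte(length(m$reactions), 60)
  expect_lte(length(m$reactions), 90)

  ra <- apply_mechanism(m, "redox_arm")
  sol <- pfba(ra, extra_bounds = core_growth_bounds())
  # growth rate 0.107 +- 0.002 h^-1 at uptake 14.9 and NGAM 3.5
  expect_lt(abs(sol$objective_value - 0.107), 0.002)
  # O2/CH4 close to 1.5 (emergent, not tuned)
  expect_lt(abs(abs(sol$fluxes[["EX_o2_e0"]]) / 14.9 - 1.5), 0.02)
  expect_lt(mass_balance_residual(m, sol), 1e-6)
})

test_that("every non-exchange reaction balances C, H, O and N", {
  m <- core_model_cached()
  imbal <- element_balance(m)
  expect_lt(max(abs(imbal)), 1e-9)
})

test_that("the malyl-CoA lyase enzyme is essential on methane", {
  m <- core_model_cached()
  # both reaction activities share one gene; the enzyme knockout removes both
  expect_equal(m$reactions$MCL1$gene_association,
               m$reactions$MCL2$gene_association)
  ko <- apply_mechanism(knockout(knockout(m, "MCL1"), "MCL2"), "redox_arm")
  sol <- fba(ko, extra_bounds = core_growth_bounds())
  growth <- if (identical(sol$status, "optimal")) sol$objective_value else 0
  expect_lt(growth, 1e-9)
})

test_that("leaving out optional subsystems degrades the model as expected", {
  # without the denitrification chain, anoxic PHB yields no ATP at all
  m_no_den <- build_core_model(include_denitrification = FALSE)
  res <- anoxic_phb_atp(m_no_den, allow_nitrate = TRUE)
  expect_identical(res$atp_per_phb, 0)
  # but aerobic growth is untouched
  sol <- fba(apply_mechanism(m_no_den, "redox_arm"),
             extra_bounds = core_growth_bounds())
  expect_lt(abs(sol$objective_value - 0.107), 0.002)

  # without overflow routes there is nothing to secrete
  m_no_ovf <- build_core_model(include_overflow_products = FALSE)
  expect_false("EX_ac_e0" %in% names(m_no_ovf$reactions))
})

test_that("respiratory proton stoichiometry realizes the ATP/O2 target", {
  # complexes I+III+IV translocate 10 H+ per NADH; with h H+ per ATP at the
  # synthase and 0.5 O2 per NADH, ATP/O2 = 20 / h
  m <- core_model_cached()
  pumped <- m$reactions$CPLX1$stoichiometry[["h_p0"]] +
    m$reactions$rxn10113_c0$stoichiometry[["h_p0"]] +
    m$reactions$CPLX4$stoichiometry[["h_p0"]]
  expect_equal(pumped, 10)
  h_per_atp <- -m$reactions$ATPS$stoichiometry[["h_p0"]]
  expect_equal(pumped / h_per_atp / 0.5, 5)
  # an alternative target rescales the synthase, not the pumps
  m4 <- build_core_model(atp_per_o2 = 4)
  expect_equal(-m4$reactions$ATPS$stoichiometry[["h_p0"]], 5)
})

test_that("the qualitative co-consumption flux pattern holds", {
  m <- core_model_cached()
  ra <- apply_mechanism(m, "redox_arm")
  ref <- pfba(ra, extra_bounds = core_growth_bounds())
  expt <- bottle_experiment(0.050, 1.8, 0.083, 15)
  cc <- co_consumption(m, expt)

  per_ch4 <- function(fluxes, id, ch4) abs(fluxes[[id]]) / ch4
  # glycine synthase demand per methane drops when PHB is co-consumed
  expect_lt(per_ch4(cc$fluxes, "GLYS", 1.8), per_ch4(ref$fluxes, "GLYS", 14.9))
  # malyl-CoA lysis of malyl-CoA also drops (competition for the enzyme)
  expect_lt(per_ch4(cc$fluxes, "MCL1", 1.8), per_ch4(ref$fluxes, "MCL1", 14.9))
  # PHB degradation: zero on methane, the imposed rate with PHB, and it is
  # carried entirely by methylmalyl-CoA lysis (the same lyase enzyme)
  expect_equal(unname(ref$fluxes[["PHB_DEG"]]), 0, tolerance = 1e-9)
  expect_gte(unname(cc$fluxes[["MCL2"]]) + 1e-4, 0.083)
})

test_that("atp_per_o2 validation rejects non-integral proton stoichiometry", {
  expect_error(build_core_model(atp_per_o2 = 3), "integer")
})
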