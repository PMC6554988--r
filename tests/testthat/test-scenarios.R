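test_that("growth-rate, maintenance, PHB and biomass arithmetic are exact", {
  expect_equal(round(growth_rate_from_doubling_time(6.45), 3), 0.107)
  expect_equal(growth_rate_from_doubling_time(log(2)), 1.0)
  # ln 2 / 4.94 is 0.140 (the printed 0.154 next to this doubling time is a
  # known inconsistency; simulations use the printed growth rate directly)
  expect_equal(round(growth_rate_from_doubling_time(4.94), 3), 0.140)
  expect_error(growth_rate_from_doubling_time(0), "positive")

  expect_equal(maintenance_from_endogenous_respiration(0.71, 5), 3.55)
  # printed as 3.5 at two significant figures: within the last digit
  expect_lt(abs(maintenance_from_endogenous_respiration(0.71, 5) - 3.5), 0.1)
  expect_equal(maintenance_from_endogenous_respiration(0, 5), 0)
  expect_equal(maintenance_from_endogenous_respiration(1, 5), 5)

  # monomer-minus-water molar mass: C4H8O3 (104.10) - H2O (18.02)
  expect_equal(PHB_MONOMER_MASS, 104.10 - 18.02, tolerance = 0.02)
  expect_lt(abs(phb_amount_from_concentrations(0.16, 0.017, 0.050) - 0.083),
            5e-4)
  expect_equal(phb_amount_from_concentrations(0.2, 0.2, 1), 0)
  expect_error(phb_amount_from_concentrations(0.1, 0.2, 1), "negative")

  expect_equal(biomass_from_concentrations(0.27, 0.69, 0.050), 21)
  expect_equal(essential_fraction_percent(380, 1326), 28.7, tolerance = 0.05)
})

test_that("co-consumption predicts biomass and oxygen from bottle totals", {
  m <- core_model_cached()
  expt <- bottle_experiment(0.050, ch4_consumed = 1.8, phb_consumed = 0.083,
                            duration = 15)
  cc <- co_consumption(m, expt)
  expect_equal(cc$status, "optimal")
  # within the measured 21 +- 3 mg of non-PHB dry biomass per bottle
  expect_gt(cc$biomass_mg, 18)
  expect_lt(cc$biomass_mg, 24)
  # oxygen close to the measured 2.6 +- 0.13 mmol per bottle
  expect_equal(cc$o2_mmol, 2.7, tolerance = 0.05)
  # the PHB route runs through methylmalyl-CoA lysis at the imposed rate
  expect_equal(unname(cc$fluxes[["MCL2"]]), 0.083, tolerance = 1e-3)

  # zero inputs give zero outputs
  cc0 <- co_consumption(m, bottle_experiment(0.050, 0, 0, 15))
  expect_equal(cc0$biomass_mg, 0, tolerance = 1e-6)
  expect_equal(cc0$o2_mmol, 0, tolerance = 1e-6)

  # linearity: doubling both inputs doubles biomass and oxygen
  cc2 <- co_consumption(m, bottle_experiment(0.050, 3.6, 0.166, 15))
  expect_equal(cc2$biomass_mg, 2 * cc$biomass_mg, tolerance = 1e-4)
  expect_equal(cc2$o2_mmol, 2 * cc$o2_mmol, tolerance = 1e-4)
})

test_that("carbon in equals carbon out at the co-consumption optimum", {
  m <- core_model_cached()
  expt <- bottle_experiment(0.050, 1.8, 0.083, 15)
  mm <- apply_mechanism(m, "redox_arm")
  eb <- list(EX_ch4_e0 = c(-1.8, -1.8), PHB_DEG = c(0.083, 0.083),
             EX_phb_c0 = c(-0.083, 0), NGAM = c(0, 0))
  sol <- pfba(mm, "biomass", "max", eb)
  carbon <- vapply(m$metabolites, function(x) {
    f <- parse_formula(x$formula)
    if ("C" %in% names(f)) f[["C"]] else 0
  }, 0)
  # net carbon flow through every exchange (positive = leaving the system)
  ex <- exchange_reactions(m)
  net_c <- vapply(ex, function(id) {
    st <- m$reactions[[id]]$stoichiometry
    -sum(st * carbon[names(st)]) * sol$fluxes[[id]]
  }, 0)
  expect_lt(abs(sum(net_c)), 1e-6)
  expect_lt(mass_balance_residual(m, sol), 1e-6)
})

test_that("anoxic PHB energetics require an electron acceptor", {
  m <- core_model_cached()
  no_acc <- anoxic_phb_atp(m, allow_nitrate = FALSE)
  expect_identical(no_acc$atp_per_phb, 0)
  with_no3 <- anoxic_phb_atp(m, allow_nitrate = TRUE)
  expect_gt(with_no3$atp_per_phb, 0)
  # nitrate open but the denitrification chain knocked out: still nothing
  mden <- m
  for (id in c("NAR", "NIR", "NOR", "NOS")) mden <- knockout(mden, id)
  expect_identical(anoxic_phb_atp(mden, allow_nitrate = TRUE)$atp_per_phb, 0)
})

test_that("anoxic overflow Pareto fronts have the reported shape", {
  m <- core_model_cached()
  for (prod in c("acetate", "butanediol")) {
    ps <- anoxic_overflow_pareto(m, prod)
    expect_true(all(ps$status == "optimal"))
    # maximal ATP is attained at zero secretion and decays along the grid
    expect_equal(which.max(ps$max_objective), 1L)
    expect_true(all(diff(ps$max_objective) < 1e-6))
    # products spare nitrate: consumption at the maximal-product point is
    # strictly below the zero-product point, and never increases
    expect_lt(ps$acceptor_consumed[nrow(ps)], ps$acceptor_consumed[1])
    expect_true(all(diff(ps$acceptor_consumed) < 1e-6))
    expect_true(all(ps$forced_product >= 0 & ps$max_objective > -1e-9 &
                      ps$acceptor_consumed >= -1e-9))
  }
  # a grid point beyond the stoichiometric maximum is flagged infeasible
  ps_over <- anoxic_overflow_pareto(m, "acetate", grid = c(0, 10))
  expect_equal(ps_over$status, c("optimal", "infeasible"))
})

test_that("degree distributions count, fit and flag degenerate cases", {
  m <- core_model_cached()
  dd <- degree_distribution(m)
  # counts cover every connected, non-hub metabolite
  S <- stoichiometric_matrix(m)
  deg <- Matrix::rowSums(S != 0)
  expect_equal(sum(dd$counts$n) + length(dd$excluded_hubs), sum(deg >= 1))
  expect_gte(length(dd$excluded_hubs), 1)
  # slope estimation is invariant to the logarithm base
  fit_ln <- stats::lm(log(n) ~ log(k), data = dd$counts)
  expect_equal(unname(stats::coef(fit_ln)[2]), dd$fitted_slope, tolerance = 1e-9)

  # every metabolite with the same degree: single point, flagged, no fit
  uni <- metabolic_model(
    "uniform",
    list(metabolite("A_c0"), metabolite("B_c0")),
    list(reaction("r1", c(A_c0 = -1, B_c0 = 1)),
         reaction("r2", c(B_c0 = -1, A_c0 = 1))),
    "r1")
  dd_u <- degree_distribution(uni, hub_quantile = 1)
  expect_true(dd_u$single_point)
  expect_true(is.na(dd_u$fitted_slope))

  # active-only restriction needs an FVA result
  expect_error(degree_distribution(m, active_only = TRUE), "fva_result")
})

test_that("model comparison matches by stoichiometric signature", {
  m <- core_model_cached()
  # a model against itself: everything shared, nothing unique
  cmp <- compare_models(list(a = m, b = m))
  expect_equal(cmp$reactions$region, "a&b")
  expect_equal(cmp$metabolites$region, "a&b")

  # adding one reaction yields exactly one unique entry
  m2 <- m
  m2$reactions[["purine_salvage"]] <- reaction(
    "purine_salvage", c(atp_c0 = -1, h2o_c0 = -1, adp_c0 = 1, pi_c0 = 1,
                        gly_c0 = -1, ser_c0 = 1, co2_c0 = -1))
  m2$id <- "with_salvage"
  cmp2 <- compare_models(list(base = m, salvage = m2))
  expect_equal(cmp2$reactions$count[cmp2$reactions$region == "salvage"], 1)
  expect_false("base" %in% cmp2$reactions$region)

  # identical chemistry under different ids and compartment tags is shared
  ra <- reaction("rxn00001_c0", c(glc_c0 = -1, atp_c0 = -1, g6p_c0 = 1,
                                  adp_c0 = 1, h_c0 = 1))
  rb <- reaction("HEX1", c(glc_c1 = -1, atp_c1 = -1, g6p_c1 = 1,
                           adp_c1 = 1, h_c1 = 1))
  ma <- metabolic_model("ma", lapply(names(ra$stoichiometry), metabolite),
                        list(ra), "rxn00001_c0")
  mb <- metabolic_model("mb", lapply(names(rb$stoichiometry), metabolite),
                        list(rb), "HEX1")
  cmp3 <- compare_models(list(ma = ma, mb = mb))
  expect_equal(cmp3$reactions$region, "ma&mb")
  expect_equal(cmp3$reactions$count, 1)
})
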