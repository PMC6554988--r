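test_that("fba solves the linear chain and the two-route diamond", {
  sol <- fba(chain_model(cap = 10))
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 10)
  expect_lt(mass_balance_residual(chain_model(10), sol), 1e-6)

  # diamond: the sink optimum is the sum of the two route capacities
  # (oracle: exhaustive enumeration of the same LP)
  d <- diamond_model(cap1 = 3, cap2 = 7)
  sol <- fba(d)
  dat <- lp_pieces(d)
  oracle <- enumerate_lp_optimum(dat$S, rep(0, nrow(dat$S)),
                                 as.numeric(dat$ids == "EX_D"),
                                 dat$lb, dat$ub, "max")
  expect_equal(sol$objective_value, oracle$objective, tolerance = 1e-9)
  expect_equal(sol$objective_value, 10)
})

test_that("fba returns statuses for infeasible and unbounded systems", {
  m <- chain_model()
  # force contradictory flux requirements
  sol <- fba(m, extra_bounds = list(EX_B = c(20, 30)))
  expect_equal(sol$status, "infeasible")
  expect_null(sol$fluxes)
  # an internal loop with open bounds on both directions is unbounded
  loop <- metabolic_model(
    "loop", list(metabolite("C_c0"), metabolite("D_c0")),
    list(reaction("f", c(C_c0 = -1, D_c0 = 1), -Inf, Inf),
         reaction("g", c(D_c0 = -1, C_c0 = 1), -Inf, Inf)),
    "f")
  expect_equal(fba(loop, "f")$status, "unbounded")
})

test_that("pfba retains the optimum, minimizes flux and silences loops", {
  # two parallel identical routes: total |v| equals the single-route total
  d <- diamond_model(cap1 = 10, cap2 = 10)
  d <- set_bounds(d, "EX_A", lb = -6, ub = 0)
  p <- pfba(d)
  f <- fba(d)
  expect_equal(p$objective_value, f$objective_value, tolerance = 1e-5)
  expect_lte(total_flux(p), total_flux(f) + 1e-6)
  expect_equal(total_flux(p), 4 * 6, tolerance = 1e-6)  # in, split, join, out

  # futile cycle C->D->C carries zero pfba flux
  m <- metabolic_model(
    "cyc",
    list(metabolite("A_c0"), metabolite("C_c0"), metabolite("D_c0")),
    list(reaction("EX_A", c(A_c0 = -1), -5, 0),
         reaction("use", c(A_c0 = -1, C_c0 = 1), 0, 1000),
         reaction("f", c(C_c0 = -1, D_c0 = 1), -1000, 1000),
         reaction("g", c(D_c0 = -1, C_c0 = 1), -1000, 1000),
         reaction("EX_C", c(C_c0 = -1), 0, 1000)),
    "EX_C")
  p <- pfba(m)
  expect_equal(p$objective_value, 5, tolerance = 1e-5)
  expect_equal(unname(p$fluxes[["f"]] + p$fluxes[["g"]]), 0, tolerance = 1e-6)
  expect_equal(unname(abs(p$fluxes[["f"]])), 0, tolerance = 1e-6)
})

test_that("fva brackets fluxes at the optimum", {
  # a dead-end reaction is blocked: (0, 0)
  m <- metabolic_model(
    "dead",
    list(metabolite("A_c0"), metabolite("B_c0"), metabolite("Z_c0")),
    list(reaction("EX_A", c(A_c0 = -1), -5, 0),
         reaction("r", c(A_c0 = -1, B_c0 = 1), 0, 1000),
         reaction("dead", c(A_c0 = -1, Z_c0 = 1), 0, 1000),
         reaction("EX_B", c(B_c0 = -1), 0, 1000)),
    "EX_B")
  res <- fva(m, "EX_B", fraction = 1)
  expect_equal(res$min[res$reaction == "dead"], 0, tolerance = 1e-9)
  expect_equal(res$max[res$reaction == "dead"], 0, tolerance = 1e-9)
  # a fixed exchange stays at its pinned value
  res2 <- fva(m, "EX_B", fraction = 1, extra_bounds = list(EX_A = c(-5, -5)))
  expect_equal(res2$min[res2$reaction == "EX_A"], -5, tolerance = 1e-9)
  expect_equal(res2$max[res2$reaction == "EX_A"], -5, tolerance = 1e-9)
  # min <= max everywhere
  expect_true(all(res$min <= res$max + 1e-9))
})

test_that("essentiality distinguishes chains from redundant routes", {
  m <- chain_model()
  ess <- essential_reactions(m, "EX_B")
  expect_setequal(ess, c("EX_A", "R_AB", "EX_B"))

  d <- diamond_model(cap1 = 10, cap2 = 10)
  ess_d <- essential_reactions(d, "EX_D")
  # neither parallel branch is essential on its own
  expect_false(any(c("R1", "R2", "R3", "R4") %in% ess_d))
  expect_true(all(c("EX_A", "EX_D") %in% ess_d))

  dead <- set_bounds(chain_model(), "EX_A", lb = 0, ub = 0)
  expect_error(essential_reactions(dead, "EX_B"), "not positive")
})

test_that("essentiality and optima scale with the bounds", {
  d <- diamond_model(3, 7)
  lam <- 2.5
  d2 <- d
  for (id in names(d2$reactions)) {
    r <- d2$reactions[[id]]
    d2 <- set_bounds(d2, id, r$lower_bound * lam, r$upper_bound * lam)
  }
  expect_equal(fba(d2)$objective_value, lam * fba(d)$objective_value,
               tolerance = 1e-8)
  expect_setequal(essential_reactions(d2, "EX_D"),
                  essential_reactions(d, "EX_D"))
})

test_that("pareto sweeps flag infeasible grid points and stay monotone", {
  d <- diamond_model(cap1 = 3, cap2 = 7)
  # treat route 1 flux cap as "product": add an explicit secretion branch
  m <- metabolic_model(
    "prod",
    list(metabolite("A_c0"), metabolite("B_c0"), metabolite("P_c0")),
    list(reaction("EX_A", c(A_c0 = -1), -10, 0),
         reaction("grow", c(A_c0 = -1, B_c0 = 1), 0, 1000),
         reaction("make_p", c(A_c0 = -1, P_c0 = 1), 0, 1000),
         reaction("EX_B", c(B_c0 = -1), 0, 1000),
         reaction("EX_P", c(P_c0 = -1), 0, 1000)),
    "EX_B")
  ps <- pareto_sweep(m, "EX_B", product_exchange_id = "EX_P",
                     grid = c(0, 5, 10, 12), acceptor_exchange_id = "EX_A")
  expect_equal(ps$status, c("optimal", "optimal", "optimal", "infeasible"))
  expect_equal(ps$max_objective[1:3], c(10, 5, 0), tolerance = 1e-5)
  # objective at zero product bounds the rest
  expect_true(all(ps$max_objective[1] >= ps$max_objective[2:3]))
})
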