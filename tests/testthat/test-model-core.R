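test_that("metabolite and reaction constructors enforce their invariants", {
  m <- metabolite("atp_c0")
  expect_equal(m$compartment, "c0")
  expect_equal(metabolite("glc_e0")$compartment, "e0")
  expect_error(metabolite(""), "non-empty")

  r <- reaction("r1", c(A_c0 = -1, B_c0 = 2), 0, 10)
  expect_false(r$is_exchange)
  expect_true(reaction("EX_A", c(A_c0 = -1), -5, 0)$is_exchange)
  expect_error(reaction("bad", c(A_c0 = -1), lower_bound = 1, upper_bound = 0),
               "lower_bound")
  expect_error(reaction("bad", numeric(0)), "non-empty")
  expect_error(reaction("bad", c(A_c0 = 0)), "zero")
})

test_that("model validation rejects dangling references and bad bounds", {
  mets <- list(metabolite("A_c0"), metabolite("B_c0"))
  ok <- list(reaction("r1", c(A_c0 = -1, B_c0 = 1)),
             reaction("EX_A", c(A_c0 = -1), -10, 0))
  expect_silent(metabolic_model("ok", mets, ok, "r1"))

  dangling <- c(ok, list(reaction("r2", c(A_c0 = -1, Z_c0 = 1))))
  expect_error(metabolic_model("bad", mets, dangling, "r1"), "r2.*Z_c0")

  expect_error(metabolic_model("bad", mets, ok, "nope"), "objective")

  dup <- list(reaction("r1", c(A_c0 = -1, B_c0 = 1)),
              reaction("r1", c(B_c0 = -1, A_c0 = 1)))
  expect_error(metabolic_model("bad", mets, dup, "r1"), "duplicated")
})

test_that("stoichiometric matrix reproduces coefficients and layout", {
  m <- chain_model()
  S <- stoichiometric_matrix(m)
  expect_equal(dim(S), c(2L, 3L))
  expect_equal(colnames(S), c("EX_A", "R_AB", "EX_B"))
  # single conversion A -> B is the column (-1, +1)
  expect_equal(as.numeric(S[, "R_AB"]), c(-1, 1))
  # exchange reaction "A ->" is a single -1 entry
  expect_equal(as.numeric(S[, "EX_A"]), c(-1, 0))

  # column sums match per-reaction coefficient sums computed independently
  core <- core_model_cached()
  Sc <- stoichiometric_matrix(core)
  independent <- vapply(core$reactions, function(r) sum(r$stoichiometry), 0)
  expect_equal(unname(Matrix::colSums(Sc)), unname(independent))
})

test_that("bound editing helpers keep the model consistent", {
  m <- chain_model()
  m2 <- set_bounds(m, "R_AB", lb = 1, ub = 5)
  expect_equal(m2$reactions$R_AB$lower_bound, 1)
  expect_error(set_bounds(m, "R_AB", lb = 2, ub = 1), "lower_bound")
  expect_error(set_bounds(m, "nope", lb = 0), "unknown")
  expect_equal(knockout(m, "R_AB")$reactions$R_AB$upper_bound, 0)
  # original untouched
  expect_equal(m$reactions$R_AB$lower_bound, 0)
})

test_that("elemental bookkeeping parses formulas and flags imbalance", {
  expect_equal(unname(parse_formula("C4H6O2")[c("C", "H", "O")]), c(4, 6, 2))
  mets <- list(metabolite("A_c0", formula = "CH4"),
               metabolite("B_c0", formula = "CH2O"))
  bad <- metabolic_model(
    "imb", mets,
    list(reaction("r1", c(A_c0 = -1, B_c0 = 1))), "r1")
  imbal <- element_balance(bad)
  expect_true(any(abs(imbal["r1", ]) > 0))
})
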