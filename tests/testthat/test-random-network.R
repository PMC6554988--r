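test_that("generated networks are reproducible and leave the RNG alone", {
  a <- random_network(5, 7, seed = 42)
  b <- random_network(5, 7, seed = 42)
  expect_identical(a, b)
  c <- random_network(5, 7, seed = 43)
  expect_false(identical(a, c))

  set.seed(99); before <- runif(1)
  set.seed(99); invisible(random_network(5, 7, seed = 1)); after <- runif(1)
  expect_identical(before, after)
})

test_that("small random networks match the enumeration oracle", {
  for (s in 1:20) {
    net <- random_network(n_metabolites = 2L + (s %% 3L),
                          n_reactions = 5L + (s %% 4L), seed = s)
    dat <- lp_pieces(net)
    got <- fba(net, "EX_snk")
    want <- enumerate_lp_optimum(dat$S, rep(0, nrow(dat$S)),
                                 as.numeric(dat$ids == "EX_snk"),
                                 dat$lb, dat$ub, "max")
    expect_equal(got$objective_value, want$objective, tolerance = 1e-6)
    expect_lt(mass_balance_residual(net, got), 1e-6)
  }
})

test_that("scale-free generation recovers the target exponent", {
  # a handful of seeds at test scale; the full 20-seed recovery runs in the
  # acceptance suite
  sl <- vapply(1:5, function(s) {
    net <- random_network(3000, seed = s, mode = "scale_free", gamma = 2.5)
    degree_distribution(net)$fitted_slope
  }, 0)
  expect_true(all(abs(sl + 2.5) < 0.2))
})
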