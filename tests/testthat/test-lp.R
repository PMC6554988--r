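# The bounded-variable simplex is the package's own LP backend; it is
# checked here against two independent oracles: exhaustive enumeration of
# basic solutions, and pracma's textbook simplex.

test_that("solver statuses are reported, not thrown", {
  # unbounded ray
  r <- solve_lp(matrix(c(1, -1), 1, 2), 0, c(1, 0),
                c(-Inf, -Inf), c(Inf, Inf), "max")
  expect_equal(r$status, "unbounded")
  # infeasible equality
  r <- solve_lp(matrix(c(1, 1), 1, 2), 50, c(1, 0), c(0, 0), c(10, 10), "max")
  expect_equal(r$status, "infeasible")
  # inconsistent bounds
  r <- solve_lp(matrix(1, 1, 1), 0, 1, 2, 1, "max")
  expect_equal(r$status, "infeasible")
})

test_that("optimum matches the enumeration oracle on random bounded LPs", {
  set.seed(101)
  for (trial in 1:60) {
    m <- sample(1:5, 1); n <- m + sample(1:4, 1)
    A <- matrix(sample(-2:2, m * n, replace = TRUE), m, n)
    b <- as.numeric(A %*% runif(n, -1, 1))
    lb <- runif(n, -3, 0); ub <- lb + runif(n, 0, 4)
    fix <- runif(n) < 0.2; ub[fix] <- lb[fix]
    obj <- rnorm(n)
    got <- solve_lp(A, b, obj, lb, ub, "max")
    want <- enumerate_lp_optimum(A, b, obj, lb, ub, "max")
    if (got$status == "optimal") {
      expect_lt(abs(got$objective - want$objective), 1e-6)
      expect_lt(max(abs(A %*% got$x - b)), 1e-6)
      expect_true(all(got$x >= lb - 1e-8 & got$x <= ub + 1e-8))
    } else {
      expect_identical(want$objective, -Inf)
    }
  }
})

test_that("optimum agrees with pracma's simplex where both apply", {
  skip_if_not_installed("pracma")
  # pracma solves the canonical form max c'x s.t. A x <= b, x >= 0; our
  # solver sees the same problem through explicit slack variables
  set.seed(7)
  compared <- 0L
  for (trial in 1:20) {
    n <- sample(3:6, 1); m <- sample(2:4, 1)
    A <- matrix(sample(0:4, m * n, replace = TRUE), m, n)
    b <- as.numeric(A %*% runif(n, 0.2, 1)) + runif(m, 0, 2)
    obj <- runif(n, 0.1, 2)
    ref <- tryCatch(
      pracma::linprog(obj, A = A, b = b, maximize = TRUE, maxiter = 500),
      error = function(e) NULL)
    if (is.null(ref) || ref$errno != 1) next
    got <- solve_lp(cbind(A, diag(m)), b, c(obj, rep(0, m)),
                    rep(0, n + m), rep(Inf, n + m), "max")
    expect_equal(got$status, "optimal")
    expect_lt(abs(got$objective - ref$fval), 1e-6)
    compared <- compared + 1L
  }
  expect_gte(compared, 5L)
})

test_that("minimize and maximize are consistent", {
  A <- matrix(c(1, 1), 1, 2)
  lo <- solve_lp(A, 2, c(1, 3), c(0, 0), c(10, 10), "min")
  hi <- solve_lp(A, 2, c(-1, -3), c(0, 0), c(10, 10), "max")
  expect_equal(lo$objective, -hi$objective, tolerance = 1e-9)
  expect_equal(lo$objective, 2)
})
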