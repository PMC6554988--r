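#' Solve a bounded linear program
#'
#' The single "solve LP" contract behind every flux computation in the
#' package: optimize \code{obj' x} subject to \code{A x = b} and
#' \code{lb <= x <= ub}. The default backend is a dense two-phase
#' bounded-variable primal simplex with Dantzig pricing and a Bland's-rule
#' anti-cycling fallback. The basis inverse is refactorized from scratch at
#' every iteration, trading speed for numerical freshness; this is entirely
#' adequate at the problem sizes of core metabolic models (tens to a few
#' hundred reactions).
#'
#' @param A Constraint matrix (dense or \code{Matrix} sparse), m x n.
#' @param b Right-hand side, length m.
#' @param obj Objective coefficients, length n.
#' @param lb,ub Variable bounds, length n; \code{-Inf}/\code{Inf} allowed.
#' @param sense \code{"max"} or \code{"min"}.
#' @param tol Optimality/feasibility tolerance on reduced costs and residuals.
#' @return A list with \code{status} (\code{"optimal"}, \code{"infeasible"}
#'   or \code{"unbounded"}), \code{objective} (the optimal value, \code{NA}
#'   unless optimal) and \code{x} (a primal optimum, \code{NULL} unless
#'   optimal).
#' @export
solve_lp <- function(A, b, obj, lb, ub, sense = c("max", "min"), tol = 1e-9) {
  sense <- match.arg(sense)
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(b) == m, length(obj) == n, length(lb) == n, length(ub) == n)
  if (any(lb > ub)) {
    return(list(status = "infeasible", objective = NA_real_, x = NULL))
  }
  cvec <- if (sense == "max") as.numeric(obj) else -as.numeric(obj)

  if (m == 0L) {
    # pure box problem
    x <- ifelse(cvec > 0, ub, ifelse(cvec < 0, lb, pmin(pmax(0, lb), ub)))
    if (any(!is.finite(x) & cvec != 0)) {
      return(list(status = "unbounded", objective = NA_real_, x = NULL))
    }
    x[!is.finite(x)] <- 0
    val <- sum(cvec * x)
    return(list(status = "optimal",
                objective = if (sense == "max") val else -val, x = x))
  }

  # -- extended problem with one artificial per row ---------------------------
  # nonbasic start: lower bound if finite, else upper, else free at 0
  start_status <- ifelse(is.finite(lb), 1L, ifelse(is.finite(ub), 2L, 3L))
  start_value <- ifelse(start_status == 1L, lb, ifelse(start_status == 2L, ub, 0))
  r0 <- as.numeric(b - A %*% start_value)
  art_sign <- ifelse(r0 >= 0, 1, -1)
  Aext <- cbind(A, diag(art_sign, nrow = m))
  lbe <- c(lb, rep(0, m))
  ube <- c(ub, rep(Inf, m))

  st <- integer(n + m)           # 0 basic, 1 at lb, 2 at ub, 3 free at 0
  st[seq_len(n)] <- start_status
  basis <- n + seq_len(m)
  st[basis] <- 0L

  core <- function(cext, basis, st, phase) {
    niter <- 0L
    max_iter <- 1000L + 200L * (n + m)
    bland_after <- 50L + 10L * (n + m)
    repeat {
      niter <- niter + 1L
      if (niter > max_iter) {
        stop("simplex iteration limit reached (", max_iter, ")")
      }
      Bmat <- Aext[, basis, drop = FALSE]
      Binv <- tryCatch(solve(Bmat), error = function(e) NULL)
      if (is.null(Binv)) stop("singular simplex basis encountered")
      nb <- which(st != 0L)
      xN <- ifelse(st[nb] == 1L, lbe[nb], ifelse(st[nb] == 2L, ube[nb], 0))
      rhs <- b - as.numeric(Aext[, nb, drop = FALSE] %*% xN)
      xB <- as.numeric(Binv %*% rhs)
      y <- as.numeric(crossprod(Binv, cext[basis]))
      d <- cext[nb] - as.numeric(crossprod(Aext[, nb, drop = FALSE], y))

      up_ok <- (st[nb] == 1L | st[nb] == 3L) & d > tol
      dn_ok <- (st[nb] == 2L | st[nb] == 3L) & d < -tol
      cand <- which(up_ok | dn_ok)
      if (length(cand) == 0L) {
        return(list(basis = basis, st = st, xB = xB, status = "optimal"))
      }
      if (niter > bland_after) {
        k <- cand[which.min(nb[cand])]
      } else {
        k <- cand[which.max(abs(d[cand]))]
      }
      e <- nb[k]
      dir <- if (d[k] > 0) 1 else -1

      w <- as.numeric(Binv %*% Aext[, e])
      delta <- dir * w
      # movement limits from basic variables
      tmax_basic <- Inf; leave <- NA_integer_; leave_to <- NA_integer_
      for (i in seq_len(m)) {
        if (delta[i] > 1e-10) {
          if (is.finite(lbe[basis[i]])) {
            ti <- (xB[i] - lbe[basis[i]]) / delta[i]
            if (ti < tmax_basic - 1e-12) { tmax_basic <- ti; leave <- i; leave_to <- 1L }
          }
        } else if (delta[i] < -1e-10) {
          if (is.finite(ube[basis[i]])) {
            ti <- (ube[basis[i]] - xB[i]) / (-delta[i])
            if (ti < tmax_basic - 1e-12) { tmax_basic <- ti; leave <- i; leave_to <- 2L }
          }
        }
      }
      tmax_basic <- max(tmax_basic, 0)
      # entering variable's own opposite bound
      t_self <- if (st[e] == 1L && is.finite(ube[e])) {
        ube[e] - lbe[e]
      } else if (st[e] == 2L && is.finite(lbe[e])) {
        ube[e] - lbe[e]
      } else Inf

      if (!is.finite(t_self) && !is.finite(tmax_basic)) {
        if (phase == 1L) stop("phase-1 subproblem unbounded (internal error)")
        return(list(status = "unbounded"))
      }
      if (t_self <= tmax_basic) {
        st[e] <- if (st[e] == 1L) 2L else 1L      # bound flip
      } else {
        st[e] <- 0L
        st[basis[leave]] <- leave_to
        basis[leave] <- e
      }
    }
  }

  # phase 1: drive artificials to zero
  c1 <- c(rep(0, n), rep(-1, m))
  res1 <- core(c1, basis, st, phase = 1L)
  art <- n + seq_len(m)
  x1 <- full_solution(res1, lbe, ube, n + m)
  if (sum(x1[art]) > 1e-7) {
    return(list(status = "infeasible", objective = NA_real_, x = NULL))
  }
  # pin artificials at zero for phase 2
  ube[art] <- 0
  st2 <- res1$st
  st2[art][st2[art] == 3L] <- 1L
  res2 <- core(c(cvec, rep(0, m)), res1$basis, st2, phase = 2L)
  if (identical(res2$status, "unbounded")) {
    return(list(status = "unbounded", objective = NA_real_, x = NULL))
  }
  xfull <- full_solution(res2, lbe, ube, n + m)
  x <- xfull[seq_len(n)]
  val <- sum(cvec * x)
  list(status = "optimal",
       objective = if (sense == "max") val else -val, x = x)
}

full_solution <- function(res, lbe, ube, ntot) {
  x <- numeric(ntot)
  nb <- which(res$st != 0L)
  x[nb] <- ifelse(res$st[nb] == 1L, lbe[nb],
                  ifelse(res$st[nb] == 2L, ube[nb], 0))
  x[res$basis] <- res$xB
  x
}

#' Brute-force reference optimum of a bounded LP
#'
#' Independent oracle for [solve_lp()]: enumerates every basic solution of
#' \code{A x = b, lb <= x <= ub} (all choices of basic variable subsets, all
#' bound assignments of the nonbasic variables), keeps the feasible ones and
#' returns the best objective. Exponential in the variable count; intended
#' for networks of at most ~8 reactions.
#'
#' @inheritParams solve_lp
#' @param feas_tol Feasibility tolerance on constraint residuals and bounds.
#' @return A list with \code{objective} (best feasible basic-solution value,
#'   \code{-Inf} if none found) and \code{x} (an attaining point or NULL).
#' @export
enumerate_lp_optimum <- function(A, b, obj, lb, ub, sense = c("max", "min"),
                                 feas_tol = 1e-8) {
  sense <- match.arg(sense)
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  if (n > 14L) stop("enumeration oracle is limited to small problems")
  sgn <- if (sense == "max") 1 else -1
  best <- -Inf; best_x <- NULL
  consider <- function(x) {
    if (any(x < lb - feas_tol) || any(x > ub + feas_tol)) return()
    if (m > 0 && max(abs(A %*% x - b)) > feas_tol) return()
    val <- sgn * sum(obj * x)
    if (val > best) { best <<- val; best_x <<- x }
  }
  r <- if (m > 0) qr(A)$rank else 0L
  subsets <- if (r == 0L) list(integer(0)) else {
    asplit(utils::combn(n, r), 2L)
  }
  for (Bset in subsets) {
    Bset <- as.integer(Bset)
    Nset <- setdiff(seq_len(n), Bset)
    AB <- A[, Bset, drop = FALSE]
    if (r > 0L && qr(AB)$rank < r) next
    # nonbasic variables at each finite bound (free ones at 0)
    choices <- lapply(Nset, function(j) {
      v <- unique(c(if (is.finite(lb[j])) lb[j], if (is.finite(ub[j])) ub[j]))
      if (length(v) == 0L) 0 else v
    })
    grid_idx <- rep(1L, length(Nset))
    repeat {
      x <- numeric(n)
      if (length(Nset)) {
        x[Nset] <- mapply(function(ch, k) ch[[k]], choices, grid_idx)
      }
      if (r > 0L) {
        rhs <- b - if (length(Nset)) A[, Nset, drop = FALSE] %*% x[Nset] else b * 0
        xb <- tryCatch(qr.solve(AB, rhs), error = function(e) NULL)
        if (!is.null(xb)) { x[Bset] <- xb; consider(x) }
      } else {
        consider(x)
      }
      # advance the mixed-radix counter over bound choices
      pos <- 1L
      while (pos <= length(Nset)) {
        grid_idx[pos] <- grid_idx[pos] + 1L
        if (grid_idx[pos] <= length(choices[[pos]])) break
        grid_idx[pos] <- 1L
        pos <- pos + 1L
      }
      if (pos > length(Nset)) break
      if (length(Nset) == 0L) break
    }
  }
  list(objective = if (is.finite(best)) sgn * best else -Inf, x = best_x)
}
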