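# Assemble LP data (dense S, bounds, ids) from a model plus bound overrides.
lp_data <- function(model, extra_bounds = NULL) {
  S <- as.matrix(stoichiometric_matrix(model))
  bounds <- reaction_bounds(model)
  if (!is.null(extra_bounds)) {
    if (is.null(names(extra_bounds))) stop("extra_bounds must be named by reaction id")
    for (id in names(extra_bounds)) {
      if (!id %in% rownames(bounds)) stop("extra_bounds: unknown reaction id: ", id)
      eb <- extra_bounds[[id]]
      if (length(eb) != 2L || eb[1] > eb[2]) {
        stop("extra_bounds for '", id, "' must be c(lb, ub) with lb <= ub")
      }
      bounds[id, ] <- as.numeric(eb)
    }
  }
  list(S = S, lb = bounds[, "lb"], ub = bounds[, "ub"],
       rxn_ids = colnames(S), met_ids = rownames(S))
}

new_flux_solution <- function(status, objective_value = NA_real_, fluxes = NULL) {
  structure(list(status = status, objective_value = objective_value,
                 fluxes = fluxes),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> status: ", x$status, sep = "")
  if (identical(x$status, "optimal")) {
    cat("   objective: ", format(x$objective_value, digits = 8), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Flux balance analysis
#'
#' Optimizes the flux of one reaction subject to steady-state mass balance
#' \code{S v = 0} and the flux bounds. The objective value is deterministic
#' for a fixed model; the flux vector may be one of multiple alternate
#' optima (use [pfba()] when individual fluxes are reported).
#'
#' @param model A [metabolic_model()].
#' @param objective_id Reaction whose flux is optimized; defaults to the
#'   model's objective (the biomass reaction).
#' @param sense \code{"max"} or \code{"min"}.
#' @param extra_bounds Named list of \code{c(lb, ub)} overrides applied on
#'   top of the model bounds for this solve only.
#' @return A \code{flux_solution}: \code{status} (\code{"optimal"},
#'   \code{"infeasible"}, \code{"unbounded"}), \code{objective_value}, and
#'   (if optimal) the named flux vector \code{fluxes}.
#' @export
fba <- function(model, objective_id = model$objective_id,
                sense = c("max", "min"), extra_bounds = NULL) {
  sense <- match.arg(sense)
  dat <- lp_data(model, extra_bounds)
  if (!objective_id %in% dat$rxn_ids) stop("unknown objective reaction: ", objective_id)
  obj <- as.numeric(dat$rxn_ids == objective_id)
  res <- solve_lp(dat$S, rep(0, nrow(dat$S)), obj, dat$lb, dat$ub, sense)
  if (!identical(res$status, "optimal")) {
    return(new_flux_solution(res$status))
  }
  fluxes <- stats::setNames(res$x, dat$rxn_ids)
  new_flux_solution("optimal", res$objective, fluxes)
}

#' Parsimonious flux balance analysis
#'
#' Among flux vectors attaining at least \code{(1 - eps)} of the FBA optimum,
#' returns one minimizing the total absolute flux. Reversible reactions are
#' split into two nonnegative half-variables; the reported flux is their
#' difference. Futile cycles carry zero flux in the returned vector, which
#' makes individual fluxes reportable.
#'
#' @inheritParams fba
#' @param eps Relative optimality slack retained during the norm
#'   minimization (default \code{1e-6}).
#' @return A \code{flux_solution}; \code{objective_value} is the flux of
#'   \code{objective_id} in the parsimonious solution (equal to the FBA
#'   optimum within \code{eps}).
#' @export
pfba <- function(model, objective_id = model$objective_id,
                 sense = c("max", "min"), extra_bounds = NULL, eps = 1e-6) {
  sense <- match.arg(sense)
  first <- fba(model, objective_id, sense, extra_bounds)
  if (!identical(first$status, "optimal")) return(first)
  opt <- first$objective_value
  dat <- lp_data(model, extra_bounds)
  # pin the objective flux to within eps of its optimum
  slack <- eps * max(1, abs(opt))
  k <- match(objective_id, dat$rxn_ids)
  if (sense == "max") {
    dat$lb[k] <- max(dat$lb[k], opt - slack)
  } else {
    dat$ub[k] <- min(dat$ub[k], opt + slack)
  }
  n <- length(dat$rxn_ids)
  # build split variables: forward-only and backward-only reactions stay
  # single variables; genuinely reversible ones get two nonnegative halves
  cols <- list(); lb2 <- numeric(0); ub2 <- numeric(0); cobj <- numeric(0)
  map <- vector("list", n)
  for (j in seq_len(n)) {
    lj <- dat$lb[j]; uj <- dat$ub[j]
    if (lj >= 0) {
      cols[[length(cols) + 1L]] <- dat$S[, j]
      lb2 <- c(lb2, lj); ub2 <- c(ub2, uj); cobj <- c(cobj, 1)
      map[[j]] <- c(length(cols), NA)
    } else if (uj <= 0) {
      cols[[length(cols) + 1L]] <- dat$S[, j]
      lb2 <- c(lb2, lj); ub2 <- c(ub2, uj); cobj <- c(cobj, -1)
      map[[j]] <- c(length(cols), NA)
    } else {
      cols[[length(cols) + 1L]] <- dat$S[, j]
      lb2 <- c(lb2, 0); ub2 <- c(ub2, uj); cobj <- c(cobj, 1)
      p <- length(cols)
      cols[[length(cols) + 1L]] <- -dat$S[, j]
      lb2 <- c(lb2, 0); ub2 <- c(ub2, -lj); cobj <- c(cobj, 1)
      map[[j]] <- c(p, length(cols))
    }
  }
  A <- do.call(cbind, cols)
  res <- solve_lp(A, rep(0, nrow(A)), cobj, lb2, ub2, "min")
  if (!identical(res$status, "optimal")) {
    # should not happen: the FBA optimum is feasible for the split problem
    return(new_flux_solution(res$status))
  }
  v <- vapply(map, function(mp) {
    if (is.na(mp[2])) res$x[mp[1]] else res$x[mp[1]] - res$x[mp[2]]
  }, 0)
  fluxes <- stats::setNames(v, dat$rxn_ids)
  new_flux_solution("optimal", unname(fluxes[objective_id]), fluxes)
}

#' Total absolute flux of a solution
#' @param solution A \code{flux_solution}.
#' @return Sum of absolute fluxes.
#' @export
total_flux <- function(solution) {
  if (!identical(solution$status, "optimal")) return(NA_real_)
  sum(abs(solution$fluxes))
}

#' Flux variability analysis
#'
#' Per-reaction minimum and maximum flux subject to the objective flux
#' retaining at least \code{fraction} of its optimum. Reactions with a zero
#' flux range (both extremes 0) are blocked at the given optimality
#' fraction; those with any nonzero attainable flux form the "active"
#' sub-network under (near-)optimal growth.
#'
#' @inheritParams fba
#' @param fraction Fraction of the optimum to retain, in (0, 1].
#' @param reactions Reaction ids to scan (default: all).
#' @return A data frame with columns \code{reaction}, \code{min}, \code{max}.
#' @export
fva <- function(model, objective_id = model$objective_id, fraction = 1.0,
                extra_bounds = NULL, reactions = NULL) {
  stopifnot(fraction > 0, fraction <= 1)
  first <- fba(model, objective_id, "max", extra_bounds)
  if (!identical(first$status, "optimal")) {
    stop("fva: base FBA is ", first$status)
  }
  opt <- first$objective_value
  dat <- lp_data(model, extra_bounds)
  k <- match(objective_id, dat$rxn_ids)
  thr <- if (opt >= 0) fraction * opt else opt
  dat$lb[k] <- max(dat$lb[k], thr)
  if (is.null(reactions)) reactions <- dat$rxn_ids
  b0 <- rep(0, nrow(dat$S))
  out <- data.frame(reaction = reactions, min = NA_real_, max = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(reactions)) {
    j <- match(reactions[i], dat$rxn_ids)
    if (is.na(j)) stop("fva: unknown reaction id: ", reactions[i])
    obj <- numeric(length(dat$rxn_ids)); obj[j] <- 1
    lo <- solve_lp(dat$S, b0, obj, dat$lb, dat$ub, "min")
    hi <- solve_lp(dat$S, b0, obj, dat$lb, dat$ub, "max")
    out$min[i] <- if (identical(lo$status, "optimal")) lo$objective else NA_real_
    out$max[i] <- if (identical(hi$status, "optimal")) hi$objective else NA_real_
  }
  out
}

#' Reaction essentiality by single-reaction knockout
#'
#' A reaction is essential when forcing its flux to zero abolishes biomass
#' production from the carbon source: the knockout optimum falls below
#' \code{threshold} times the wild-type optimum. The default threshold
#' \code{1e-6} is a numerically robust reading of "no biomass production
#' possible".
#'
#' @inheritParams fba
#' @param threshold Relative growth cutoff below which a knockout counts as
#'   lethal.
#' @param reactions Reaction ids to test (default: all).
#' @return Character vector of essential reaction ids.
#' @export
essential_reactions <- function(model, objective_id = model$objective_id,
                                threshold = 1e-6, extra_bounds = NULL,
                                reactions = NULL) {
  wt <- fba(model, objective_id, "max", extra_bounds)
  if (!identical(wt$status, "optimal") || wt$objective_value <= 0) {
    stop("essentiality is undefined: wild-type optimum is not positive")
  }
  if (is.null(reactions)) reactions <- names(model$reactions)
  ess <- logical(length(reactions))
  for (i in seq_along(reactions)) {
    id <- reactions[i]
    eb <- extra_bounds
    eb[[id]] <- c(0, 0)
    ko <- fba(model, objective_id, "max", eb)
    g <- if (identical(ko$status, "optimal")) ko$objective_value else 0
    ess[i] <- g < threshold * wt$objective_value
  }
  reactions[ess]
}

#' Two-objective Pareto sweep
#'
#' Fixes the secretion of a product at each grid value, maximizes the
#' objective, and records the consumption of an electron acceptor from the
#' parsimonious optimal solution. Infeasible grid points are reported as
#' such, never dropped.
#'
#' @inheritParams fba
#' @param product_exchange_id Exchange reaction of the forced product
#'   (positive flux = secretion).
#' @param grid Numeric vector of forced secretion amounts; if \code{NULL},
#'   21 evenly spaced points from 0 to the product's stoichiometric maximum
#'   (found by maximizing the product first).
#' @param acceptor_exchange_id Exchange reaction of the electron acceptor;
#'   consumption is reported as a nonnegative number (uptake is negative
#'   flux).
#' @return A data frame of Pareto points: \code{forced_product},
#'   \code{max_objective}, \code{acceptor_consumed}, \code{status}.
#' @export
pareto_sweep <- function(model, objective_id = model$objective_id,
                         product_exchange_id, grid = NULL,
                         acceptor_exchange_id, extra_bounds = NULL) {
  if (!product_exchange_id %in% names(model$reactions)) {
    stop("unknown product exchange: ", product_exchange_id)
  }
  if (!acceptor_exchange_id %in% names(model$reactions)) {
    stop("unknown acceptor exchange: ", acceptor_exchange_id)
  }
  if (is.null(grid)) {
    pm <- fba(model, product_exchange_id, "max", extra_bounds)
    if (!identical(pm$status, "optimal")) {
      stop("cannot establish the product's stoichiometric maximum: ", pm$status)
    }
    grid <- seq(0, pm$objective_value, length.out = 21L)
  }
  if (any(grid < 0)) stop("grid values must be nonnegative")
  out <- data.frame(forced_product = grid, max_objective = NA_real_,
                    acceptor_consumed = NA_real_, status = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(grid)) {
    eb <- extra_bounds
    eb[[product_exchange_id]] <- c(grid[i], grid[i])
    sol <- pfba(model, objective_id, "max", eb)
    out$status[i] <- sol$status
    if (identical(sol$status, "optimal")) {
      out$max_objective[i] <- sol$objective_value
      out$acceptor_consumed[i] <- max(0, -sol$fluxes[[acceptor_exchange_id]])
    }
  }
  out
}

#' Mass-balance residual of a flux solution
#'
#' @param model A [metabolic_model()].
#' @param solution A \code{flux_solution} on the same model.
#' @return \code{max_i |(S v)_i|}, the worst metabolite imbalance.
#' @export
mass_balance_residual <- function(model, solution) {
  if (!identical(solution$status, "optimal")) return(NA_real_)
  S <- stoichiometric_matrix(model)
  v <- solution$fluxes[colnames(S)]
  max(abs(as.numeric(S %*% v)))
}
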