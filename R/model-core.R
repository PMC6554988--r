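#' @importFrom Matrix sparseMatrix
NULL

#' Create a metabolite
#'
#' Metabolites carry SEED-style identifiers in which the compartment is a
#' suffix of the id itself (e.g. \code{"cpd00011_c0"} for cytosolic CO2,
#' \code{"ch4_e0"} for extracellular methane). The suffix is kept as part of
#' the id and additionally parsed into the \code{compartment} field.
#'
#' @param id Unique metabolite identifier, non-empty string.
#' @param name Human-readable name; defaults to the id.
#' @param compartment Compartment label. If \code{NULL}, parsed from a
#'   trailing \code{"_<letter><digits>"} suffix of the id (e.g. \code{"c0"}).
#' @param formula Optional elemental formula string (e.g. \code{"C4H6O2"}).
#' @param charge Optional integer charge.
#' @return An object of class \code{"mf_metabolite"}.
#' @export
metabolite <- function(id, name = id, compartment = NULL, formula = NA_character_,
                       charge = NA_integer_) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("metabolite id must be a non-empty string")
  }
  if (is.null(compartment)) {
    compartment <- compartment_from_id(id)
  }
  structure(
    list(id = id, name = name, compartment = compartment,
         formula = as.character(formula), charge = as.integer(charge)),
    class = "mf_metabolite"
  )
}

# Parse a SEED-style compartment suffix ("_c0", "_e0", ...); "" if absent.
compartment_from_id <- function(id) {
  m <- regmatches(id, regexpr("_[a-z][0-9]+$", id))
  if (length(m) == 1L && nzchar(m)) sub("^_", "", m) else ""
}

#' Create a reaction
#'
#' Stoichiometry is a named numeric vector over metabolite ids; negative
#' coefficients are consumed, positive produced. Irreversibility is encoded
#' through bounds only: an irreversible reaction has \code{lower_bound = 0}.
#' Exchange reactions touch exactly one metabolite and follow the secretion
#' convention: \code{"met_e0 ->"} with positive flux = secretion, so uptake
#' is a negative flux enabled by a negative lower bound.
#'
#' @param id Unique reaction identifier.
#' @param stoichiometry Named numeric vector, metabolite id -> coefficient.
#' @param lower_bound,upper_bound Flux bounds in mmol g-DW^-1 h^-1 (the
#'   biomass reaction is in h^-1). Must satisfy \code{lower_bound <=
#'   upper_bound}.
#' @param name Human-readable name.
#' @param gene_association Optional boolean gene expression string.
#' @param ec_numbers Optional character vector of EC numbers.
#' @param is_exchange Exchange flag; by default detected as a single-metabolite
#'   reaction.
#' @return An object of class \code{"mf_reaction"}.
#' @export
reaction <- function(id, stoichiometry, lower_bound = 0, upper_bound = 1000,
                     name = id, gene_association = NA_character_,
                     ec_numbers = character(0), is_exchange = NULL) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("reaction id must be a non-empty string")
  }
  if (length(stoichiometry) == 0L) {
    stop("reaction '", id, "': stoichiometry must be non-empty")
  }
  if (is.null(names(stoichiometry)) || any(!nzchar(names(stoichiometry)))) {
    stop("reaction '", id, "': stoichiometry must be a named vector")
  }
  if (anyDuplicated(names(stoichiometry))) {
    stop("reaction '", id, "': duplicated metabolite in stoichiometry")
  }
  stoichiometry <- stoichiometry[stoichiometry != 0]
  if (length(stoichiometry) == 0L) {
    stop("reaction '", id, "': all stoichiometric coefficients are zero")
  }
  if (!is.numeric(lower_bound) || !is.numeric(upper_bound) ||
      lower_bound > upper_bound) {
    stop("reaction '", id, "': lower_bound must be <= upper_bound")
  }
  if (is.null(is_exchange)) is_exchange <- length(stoichiometry) == 1L
  structure(
    list(id = id, name = name, stoichiometry = stoichiometry,
         lower_bound = as.numeric(lower_bound),
         upper_bound = as.numeric(upper_bound),
         gene_association = gene_association, ec_numbers = ec_numbers,
         is_exchange = isTRUE(is_exchange)),
    class = "mf_reaction"
  )
}

#' Assemble a constraint-based metabolic model
#'
#' @param id Model identifier.
#' @param metabolites List of [metabolite()] objects.
#' @param reactions List of [reaction()] objects.
#' @param objective_id Reaction id carrying the objective role (typically the
#'   biomass reaction, scaled so that flux 1 equals a specific growth rate of
#'   1 h^-1).
#' @param validate Run [validate_model()] on the result (default TRUE).
#' @return An object of class \code{"metabolic_model"}: a list with named
#'   metabolite and reaction lists, the objective id and the compartment set.
#' @export
metabolic_model <- function(id, metabolites, reactions, objective_id,
                            validate = TRUE) {
  names(metabolites) <- vapply(metabolites, `[[`, "", "id")
  names(reactions) <- vapply(reactions, `[[`, "", "id")
  model <- structure(
    list(id = id, metabolites = metabolites, reactions = reactions,
         objective_id = objective_id,
         compartments = sort(unique(vapply(metabolites, `[[`, "", "compartment")))),
    class = "metabolic_model"
  )
  if (validate) validate_model(model)
  model
}

#' Validate a metabolic model
#'
#' Checks the structural invariants: unique non-empty metabolite and reaction
#' ids, no dangling metabolite references, bounds ordered, metabolite
#' compartments drawn from the declared compartment set, exchange reactions
#' touching exactly one metabolite, and the objective id present.
#'
#' @param model A [metabolic_model()].
#' @return The model, invisibly; errors describe the offending reaction.
#' @export
validate_model <- function(model) {
  met_ids <- names(model$metabolites)
  rxn_ids <- names(model$reactions)
  if (anyDuplicated(met_ids)) {
    stop("duplicated metabolite ids: ",
         paste(unique(met_ids[duplicated(met_ids)]), collapse = ", "))
  }
  if (anyDuplicated(rxn_ids)) {
    stop("duplicated reaction ids: ",
         paste(unique(rxn_ids[duplicated(rxn_ids)]), collapse = ", "))
  }
  comps <- vapply(model$metabolites, `[[`, "", "compartment")
  bad_comp <- comps[!comps %in% model$compartments]
  if (length(bad_comp)) {
    stop("metabolite compartment outside the declared set: ",
         paste(unique(bad_comp), collapse = ", "))
  }
  for (r in model$reactions) {
    missing <- setdiff(names(r$stoichiometry), met_ids)
    if (length(missing)) {
      stop("reaction '", r$id, "' references unknown metabolite(s): ",
           paste(missing, collapse = ", "))
    }
    if (r$lower_bound > r$upper_bound) {
      stop("reaction '", r$id, "': lower_bound > upper_bound")
    }
    if (r$is_exchange && length(r$stoichiometry) != 1L) {
      stop("exchange reaction '", r$id, "' must touch exactly one metabolite")
    }
  }
  if (length(model$objective_id) != 1L ||
      !model$objective_id %in% rxn_ids) {
    stop("objective_id must name exactly one existing reaction")
  }
  invisible(model)
}

#' Stoichiometric matrix
#'
#' @param model A [metabolic_model()].
#' @return A sparse \code{Matrix::dgCMatrix}, metabolites x reactions, entry
#'   (i, j) the signed coefficient of metabolite i in reaction j; column
#'   order follows the model's reaction order.
#' @export
stoichiometric_matrix <- function(model) {
  met_ids <- names(model$metabolites)
  rxn_ids <- names(model$reactions)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_along(model$reactions)) {
    st <- model$reactions[[j]]$stoichiometry
    ii <- c(ii, match(names(st), met_ids))
    jj <- c(jj, rep.int(j, length(st)))
    xx <- c(xx, unname(st))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(met_ids), length(rxn_ids)),
                       dimnames = list(met_ids, rxn_ids))
}

#' Modify flux bounds
#'
#' @param model A [metabolic_model()].
#' @param id Reaction id.
#' @param lb,ub New bounds; \code{NULL} leaves the bound unchanged.
#' @return The modified model.
#' @export
set_bounds <- function(model, id, lb = NULL, ub = NULL) {
  if (!id %in% names(model$reactions)) {
    stop("unknown reaction id: ", id)
  }
  r <- model$reactions[[id]]
  if (!is.null(lb)) r$lower_bound <- as.numeric(lb)
  if (!is.null(ub)) r$upper_bound <- as.numeric(ub)
  if (r$lower_bound > r$upper_bound) {
    stop("reaction '", id, "': lower_bound > upper_bound")
  }
  model$reactions[[id]] <- r
  model
}

#' Fix a reaction flux to a single value
#'
#' @inheritParams set_bounds
#' @param value Flux value to pin both bounds to.
#' @return The modified model.
#' @export
fix_flux <- function(model, id, value) {
  set_bounds(model, id, lb = value, ub = value)
}

#' Force a reaction to carry zero flux (reaction-level knockout)
#'
#' @inheritParams set_bounds
#' @return The modified model.
#' @export
knockout <- function(model, id) {
  fix_flux(model, id, 0)
}

#' Change the objective reaction
#'
#' @inheritParams set_bounds
#' @return The modified model.
#' @export
set_objective <- function(model, id) {
  if (!id %in% names(model$reactions)) stop("unknown reaction id: ", id)
  model$objective_id <- id
  model
}

#' Reaction bounds as a two-column matrix
#' @param model A [metabolic_model()].
#' @return Numeric matrix with columns \code{lb}, \code{ub}, one row per
#'   reaction, rownames the reaction ids.
#' @export
reaction_bounds <- function(model) {
  cbind(lb = vapply(model$reactions, `[[`, 0, "lower_bound"),
        ub = vapply(model$reactions, `[[`, 0, "upper_bound"))
}

#' Ids of exchange reactions
#' @param model A [metabolic_model()].
#' @return Character vector of reaction ids flagged as exchanges.
#' @export
exchange_reactions <- function(model) {
  names(model$reactions)[vapply(model$reactions, `[[`, TRUE, "is_exchange")]
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, "\n", sep = "")
  cat("  metabolites: ", length(x$metabolites),
      "   reactions: ", length(x$reactions),
      "   exchanges: ", length(exchange_reactions(x)), "\n", sep = "")
  cat("  compartments: ", paste(x$compartments, collapse = ", "), "\n", sep = "")
  cat("  objective: ", x$objective_id, "\n", sep = "")
  invisible(x)
}

#' @export
print.mf_reaction <- function(x, ...) {
  cat(x$id, ": ", reaction_equation(x), "  [", x$lower_bound, ", ",
      x$upper_bound, "]\n", sep = "")
  invisible(x)
}

#' Render a reaction equation string
#'
#' @param r An \code{mf_reaction}.
#' @return A string such as \code{"A_c0 + 2 B_c0 -> C_c0"}; reversible
#'   reactions (negative lower bound) use \code{"<=>"}.
#' @export
reaction_equation <- function(r) {
  st <- r$stoichiometry
  fmt <- function(v) {
    vapply(seq_along(v), function(i) {
      cf <- abs(v[[i]])
      if (cf == 1) names(v)[i] else paste(format(cf, digits = 15), names(v)[i])
    }, "")
  }
  lhs <- st[st < 0]; rhs <- st[st > 0]
  arrow <- if (r$lower_bound < 0) "<=>" else "->"
  paste(paste(fmt(lhs), collapse = " + "), arrow,
        paste(fmt(rhs), collapse = " + "))
}

# Parse an elemental formula such as "C4H6O2" into a named count vector.
parse_formula <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) return(numeric(0))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", formula)
  parts <- regmatches(formula, m)[[1]]
  el <- sub("^([A-Z][a-z]?).*$", "\\1", parts)
  n <- sub("^[A-Z][a-z]?", "", parts)
  n[n == ""] <- "1"
  out <- tapply(as.numeric(n), el, sum)
  stats::setNames(as.numeric(out), names(out))
}

#' Elemental imbalance of every non-exchange reaction
#'
#' Computes, per reaction, the net production of each element implied by the
#' stoichiometry and the metabolite formulas. Exchange reactions are exempt
#' (they are net system inputs/outputs by construction).
#'
#' @param model A [metabolic_model()].
#' @param elements Elements to check (default C, H, O, N).
#' @return Numeric matrix reactions x elements of net element production;
#'   all-zero rows are elementally balanced.
#' @export
element_balance <- function(model, elements = c("C", "H", "O", "N")) {
  formulas <- lapply(model$metabolites, function(m) parse_formula(m$formula))
  rxns <- model$reactions[!vapply(model$reactions, `[[`, TRUE, "is_exchange")]
  out <- matrix(0, nrow = length(rxns), ncol = length(elements),
                dimnames = list(vapply(rxns, `[[`, "", "id"), elements))
  for (i in seq_along(rxns)) {
    st <- rxns[[i]]$stoichiometry
    for (k in seq_along(st)) {
      f <- formulas[[names(st)[k]]]
      for (e in intersect(names(f), elements)) {
        out[i, e] <- out[i, e] + st[[k]] * f[[e]]
      }
    }
  }
  out
}
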