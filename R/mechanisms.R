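#' Define a methane-oxidation mechanism variant
#'
#' The electron donor of particulate methane monooxygenase (pMMO) is not
#' settled; three alternative mechanisms are modeled. \code{redox_arm}
#' couples methane oxidation to ubiquinol (regenerated from NADH by complex
#' I). \code{direct_coupling} couples it to cytochrome c (regenerated by
#' methanol dehydrogenase). \code{uphill} couples it to ubiquinol
#' regenerated from cytochrome c by reverse ("uphill") flux through complex
#' III, driven by the proton-motive force; it is expressed by opening the
#' complex III lower bound to negative flux while the ubiquinol-coupled
#' pMMO stoichiometry is active.
#'
#' @param name One of \code{"redox_arm"}, \code{"direct_coupling"},
#'   \code{"uphill"}.
#' @param id_map Role-to-reaction-id map (see [core_id_map()]); needs
#'   \code{pmmo_cytc}, \code{pmmo_ubiquinol} and \code{complex_iii}.
#' @param pmmo_ub Upper flux bound of the active pMMO (default 1000).
#' @return A \code{mechanism_variant}: the variant name, the enabled and
#'   disabled reaction sets, and reversibility overrides.
#' @export
mechanism_variant <- function(name = c("redox_arm", "direct_coupling", "uphill"),
                              id_map = core_id_map(), pmmo_ub = 1000) {
  name <- match.arg(name)
  need <- c("pmmo_cytc", "pmmo_ubiquinol", "complex_iii")
  if (!all(need %in% names(id_map))) {
    stop("id_map must define: ", paste(setdiff(need, names(id_map)), collapse = ", "))
  }
  pmmo1 <- id_map[["pmmo_cytc"]]; pmmo2 <- id_map[["pmmo_ubiquinol"]]
  c3 <- id_map[["complex_iii"]]
  ov <- switch(
    name,
    redox_arm = list(stats::setNames(list(c(0, pmmo_ub), c(0, 0), c(0, 1000)),
                                     c(pmmo2, pmmo1, c3)),
                     active = pmmo2, disabled = pmmo1),
    direct_coupling = list(stats::setNames(list(c(0, pmmo_ub), c(0, 0), c(0, 1000)),
                                           c(pmmo1, pmmo2, c3)),
                           active = pmmo1, disabled = pmmo2),
    uphill = list(stats::setNames(list(c(0, pmmo_ub), c(0, 0), c(-1000, 1000)),
                                  c(pmmo2, pmmo1, c3)),
                  active = pmmo2, disabled = pmmo1)
  )
  structure(list(name = name,
                 active_reactions = ov$active,
                 disabled_reactions = ov$disabled,
                 reversibility_overrides = ov[[1]]),
            class = "mechanism_variant")
}

#' Apply a mechanism variant to a model
#'
#' Returns a copy of the model with the variant's bounds set: exactly one
#' pMMO stoichiometry carries nonzero bounds, and complex III is reversible
#' only under the uphill variant. Applying a variant twice is idempotent;
#' the input model is not modified.
#'
#' @param model A [metabolic_model()] containing both pMMO reactions and the
#'   complex III reaction under the ids of the variant's id map.
#' @param variant A [mechanism_variant()] (or its name as a string).
#' @param id_map Used only when \code{variant} is given as a name.
#' @return The modified model copy.
#' @export
apply_mechanism <- function(model, variant, id_map = core_id_map()) {
  if (is.character(variant)) variant <- mechanism_variant(variant, id_map)
  stopifnot(inherits(variant, "mechanism_variant"))
  for (id in names(variant$reversibility_overrides)) {
    if (!id %in% names(model$reactions)) {
      stop("mechanism variant '", variant$name,
           "' needs reaction '", id, "', absent from the model")
    }
    b <- variant$reversibility_overrides[[id]]
    model <- set_bounds(model, id, lb = b[1], ub = b[2])
  }
  model
}

#' Predicted biomass yields under each methane-oxidation mechanism
#'
#' Fixes the methane uptake rate and the non-growth ATP maintenance flux,
#' maximizes biomass under each of the three mechanism variants, and
#' converts the growth rate to a yield on methane:
#' \code{yield = 1000 * mu / uptake_ch4} (g-DW per mol CH4).
#'
#' @param model A [metabolic_model()].
#' @param uptake_ch4 Methane uptake in mmol g-DW^-1 h^-1 (> 0); imposed as
#'   a negative lower/upper bound on the methane exchange.
#' @param ngam_atp Maintenance ATP flux in mmol g-DW^-1 h^-1 (>= 0).
#' @param id_map Role-to-reaction-id map.
#' @return Data frame with one row per variant: \code{variant},
#'   \code{growth_rate} (h^-1), \code{yield_gdw_per_mol} and
#'   \code{status}; an infeasible variant reports yield 0.
#' @export
mechanism_panel <- function(model, uptake_ch4, ngam_atp, id_map = core_id_map()) {
  stopifnot(uptake_ch4 > 0, ngam_atp >= 0)
  variants <- c("redox_arm", "direct_coupling", "uphill")
  out <- data.frame(variant = variants, growth_rate = NA_real_,
                    yield_gdw_per_mol = 0, status = NA_character_,
                    stringsAsFactors = FALSE)
  eb <- stats::setNames(list(c(-uptake_ch4, -uptake_ch4), c(ngam_atp, ngam_atp)),
                        c(id_map[["ex_ch4"]], id_map[["atp_maintenance"]]))
  for (i in seq_along(variants)) {
    m <- apply_mechanism(model, variants[i], id_map)
    sol <- fba(m, id_map[["biomass"]], "max", eb)
    out$status[i] <- sol$status
    if (identical(sol$status, "optimal")) {
      out$growth_rate[i] <- sol$objective_value
      out$yield_gdw_per_mol[i] <- 1000 * sol$objective_value / uptake_ch4
    }
  }
  out
}

#' Molar oxygen/methane consumption ratio at the biomass optimum
#'
#' @param model A model with a mechanism variant already applied (see
#'   [apply_mechanism()]).
#' @inheritParams mechanism_panel
#' @return \code{|O2 exchange flux| / |CH4 exchange flux|} at the
#'   parsimonious biomass optimum (mol O2 per mol CH4).
#' @export
oxygen_methane_ratio <- function(model, uptake_ch4, ngam_atp,
                                 id_map = core_id_map()) {
  stopifnot(uptake_ch4 > 0, ngam_atp >= 0)
  eb <- stats::setNames(list(c(-uptake_ch4, -uptake_ch4), c(ngam_atp, ngam_atp)),
                        c(id_map[["ex_ch4"]], id_map[["atp_maintenance"]]))
  sol <- pfba(model, id_map[["biomass"]], "max", eb)
  if (!identical(sol$status, "optimal")) {
    stop("oxygen_methane_ratio: FBA is ", sol$status)
  }
  v_ch4 <- sol$fluxes[[id_map[["ex_ch4"]]]]
  if (abs(v_ch4) < 1e-12) stop("methane exchange flux is zero")
  abs(sol$fluxes[[id_map[["ex_o2"]]]]) / abs(v_ch4)
}
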