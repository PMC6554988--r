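#' Growth rate from doubling time
#' @param td Doubling time in hours (> 0).
#' @return Specific growth rate \code{mu = ln(2) / td} in h^-1.
#' @export
growth_rate_from_doubling_time <- function(td) {
  if (!is.numeric(td) || any(td <= 0)) stop("doubling time must be positive")
  log(2) / td
}

#' Non-growth ATP maintenance from endogenous respiration
#'
#' After substrate depletion, the endogenous O2 consumption rate reflects
#' maintenance energy generation; assuming a fixed ATP yield per O2, the
#' non-growth-associated maintenance (NGAM) is their product.
#'
#' @param q_o2 Endogenous respiration, mmol O2 g-DW^-1 h^-1 (>= 0).
#' @param atp_per_o2 ATP produced per O2 (mol/mol, > 0; default 5).
#' @return NGAM in mmol ATP g-DW^-1 h^-1.
#' @export
maintenance_from_endogenous_respiration <- function(q_o2, atp_per_o2 = 5) {
  if (!is.numeric(q_o2) || any(q_o2 < 0)) stop("q_o2 must be >= 0")
  if (!is.numeric(atp_per_o2) || any(atp_per_o2 <= 0)) stop("atp_per_o2 must be > 0")
  q_o2 * atp_per_o2
}

#' Molar mass of the PHB monomer equivalent (3-hydroxybutyrate minus water)
#' @export
PHB_MONOMER_MASS <- 86.09

#' PHB amount from concentration change
#'
#' @param c_initial,c_final PHB concentrations in g/L with
#'   \code{c_initial >= c_final >= 0}.
#' @param volume Liquid volume in L.
#' @param monomer_mass Molar mass used for monomer equivalents (g/mol;
#'   default [PHB_MONOMER_MASS], the 3-hydroxybutyrate monomer minus one
#'   water).
#' @return Consumed PHB in mmol monomer equivalents.
#' @export
phb_amount_from_concentrations <- function(c_initial, c_final, volume,
                                           monomer_mass = PHB_MONOMER_MASS) {
  if (any(c_final < 0) || any(volume <= 0)) stop("concentrations and volume must be nonnegative")
  if (any(c_initial < c_final)) stop("negative PHB consumption (c_initial < c_final)")
  (c_initial - c_final) * volume / monomer_mass * 1000
}

#' Biomass formed from concentration change
#' @param c_initial,c_final Non-PHB dry biomass concentrations in g/L.
#' @param volume Liquid volume in L.
#' @return Biomass formed in mg per bottle.
#' @export
biomass_from_concentrations <- function(c_initial, c_final, volume) {
  if (any(volume <= 0)) stop("volume must be positive")
  (c_final - c_initial) * volume * 1000
}

#' Essential-reaction fraction as a percentage
#' @param n_essential,n_reactions Counts with
#'   \code{0 <= n_essential <= n_reactions}.
#' @return \code{100 * n_essential / n_reactions}.
#' @export
essential_fraction_percent <- function(n_essential, n_reactions) {
  stopifnot(n_reactions > 0, n_essential >= 0, n_essential <= n_reactions)
  100 * n_essential / n_reactions
}

#' Describe a closed-bottle co-consumption experiment
#'
#' @param liquid_volume Liquid volume in L (> 0).
#' @param ch4_consumed Methane consumed, mmol per bottle (>= 0).
#' @param phb_consumed PHB consumed, mmol monomer equivalents (>= 0).
#' @param duration Duration in h (> 0).
#' @param o2_consumed Optional O2 consumed, mmol per bottle.
#' @param biomass_formed Optional non-PHB dry biomass formed, mg per bottle.
#' @return A \code{bottle_experiment} object.
#' @export
bottle_experiment <- function(liquid_volume, ch4_consumed, phb_consumed,
                              duration, o2_consumed = NA_real_,
                              biomass_formed = NA_real_) {
  stopifnot(liquid_volume > 0, ch4_consumed >= 0, phb_consumed >= 0,
            duration > 0)
  structure(list(liquid_volume = liquid_volume, ch4_consumed = ch4_consumed,
                 phb_consumed = phb_consumed, duration = duration,
                 o2_consumed = o2_consumed, biomass_formed = biomass_formed),
            class = "bottle_experiment")
}

#' Predict biomass and oxygen for methane-PHB co-consumption
#'
#' The measured bottle totals of methane and PHB consumed are imposed
#' directly as flux-scale constraints (valid by the linearity and
#' time-invariance of FBA), biomass formation is maximized, and the fluxes
#' of the anaplerosis-diagnostic reactions are reported from the
#' parsimonious optimum. Maintenance ATP is excluded from this totals-mode
#' optimization by default; \code{include_ngam = TRUE} charges
#' \code{ngam_atp * duration * mean_biomass_g} as a sensitivity run.
#'
#' @param model A [metabolic_model()].
#' @param expt A [bottle_experiment()].
#' @param variant A [mechanism_variant()] or name (default
#'   \code{"redox_arm"}).
#' @param id_map Role-to-reaction-id map.
#' @param include_ngam Charge maintenance ATP over the incubation (default
#'   FALSE).
#' @param ngam_atp NGAM rate, mmol ATP g-DW^-1 h^-1 (used only when
#'   \code{include_ngam}).
#' @param mean_biomass_g Time-averaged (trapezoidal) biomass in g per
#'   bottle; required when \code{include_ngam}.
#' @return A list: \code{biomass_mg}, \code{o2_mmol}, \code{status}, and
#'   \code{fluxes} — the parsimonious flux report (glycine synthase, both
#'   malyl-CoA lyase activities, propionyl-CoA carboxylation, PHB
#'   degradation, exchanges).
#' @export
co_consumption <- function(model, expt, variant = "redox_arm",
                           id_map = core_id_map(), include_ngam = FALSE,
                           ngam_atp = 3.5, mean_biomass_g = NULL) {
  stopifnot(inherits(expt, "bottle_experiment"))
  if (!id_map[["phb_degradation"]] %in% names(model$reactions)) {
    stop("model has no PHB-degradation entry reaction ('",
         id_map[["phb_degradation"]], "')")
  }
  m <- apply_mechanism(model, variant, id_map)
  eb <- list()
  eb[[id_map[["ex_ch4"]]]] <- c(-expt$ch4_consumed, -expt$ch4_consumed)
  eb[[id_map[["phb_degradation"]]]] <- c(expt$phb_consumed, expt$phb_consumed)
  if ("phb_storage" %in% names(id_map)) {
    eb[[id_map[["phb_storage"]]]] <- c(-expt$phb_consumed, 0)
  }
  ngam_flux <- 0
  if (include_ngam) {
    if (is.null(mean_biomass_g)) {
      stop("include_ngam = TRUE requires mean_biomass_g")
    }
    ngam_flux <- ngam_atp * expt$duration * mean_biomass_g
  }
  eb[[id_map[["atp_maintenance"]]]] <- c(ngam_flux, ngam_flux)
  sol <- pfba(m, id_map[["biomass"]], "max", eb)
  if (!identical(sol$status, "optimal")) {
    return(list(biomass_mg = NA_real_, o2_mmol = NA_real_,
                status = sol$status, fluxes = NULL))
  }
  report_ids <- intersect(
    unname(id_map[c("glycine_synthase", "malyl_coa_lyase",
                    "methylmalyl_lyase", "propionyl_coa_carboxylase",
                    "phb_degradation", "ex_ch4", "ex_o2", "ex_co2")]),
    names(sol$fluxes))
  list(biomass_mg = 1000 * sol$objective_value,
       o2_mmol = max(0, -sol$fluxes[[id_map[["ex_o2"]]]]),
       status = "optimal",
       fluxes = sol$fluxes[report_ids])
}

# shared anoxic bound set: oxygen closed, methane closed, PHB degradation
# fixed, nitrate uptake opened on request
anoxic_bounds <- function(expt_phb, allow_nitrate, id_map) {
  eb <- list()
  eb[[id_map[["ex_o2"]]]] <- c(0, 0)
  eb[[id_map[["ex_ch4"]]]] <- c(0, 0)
  eb[[id_map[["phb_degradation"]]]] <- c(expt_phb, expt_phb)
  if ("phb_storage" %in% names(id_map)) {
    eb[[id_map[["phb_storage"]]]] <- c(-expt_phb, 0)
  }
  if ("ex_no3" %in% names(id_map)) {
    eb[[id_map[["ex_no3"]]]] <- if (allow_nitrate) c(-1000, 0) else c(0, 0)
  } else if (allow_nitrate) {
    stop("id_map has no nitrate exchange but allow_nitrate = TRUE")
  }
  eb
}

#' Maximal anoxic ATP yield from PHB
#'
#' Closes oxygen uptake, fixes PHB degradation, opens nitrate uptake only on
#' request and maximizes the flux through the ATP-maintenance reaction —
#' the maximal rate at which the network can regenerate ATP from stored
#' PHB. Without any electron acceptor the model has no route to dispose of
#' the electrons released by PHB oxidation, so the maximal ATP is zero.
#'
#' @param model A [metabolic_model()].
#' @param phb PHB degradation flux to impose (default 1, so the result is
#'   mol ATP per mol PHB).
#' @param allow_nitrate Open nitrate uptake (logical).
#' @param id_map Role-to-reaction-id map.
#' @return A list: \code{atp_per_phb} (0 when infeasible) and
#'   \code{status}.
#' @export
anoxic_phb_atp <- function(model, phb = 1, allow_nitrate = TRUE,
                           id_map = core_id_map()) {
  eb <- anoxic_bounds(phb, allow_nitrate, id_map)
  sol <- fba(model, id_map[["atp_maintenance"]], "max", eb)
  if (!identical(sol$status, "optimal")) {
    return(list(atp_per_phb = 0, status = sol$status))
  }
  list(atp_per_phb = sol$objective_value, status = "optimal")
}

#' Anoxic overflow Pareto sweep
#'
#' Under anoxic, nitrate-respiring conditions with PHB degradation fixed at
#' 1 mol, forces increasing secretion of an overflow product (acetate or
#' butane-2,3-diol), maximizes ATP production at each grid point and
#' records the nitrate consumed. The trade-off curve shows that maximal ATP
#' coincides with zero overflow and that product secretion lowers the
#' nitrate demand.
#'
#' @param model A [metabolic_model()].
#' @param product \code{"acetate"} or \code{"butanediol"}.
#' @param grid Forced secretion grid (mol per mol PHB); default 21 points
#'   from 0 to the product's stoichiometric maximum.
#' @param id_map Role-to-reaction-id map.
#' @return A data frame of Pareto points (see [pareto_sweep()]).
#' @export
anoxic_overflow_pareto <- function(model, product = c("acetate", "butanediol"),
                                   grid = NULL, id_map = core_id_map()) {
  product <- match.arg(product)
  ex_prod <- id_map[[if (product == "acetate") "ex_ac" else "ex_btd"]]
  eb <- anoxic_bounds(1, allow_nitrate = TRUE, id_map = id_map)
  pareto_sweep(model, objective_id = id_map[["atp_maintenance"]],
               product_exchange_id = ex_prod, grid = grid,
               acceptor_exchange_id = id_map[["ex_no3"]], extra_bounds = eb)
}

#' Metabolite degree distribution with power-law fit
#'
#' The degree of a metabolite is the number of reactions it takes part in.
#' Metabolic networks are scale free: log n(k) falls linearly in log k. The
#' slope is fitted by ordinary least squares on (log10 k, log10 n(k)) over
#' all degrees with n(k) >= 1, after excluding hub metabolites (ATP, NADH
#' and other cofactors) above the \code{hub_quantile} degree percentile.
#'
#' @param model A [metabolic_model()].
#' @param active_only Restrict to reactions active under (near-)optimal
#'   growth; requires \code{fva_result}.
#' @param fva_result An [fva()] result at fraction 1 (used when
#'   \code{active_only}).
#' @param hub_quantile Degree percentile above which metabolites are
#'   excluded as hubs (default 0.99).
#' @return A \code{degree_distribution}: \code{counts} (data frame of k and
#'   n), \code{fitted_slope}, \code{fitted_intercept},
#'   \code{excluded_hubs}, and \code{single_point} flag when no fit is
#'   possible.
#' @export
degree_distribution <- function(model, active_only = FALSE, fva_result = NULL,
                                hub_quantile = 0.99) {
  if (length(model$metabolites) == 0L) stop("empty model")
  S <- stoichiometric_matrix(model)
  if (active_only) {
    if (is.null(fva_result)) stop("active_only = TRUE requires fva_result")
    act <- fva_result$reaction[pmax(abs(fva_result$min), abs(fva_result$max)) > 1e-6]
    S <- S[, colnames(S) %in% act, drop = FALSE]
  }
  deg <- Matrix::rowSums(S != 0)
  deg <- deg[deg >= 1]
  if (length(deg) == 0L) stop("no connected metabolites")
  thr <- stats::quantile(deg, hub_quantile, names = FALSE, type = 7)
  hubs <- names(deg)[deg > thr]
  kept <- deg[deg <= thr]
  tab <- table(kept)
  counts <- data.frame(k = as.integer(names(tab)), n = as.integer(tab))
  out <- list(counts = counts, fitted_slope = NA_real_,
              fitted_intercept = NA_real_, excluded_hubs = hubs,
              single_point = nrow(counts) < 2L)
  if (!out$single_point) {
    fit <- stats::lm(log10(n) ~ log10(k), data = counts)
    out$fitted_slope <- unname(stats::coef(fit)[2])
    out$fitted_intercept <- unname(stats::coef(fit)[1])
  }
  structure(out, class = "degree_distribution")
}

#' @export
print.degree_distribution <- function(x, ...) {
  cat("<degree_distribution> ", nrow(x$counts), " degree classes; slope ",
      format(x$fitted_slope, digits = 4), "; ", length(x$excluded_hubs),
      " hub(s) excluded\n", sep = "")
  invisible(x)
}

# canonical, direction- and compartment-invariant stoichiometric signature
reaction_signature <- function(r) {
  st <- r$stoichiometry
  mets <- sub("_[a-z][0-9]+$", "", names(st))
  agg <- tapply(unname(st), mets, sum)
  agg <- agg[abs(agg) > 1e-9]
  if (length(agg) == 0L) return("<empty>")
  fmt <- function(v) paste(sort(paste0(names(v), ":", round(v, 6))), collapse = "|")
  s1 <- fmt(agg); s2 <- fmt(-agg)
  if (s1 <= s2) s1 else s2
}

#' Compare models by shared and unique reactions and metabolites
#'
#' Reactions are matched by canonical stoichiometric signature (the sorted
#' coefficient multiset over compartment-stripped metabolite ids, direction
#' normalized) rather than by reaction id, because independently
#' reconstructed models spell ids differently. Metabolites are matched by
#' compartment-stripped id. Every region of the Venn partition is counted;
#' region counts sum to the union size.
#'
#' @param models A named list of at least two [metabolic_model()] objects
#'   (unnamed lists are named by model id).
#' @return A list with data frames \code{reactions} and \code{metabolites}:
#'   one row per Venn region (\code{region} = model names joined by
#'   \code{"&"}) with its \code{count}; and \code{reaction_ids}, the
#'   signature-to-region assignment used.
#' @export
compare_models <- function(models) {
  if (length(models) < 2L) stop("need at least two models")
  if (is.null(names(models)) || any(!nzchar(names(models)))) {
    names(models) <- vapply(models, `[[`, "", "id")
  }
  venn <- function(sets) {
    items <- unique(unlist(sets))
    membership <- vapply(sets, function(s) items %in% s, logical(length(items)))
    if (length(items) == 1L) membership <- matrix(membership, nrow = 1)
    region <- apply(membership, 1L, function(row) {
      paste(names(sets)[row], collapse = "&")
    })
    agg <- table(region)
    data.frame(region = names(agg), count = as.integer(agg),
               stringsAsFactors = FALSE)
  }
  rxn_sets <- lapply(models, function(m) {
    unique(vapply(m$reactions, reaction_signature, ""))
  })
  met_sets <- lapply(models, function(m) {
    unique(sub("_[a-z][0-9]+$", "", names(m$metabolites)))
  })
  list(reactions = venn(rxn_sets), metabolites = venn(met_sets))
}
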