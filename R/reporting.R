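#' Run a named scenario and write its artifacts
#'
#' Thin pipeline driver over the scenario functions: runs one of the
#' in-silico experiments on a model, returns its results as a list, and
#' (optionally) writes them as machine-readable JSON plus human-readable
#' TSV tables into an output directory. Identical model + configuration
#' give identical JSON (fluxes are reported through parsimonious FBA).
#'
#' Scenarios:
#' \describe{
#'   \item{\code{mechanism-panel}}{Yields and O2/CH4 ratios under the three
#'     pMMO mechanisms at fixed methane uptake and maintenance.}
#'   \item{\code{co-consumption}}{Bottle-totals methane + PHB co-consumption
#'     biomass and O2 prediction with anaplerosis flux report.}
#'   \item{\code{anoxic-phb}}{Anoxic ATP from PHB with/without nitrate and
#'     Pareto sweeps over acetate and butane-2,3-diol secretion.}
#'   \item{\code{topology}}{Metabolite degree distribution, power-law slope,
#'     whole network and the FVA-active sub-network.}
#'   \item{\code{compare}}{Shared/unique reaction and metabolite counts
#'     against the additional models in \code{extra_models}.}
#' }
#'
#' @param scenario Scenario name (see Details).
#' @param model A [metabolic_model()]; default is the packaged core model.
#' @param id_map Role-to-reaction-id map.
#' @param out_dir Output directory (created if absent); \code{NULL} writes
#'   nothing.
#' @param uptake_ch4,ngam_atp Reference constraints (defaults 14.9 and 3.5
#'   mmol g-DW^-1 h^-1).
#' @param expt A [bottle_experiment()] for \code{co-consumption}; default is
#'   the reference bottle (0.050 L, 1.8 mmol CH4, 0.083 mmol PHB, 15 h).
#' @param extra_models Named list of further models for \code{compare}.
#' @param seed Integer seed recorded in the log (scenarios themselves are
#'   deterministic).
#' @return The scenario result list, invisibly when writing files.
#' @export
run_scenario <- function(scenario = c("mechanism-panel", "co-consumption",
                                      "anoxic-phb", "topology", "compare"),
                         model = build_core_model(), id_map = core_id_map(),
                         out_dir = NULL, uptake_ch4 = 14.9, ngam_atp = 3.5,
                         expt = bottle_experiment(0.050, 1.8, 0.083, 15),
                         extra_models = NULL, seed = NULL) {
  scenario <- match.arg(scenario)
  res <- switch(
    scenario,
    "mechanism-panel" = {
      panel <- mechanism_panel(model, uptake_ch4, ngam_atp, id_map)
      panel$o2_ch4 <- vapply(panel$variant, function(v) {
        if (panel$status[panel$variant == v] != "optimal") return(NA_real_)
        oxygen_methane_ratio(apply_mechanism(model, v, id_map),
                             uptake_ch4, ngam_atp, id_map)
      }, 0)
      list(panel = panel)
    },
    "co-consumption" = {
      cc <- co_consumption(model, expt, "redox_arm", id_map)
      list(prediction = list(biomass_mg = cc$biomass_mg, o2_mmol = cc$o2_mmol,
                             status = cc$status),
           fluxes = as.list(cc$fluxes))
    },
    "anoxic-phb" = {
      list(atp = list(
             with_nitrate = anoxic_phb_atp(model, 1, TRUE, id_map)$atp_per_phb,
             without_nitrate = anoxic_phb_atp(model, 1, FALSE, id_map)$atp_per_phb),
           pareto_acetate = anoxic_overflow_pareto(model, "acetate", id_map = id_map),
           pareto_butanediol = anoxic_overflow_pareto(model, "butanediol", id_map = id_map))
    },
    "topology" = {
      dd <- degree_distribution(model)
      act <- fva(model, id_map[["biomass"]], 1.0,
                 extra_bounds = stats::setNames(
                   list(c(-uptake_ch4, -uptake_ch4), c(ngam_atp, ngam_atp)),
                   c(id_map[["ex_ch4"]], id_map[["atp_maintenance"]])))
      dd_act <- degree_distribution(model, active_only = TRUE, fva_result = act)
      list(full = list(slope = dd$fitted_slope, counts = dd$counts,
                       excluded_hubs = dd$excluded_hubs),
           active = list(slope = dd_act$fitted_slope, counts = dd_act$counts))
    },
    "compare" = {
      if (is.null(extra_models)) stop("scenario 'compare' needs extra_models")
      models <- c(stats::setNames(list(model), model$id), extra_models)
      compare_models(models)
    })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    res$log <- list(scenario = scenario, model_id = model$id,
                    n_reactions = length(model$reactions),
                    n_metabolites = length(model$metabolites),
                    lp_tolerance = 1e-9, balance_tolerance = 1e-6,
                    seed = seed, package_version = as.character(
                      utils::packageVersion("methanoflux")))
    jsonlite::write_json(res, file.path(out_dir, paste0(scenario, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (nm in names(res)) {
      if (is.data.frame(res[[nm]])) {
        utils::write.table(res[[nm]],
                           file.path(out_dir, paste0(scenario, "_", nm, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    return(invisible(res))
  }
  res
}
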