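# Calibrated constants of the core model's biomass equation (all mmol per
# g DW). The carbon/nitrogen composition (`precursors` x `scale`, about 41
# mmol C and 10 mmol N per g DW) and the growth-associated ATP demand
# (`gam`) are fixed at textbook-realistic values. `nadh` is the lumped
# anabolic reductant demand (NADPH-equivalent reduction steps of amino
# acid, lipid and nucleotide synthesis, which the compact network does not
# resolve); it is the single tuned constant, fitted once with
# tools/calibrate_core_model.R so that redox-arm growth at a methane uptake
# of 14.9 mmol g-DW^-1 h^-1 and a non-growth maintenance of 3.5 mmol ATP
# g-DW^-1 h^-1 gives a specific growth rate of 0.107 h^-1 (biomass yield
# 7.2 g-DW per mol CH4). The O2/CH4 consumption ratio of 1.5 mol/mol is
# not tuned: it emerges from the redox-arm electron bookkeeping.
CORE_CALIBRATION <- list(
  scale = 1.2,
  gam = 40,
  nadh = 24.651,
  precursors = c(accoa_c0 = 2.5, ser_c0 = 5.5, gly_c0 = 1.0, akg_c0 = 1.0,
                 oaa_c0 = 1.0, nh4_c0 = 4.0)
)

core_metabolite_formulas <- function() {
  c(
    ch4 = "CH4", o2 = "O2", co2 = "CO2", h2o = "H2O", h = "H", nh4 = "H4N",
    no3 = "NO3", no2 = "NO2", no = "NO", n2o = "N2O", n2 = "N2",
    pi = "HO4P", meoh = "CH4O", fald = "CH2O", fortm = "CHO2",
    thf = "C19H23N7O6", mlthf = "C20H23N7O6",
    nad = "C21H26N7O14P2", nadh = "C21H27N7O14P2",
    q8 = "C49H74O4", q8h2 = "C49H76O4",
    cytcox = "C42H44FeN8O8S2", cytcred = "C42H44FeN8O8S2",
    atp = "C10H12N5O13P3", adp = "C10H12N5O10P2",
    coa = "C21H32N7O16P3S", accoa = "C23H34N7O17P3S",
    gly = "C2H5NO2", ser = "C3H7NO3", glx = "C2HO3", hpyr = "C3H3O4",
    glyc = "C3H5O4", pg2 = "C3H4O7P", pep = "C3H2O6P",
    oaa = "C4H2O5", mal = "C4H4O5", malcoa = "C25H35N7O20P3S",
    cit = "C6H5O7", icit = "C6H5O7", akg = "C5H4O5",
    succoa = "C25H35N7O19P3S", succ = "C4H4O4", fum = "C4H2O4",
    aacoa = "C25H36N7O18P3S", hbcoa = "C25H38N7O18P3S", phb = "C4H6O2",
    b2coa = "C25H36N7O17P3S", emcoa = "C26H37N7O19P3S",
    mscoa = "C26H37N7O19P3S", mescoa = "C26H35N7O19P3S",
    mmalcoa = "C26H37N7O20P3S", ppcoa = "C24H36N7O17P3S",
    mmcoa = "C25H35N7O19P3S", hco3 = "CHO3", oxa = "C2O4",
    pyr = "C3H3O3", alac = "C5H7O4", actn = "C4H8O2", btd = "C4H10O2",
    ac = "C2H3O2"
  )
}

core_metabolite_names <- function() {
  c(ch4 = "Methane", o2 = "Oxygen", co2 = "Carbon dioxide", h2o = "Water",
    h = "Proton", nh4 = "Ammonium", no3 = "Nitrate", no2 = "Nitrite",
    no = "Nitric oxide", n2o = "Nitrous oxide", n2 = "Dinitrogen",
    pi = "Phosphate", meoh = "Methanol", fald = "Formaldehyde",
    fortm = "Formate", thf = "Tetrahydrofolate",
    mlthf = "5,10-Methylene-tetrahydrofolate", nad = "NAD+", nadh = "NADH",
    q8 = "Ubiquinone-8", q8h2 = "Ubiquinol-8",
    cytcox = "Cytochrome c (oxidized)", cytcred = "Cytochrome c (reduced)",
    atp = "ATP", adp = "ADP", coa = "Coenzyme A", accoa = "Acetyl-CoA",
    gly = "Glycine", ser = "L-Serine", glx = "Glyoxylate",
    hpyr = "Hydroxypyruvate", glyc = "D-Glycerate",
    pg2 = "2-Phospho-D-glycerate", pep = "Phosphoenolpyruvate",
    oaa = "Oxaloacetate", mal = "L-Malate", malcoa = "L-Malyl-CoA",
    cit = "Citrate", icit = "Isocitrate", akg = "2-Oxoglutarate",
    succoa = "Succinyl-CoA", succ = "Succinate", fum = "Fumarate",
    aacoa = "Acetoacetyl-CoA", hbcoa = "(R)-3-Hydroxybutyryl-CoA",
    phb = "PHB (monomer equivalent)", b2coa = "Crotonyl-CoA",
    emcoa = "Ethylmalonyl-CoA", mscoa = "Methylsuccinyl-CoA",
    mescoa = "Mesaconyl-CoA", mmalcoa = "L-erythro-3-Methylmalyl-CoA",
    ppcoa = "Propionyl-CoA", mmcoa = "Methylmalonyl-CoA",
    hco3 = "Bicarbonate", oxa = "Oxalate",
    pyr = "Pyruvate", alac = "2-Acetolactate",
    actn = "Acetoin", btd = "Butane-2,3-diol", ac = "Acetate")
}

# Reaction inventory. Each row: id, equation over suffixed metabolite ids,
# reversible flag, enzyme name. Directionality is curated: no reaction chain
# can generate ATP or translocate protons without a thermodynamic driver
# (e.g. succinate dehydrogenase is forward-only, so fumarate cannot serve as
# an anaerobic electron acceptor).
core_reaction_table <- function(h_per_atp) {
  hp <- function(n) if (n == 1) "h_p0" else paste(n, "h_p0")
  list(
    # methane oxidation: the two alternative pMMO electron-donor
    # stoichiometries, and the downstream C1 oxidation ladder
    list("pMMO1", "ch4_c0 + o2_c0 + 2 cytcred_c0 + 2 h_c0 -> meoh_c0 + h2o_c0 + 2 cytcox_c0",
         FALSE, "Particulate methane monooxygenase (cytochrome-c coupled)"),
    list("pMMO2", "ch4_c0 + o2_c0 + q8h2_c0 -> meoh_c0 + h2o_c0 + q8_c0",
         FALSE, "Particulate methane monooxygenase (ubiquinol coupled)"),
    list("MEDH", "meoh_c0 + 2 cytcox_c0 -> fald_c0 + 2 cytcred_c0 + 2 h_c0",
         FALSE, "Methanol dehydrogenase (cytochrome c)"),
    list("FALDH", "fald_c0 + nad_c0 + h2o_c0 -> fortm_c0 + nadh_c0 + 2 h_c0",
         FALSE, "Formaldehyde dehydrogenase"),
    list("FDH", "fortm_c0 + nad_c0 -> co2_c0 + nadh_c0", FALSE,
         "Formate dehydrogenase"),
    list("FALDTHF", "fald_c0 + thf_c0 <=> mlthf_c0 + h2o_c0", TRUE,
         "Formaldehyde-tetrahydrofolate condensation"),
    # respiratory chain; proton translocation totals 10 H+ per NADH
    list("CPLX1", "nadh_c0 + 5 h_c0 + q8_c0 -> nad_c0 + q8h2_c0 + 4 h_p0",
         FALSE, "NADH dehydrogenase (complex I)"),
    list("NDH2", "nadh_c0 + h_c0 + q8_c0 -> nad_c0 + q8h2_c0", FALSE,
         "NADH dehydrogenase, non-proton-pumping (NDH-2)"),
    list("rxn10113_c0", "q8h2_c0 + 2 cytcox_c0 + 2 h_c0 -> q8_c0 + 2 cytcred_c0 + 4 h_p0",
         FALSE, "Ubiquinol-cytochrome c oxidoreductase (complex III)"),
    list("CPLX4", "2 cytcred_c0 + 0.5 o2_c0 + 4 h_c0 -> 2 cytcox_c0 + h2o_c0 + 2 h_p0",
         FALSE, "Cytochrome c oxidase (complex IV)"),
    list("ATPS", paste0("adp_c0 + pi_c0 + ", hp(h_per_atp), " <=> atp_c0 + h2o_c0 + ",
                        h_per_atp - 1, " h_c0"), TRUE, "ATP synthase"),
    list("NGAM", "atp_c0 + h2o_c0 -> adp_c0 + pi_c0 + h_c0", FALSE,
         "Non-growth-associated ATP maintenance"),
    list("LEAK", "h_p0 -> h_c0", FALSE, "Membrane proton leak"),
    # serine cycle
    list("GLYS", "co2_c0 + nh4_c0 + mlthf_c0 + nadh_c0 -> gly_c0 + thf_c0 + nad_c0",
         FALSE, "Glycine synthase (reverse glycine cleavage system)"),
    list("SHMT", "gly_c0 + mlthf_c0 + h2o_c0 -> ser_c0 + thf_c0", FALSE,
         "Serine hydroxymethyltransferase"),
    list("SGAT", "ser_c0 + glx_c0 <=> hpyr_c0 + gly_c0", TRUE,
         "Serine-glyoxylate aminotransferase"),
    list("GLYAT", "glx_c0 + nh4_c0 + nadh_c0 + h_c0 -> gly_c0 + nad_c0 + h2o_c0",
         FALSE, "Glyoxylate amination to glycine (transaminase, net)"),
    list("HPR", "hpyr_c0 + nadh_c0 + h_c0 -> glyc_c0 + nad_c0", FALSE,
         "Hydroxypyruvate reductase"),
    list("GLYCK", "glyc_c0 + atp_c0 -> pg2_c0 + adp_c0 + h_c0", FALSE,
         "Glycerate kinase"),
    list("ENO", "pg2_c0 <=> pep_c0 + h2o_c0", TRUE, "Enolase"),
    list("PPC", "pep_c0 + co2_c0 + h2o_c0 -> oaa_c0 + pi_c0 + h_c0", FALSE,
         "Phosphoenolpyruvate carboxylase"),
    list("MDH", "oaa_c0 + nadh_c0 + h_c0 <=> mal_c0 + nad_c0", TRUE,
         "Malate dehydrogenase"),
    list("MTK", "mal_c0 + atp_c0 + coa_c0 -> malcoa_c0 + adp_c0 + pi_c0",
         FALSE, "Malate thiokinase"),
    list("MCL1", "malcoa_c0 <=> accoa_c0 + glx_c0", TRUE,
         "Malyl-CoA lyase (malyl-CoA activity)", "mclA"),
    list("GLXO", "glx_c0 + nad_c0 + h2o_c0 -> oxa_c0 + nadh_c0 + 2 h_c0",
         FALSE, "Glyoxylate oxidase (to oxalate)"),
    list("OXADC", "oxa_c0 + h_c0 -> fortm_c0 + co2_c0", FALSE,
         "Oxalate decarboxylase"),
    # TCA cycle
    list("CS", "accoa_c0 + oaa_c0 + h2o_c0 -> cit_c0 + coa_c0 + h_c0", FALSE,
         "Citrate synthase"),
    list("ACONT", "cit_c0 <=> icit_c0", TRUE, "Aconitase"),
    list("ICDH", "icit_c0 + nad_c0 -> akg_c0 + co2_c0 + nadh_c0", FALSE,
         "Isocitrate dehydrogenase"),
    list("AKGDH", "akg_c0 + coa_c0 + nad_c0 -> succoa_c0 + co2_c0 + nadh_c0",
         FALSE, "2-Oxoglutarate dehydrogenase"),
    list("SUCOAS", "succoa_c0 + adp_c0 + pi_c0 <=> succ_c0 + coa_c0 + atp_c0",
         TRUE, "Succinyl-CoA synthetase"),
    list("SUCD", "succ_c0 + q8_c0 -> fum_c0 + q8h2_c0", FALSE,
         "Succinate dehydrogenase"),
    list("FUM", "fum_c0 + h2o_c0 <=> mal_c0", TRUE, "Fumarase"),
    list("PDH", "pyr_c0 + coa_c0 + nad_c0 -> accoa_c0 + co2_c0 + nadh_c0",
         FALSE, "Pyruvate dehydrogenase"),
    # PHB synthesis and the ethylmalonyl-CoA-type degradation route ending
    # in glyoxylate + propionyl-CoA
    # thiolase is curated to the condensation direction: PHB carbon re-enters
    # central metabolism through the ethylmalonyl-CoA-type route, not by
    # direct thiolysis back to acetyl-CoA
    list("PHAA", "2 accoa_c0 -> aacoa_c0 + coa_c0", FALSE,
         "Acetyl-CoA acetyltransferase (thiolase, condensation)"),
    list("PHAB", "aacoa_c0 + nadh_c0 + h_c0 <=> hbcoa_c0 + nad_c0", TRUE,
         "Acetoacetyl-CoA reductase"),
    list("PHAC", "hbcoa_c0 -> phb_c0 + coa_c0", FALSE, "PHB polymerase"),
    list("PHB_DEG", "phb_c0 + coa_c0 + atp_c0 + h2o_c0 -> hbcoa_c0 + adp_c0 + pi_c0 + h_c0",
         FALSE, "PHB depolymerase + 3-hydroxybutyryl-CoA activation (lumped)"),
    list("ECH", "hbcoa_c0 <=> b2coa_c0 + h2o_c0", TRUE, "Enoyl-CoA hydratase"),
    list("CCR", "b2coa_c0 + co2_c0 + nadh_c0 -> emcoa_c0 + nad_c0", FALSE,
         "Crotonyl-CoA carboxylase/reductase"),
    list("ECM", "emcoa_c0 <=> mscoa_c0", TRUE, "Ethylmalonyl-CoA mutase"),
    list("MSD", "mscoa_c0 + q8_c0 -> mescoa_c0 + q8h2_c0", FALSE,
         "Methylsuccinyl-CoA dehydrogenase"),
    list("MCH", "mescoa_c0 + h2o_c0 <=> mmalcoa_c0", TRUE,
         "Mesaconyl-CoA hydratase"),
    list("MCL2", "mmalcoa_c0 -> glx_c0 + ppcoa_c0", FALSE,
         "Malyl-CoA lyase (L-erythro-3-methylmalyl-CoA activity)", "mclA"),
    list("PCC", "ppcoa_c0 + hco3_c0 + atp_c0 -> mmcoa_c0 + adp_c0 + pi_c0 + h_c0",
         FALSE, "Propionyl-CoA carboxylase"),
    list("MMM", "mmcoa_c0 <=> succoa_c0", TRUE, "Methylmalonyl-CoA mutase"),
    list("HCO3E", "co2_c0 + h2o_c0 <=> hco3_c0 + h_c0", TRUE,
         "Carbonic anhydrase"),
    # acetate and butane-2,3-diol overflow routes
    list("ME", "mal_c0 + nad_c0 -> pyr_c0 + co2_c0 + nadh_c0", FALSE,
         "Malic enzyme"),
    list("ACK", "accoa_c0 + adp_c0 + pi_c0 -> ac_c0 + coa_c0 + atp_c0", FALSE,
         "Phosphotransacetylase + acetate kinase (lumped)"),
    list("ALS", "2 pyr_c0 + h_c0 -> alac_c0 + co2_c0", FALSE,
         "Acetolactate synthase"),
    list("ALDC", "alac_c0 + h_c0 -> actn_c0 + co2_c0", FALSE,
         "Acetolactate decarboxylase"),
    list("BTDD", "actn_c0 + nadh_c0 + h_c0 <=> btd_c0 + nad_c0", TRUE,
         "Butane-2,3-diol dehydrogenase"),
    # assimilatory nitrate reduction (nitrate mineral medium: all biomass
    # nitrogen enters as nitrate and is reduced to ammonium at 4 NADH per N)
    list("NASA", "no3_c0 + nadh_c0 + h_c0 -> no2_c0 + nad_c0 + h2o_c0",
         FALSE, "Assimilatory nitrate reductase"),
    list("NASB", "no2_c0 + 3 nadh_c0 + 5 h_c0 -> nh4_c0 + 3 nad_c0 + 2 h2o_c0",
         FALSE, "Assimilatory nitrite reductase (to ammonium)"),
    # denitrification chain: nitrate stepwise to dinitrogen
    list("NAR", "no3_c0 + q8h2_c0 + 2 h_c0 -> no2_c0 + h2o_c0 + q8_c0 + 2 h_p0",
         FALSE, "Nitrate reductase"),
    list("NIR", "no2_c0 + cytcred_c0 + 2 h_c0 -> no_c0 + h2o_c0 + cytcox_c0",
         FALSE, "Nitrite reductase"),
    list("NOR", "2 no_c0 + 2 cytcred_c0 + 2 h_c0 -> n2o_c0 + h2o_c0 + 2 cytcox_c0",
         FALSE, "Nitric oxide reductase"),
    list("NOS", "n2o_c0 + 2 cytcred_c0 + 2 h_c0 -> n2_c0 + h2o_c0 + 2 cytcox_c0",
         FALSE, "Nitrous oxide reductase")
  )
}

# species with a transporter and an exchange; default exchange bounds follow
# the secretion convention (uptake needs a negative lower bound)
core_external_species <- function() {
  list(ch4 = c(-DEFAULT_FLUX_BOUND, DEFAULT_FLUX_BOUND),
       o2 = c(-DEFAULT_FLUX_BOUND, DEFAULT_FLUX_BOUND),
       co2 = c(-DEFAULT_FLUX_BOUND, DEFAULT_FLUX_BOUND),
       nh4 = c(0, DEFAULT_FLUX_BOUND),
       no3 = c(-DEFAULT_FLUX_BOUND, DEFAULT_FLUX_BOUND),
       ac = c(0, DEFAULT_FLUX_BOUND),
       btd = c(0, DEFAULT_FLUX_BOUND),
       n2 = c(0, DEFAULT_FLUX_BOUND),
       h2o = c(-DEFAULT_FLUX_BOUND, DEFAULT_FLUX_BOUND),
       h = c(-DEFAULT_FLUX_BOUND, DEFAULT_FLUX_BOUND))
}

#' Build the core methanotroph model
#'
#' Constructs a compact (~80 reaction) type II methanotroph network covering
#' every pathway the package's scenarios traverse: both pMMO electron-donor
#' stoichiometries plus complex III; methanol, formaldehyde and formate
#' oxidation; formaldehyde entry into methylene-tetrahydrofolate; the full
#' serine cycle with a malyl-CoA lyase shared between malyl-CoA and
#' L-erythro-3-methylmalyl-CoA lysis; glycine synthase; PHB synthesis and
#' the ethylmalonyl-CoA-type degradation route ending in glyoxylate +
#' propionyl-CoA; propionyl-CoA carboxylation to succinyl-CoA; the TCA
#' cycle; a respiratory chain whose proton stoichiometry yields
#' \code{atp_per_o2} ATP per O2 on NADH (10 H+ pumped per NADH, 20 /
#' \code{atp_per_o2} H+ per ATP at the synthase); an ATP-maintenance
#' reaction; a calibrated biomass equation; and optionally a nitrate-to-N2
#' denitrification chain and acetate / butane-2,3-diol secretion routes.
#' The biomass reaction is scaled so that flux 1 equals a specific growth
#' rate of 1 h^-1. All non-exchange reactions balance C, H, O and N under
#' the model's metabolite formulas (the biomass macromolecule's formula is
#' the exact elemental residual of its equation).
#'
#' @param include_denitrification Include the nitrate-to-N2 chain (default
#'   TRUE).
#' @param include_overflow_products Include acetate and butane-2,3-diol
#'   synthesis and secretion (default TRUE).
#' @param atp_per_o2 Target P/O-derived ATP yield per O2 on NADH (default 5,
#'   the classical assumption for this respiratory chain).
#' @param biomass_scale,gam,nadh_demand Calibration constants: multiplier on
#'   the carbon/nitrogen precursor demands, growth-associated ATP and the
#'   anabolic reductant (NADH) demand, all in mmol per g DW. The carbon
#'   composition and ATP demand are fixed at textbook-realistic values; the
#'   reductant demand was tuned once so that the redox-arm growth rate at
#'   the reference constraints is 0.107 h^-1. Defaults are the committed
#'   calibration (see the package vignette).
#' @return A [metabolic_model()] with objective \code{"biomass"}.
#' @export
build_core_model <- function(include_denitrification = TRUE,
                             include_overflow_products = TRUE,
                             atp_per_o2 = 5,
                             biomass_scale = CORE_CALIBRATION$scale,
                             gam = CORE_CALIBRATION$gam,
                             nadh_demand = CORE_CALIBRATION$nadh) {
  stopifnot(atp_per_o2 > 0)
  h_per_atp <- 20 / atp_per_o2
  if (abs(h_per_atp - round(h_per_atp)) > 1e-9) {
    stop("atp_per_o2 must divide 20 into an integer H+/ATP stoichiometry")
  }
  h_per_atp <- as.integer(round(h_per_atp))

  tab <- core_reaction_table(h_per_atp)
  if (!include_denitrification) {
    tab <- Filter(function(r) !r[[1]] %in% c("NAR", "NIR", "NOR", "NOS"), tab)
  }
  if (!include_overflow_products) {
    tab <- Filter(function(r) !r[[1]] %in% c("ME", "ACK", "ALS", "ALDC", "BTDD"), tab)
  }
  reactions <- lapply(tab, function(r) {
    parsed <- parse_equation(r[[2]])
    reaction(r[[1]], parsed$stoichiometry,
             lower_bound = if (r[[3]]) -DEFAULT_FLUX_BOUND else 0,
             upper_bound = DEFAULT_FLUX_BOUND, name = r[[4]],
             gene_association = if (length(r) >= 5) r[[5]] else NA_character_)
  })
  names(reactions) <- vapply(reactions, `[[`, "", "id")

  # transport + exchange per external species
  # nitrate stays even without the denitrification chain: it is the medium's
  # nitrogen source via the assimilatory route
  ext <- core_external_species()
  if (!include_overflow_products) { ext$ac <- NULL; ext$btd <- NULL }
  if (!include_denitrification) ext$n2 <- NULL
  for (sp in names(ext)) {
    tid <- paste0(toupper(sp), "t")
    reactions[[tid]] <- reaction(
      tid, stats::setNames(c(-1, 1), paste0(sp, c("_e0", "_c0"))),
      lower_bound = -DEFAULT_FLUX_BOUND, upper_bound = DEFAULT_FLUX_BOUND,
      name = paste0(sp, " transport"))
    eid <- paste0("EX_", sp, "_e0")
    reactions[[eid]] <- reaction(
      eid, stats::setNames(-1, paste0(sp, "_e0")),
      lower_bound = ext[[sp]][1], upper_bound = ext[[sp]][2],
      name = paste0(sp, " exchange"), is_exchange = TRUE)
  }
  # PHB storage pool: positive flux = deposition into storage; mobilization
  # is enabled per scenario by opening the lower bound
  reactions[["EX_phb_c0"]] <- reaction(
    "EX_phb_c0", c(phb_c0 = -1), lower_bound = 0,
    upper_bound = DEFAULT_FLUX_BOUND, name = "PHB storage pool",
    is_exchange = TRUE)

  # biomass equation: scaled precursor demands + growth-associated ATP
  pre <- CORE_CALIBRATION$precursors * biomass_scale
  st <- c(-unname(pre["accoa_c0"]), -unname(pre["ser_c0"]),
          -unname(pre["gly_c0"]), -unname(pre["akg_c0"]),
          -unname(pre["oaa_c0"]), -unname(pre["nh4_c0"]),
          -nadh_demand, -gam, -gam,
          unname(pre["accoa_c0"]), nadh_demand, gam, gam, gam, 1)
  names(st) <- c("accoa_c0", "ser_c0", "gly_c0", "akg_c0", "oaa_c0",
                 "nh4_c0", "nadh_c0", "atp_c0", "h2o_c0", "coa_c0",
                 "nad_c0", "adp_c0", "pi_c0", "h_c0", "biomass_c0")
  reactions[["biomass"]] <- reaction("biomass", st, lower_bound = 0,
                                     upper_bound = DEFAULT_FLUX_BOUND,
                                     name = "Biomass synthesis")
  reactions[["DM_biomass_c0"]] <- reaction(
    "DM_biomass_c0", c(biomass_c0 = -1), lower_bound = 0,
    upper_bound = DEFAULT_FLUX_BOUND, name = "Biomass drain",
    is_exchange = TRUE)

  # metabolite inventory with formulas; biomass formula is the elemental
  # residual of its own equation so the whole model balances exactly
  formulas <- core_metabolite_formulas()
  longnames <- core_metabolite_names()
  met_ids <- sort(unique(unlist(lapply(reactions, function(r) names(r$stoichiometry)))))
  mets <- lapply(met_ids, function(mid) {
    base <- sub("_[a-z][0-9]+$", "", mid)
    if (base == "h" && grepl("_p0$", mid)) {
      return(metabolite(mid, name = "Proton (periplasm)", formula = "H"))
    }
    if (base == "biomass") {
      return(metabolite(mid, name = "Biomass", formula = biomass_formula(reactions, formulas)))
    }
    metabolite(mid, name = if (base %in% names(longnames)) longnames[[base]] else mid,
               formula = if (base %in% names(formulas)) formulas[[base]] else NA_character_)
  })

  model <- metabolic_model("methanotroph_core", mets, reactions, "biomass")
  # constructional sanity: the finished model must be able to grow
  sol <- fba(apply_mechanism(model, mechanism_variant("redox_arm")),
             extra_bounds = list(EX_ch4_e0 = c(-14.9, -14.9), NGAM = c(3.5, 3.5)))
  if (!identical(sol$status, "optimal") || sol$objective_value <= 1e-6) {
    stop("core model calibration failure: no growth at the reference constraints")
  }
  model
}

# elemental residual (LHS minus RHS over C,H,O,N,P,S,Fe) of the biomass
# equation, rendered as a formula string
biomass_formula <- function(reactions, formulas) {
  st <- reactions[["biomass"]]$stoichiometry
  elements <- c("C", "H", "O", "N", "P", "S", "Fe")
  tot <- stats::setNames(numeric(length(elements)), elements)
  for (mid in names(st)) {
    base <- sub("_[a-z][0-9]+$", "", mid)
    if (base == "biomass") next
    f <- parse_formula(formulas[[base]])
    for (e in intersect(names(f), elements)) {
      tot[e] <- tot[e] - st[[mid]] * f[[e]]
    }
  }
  tot <- tot[abs(tot) > 1e-9]
  if (any(tot < 0)) stop("biomass equation produces a negative elemental residual")
  paste0(names(tot), ifelse(abs(tot - 1) < 1e-12, "",
                            format(tot, digits = 10, trim = TRUE)), collapse = "")
}

#' Canonical reaction-id map of the core model
#'
#' The scenario functions address reactions through a role-to-id map, so the
#' same experiments run on the packaged core model or on an externally
#' deposited genome-scale model whose id spellings differ.
#'
#' @return Named character vector: roles (\code{pmmo_cytc},
#'   \code{pmmo_ubiquinol}, \code{complex_iii}, \code{atp_maintenance},
#'   \code{biomass}, \code{phb_degradation}, \code{phb_storage},
#'   \code{glycine_synthase}, \code{malyl_coa_lyase},
#'   \code{methylmalyl_lyase}, \code{propionyl_coa_carboxylase} and the
#'   \code{ex_*} exchanges) to core-model reaction ids.
#' @export
core_id_map <- function() {
  c(pmmo_cytc = "pMMO1",
    pmmo_ubiquinol = "pMMO2",
    complex_iii = "rxn10113_c0",
    atp_maintenance = "NGAM",
    biomass = "biomass",
    phb_degradation = "PHB_DEG",
    phb_storage = "EX_phb_c0",
    glycine_synthase = "GLYS",
    malyl_coa_lyase = "MCL1",
    methylmalyl_lyase = "MCL2",
    propionyl_coa_carboxylase = "PCC",
    ex_ch4 = "EX_ch4_e0",
    ex_o2 = "EX_o2_e0",
    ex_co2 = "EX_co2_e0",
    ex_nh4 = "EX_nh4_e0",
    ex_no3 = "EX_no3_e0",
    ex_ac = "EX_ac_e0",
    ex_btd = "EX_btd_e0",
    ex_n2 = "EX_n2_e0")
}
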