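SBML_L3_NS <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

#' Write a metabolic model as SBML
#'
#' Writes SBML Level 3 Version 1 with the flux-balance-constraints (fbc)
#' version 2 package: species carry chemical formulas and charges, flux
#' bounds are shared \code{listOfParameters} entries referenced through
#' \code{fbc:lowerFluxBound}/\code{fbc:upperFluxBound}, and the objective
#' reaction is declared as the active \code{fbc:objective}. Species and
#' reaction ids receive the conventional \code{M_}/\code{R_} prefixes, which
#' [read_sbml()] strips again, so write-then-read restores the original
#' model exactly (ids, coefficients and bounds as decimal values). Gene
#' associations are stored as classic \code{GENE_ASSOCIATION} note lines.
#'
#' @param model A [metabolic_model()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_sbml <- function(model, path) {
  num <- function(x) format(x, digits = 17, trim = TRUE, scientific = FALSE)
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub("\"", "&quot;", x, fixed = TRUE)
  }
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf(paste0("<sbml xmlns=\"%s\" xmlns:fbc=\"%s\" level=\"3\" ",
                   "version=\"1\" fbc:required=\"false\">"),
            SBML_L3_NS, SBML_FBC_NS),
    sprintf("  <model id=\"%s\" fbc:strict=\"true\">", esc(model$id)),
    "    <listOfCompartments>",
    sprintf("      <compartment id=\"%s\" constant=\"true\"/>",
            ifelse(nzchar(model$compartments), esc(model$compartments), "default")),
    "    </listOfCompartments>",
    "    <listOfSpecies>"
  )
  for (m in model$metabolites) {
    attrs <- sprintf(paste0("id=\"M_%s\" name=\"%s\" compartment=\"%s\" ",
                            "hasOnlySubstanceUnits=\"false\" ",
                            "boundaryCondition=\"false\" constant=\"false\""),
                     esc(m$id), esc(m$name),
                     if (nzchar(m$compartment)) esc(m$compartment) else "default")
    if (!is.na(m$formula) && nzchar(m$formula)) {
      attrs <- paste0(attrs, sprintf(" fbc:chemicalFormula=\"%s\"", esc(m$formula)))
    }
    if (!is.na(m$charge)) {
      attrs <- paste0(attrs, sprintf(" fbc:charge=\"%d\"", m$charge))
    }
    lines <- c(lines, sprintf("      <species %s/>", attrs))
  }
  lines <- c(lines, "    </listOfSpecies>")
  # shared bound parameters
  bounds <- reaction_bounds(model)
  vals <- sort(unique(as.numeric(bounds)))
  pid <- stats::setNames(sprintf("fb_%d", seq_along(vals)), num(vals))
  lines <- c(lines, "    <listOfParameters>",
             sprintf(paste0("      <parameter id=\"%s\" value=\"%s\" ",
                            "constant=\"true\"/>"),
                     pid, names(pid)),
             "    </listOfParameters>",
             "    <listOfReactions>")
  for (r in model$reactions) {
    head <- sprintf(paste0("      <reaction id=\"R_%s\" name=\"%s\" ",
                           "reversible=\"%s\" fast=\"false\" ",
                           "fbc:lowerFluxBound=\"%s\" fbc:upperFluxBound=\"%s\">"),
                    esc(r$id), esc(r$name),
                    if (r$lower_bound < 0) "true" else "false",
                    pid[[num(r$lower_bound)]], pid[[num(r$upper_bound)]])
    lines <- c(lines, head)
    notes <- character(0)
    if (!is.na(r$gene_association) && nzchar(r$gene_association)) {
      notes <- c(notes, paste0("GENE_ASSOCIATION: ", esc(r$gene_association)))
    }
    if (length(r$ec_numbers)) {
      notes <- c(notes, paste0("EC_NUMBER: ", esc(paste(r$ec_numbers, collapse = " "))))
    }
    if (length(notes)) {
      lines <- c(lines,
                 "        <notes><body xmlns=\"http://www.w3.org/1999/xhtml\">",
                 sprintf("          <p>%s</p>", notes),
                 "        </body></notes>")
    }
    st <- r$stoichiometry
    for (side in c(-1, 1)) {
      sel <- st[sign(st) == side]
      if (length(sel) == 0L) next
      tag <- if (side < 0) "listOfReactants" else "listOfProducts"
      lines <- c(lines, sprintf("        <%s>", tag),
                 sprintf(paste0("          <speciesReference species=\"M_%s\" ",
                                "stoichiometry=\"%s\" constant=\"true\"/>"),
                         esc(names(sel)), num(abs(sel))),
                 sprintf("        </%s>", tag))
    }
    lines <- c(lines, "      </reaction>")
  }
  lines <- c(lines, "    </listOfReactions>",
             "    <fbc:listOfObjectives fbc:activeObjective=\"obj\">",
             "      <fbc:objective fbc:id=\"obj\" fbc:type=\"maximize\">",
             "        <fbc:listOfFluxObjectives>",
             sprintf(paste0("          <fbc:fluxObjective fbc:reaction=\"R_%s\" ",
                            "fbc:coefficient=\"1\"/>"), esc(model$objective_id)),
             "        </fbc:listOfFluxObjectives>",
             "      </fbc:objective>",
             "    </fbc:listOfObjectives>",
             "  </model>",
             "</sbml>")
  writeLines(lines, path)
  invisible(path)
}

#' Read a metabolic model from SBML
#'
#' Accepts SBML Level 3 with the fbc package (flux bounds as referenced
#' parameters, objective from the active \code{fbc:objective}) as written by
#' [write_sbml()] and by COBRA-family tools, and SBML Level 2 with
#' \code{LOWER_BOUND}/\code{UPPER_BOUND} kinetic-law parameters (the legacy
#' COBRA dialect). Conventional \code{M_}/\code{R_} id prefixes are stripped
#' when all species/reactions carry them. Species flagged
#' \code{boundaryCondition="true"} are dropped from stoichiometries.
#' Reactions without discoverable bounds get defaults from their
#' \code{reversible} flag, with a warning.
#'
#' @param path Path to an SBML file.
#' @return A [metabolic_model()]; malformed XML raises a parse error naming
#'   the line, and a reaction referencing an undeclared species raises a
#'   validation error naming the reaction.
#' @export
read_sbml <- function(path) {
  doc <- xml2::read_xml(path)  # malformed XML -> error with line number
  model_node <- xml2::xml_find_first(doc, ".//*[local-name() = 'model']")
  if (is.na(xml2::xml_name(model_node))) stop("no <model> element in ", path)
  model_id <- xml2::xml_attr(model_node, "id")
  if (is.na(model_id)) model_id <- tools::file_path_sans_ext(basename(path))

  sp_nodes <- xml2::xml_find_all(doc, ".//*[local-name() = 'species']")
  if (length(sp_nodes) == 0L) stop("no species declared in ", path)
  sp_id <- xml2::xml_attr(sp_nodes, "id")
  strip_m <- all(startsWith(sp_id, "M_"))
  sp_boundary <- xml2::xml_attr(sp_nodes, "boundaryCondition") %in% "true"
  formula <- xml2::xml_attr(sp_nodes, "chemicalFormula")
  charge <- suppressWarnings(as.integer(xml2::xml_attr(sp_nodes, "charge")))
  metabolites <- list()
  boundary_ids <- character(0)
  for (i in seq_along(sp_nodes)) {
    id <- if (strip_m) sub("^M_", "", sp_id[i]) else sp_id[i]
    if (sp_boundary[i]) { boundary_ids <- c(boundary_ids, id); next }
    nm <- xml2::xml_attr(sp_nodes[i], "name")
    comp <- xml2::xml_attr(sp_nodes[i], "compartment")
    metabolites[[id]] <- metabolite(
      id, name = if (is.na(nm)) id else nm,
      compartment = if (is.na(comp) || identical(comp, "default")) {
        compartment_from_id(id)
      } else comp,
      formula = formula[i], charge = charge[i])
  }

  # global parameters (L3 fbc bound references)
  par_nodes <- xml2::xml_find_all(
    doc, ".//*[local-name() = 'listOfParameters']/*[local-name() = 'parameter']")
  par_val <- stats::setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                             xml2::xml_attr(par_nodes, "id"))

  rx_nodes <- xml2::xml_find_all(doc, ".//*[local-name() = 'reaction']")
  if (length(rx_nodes) == 0L) stop("no reactions declared in ", path)
  rx_id <- xml2::xml_attr(rx_nodes, "id")
  strip_r <- all(startsWith(rx_id, "R_"))
  reactions <- list()
  for (i in seq_along(rx_nodes)) {
    node <- rx_nodes[i]
    id <- if (strip_r) sub("^R_", "", rx_id[i]) else rx_id[i]
    nm <- xml2::xml_attr(node, "name")
    reversible <- !identical(xml2::xml_attr(node, "reversible"), "false")
    st <- numeric(0)
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(
        node, sprintf("./*[local-name() = '%s']/*[local-name() = 'speciesReference']", side))
      if (length(refs) == 0L) next
      sp <- xml2::xml_attr(refs, "species")
      if (strip_m) sp <- sub("^M_", "", sp)
      coef <- suppressWarnings(as.numeric(xml2::xml_attr(refs, "stoichiometry")))
      coef[is.na(coef)] <- 1
      sgn <- if (side == "listOfReactants") -1 else 1
      for (k in seq_along(sp)) {
        if (sp[k] %in% boundary_ids) next
        st[sp[k]] <- (if (is.na(st[sp[k]])) 0 else st[sp[k]]) + sgn * coef[k]
      }
    }
    st <- st[st != 0]
    if (length(st) == 0L) next  # pure-boundary pseudo reaction
    # bounds: L3 fbc attributes, else L2 kinetic-law parameters
    lb <- ub <- NA_real_
    lb_ref <- xml2::xml_attr(node, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(node, "upperFluxBound")
    if (!is.na(lb_ref) && lb_ref %in% names(par_val)) lb <- par_val[[lb_ref]]
    if (!is.na(ub_ref) && ub_ref %in% names(par_val)) ub <- par_val[[ub_ref]]
    if (is.na(lb) || is.na(ub)) {
      kl <- xml2::xml_find_all(
        node, ".//*[local-name() = 'parameter']")
      if (length(kl)) {
        kid <- xml2::xml_attr(kl, "id")
        kval <- as.numeric(xml2::xml_attr(kl, "value"))
        if (is.na(lb) && "LOWER_BOUND" %in% kid) lb <- kval[match("LOWER_BOUND", kid)]
        if (is.na(ub) && "UPPER_BOUND" %in% kid) ub <- kval[match("UPPER_BOUND", kid)]
      }
    }
    if (is.na(lb) || is.na(ub)) {
      warning("reaction '", id, "': no flux bounds found; applying defaults")
      if (is.na(lb)) lb <- if (reversible) -DEFAULT_FLUX_BOUND else 0
      if (is.na(ub)) ub <- DEFAULT_FLUX_BOUND
    }
    ga <- NA_character_; ecs <- character(0)
    note_p <- xml2::xml_text(xml2::xml_find_all(node, ".//*[local-name() = 'p']"))
    for (p in note_p) {
      if (grepl("^\\s*GENE_ASSOCIATION:", p)) {
        ga <- trimws(sub("^\\s*GENE_ASSOCIATION:", "", p))
      }
      if (grepl("^\\s*EC_NUMBER:", p)) {
        ecs <- strsplit(trimws(sub("^\\s*EC_NUMBER:", "", p)), "\\s+")[[1]]
      }
    }
    reactions[[id]] <- reaction(id, st, lower_bound = lb, upper_bound = ub,
                                name = if (is.na(nm)) id else nm,
                                gene_association = ga, ec_numbers = ecs)
  }

  # objective: active fbc objective, else biomass-name guess
  objective_id <- NULL
  fo <- xml2::xml_find_first(doc, ".//*[local-name() = 'fluxObjective']")
  if (!is.na(xml2::xml_name(fo))) {
    oid <- xml2::xml_attr(fo, "reaction")
    if (!is.na(oid)) {
      if (strip_r) oid <- sub("^R_", "", oid)
      if (oid %in% names(reactions)) objective_id <- oid
    }
  }
  if (is.null(objective_id)) {
    guess <- grep("biomass", names(reactions), ignore.case = TRUE, value = TRUE)
    objective_id <- if (length(guess)) guess[1] else names(reactions)[1]
  }
  metabolic_model(model_id, metabolites, reactions, objective_id)
}
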