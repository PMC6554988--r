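DEFAULT_FLUX_BOUND <- 1000

#' Parse a reaction equation string
#'
#' Accepts explicit-coefficient equations over compartment-tagged metabolite
#' ids, e.g. \code{"A_c0 + 2 B_c0 -> C_c0"}. Recognized arrows:
#' \code{"->"}, \code{"=>"} (irreversible) and \code{"<=>"}, \code{"<->"},
#' \code{"⇌"} (reversible). A one-sided equation such as
#' \code{"A_e0 ->"} denotes an exchange.
#'
#' @param eq Equation string.
#' @return A list with \code{stoichiometry} (named numeric, negative =
#'   consumed) and \code{reversible} (logical).
#' @export
parse_equation <- function(eq) {
  eq <- trimws(eq)
  rev_arrows <- c("<=>", "<->", "⇌")
  irr_arrows <- c("-->", "->", "=>")
  arrow <- NULL; reversible <- NA
  for (a in rev_arrows) if (grepl(a, eq, fixed = TRUE)) { arrow <- a; reversible <- TRUE; break }
  if (is.null(arrow)) {
    for (a in irr_arrows) if (grepl(a, eq, fixed = TRUE)) { arrow <- a; reversible <- FALSE; break }
  }
  if (is.null(arrow)) stop("no reaction arrow found in equation: ", eq)
  sides <- strsplit(eq, arrow, fixed = TRUE)[[1]]
  if (length(sides) == 1L) sides <- c(sides, "")
  if (length(sides) != 2L) stop("malformed equation: ", eq)
  parse_side <- function(s, sign) {
    s <- trimws(s)
    if (!nzchar(s)) return(numeric(0))
    terms <- trimws(strsplit(s, " + ", fixed = TRUE)[[1]])
    out <- numeric(0)
    for (term in terms) {
      m <- regexec("^([0-9]*\\.?[0-9]+(?:[eE][+-]?[0-9]+)?\\s+)?(\\S+)$", term)
      g <- regmatches(term, m)[[1]]
      if (length(g) == 0L) stop("unparsable term '", term, "' in equation: ", eq)
      coef <- if (nzchar(trimws(g[2]))) as.numeric(trimws(g[2])) else 1
      met <- g[3]
      out[met] <- (if (is.na(out[met])) 0 else out[met]) + sign * coef
    }
    out
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  st <- lhs
  for (m in names(rhs)) st[m] <- (if (is.na(st[m])) 0 else st[m]) + rhs[m]
  st <- st[st != 0]
  if (length(st) == 0L) stop("equation has empty net stoichiometry: ", eq)
  list(stoichiometry = st, reversible = reversible)
}

#' Read a metabolic model from a tab-separated reaction table
#'
#' One reaction per row. Two dialects are accepted: a headered table with
#' columns \code{id}, \code{equation} and optionally \code{name},
#' \code{reversibility}, \code{gene_association}, \code{lower_bound},
#' \code{upper_bound}; or a bare positional table \code{id <TAB> equation
#' <TAB> reversibility [<TAB> gene_association]}. Reversibility markers
#' \code{"rev"}/\code{"irrev"} (or the equation arrow when the column is
#' absent) set default bounds of \code{[-1000, 1000]} / \code{[0, 1000]};
#' explicit bound columns override them. Comment lines \code{"# model:"} and
#' \code{"# objective:"} carry the model id and objective reaction.
#' Metabolites are inferred from the equations, compartments from their id
#' suffixes.
#'
#' @param path Path to the TSV file.
#' @return A [metabolic_model()].
#' @export
read_tsv_model <- function(path) {
  lines <- readLines(path, warn = FALSE)
  model_id <- tools::file_path_sans_ext(basename(path))
  objective_id <- NULL
  header_meta <- grep("^#", lines, value = TRUE)
  for (hm in header_meta) {
    if (grepl("^#\\s*model:", hm)) model_id <- trimws(sub("^#\\s*model:", "", hm))
    if (grepl("^#\\s*objective:", hm)) objective_id <- trimws(sub("^#\\s*objective:", "", hm))
  }
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no reaction rows in ", path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  has_header <- identical(tolower(cells[[1]][1]), "id")
  if (has_header) {
    cols <- tolower(trimws(cells[[1]]))
    rows <- cells[-1]
    get <- function(row, col) {
      k <- match(col, cols)
      if (is.na(k) || k > length(row)) NA_character_ else row[k]
    }
  } else {
    rows <- cells
    get <- function(row, col) {
      k <- match(col, c("id", "equation", "reversibility", "gene_association"))
      if (is.na(k) || k > length(row)) NA_character_ else row[k]
    }
  }
  reactions <- list()
  for (i in seq_along(rows)) {
    row <- rows[[i]]
    id <- trimws(get(row, "id"))
    eq <- get(row, "equation")
    if (is.na(id) || !nzchar(id) || is.na(eq)) {
      stop("row ", i + has_header, " of ", path, ": missing id or equation")
    }
    parsed <- tryCatch(parse_equation(eq), error = function(e) {
      stop("row ", i + has_header, " of ", path, ": ", conditionMessage(e))
    })
    revmark <- get(row, "reversibility")
    reversible <- if (!is.na(revmark) && nzchar(trimws(revmark))) {
      tolower(trimws(revmark)) %in% c("rev", "reversible", "r", "true")
    } else parsed$reversible
    lb <- suppressWarnings(as.numeric(get(row, "lower_bound")))
    ub <- suppressWarnings(as.numeric(get(row, "upper_bound")))
    if (is.na(lb)) lb <- if (reversible) -DEFAULT_FLUX_BOUND else 0
    if (is.na(ub)) ub <- DEFAULT_FLUX_BOUND
    ga <- get(row, "gene_association")
    nm <- get(row, "name")
    if (!is.null(reactions[[id]])) stop("duplicate reaction id '", id, "' in ", path)
    reactions[[id]] <- reaction(
      id, parsed$stoichiometry, lower_bound = lb, upper_bound = ub,
      name = if (is.na(nm)) id else nm,
      gene_association = if (is.na(ga)) NA_character_ else ga
    )
  }
  met_ids <- sort(unique(unlist(lapply(reactions, function(r) names(r$stoichiometry)))))
  metabolites <- lapply(met_ids, metabolite)
  if (is.null(objective_id)) {
    guess <- grep("biomass", names(reactions), ignore.case = TRUE, value = TRUE)
    objective_id <- if (length(guess)) guess[1] else names(reactions)[1]
  }
  metabolic_model(model_id, metabolites, reactions, objective_id)
}

#' Write a metabolic model as a tab-separated reaction table
#'
#' Writes the headered dialect of [read_tsv_model()] with explicit bounds,
#' so that write-then-read preserves ids, coefficients and bounds exactly.
#'
#' @param model A [metabolic_model()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_tsv_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# model: ", model$id),
               paste0("# objective: ", model$objective_id),
               paste("id", "name", "equation", "reversibility",
                     "lower_bound", "upper_bound", "gene_association",
                     sep = "\t")), con)
  for (r in model$reactions) {
    writeLines(paste(
      r$id, r$name, reaction_equation(r),
      if (r$lower_bound < 0) "rev" else "irrev",
      format(r$lower_bound, digits = 17),
      format(r$upper_bound, digits = 17),
      if (is.na(r$gene_association)) "" else r$gene_association,
      sep = "\t"), con)
  }
  invisible(path)
}
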