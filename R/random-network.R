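# run code under a local, restorable RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a random metabolic network
#'
#' Two generator modes serve two testing purposes.
#'
#' \code{mode = "fba"} builds a small connected mass-flow network with one
#' source exchange, one sink exchange and random internal conversions, every
#' metabolite reachable, all bounds finite — the substrate for comparing
#' the LP engine against the brute-force enumeration oracle.
#'
#' \code{mode = "scale_free"} draws metabolite degrees from a discrete
#' power law \code{P(k) ~ k^-gamma} and wires stubs into random two-sided
#' reactions, producing a network whose degree distribution follows the
#' target exponent — the substrate for degree-slope recovery tests.
#'
#' Both modes are deterministic for a fixed seed.
#'
#' @param n_metabolites Number of internal metabolites (>= 2).
#' @param n_reactions Number of internal reactions (\code{"fba"} mode;
#'   ignored in \code{"scale_free"} mode where the stub count decides).
#' @param seed Integer seed.
#' @param mode \code{"fba"} or \code{"scale_free"}.
#' @param gamma Target power-law exponent (\code{"scale_free"} mode).
#' @param k_max Largest degree sampled (\code{"scale_free"} mode, default 15).
#' @return A [metabolic_model()]. In \code{"fba"} mode the objective is the
#'   sink exchange.
#' @export
random_network <- function(n_metabolites, n_reactions = NULL, seed = 1L,
                           mode = c("fba", "scale_free"), gamma = 2.5,
                           k_max = 15L) {
  mode <- match.arg(mode)
  stopifnot(n_metabolites >= 2)
  if (mode == "fba") {
    stopifnot(!is.null(n_reactions), n_reactions >= 2)
    with_seed(seed, random_fba_network(n_metabolites, n_reactions))
  } else {
    with_seed(seed, random_scalefree_network(n_metabolites, gamma, k_max))
  }
}

random_fba_network <- function(m, n) {
  for (attempt in 1:25) {
    mets <- sprintf("M%d_c0", seq_len(m))
    rxns <- list()
    # backbone: source exchange -> M1 ... Mm -> sink exchange
    rxns[["EX_src"]] <- reaction("EX_src", stats::setNames(-1, mets[1]),
                                 lower_bound = -stats::runif(1, 1, 10),
                                 upper_bound = 0, is_exchange = TRUE)
    rxns[["EX_snk"]] <- reaction("EX_snk", stats::setNames(-1, mets[m]),
                                 lower_bound = 0,
                                 upper_bound = stats::runif(1, 5, 20),
                                 is_exchange = TRUE)
    n_internal <- n - 2L
    # a random spanning chain guarantees connectivity and a source-to-sink path
    mid <- if (m > 2L) 2:(m - 1L) else integer(0)
    if (length(mid) > 1L) mid <- sample(mid)
    path <- c(1L, mid, m)
    for (i in seq_len(n_internal)) {
      id <- sprintf("R%d", i)
      if (i < m) {
        a <- path[i]; bmet <- path[i + 1L]
      } else {
        a <- sample.int(m, 1L); bmet <- sample.int(m, 1L)
        if (a == bmet) bmet <- if (bmet == m) 1L else bmet + 1L
      }
      coef_a <- sample(1:2, 1L); coef_b <- sample(1:2, 1L)
      st <- stats::setNames(c(-coef_a, coef_b), c(mets[a], mets[bmet]))
      reversible <- stats::runif(1) < 0.3
      rxns[[id]] <- reaction(
        id, st,
        lower_bound = if (reversible) -stats::runif(1, 1, 10) else 0,
        upper_bound = stats::runif(1, 1, 10))
    }
    model <- metabolic_model(sprintf("random_fba_%d_%d", m, n),
                             lapply(mets, metabolite), rxns, "EX_snk")
    sol <- fba(model, "EX_snk", "max")
    if (identical(sol$status, "optimal")) return(model)
  }
  stop("failed to generate a feasible random network after 25 attempts")
}

# sample degrees from P(k) ~ k^-gamma on 1..k_max, wire stubs pairwise
random_scalefree_network <- function(m, gamma, k_max) {
  k <- seq_len(k_max)
  p <- k^(-gamma); p <- p / sum(p)
  deg <- sample(k, m, replace = TRUE, prob = p)
  mets <- sprintf("M%d_c0", seq_len(m))
  stubs <- sample(rep.int(seq_len(m), deg))
  if (length(stubs) %% 2L == 1L) stubs <- stubs[-length(stubs)]
  half <- length(stubs) / 2L
  lhs <- stubs[seq_len(half)]; rhs <- stubs[half + seq_len(half)]
  rxns <- vector("list", half)
  for (i in seq_len(half)) {
    a <- lhs[i]; b <- rhs[i]
    st <- if (a == b) stats::setNames(-1, mets[a]) else {
      stats::setNames(c(-1, 1), c(mets[a], mets[b]))
    }
    rxns[[i]] <- reaction(sprintf("R%d", i), st, lower_bound = 0,
                          upper_bound = DEFAULT_FLUX_BOUND,
                          is_exchange = length(st) == 1L)
  }
  names(rxns) <- vapply(rxns, `[[`, "", "id")
  metabolic_model(sprintf("random_scalefree_%d", m), lapply(mets, metabolite),
                  rxns, names(rxns)[1], validate = TRUE)
}
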