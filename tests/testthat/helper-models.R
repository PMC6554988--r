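# Shared fixtures. The core model is expensive enough to build once.

core_model_cached <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- build_core_model()
    m
  }
})

# ->A, A->B, B->  with a capacity on the inflow
chain_model <- function(cap = 10) {
  metabolic_model(
    "chain",
    list(metabolite("A_c0"), metabolite("B_c0")),
    list(reaction("EX_A", c(A_c0 = -1), lower_bound = -cap, upper_bound = 0),
         reaction("R_AB", c(A_c0 = -1, B_c0 = 1), 0, 1000),
         reaction("EX_B", c(B_c0 = -1), 0, 1000)),
    objective_id = "EX_B")
}

# two parallel routes with individual capacities feeding one sink
diamond_model <- function(cap1 = 3, cap2 = 7) {
  metabolic_model(
    "diamond",
    list(metabolite("A_c0"), metabolite("B_c0"), metabolite("C_c0"),
         metabolite("D_c0")),
    list(reaction("EX_A", c(A_c0 = -1), -1000, 0),
         reaction("R1", c(A_c0 = -1, B_c0 = 1), 0, cap1),
         reaction("R2", c(A_c0 = -1, C_c0 = 1), 0, cap2),
         reaction("R3", c(B_c0 = -1, D_c0 = 1), 0, 1000),
         reaction("R4", c(C_c0 = -1, D_c0 = 1), 0, 1000),
         reaction("EX_D", c(D_c0 = -1), 0, 1000)),
    objective_id = "EX_D")
}

# reference growth constraints for the core model
core_growth_bounds <- function(uptake = 14.9, ngam = 3.5) {
  list(EX_ch4_e0 = c(-uptake, -uptake), NGAM = c(ngam, ngam))
}

# LP data (dense S, bounds) straight from a model, for oracle comparisons
lp_pieces <- function(model, extra_bounds = NULL) {
  S <- as.matrix(stoichiometric_matrix(model))
  b <- reaction_bounds(model)
  if (!is.null(extra_bounds)) {
    for (id in names(extra_bounds)) b[id, ] <- extra_bounds[[id]]
  }
  list(S = S, lb = b[, "lb"], ub = b[, "ub"], ids = colnames(S))
}
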