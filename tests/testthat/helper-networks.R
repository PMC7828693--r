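# Small networks and tables built in code for the unit tests.

toy_metabolites <- function() {
  tibble::tibble(
    id = c("A_e", "B_e", "A_c", "B_c", "X_c", "atp_c", "adp_c"),
    name = c("A (out)", "B (out)", "A", "B", "X", "ATP", "ADP"),
    compartment = c("extracellular", "extracellular", rep("cytosol", 5)),
    carbons = c(2L, 2L, 2L, 2L, 2L, 0L, 0L),
    role = c("boundary", "boundary", rep("substrate", 3), "cofactor", "cofactor"),
    pair = "",
    reduced = 0L
  )
}

toy_reaction_row <- function(id, equation, reversible = 0, lb = 0, ub = 10,
                             enzymes = character(0), subsystem = "core",
                             pseudo = 0L) {
  tibble::tibble(
    id = id, enzyme_no = NA_integer_, name = id, compartment = "cytosol",
    equation = equation, reversible = as.integer(reversible),
    lb = lb, ub = ub, enzymes = list(enzymes), subsystem = subsystem,
    pseudo = as.integer(pseudo)
  )
}

# Uptake of A (capacity 1), two routes to B: direct (1 ATP) or via X (2 ATP).
# The ATP optimum is 2, attained by routing everything through X.
toy_branched_network <- function() {
  rx <- dplyr::bind_rows(
    toy_reaction_row("ex_a", "A_e ->", lb = -1, ub = 0, subsystem = "exchange"),
    toy_reaction_row("ex_b", "B_e ->", lb = 0, ub = 10, subsystem = "exchange"),
    toy_reaction_row("t_a", "A_e -> A_c"),
    toy_reaction_row("t_b", "B_c -> B_e"),
    toy_reaction_row("r1", "A_c + adp_c -> B_c + atp_c"),
    toy_reaction_row("r2", "A_c + adp_c -> X_c + atp_c"),
    toy_reaction_row("r3", "X_c + adp_c -> B_c + atp_c"),
    toy_reaction_row("drain", "atp_c -> adp_c", subsystem = "atp_drain",
                     pseudo = 1L)
  )
  build_network(rx, toy_metabolites())
}

# A_e -> A -> B -> B_e straight line, no choices: every flux is pinned.
toy_linear_network <- function() {
  rx <- dplyr::bind_rows(
    toy_reaction_row("ex_a", "A_e ->", lb = -1, ub = -1, subsystem = "exchange"),
    toy_reaction_row("ex_b", "B_e ->", lb = 0, ub = 10, subsystem = "exchange"),
    toy_reaction_row("t_a", "A_e -> A_c"),
    toy_reaction_row("r1", "A_c -> B_c"),
    toy_reaction_row("t_b", "B_c -> B_e"),
    toy_reaction_row("drain", "atp_c -> adp_c", subsystem = "atp_drain",
                     pseudo = 1L)
  )
  build_network(rx, toy_metabolites())
}

# every preset x oxygen combination
preset_oxygen_grid <- function() {
  expand.grid(preset = vickerflux_presets(), aerobic = c(TRUE, FALSE),
              stringsAsFactors = FALSE)
}

expect_rat_equal <- function(x, y, tol = 1e-9) {
  expect_true(abs(x - y) < tol,
              label = paste0(format(x), " == ", format(y)))
}

# carbon flowing through the exchanges, export-positive
exchange_carbon_flux <- function(solution, network) {
  rx <- network$reactions
  ex <- rx$id[rx$exchange]
  carbons <- stats::setNames(network$metabolites$carbons,
                             network$metabolites$id)
  v <- stats::setNames(solution$fluxes$flux, solution$fluxes$reaction)
  sum(vapply(ex, function(id) {
    st <- network$stoich[network$stoich$reaction == id, ]
    # exchange is met_e -> with coefficient -1: export-positive flux carries
    # carbon out
    -sum(st$coef * carbons[st$metabolite]) * v[id]
  }, numeric(1)))
}

all_cofactor_closures <- function(solution, network) {
  m <- network$metabolites
  pairs <- unique(m[nzchar(m$pair), c("compartment", "pair")])
  vapply(seq_len(nrow(pairs)), function(i) {
    cofactor_closure(solution, network, pairs$compartment[i], pairs$pair[i])
  }, numeric(1))
}
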