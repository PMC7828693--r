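# Network data model: metabolites, reactions, stoichiometric matrix, and the
# mass/redox audits that guard the transcription of the enzyme map.

COMPARTMENTS <- c("glycosome", "cytosol", "mitochondrion", "extracellular")

#' Packaged metabolite registry
#'
#' The curated list of chemical species used by the core-metabolism models,
#' one row per metabolite and compartment. Carbon counts follow the carbon
#' skeleton of each compound; CoA, adenine nucleotides, NAD(H), ubiquinone,
#' cytochrome c and the proton-motive coupling unit are carried with zero
#' carbons, so carbon balance tracks substrate skeletons only. Redox partners
#' (NAD+/NADH, Q/QH2, oxidized/reduced cytochrome c) are linked through the
#' `pair` label, with `reduced` flagging the reduced member.
#'
#' @return A tibble with columns `id`, `name`, `compartment`, `carbons`,
#'   `role` (substrate/cofactor/boundary), `pair` and `reduced`.
#' @examples
#' vickerflux_metabolites()
#' @export
vickerflux_metabolites <- function() {
  read_metabolite_table(vflx_extdata("metabolites.tsv"))
}

read_metabolite_table <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    id = readr::col_character(),
    name = readr::col_character(),
    compartment = readr::col_character(),
    carbons = readr::col_integer(),
    role = readr::col_character(),
    pair = readr::col_character(),
    reduced = readr::col_integer()
  ))
  tbl$pair[is.na(tbl$pair)] <- ""
  validate_metabolites(tbl)
  tbl
}

validate_metabolites <- function(tbl) {
  if (anyDuplicated(tbl$id)) {
    stop("duplicate metabolite ids: ",
         paste(unique(tbl$id[duplicated(tbl$id)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(tbl$compartment), COMPARTMENTS)
  if (length(bad)) {
    stop("unknown compartments: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(tbl$carbons < 0)) stop("negative carbon counts", call. = FALSE)
  misplaced <- tbl$id[tbl$role == "boundary" & tbl$compartment != "extracellular"]
  if (length(misplaced)) {
    stop("boundary metabolites outside the extracellular compartment: ",
         paste(misplaced, collapse = ", "), call. = FALSE)
  }
  # redox pairs must be symmetric within one compartment: exactly one
  # oxidized and one reduced member per (compartment, pair label)
  paired <- tbl[nzchar(tbl$pair), ]
  if (nrow(paired)) {
    key <- paste(paired$compartment, paired$pair)
    for (k in unique(key)) {
      members <- paired[key == k, ]
      if (nrow(members) != 2 || sum(members$reduced) != 1) {
        stop("cofactor pair '", k, "' is not a symmetric oxidized/reduced pair",
             call. = FALSE)
      }
    }
  }
  invisible(tbl)
}

#' Read a curated reaction table
#'
#' Reads the tab-separated reaction dialect used by the packaged models:
#' columns `id`, `enzyme_no` (number in the curated enzyme map, where one
#' exists), `name`, `compartment` (comma-separated for transports),
#' `equation`, `reversible` (0/1), `lb`, `ub`, `enzymes` (comma-separated
#' enzyme identifiers whose joint presence activates the reaction; empty for
#' transports, exchanges and pseudo-reactions) and `pseudo` (0/1 marking
#' drains, shuttles and coupling sinks). Equations are written
#' `"a + 2 b -> c"` with metabolite ids from the metabolite registry;
#' coefficients may be integers, fractions (`1/2`) or finite decimals (`0.5`)
#' and are stored exactly. Exchange reactions are one-sided
#' (`"glc_e ->"`) and export-positive, so nutrient uptake is a negative flux.
#'
#' @param path Path to a TSV file.
#' @return A tibble, one row per reaction, with `enzymes` as a list-column.
#' @seealso [build_network()], [vickerflux_reactions()]
#' @export
read_reaction_table <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    id = readr::col_character(),
    enzyme_no = readr::col_integer(),
    name = readr::col_character(),
    compartment = readr::col_character(),
    equation = readr::col_character(),
    reversible = readr::col_integer(),
    lb = readr::col_double(),
    ub = readr::col_double(),
    enzymes = readr::col_character(),
    subsystem = readr::col_character(),
    pseudo = readr::col_integer()
  ))
  tbl$enzymes <- lapply(tbl$enzymes, function(x) {
    if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ",", fixed = TRUE)[[1]]
  })
  tbl$equation[is.na(tbl$equation)] <- ""
  tbl
}

#' The full curated core-metabolism reaction table
#'
#' The packaged transcription of the trypanosomatid core carbon/energy map:
#' glycosomal glycolysis, the cytosolic lower glycolytic steps, the glycosomal
#' succinate branch (PEP carboxykinase, malate dehydrogenase, fumarate
#' hydratase, NADH-dependent fumarate reductase), pyruvate dismutation
#' (pyruvate dehydrogenase / acetate:succinate CoA transferase / succinyl-CoA
#' ligase on the oxidative side, pyruvate decarboxylase / Zn-type alcohol
#' dehydrogenase on the reductive side), the mitochondrial methylmalonyl-CoA
#' propionate cycle, the respiratory chain (complexes I-V, alternative
#' oxidase, cytochrome c), transports, exchanges and the per-compartment ATP
#' drains that form the optimization objective.
#'
#' @return A tibble in the [read_reaction_table()] dialect.
#' @export
vickerflux_reactions <- function() {
  read_reaction_table(vflx_extdata("reactions_core.tsv"))
}

# Parse one equation string into a signed exact stoichiometry.
# Returns a data.frame(metabolite, num, den); consumption negative.
parse_equation <- function(eq, context = "equation") {
  eq <- trimws(eq)
  if (!grepl("->", eq, fixed = TRUE)) {
    stop("malformed stoichiometry in ", context, ": no '->' in '", eq, "'",
         call. = FALSE)
  }
  sides <- strsplit(eq, "->", fixed = TRUE)[[1]]
  sides <- c(sides, rep("", 2 - length(sides)))
  parse_side <- function(side, sign) {
    side <- trimws(side)
    if (!nzchar(side)) {
      return(data.frame(metabolite = character(0), num = numeric(0),
                        den = numeric(0)))
    }
    terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
    out <- lapply(terms, function(term) {
      if (!nzchar(term)) {
        stop("malformed stoichiometry in ", context, ": empty term", call. = FALSE)
      }
      bits <- strsplit(term, "[[:space:]]+")[[1]]
      if (length(bits) == 1) {
        coef <- rat(1)
        met <- bits[1]
      } else if (length(bits) == 2) {
        coef <- tryCatch(rat_parse(bits[1]), error = function(e) {
          stop("malformed stoichiometry in ", context, ": bad coefficient '",
               bits[1], "'", call. = FALSE)
        })
        met <- bits[2]
      } else {
        stop("malformed stoichiometry in ", context, ": term '", term, "'",
             call. = FALSE)
      }
      data.frame(metabolite = met, num = sign * coef$num, den = coef$den)
    })
    do.call(rbind, out)
  }
  out <- rbind(parse_side(sides[1], -1), parse_side(sides[2], +1))
  # merge duplicate metabolites (a species on both sides) exactly
  if (anyDuplicated(out$metabolite)) {
    merged <- lapply(split(out, out$metabolite), function(d) {
      s <- rat_sum(list(num = d$num, den = d$den))
      data.frame(metabolite = d$metabolite[1], num = s$num, den = s$den)
    })
    out <- do.call(rbind, merged)
  }
  out <- out[out$num != 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a compartmentalized metabolic network
#'
#' Assembles a validated `flux_network` from a curated reaction table: parses
#' every equation into an exact signed stoichiometry, resolves metabolites
#' against the registry, classifies exchanges (reactions touching the
#' extracellular boundary), and audits every non-exchange reaction for carbon
#' balance. Transcription errors surface here, not at solve time: a malformed
#' equation names its row, and a carbon-unbalanced reaction names the reaction
#' and its carbon deficit.
#'
#' @param reactions A reaction tibble in the [read_reaction_table()] dialect
#'   (path to a TSV also accepted). Defaults to the full curated table.
#' @param metabolites Metabolite registry tibble; defaults to the packaged one.
#' @return An object of class `flux_network`: a list with tibbles
#'   `metabolites`, `reactions` (with resolved bounds) and `stoich` (long
#'   triplet form with exact `num`/`den` and numeric `coef`).
#' @examples
#' net <- build_network()
#' net
#' @export
build_network <- function(reactions = vickerflux_reactions(),
                          metabolites = vickerflux_metabolites()) {
  if (is.character(reactions)) reactions <- read_reaction_table(reactions)
  reactions <- tibble::as_tibble(reactions)
  validate_metabolites(metabolites)
  if (anyDuplicated(reactions$id)) {
    stop("duplicate reaction ids: ",
         paste(unique(reactions$id[duplicated(reactions$id)]), collapse = ", "),
         call. = FALSE)
  }
  if (!"pseudo" %in% names(reactions)) reactions$pseudo <- 0L
  if (!"subsystem" %in% names(reactions)) reactions$subsystem <- NA_character_
  if (!is.list(reactions$enzymes)) {
    reactions$enzymes <- lapply(reactions$enzymes, function(x) {
      if (is.null(x) || is.na(x) || !nzchar(x)) character(0)
      else strsplit(x, ",", fixed = TRUE)[[1]]
    })
  }

  stoich <- purrr::map2_dfr(reactions$equation, reactions$id, function(eq, id) {
    if (!nzchar(eq)) {
      return(tibble::tibble(reaction = character(0), metabolite = character(0),
                            num = numeric(0), den = numeric(0)))
    }
    s <- parse_equation(eq, context = paste0("reaction '", id, "'"))
    tibble::tibble(reaction = id, metabolite = s$metabolite,
                   num = s$num, den = s$den)
  })
  if (!nrow(stoich)) {
    stoich <- tibble::tibble(reaction = character(0), metabolite = character(0),
                             num = numeric(0), den = numeric(0))
  }

  unknown <- setdiff(unique(stoich$metabolite), metabolites$id)
  if (length(unknown)) {
    rows <- unique(stoich$reaction[stoich$metabolite %in% unknown])
    stop("unknown metabolite id(s) ", paste(unknown, collapse = ", "),
         " in reaction(s) ", paste(rows, collapse = ", "), call. = FALSE)
  }
  stoich$coef <- stoich$num / stoich$den

  comp <- stats::setNames(metabolites$compartment, metabolites$id)
  reactions$boundary <- vapply(reactions$id, function(id) {
    mets <- stoich$metabolite[stoich$reaction == id]
    any(comp[mets] == "extracellular")
  }, logical(1))
  # an exchange involves extracellular species only: it is the open boundary
  reactions$exchange <- vapply(reactions$id, function(id) {
    mets <- stoich$metabolite[stoich$reaction == id]
    length(mets) > 0 && all(comp[mets] == "extracellular")
  }, logical(1))

  empty <- reactions$id[!reactions$id %in% stoich$reaction]
  if (length(empty)) {
    # pseudo sinks (e.g. the coupling sink at P/O 0) may be one-sided, but a
    # fully empty stoichiometry is only legal for nothing
    stop("reaction(s) with empty stoichiometry: ", paste(empty, collapse = ", "),
         call. = FALSE)
  }

  for (i in seq_len(nrow(reactions))) {
    id <- reactions$id[i]
    rows <- stoich[stoich$reaction == id, ]
    two_sided <- any(rows$num < 0) && any(rows$num > 0)
    if (!two_sided && !reactions$exchange[i] && !reactions$pseudo[i]) {
      stop("reaction '", id, "' is one-sided but is neither an exchange nor ",
           "a pseudo-reaction", call. = FALSE)
    }
    if (!reactions$reversible[i] && reactions$lb[i] < 0 && !reactions$exchange[i]) {
      stop("irreversible reaction '", id, "' has negative lower bound",
           call. = FALSE)
    }
  }

  net <- structure(
    list(metabolites = tibble::as_tibble(metabolites),
         reactions = reactions,
         stoich = stoich),
    class = "flux_network"
  )

  audit <- check_carbon_balance(net)
  bad <- audit[!audit$pass, ]
  if (nrow(bad)) {
    stop("carbon-unbalanced reaction(s): ",
         paste0(bad$reaction, " (net carbon ", bad$net_carbon_exact, ")",
                collapse = ", "),
         call. = FALSE)
  }
  net
}

#' @export
print.flux_network <- function(x, ...) {
  n_int <- sum(x$metabolites$compartment != "extracellular" &
                 x$metabolites$id %in% x$stoich$metabolite)
  cat("<flux_network> ", nrow(x$reactions), " reactions (",
      sum(x$reactions$exchange), " exchanges), ",
      nrow(x$metabolites), " metabolites (", n_int, " internal, in use)\n",
      sep = "")
  comps <- table(x$metabolites$compartment)
  cat("  compartments:",
      paste(names(comps), paste0("(", comps, ")"), collapse = ", "), "\n")
  invisible(x)
}

internal_metabolites <- function(network) {
  used <- unique(network$stoich$metabolite)
  network$metabolites$id[network$metabolites$id %in% used]
}

#' Stoichiometric matrix of a network
#'
#' Builds the metabolite x reaction matrix S used by the steady-state
#' constraint S v = 0. Every species that occurs in a reaction is a row,
#' including extracellular ones: the system is opened at the boundary by the
#' one-sided exchange reactions (`met_e ->`), which are the only unbalanced
#' entry/exit points, so a transporter can never smuggle matter past a closed
#' exchange. Column order follows the reaction table; row order follows the
#' metabolite registry restricted to species in use.
#'
#' @param network A `flux_network`.
#' @param exact If `TRUE`, return exact numerator/denominator matrices
#'   alongside the numeric matrix.
#' @return A dense numeric matrix with dimnames (or, with `exact = TRUE`, a
#'   list with elements `S`, `num`, `den`).
#' @export
stoichiometric_matrix <- function(network, exact = FALSE) {
  stopifnot(inherits(network, "flux_network"))
  rows <- internal_metabolites(network)
  cols <- network$reactions$id
  S <- matrix(0, nrow = length(rows), ncol = length(cols),
              dimnames = list(rows, cols))
  keep <- network$stoich$metabolite %in% rows
  st <- network$stoich[keep, ]
  S[cbind(match(st$metabolite, rows), match(st$reaction, cols))] <- st$coef
  if (!exact) return(S)
  num <- den <- matrix(0, nrow = length(rows), ncol = length(cols),
                       dimnames = list(rows, cols))
  den[] <- 1
  num[cbind(match(st$metabolite, rows), match(st$reaction, cols))] <- st$num
  den[cbind(match(st$metabolite, rows), match(st$reaction, cols))] <- st$den
  list(S = S, num = num, den = den)
}

#' Audit carbon balance
#'
#' Computes, in exact rational arithmetic, the net carbon of each reaction
#' (sum over metabolites of coefficient x carbon count). A reaction passes if
#' its net carbon is exactly zero or it is an exchange (exchanges cross the
#' open boundary and are exempt). Zero-carbon carriers (CoA, nucleotides,
#' NAD(H), quinones) make acyl transfers balance on carbon skeletons alone.
#'
#' @param network A `flux_network`.
#' @param reaction Optional reaction id(s) to restrict the audit to.
#' @return A tibble with columns `reaction`, `net_carbon` (numeric),
#'   `net_carbon_exact` (character rational), `exchange`, `pass`.
#' @examples
#' audit <- check_carbon_balance(build_network())
#' all(audit$pass)
#' @export
check_carbon_balance <- function(network, reaction = NULL) {
  stopifnot(inherits(network, "flux_network"))
  ids <- reaction %||% network$reactions$id
  missing <- setdiff(ids, network$reactions$id)
  if (length(missing)) {
    stop("unknown reaction id(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!length(ids)) {
    return(tibble::tibble(reaction = character(0), net_carbon = numeric(0),
                          net_carbon_exact = character(0), exchange = logical(0),
                          pass = logical(0)))
  }
  carbons <- stats::setNames(network$metabolites$carbons, network$metabolites$id)
  out <- lapply(ids, function(id) {
    rows <- network$stoich[network$stoich$reaction == id, ]
    contrib <- rat_mul(list(num = rows$num, den = rows$den),
                       rat(carbons[rows$metabolite]))
    net <- rat_sum(contrib)
    is_ex <- network$reactions$exchange[network$reactions$id == id]
    tibble::tibble(
      reaction = id,
      net_carbon = rat_as_numeric(net),
      net_carbon_exact = rat_format(net),
      exchange = is_ex,
      pass = is_ex || rat_is_zero(net)
    )
  })
  dplyr::bind_rows(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Net cofactor turnover of a flux vector
#'
#' For a redox pair (NAD+/NADH per compartment, Q/QH2, cytochrome c) returns
#' the net production rate of the reduced member summed over reactions, i.e.
#' sum over reactions of flux x coefficient of the reduced species in the
#' given compartment. At steady state this is zero for every pair, because
#' cofactors are internal species: the glycosomal succinate branch, for
#' example, must regenerate exactly the NAD+ that glycosomal glycolysis
#' reduces. Restricting `reactions` to a pathway isolates that pathway's
#' contribution: the four-step succinate branch at unit succinate flux yields
#' -2, i.e. two moles of NAD+ regenerated per succinate.
#'
#' @param fluxes Either a `flux_solution` or a named numeric vector of fluxes
#'   (one per reaction; missing reactions count as zero).
#' @param network The `flux_network` the fluxes refer to.
#' @param compartment Compartment id.
#' @param pair Pair label, e.g. `"nad"`, `"q"`, `"cytc"`.
#' @param reactions Optional reaction ids to restrict the sum to.
#' @return A single number: net production of the reduced member.
#' @examples
#' net <- load_preset("vickermania")
#' v <- accounting_vector(net)
#' cofactor_closure(v, net, "glycosome", "nad") # 0 at steady state
#' @export
cofactor_closure <- function(fluxes, network, compartment, pair,
                             reactions = NULL) {
  stopifnot(inherits(network, "flux_network"))
  if (inherits(fluxes, "flux_solution")) {
    fluxes <- stats::setNames(fluxes$fluxes$flux, fluxes$fluxes$reaction)
  } else if (is.data.frame(fluxes)) {
    fluxes <- stats::setNames(fluxes$flux, fluxes$reaction)
  }
  m <- network$metabolites
  member <- m$id[m$compartment == compartment & m$pair == pair & m$reduced == 1]
  if (length(member) != 1) {
    stop("cofactor pair '", pair, "' not present in compartment '",
         compartment, "'", call. = FALSE)
  }
  st <- network$stoich[network$stoich$metabolite == member, ]
  if (!is.null(reactions)) st <- st[st$reaction %in% reactions, ]
  v <- fluxes[st$reaction]
  v[is.na(v)] <- 0
  sum(v * st$coef)
}
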