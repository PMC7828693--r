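# Organism presets and scenario resolution: which enzymes an organism carries
# decides which reactions exist; a scenario (oxygen, inhibitors, knockouts)
# decides their bounds.

preset_manifest <- function() {
  jsonlite::read_json(vflx_extdata("presets.json"), simplifyVector = TRUE)
}

#' Available organism presets
#'
#' @return Character vector of preset identifiers.
#' @export
vickerflux_presets <- function() names(preset_manifest())

#' Load an organism preset network
#'
#' Restricts the full curated reaction table to the enzyme complement of one
#' organism preset and builds the network:
#'
#' * `vickermania` - complexes I, II and V plus the alternative oxidase, but
#'   no complex III, complex IV or cytochrome c; glycolysis split between
#'   glycosome and cytosol; glycosomal succinate branch; pyruvate
#'   dehydrogenase with the acetate:succinate CoA-transferase/succinyl-CoA
#'   ligase cycle; pyruvate decarboxylase and Zn-type alcohol dehydrogenase;
#'   the mitochondrial methylmalonyl-CoA propionate cycle; no glycerol kinase.
#' * `phytomonas_like` - the same respiratory losses but no propionate cycle;
#'   glycerol kinase and the mitochondrial G3P:Q shuttle; excretes pyruvate
#'   and glycerol as well.
#' * `leishmania_like` - the full curated set including complexes III/IV and
#'   cytochrome c; the baseline against which the respiratory losses are
#'   diffed (see [preset_enzyme_diff()]).
#' * `tbrucei_bloodstream` - glycosomal glycolysis with the glycerol
#'   3-phosphate/dihydroxyacetone phosphate shuttle, alternative oxidase, and
#'   reversible glycerol kinase; excretes pyruvate and glycerol.
#'
#' Enzyme-gated reactions are kept when every required enzyme is in the
#' preset's active set; transports, drains and the redox shuttle are kept
#' unconditionally (unused ones are forced to zero flux by steady state);
#' nutrient exchanges (glucose, oxygen, CO2) are always kept and product
#' exchanges only for the preset's excretable end products.
#'
#' @param preset Preset id, one of [vickerflux_presets()].
#' @param reactions,metabolites Optional overrides of the packaged tables.
#' @return A `flux_network` with attributes `preset` and `excretes`.
#' @examples
#' net <- load_preset("vickermania")
#' any(grepl("complex III", net$reactions$name)) # FALSE
#' @export
load_preset <- function(preset,
                        reactions = vickerflux_reactions(),
                        metabolites = vickerflux_metabolites()) {
  manifest <- preset_manifest()
  if (!preset %in% names(manifest)) {
    stop("unknown preset '", preset, "'; available: ",
         paste(names(manifest), collapse = ", "), call. = FALSE)
  }
  def <- manifest[[preset]]
  active <- unlist(def$enzymes)
  if (is.character(reactions)) reactions <- read_reaction_table(reactions)
  gated <- vapply(reactions$enzymes, function(e) length(e) > 0, logical(1))
  keep_enzymatic <- vapply(reactions$enzymes, function(e) {
    length(e) == 0 || all(e %in% active)
  }, logical(1))
  ex_always <- c("ex_glc", "ex_o2", "ex_co2")
  ex_products <- paste0("ex_", unlist(def$excretes))
  is_ex <- grepl("^ex_", reactions$id)
  keep_ex <- !is_ex | reactions$id %in% c(ex_always, ex_products)
  kept <- reactions[keep_enzymatic & keep_ex, ]
  net <- build_network(kept, metabolites)
  attr(net, "preset") <- preset
  attr(net, "excretes") <- unlist(def$excretes)
  attr(net, "flags") <- def$flags
  net
}

#' Machine-readable respiratory-loss diff
#'
#' The packaged list of enzyme identifiers present in the `leishmania_like`
#' baseline but absent from the `vickermania` preset: the subunits of
#' respiratory complexes III and IV and cytochrome c. The same losses are
#' encoded in the packaged gene table, so gene-level absence calls and the
#' preset definition can be cross-checked against each other.
#'
#' @return A tibble with columns `enzyme_id`, `component`,
#'   `status_vickermania`.
#' @export
preset_enzyme_diff <- function() {
  readr::read_tsv(vflx_extdata("respiratory_loss_diff.tsv"),
                  col_types = readr::cols(.default = readr::col_character()))
}

#' Define a simulation scenario
#'
#' A scenario resolves to reaction bounds: glucose uptake is fixed, the oxygen
#' exchange is opened or closed, and inhibitors/knockouts zero their target
#' reactions. The classical inhibitor set follows the organism's pharmacology:
#' SHAM (salicyl-hydroxamic acid) zeroes the alternative oxidase, cyanide
#' zeroes complex IV (a no-op in presets that lack it, which is exactly the
#' observed cyanide insensitivity), and malonate zeroes succinate
#' dehydrogenase.
#'
#' @param aerobic Logical; `FALSE` closes the oxygen exchange.
#' @param glucose_uptake Positive glucose uptake in mol (fixed; yields are
#'   therefore per `glucose_uptake` mol glucose). Zero is allowed for the
#'   no-substrate control.
#' @param inhibitors Character subset of `c("SHAM", "cyanide", "malonate")`.
#' @param knockouts Character vector of enzyme identifiers to delete.
#' @param block_succinate_export If `TRUE`, closes succinate excretion; used
#'   by the anaerobic accounting scenario to pin the full
#'   succinate-to-propionate corner of the optimum.
#' @param po_ratio Mol ATP per proton-pumping coupling unit (see the methods
#'   vignette); the default 0 reproduces substrate-level-phosphorylation-only
#'   accounting.
#' @return An object of class `vflx_scenario`.
#' @examples
#' scenario(aerobic = FALSE)
#' @export
scenario <- function(aerobic = TRUE,
                     glucose_uptake = 1,
                     inhibitors = character(0),
                     knockouts = character(0),
                     block_succinate_export = FALSE,
                     po_ratio = 0) {
  if (!is.numeric(glucose_uptake) || glucose_uptake < 0) {
    stop("glucose_uptake must be a non-negative number", call. = FALSE)
  }
  bad <- setdiff(inhibitors, c("SHAM", "cyanide", "malonate"))
  if (length(bad)) {
    stop("unknown inhibitor(s): ", paste(bad, collapse = ", "),
         "; known: SHAM, cyanide, malonate", call. = FALSE)
  }
  if (!is.numeric(po_ratio) || po_ratio < 0) {
    stop("po_ratio must be a non-negative number", call. = FALSE)
  }
  structure(
    list(aerobic = isTRUE(aerobic),
         glucose_uptake = glucose_uptake,
         inhibitors = unique(inhibitors),
         knockouts = unique(knockouts),
         block_succinate_export = isTRUE(block_succinate_export),
         po_ratio = po_ratio),
    class = "vflx_scenario"
  )
}

#' @export
print.vflx_scenario <- function(x, ...) {
  cat("<scenario> ", if (x$aerobic) "aerobic" else "anaerobic",
      ", glucose uptake ", x$glucose_uptake, " mol", sep = "")
  if (length(x$inhibitors)) cat(", inhibitors:", paste(x$inhibitors, collapse = "+"))
  if (length(x$knockouts)) cat(", knockouts:", paste(x$knockouts, collapse = "+"))
  if (x$block_succinate_export) cat(", succinate export blocked")
  if (x$po_ratio > 0) cat(", P/O ", x$po_ratio, sep = "")
  cat("\n")
  invisible(x)
}

#' Read a scenario from a flat key/value config file
#'
#' Accepts a JSON object with any of the fields of [scenario()]; `inhibitors`
#' and `knockouts` may be arrays or comma-separated strings.
#'
#' @param path Path to a JSON file.
#' @return A `vflx_scenario`.
#' @export
read_scenario <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  split_if_chr <- function(x) {
    if (is.null(x)) character(0)
    else if (length(x) == 1 && grepl(",", x)) trimws(strsplit(x, ",")[[1]])
    else as.character(x)
  }
  scenario(
    aerobic = cfg$aerobic %||% TRUE,
    glucose_uptake = cfg$glucose_uptake %||% 1,
    inhibitors = split_if_chr(cfg$inhibitors),
    knockouts = split_if_chr(cfg$knockouts),
    block_succinate_export = cfg$block_succinate_export %||% FALSE,
    po_ratio = cfg$po_ratio %||% 0
  )
}

zero_reaction_bounds <- function(network, ids) {
  hit <- network$reactions$id %in% ids
  network$reactions$lb[hit] <- 0
  network$reactions$ub[hit] <- 0
  network
}

#' Apply a scenario to a preset network
#'
#' Resolves a [scenario()] into flux bounds on a copy of the network:
#' the glucose exchange gets uptake capacity `glucose_uptake` (exchanges are
#' export-positive, so uptake is negative flux, bounded at
#' `-glucose_uptake`), the oxygen exchange is closed under anaerobiosis, inhibitor targets and all reactions requiring a
#' knocked-out enzyme get zero bounds, and a non-zero `po_ratio` rewrites the
#' ATP synthase coupling stoichiometry. The operation is idempotent: applying
#' the same scenario twice gives identical bounds.
#'
#' @param network A `flux_network` from [load_preset()].
#' @param scn A `vflx_scenario` (default: aerobic, glucose uptake 1).
#' @return The bounded `flux_network`, carrying the scenario in its
#'   `scenario` attribute.
#' @examples
#' net <- load_preset("vickermania") |> apply_scenario(scenario(aerobic = FALSE))
#' net$reactions[net$reactions$id == "ex_o2", c("lb", "ub")]
#' @export
apply_scenario <- function(network, scn = scenario()) {
  stopifnot(inherits(network, "flux_network"))
  if (!inherits(scn, "vflx_scenario")) stop("scn must be a scenario()", call. = FALSE)
  rx <- network$reactions
  set_bounds <- function(id, lb, ub) {
    hit <- rx$id == id
    rx$lb[hit] <<- lb
    rx$ub[hit] <<- ub
  }
  # uptake capacity: exchanges are export-positive, so uptake is negative
  # flux; the optimum consumes the full capacity whenever glucose has value,
  # and structural cuts (e.g. a hexokinase knockout) give yield 0 rather
  # than an infeasible program
  set_bounds("ex_glc", -scn$glucose_uptake, 0)
  if ("ex_o2" %in% rx$id) {
    if (scn$aerobic) set_bounds("ex_o2", -VFLX_CAP, 0) else set_bounds("ex_o2", 0, 0)
  }
  network$reactions <- rx
  if ("SHAM" %in% scn$inhibitors) network <- zero_reaction_bounds(network, "aox_m")
  if ("cyanide" %in% scn$inhibitors) network <- zero_reaction_bounds(network, "cox_m")
  if ("malonate" %in% scn$inhibitors) network <- zero_reaction_bounds(network, "sdh_m")
  if (scn$block_succinate_export) {
    network <- zero_reaction_bounds(network, c("succt_ge", "ex_succ"))
  }
  if (length(scn$knockouts)) {
    vocab <- enzyme_vocabulary()$enzyme_id
    bad <- setdiff(scn$knockouts, vocab)
    if (length(bad)) {
      stop("unknown enzyme id(s) in knockouts: ", paste(bad, collapse = ", "),
           "\nvalid enzyme ids: ", paste(vocab, collapse = ", "), call. = FALSE)
    }
    hit <- vapply(network$reactions$enzymes, function(e) {
      length(e) > 0 && any(e %in% scn$knockouts)
    }, logical(1))
    network$reactions$lb[hit] <- 0
    network$reactions$ub[hit] <- 0
  }
  if (scn$po_ratio > 0 && "atps_m" %in% network$reactions$id) {
    network <- set_po_ratio(network, scn$po_ratio)
  }
  attr(network, "scenario") <- scn
  network
}

# Rewrite the ATP synthase coupling: one proton-motive unit yields `po` ATP.
# po is snapped to an exact rational (denominator <= 1000) so the exact
# arithmetic path stays exact.
set_po_ratio <- function(network, po) {
  r <- rat_parse(format(round(po, 3), scientific = FALSE))
  st <- network$stoich[network$stoich$reaction != "atps_m", ]
  add <- tibble::tibble(
    reaction = "atps_m",
    metabolite = c("pmf_m", "adp_m", "atp_m"),
    num = c(-1, -r$num, r$num),
    den = c(1, r$den, r$den)
  )
  add$coef <- add$num / add$den
  network$stoich <- dplyr::bind_rows(st, add)
  network
}

VFLX_CAP <- 100
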