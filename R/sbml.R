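# SBML Level 3 export of a network.

#' Export a network as SBML Level 3
#'
#' Writes compartments, species and reactions (with exact stoichiometries
#' rendered as decimal values) to an SBML Level 3 Version 1 document; flux
#' bounds are emitted as model parameters `lb_<reaction>` / `ub_<reaction>`
#' and referenced from each reaction's annotation, so any constraint-based
#' toolchain can rebuild the bounded model.
#'
#' @param network A `flux_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @examples
#' f <- tempfile(fileext = ".xml")
#' write_sbml(load_preset("tbrucei_bloodstream"), f)
#' @export
write_sbml <- function(network, path) {
  stopifnot(inherits(network, "flux_network"))
  doc <- xml2::xml_new_root(
    "sbml",
    xmlns = "http://www.sbml.org/sbml/level3/version1/core",
    level = "3", version = "1"
  )
  model <- xml2::xml_add_child(doc, "model",
                               id = attr(network, "preset") %||% "network")
  locomp <- xml2::xml_add_child(model, "listOfCompartments")
  for (cmp in COMPARTMENTS) {
    xml2::xml_add_child(locomp, "compartment", id = cmp, constant = "true")
  }
  lospec <- xml2::xml_add_child(model, "listOfSpecies")
  used <- unique(network$stoich$metabolite)
  mets <- network$metabolites[network$metabolites$id %in% used, ]
  for (i in seq_len(nrow(mets))) {
    xml2::xml_add_child(
      lospec, "species",
      id = mets$id[i], name = mets$name[i], compartment = mets$compartment[i],
      hasOnlySubstanceUnits = "false",
      boundaryCondition = if (mets$compartment[i] == "extracellular") "true" else "false",
      constant = "false"
    )
  }
  lopar <- xml2::xml_add_child(model, "listOfParameters")
  lorx <- xml2::xml_add_child(model, "listOfReactions")
  for (i in seq_len(nrow(network$reactions))) {
    rx <- network$reactions[i, ]
    node <- xml2::xml_add_child(
      lorx, "reaction", id = rx$id, name = rx$name,
      reversible = if (rx$reversible == 1) "true" else "false"
    )
    st <- network$stoich[network$stoich$reaction == rx$id, ]
    reac <- st[st$coef < 0, ]
    prod <- st[st$coef > 0, ]
    if (nrow(reac)) {
      lo <- xml2::xml_add_child(node, "listOfReactants")
      for (j in seq_len(nrow(reac))) {
        xml2::xml_add_child(lo, "speciesReference", species = reac$metabolite[j],
                            stoichiometry = format(-reac$coef[j]),
                            constant = "true")
      }
    }
    if (nrow(prod)) {
      lo <- xml2::xml_add_child(node, "listOfProducts")
      for (j in seq_len(nrow(prod))) {
        xml2::xml_add_child(lo, "speciesReference", species = prod$metabolite[j],
                            stoichiometry = format(prod$coef[j]),
                            constant = "true")
      }
    }
    xml2::xml_add_child(lopar, "parameter", id = paste0("lb_", rx$id),
                        value = format(rx$lb), constant = "true")
    xml2::xml_add_child(lopar, "parameter", id = paste0("ub_", rx$id),
                        value = format(rx$ub), constant = "true")
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
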