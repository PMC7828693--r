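# Gene presence/copy-number tables, the gene-to-reaction activity rule, and
# the RPKM expression utility.

#' Curated enzyme vocabulary
#'
#' All enzyme identifiers the models know about: the numbered entries of the
#' curated enzyme map plus named respiratory-chain components (complex
#' subunits, cytochrome c, alternative oxidase). Gene tables are validated
#' against this vocabulary. Isoenzymes confined to different compartments
#' (e.g. the glycosomal and cytosolic glyceraldehyde-3-phosphate
#' dehydrogenases) carry separate identifiers.
#'
#' @return A tibble with columns `enzyme_id`, `fig1_no` (map number, `NA` for
#'   unnumbered respiratory components), `name`.
#' @export
enzyme_vocabulary <- function() {
  readr::read_tsv(vflx_extdata("enzymes.tsv"), col_types = readr::cols(
    enzyme_id = readr::col_character(),
    fig1_no = readr::col_integer(),
    name = readr::col_character()
  ))
}

#' Read an enzyme presence/copy-number table
#'
#' Reads a tab-separated gene table with columns `enzyme_id`, `gene_id`,
#' `copy_number` and optionally `read_count` and `length_bp`. A copy number of
#' zero is an absence call; negative copy numbers are a validation error;
#' enzyme ids outside the curated vocabulary are kept but reported with a
#' warning (they cannot map to any reaction).
#'
#' The packaged table `genes_vickermania_synthetic.tsv` encodes the published
#' absence/copy-number calls for the key enzymes (hexokinase 19 copies,
#' glycosomal/cytosolic GAPDH 39/38, alternative oxidase 6, all complex
#' III/IV subunits and cytochrome c absent, no glycerol kinase); gene ids,
#' expression columns and the copy numbers of the remaining enzymes are
#' synthetic placeholders, as the filename says.
#'
#' @param path Path to a TSV file.
#' @return A validated gene-table tibble.
#' @examples
#' genes <- read_gene_table(vickerflux_example("genes_vickermania_synthetic.tsv"))
#' genes[genes$enzyme_id == "aox", "copy_number"] # 6 copies
#' @export
read_gene_table <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    enzyme_id = readr::col_character(),
    gene_id = readr::col_character(),
    copy_number = readr::col_integer(),
    .default = readr::col_double()
  ))
  validate_gene_table(tbl)
}

validate_gene_table <- function(tbl) {
  required <- c("enzyme_id", "gene_id", "copy_number")
  missing <- setdiff(required, names(tbl))
  if (length(missing)) {
    stop("gene table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(tbl$copy_number < 0, na.rm = TRUE)) {
    stop("negative copy number(s) for enzyme(s): ",
         paste(tbl$enzyme_id[which(tbl$copy_number < 0)], collapse = ", "),
         call. = FALSE)
  }
  if ("length_bp" %in% names(tbl) && any(tbl$length_bp <= 0, na.rm = TRUE)) {
    stop("non-positive gene length(s)", call. = FALSE)
  }
  unknown <- setdiff(unique(tbl$enzyme_id), enzyme_vocabulary()$enzyme_id)
  if (length(unknown)) {
    warning("enzyme id(s) outside the curated vocabulary: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(tbl)
}

#' Write a gene table
#'
#' @param tbl A gene-table tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(tbl, path) {
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' Path to a packaged example data file
#'
#' @param file File name under the package's `extdata/` (empty to list them).
#' @return A file path, or a vector of available file names.
#' @export
vickerflux_example <- function(file = NULL) {
  if (is.null(file)) {
    return(list.files(system.file("extdata", package = "vickerflux")))
  }
  vflx_extdata(file)
}

#' Derive reaction activity from a gene table
#'
#' Applies the gene-to-reaction rule: a reaction is active iff every enzyme in
#' its requirement set has copy number >= 1 (a pure AND over required
#' subunits, so losing a single complex subunit inactivates the whole
#' complex). Reactions with no enzyme requirement (transports, exchanges,
#' pseudo-reactions) are always active. Enzymes absent from the table count
#' as absent. The rule is monotone: raising any copy number can only activate.
#'
#' @param table A gene-table tibble from [read_gene_table()].
#' @param network A `flux_network`.
#' @return A tibble with columns `reaction`, `active`, and `missing_enzymes`
#'   (list-column naming the absent requirements of inactive reactions).
#' @examples
#' genes <- read_gene_table(vickerflux_example("genes_vickermania_synthetic.tsv"))
#' act <- derive_activity(genes, load_preset("leishmania_like"))
#' act[act$reaction == "cox_m", ] # complex IV inactive
#' @export
derive_activity <- function(table, network) {
  stopifnot(inherits(network, "flux_network"))
  table <- validate_gene_table(table)
  present <- unique(table$enzyme_id[table$copy_number >= 1])
  rx <- network$reactions
  missing <- lapply(rx$enzymes, function(e) setdiff(e, present))
  tibble::tibble(
    reaction = rx$id,
    active = lengths(missing) == 0,
    missing_enzymes = missing
  )
}

#' Restrict a network to gene-supported reactions
#'
#' Combines [derive_activity()] with the network: inactive reactions are
#' dropped, giving the genotype-implied capability network. Applying the
#' packaged gene calls to the `leishmania_like` baseline reproduces the
#' `vickermania` preset's reaction set.
#'
#' @inheritParams derive_activity
#' @return A `flux_network`.
#' @export
apply_activity <- function(table, network) {
  act <- derive_activity(table, network)
  keep <- network$reactions$id[act$active]
  build_network(network$reactions[network$reactions$id %in% keep, ],
                network$metabolites)
}

#' Reads per kilobase per million mapped reads
#'
#' `RPKM = read_count x 10^9 / (length_bp x total_mapped)`.
#'
#' @param count Non-negative read count(s).
#' @param length_bp Positive gene length(s) in base pairs.
#' @param total_mapped Positive total number of mapped reads in the library.
#' @return Numeric vector of RPKM values.
#' @examples
#' compute_rpkm(1000, 1000, 1e6) # 1000
#' compute_rpkm(500, 2000, 2e6)  # 125
#' @export
compute_rpkm <- function(count, length_bp, total_mapped) {
  if (any(count < 0)) stop("read counts must be non-negative", call. = FALSE)
  if (any(length_bp <= 0)) stop("gene lengths must be positive", call. = FALSE)
  if (any(total_mapped <= 0)) stop("total mapped reads must be positive", call. = FALSE)
  count * 1e9 / (length_bp * total_mapped)
}

#' Append an RPKM column to a gene table
#'
#' @param tbl A gene table with `read_count` and `length_bp` columns.
#' @param total_mapped Library size; defaults to the sum of `read_count`.
#' @return The table with an `rpkm` column appended.
#' @export
add_rpkm <- function(tbl, total_mapped = sum(tbl$read_count)) {
  if (!all(c("read_count", "length_bp") %in% names(tbl))) {
    stop("gene table lacks expression columns read_count/length_bp", call. = FALSE)
  }
  dplyr::mutate(tbl, rpkm = compute_rpkm(.data$read_count, .data$length_bp,
                                         total_mapped))
}
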