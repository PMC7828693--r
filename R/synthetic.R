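# Seeded generators for gene tables and knockout scenarios, so every stage of
# the pipeline is testable without external data.

#' Configure the synthetic-data generator
#'
#' The generator emulates the structure of trypanosomatid gene inventories:
#' most enzymes present in one or a few copies, occasional large multi-copy
#' families (copy numbers are drawn from a geometric distribution with
#' configurable mean, truncated at 200, a plausibility envelope for the
#' amplified glycolytic families), a configurable fraction of absent enzymes,
#' and log-normally dispersed read counts for the expression columns.
#'
#' @param seed Integer seed; identical seed and configuration give
#'   byte-identical outputs.
#' @param n_enzymes Number of enzymes drawn from the curated vocabulary
#'   (default: all of it).
#' @param absence_rate Probability that an enzyme is absent (copy number 0).
#' @param copy_mean Mean copy number of present enzymes (geometric, >= 1).
#' @param expression_sdlog Log-normal dispersion of read counts.
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed = 1L,
                             n_enzymes = nrow(enzyme_vocabulary()),
                             absence_rate = 0.2,
                             copy_mean = 2,
                             expression_sdlog = 1) {
  if (absence_rate < 0 || absence_rate > 1) {
    stop("absence_rate must be in [0, 1]", call. = FALSE)
  }
  if (copy_mean < 1) stop("copy_mean must be >= 1", call. = FALSE)
  vocab <- enzyme_vocabulary()
  if (n_enzymes < 1 || n_enzymes > nrow(vocab)) {
    stop("n_enzymes must be between 1 and ", nrow(vocab), call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed), n_enzymes = as.integer(n_enzymes),
         absence_rate = absence_rate, copy_mean = copy_mean,
         expression_sdlog = expression_sdlog),
    class = "generator_config"
  )
}

with_generator_seed <- function(config, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(config$seed)
  force(expr)
}

#' Generate a random gene table
#'
#' Draws a synthetic enzyme presence/copy-number table over the curated
#' vocabulary: each enzyme is absent with probability `absence_rate`; present
#' enzymes get geometric copy numbers (mean `copy_mean`, truncated at 200),
#' log-normal read counts scaled by copy number, and plausible gene lengths.
#' Output is fully reproducible from the seed and always passes
#' [read_gene_table()] validation.
#'
#' @param config A [generator_config()].
#' @return A gene-table tibble.
#' @examples
#' random_gene_table(generator_config(seed = 7, absence_rate = 0))
#' @export
random_gene_table <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  vocab <- enzyme_vocabulary()
  with_generator_seed(config, {
    ids <- vocab$enzyme_id[seq_len(config$n_enzymes)]
    absent <- stats::runif(length(ids)) < config$absence_rate
    p <- 1 / config$copy_mean
    copies <- pmin(stats::rgeom(length(ids), p) + 1L, 200L)
    copies[absent] <- 0L
    length_bp <- 3L * (100L + stats::rpois(length(ids), 400L))
    mu <- log(pmax(copies, 1) * 1000)
    counts <- as.integer(round(stats::rlnorm(length(ids), mu,
                                             config$expression_sdlog)))
    counts[absent] <- 0L
    tibble::tibble(
      enzyme_id = ids,
      gene_id = sprintf("SYN_%04d", seq_along(ids)),
      copy_number = as.integer(copies),
      read_count = counts,
      length_bp = length_bp
    )
  })
}

#' Generate random knockout scenarios
#'
#' Draws `k` scenarios, each knocking out an independent random subset of the
#' curated enzyme vocabulary (each enzyme deleted with probability
#' `absence_rate`); used to exercise the knockout-monotonicity property of
#' the ATP optimum. Seeded and reproducible.
#'
#' @param config A [generator_config()].
#' @param k Number of scenarios.
#' @param aerobic Oxygen availability passed to each scenario.
#' @return A list of `k` [scenario()] objects.
#' @examples
#' length(random_knockouts(generator_config(seed = 1), k = 3))
#' @export
random_knockouts <- function(config = generator_config(), k,
                             aerobic = FALSE) {
  stopifnot(inherits(config, "generator_config"))
  if (k < 0) stop("k must be non-negative", call. = FALSE)
  if (k == 0) return(list())
  vocab <- enzyme_vocabulary()$enzyme_id[seq_len(config$n_enzymes)]
  with_generator_seed(config, {
    lapply(seq_len(k), function(i) {
      ko <- vocab[stats::runif(length(vocab)) < config$absence_rate]
      scenario(aerobic = aerobic, knockouts = ko)
    })
  })
}
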