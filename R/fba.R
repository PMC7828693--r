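# Flux balance analysis of the curated networks: ATP-yield maximization,
# end-product profiles, flux variability, the exact-rational certification
# route, and verification of the hand-accounting flux vector.

PRODUCT_NAMES <- c(ac = "acetate", etoh = "ethanol", succ = "succinate",
                   prop = "propionate", co2 = "CO2", glyc = "glycerol",
                   pyr = "pyruvate")

network_lp <- function(network) {
  S <- stoichiometric_matrix(network)
  list(
    S = S,
    b = rep(0, nrow(S)),
    lb = network$reactions$lb,
    ub = network$reactions$ub,
    obj = as.numeric(network$reactions$subsystem %in% "atp_drain")
  )
}

yields_from_fluxes <- function(network, v) {
  rx <- network$reactions
  ex <- rx$id[rx$exchange & !rx$id %in% c("ex_glc", "ex_o2")]
  key <- sub("^ex_", "", ex)
  tibble::tibble(
    product = unname(PRODUCT_NAMES[key]),
    yield = unname(v[match(ex, rx$id)])
  )
}

new_flux_solution <- function(network, v, objective, status, violated = NULL) {
  rx <- network$reactions
  fluxes <- tibble::tibble(
    reaction = rx$id, name = rx$name, subsystem = rx$subsystem,
    flux = unname(v), lb = rx$lb, ub = rx$ub
  )
  yields <- if (status == "optimal") yields_from_fluxes(network, v) else
    tibble::tibble(product = character(0), yield = numeric(0))
  structure(
    list(fluxes = fluxes, objective = objective, status = status,
         yields = yields, violated = violated,
         preset = attr(network, "preset"),
         scenario = attr(network, "scenario")),
    class = "flux_solution"
  )
}

#' Maximize ATP yield by flux balance analysis
#'
#' Solves the linear program `max sum(ATP-drain fluxes)` subject to steady
#' state (`S v = 0` over internal metabolites) and the network's flux bounds,
#' i.e. the maximal mol ATP per mol glucose the bounded network can sustain.
#' The objective pools the per-compartment ATP-drain pseudo-reactions, so ATP
#' made in the glycosome, cytosol and mitochondrion counts alike.
#'
#' Degenerate optima (e.g. the split between succinate excretion and
#' propionate conversion when the cycle carries no ATP advantage) are resolved
#' for reporting by a parsimonious second stage that minimizes total absolute
#' flux at the fixed optimum - the standard parsimonious-FBA convention, which
#' makes the reported flux vector deterministic.
#'
#' @param network A bounded `flux_network` (see [apply_scenario()]). The
#'   network must contain ATP-drain reactions and a glucose exchange.
#' @param parsimonious Run the total-flux minimization second stage
#'   (default `TRUE`).
#' @return A `flux_solution`: fluxes tibble, `objective` (mol ATP per mol
#'   glucose), `status` (`"optimal"`, `"infeasible"` or `"unbounded"`), and
#'   `yields` (end-product exchange fluxes). For non-optimal statuses the
#'   violated constraint set is named in `$violated`.
#' @examples
#' sol <- load_preset("vickermania") |>
#'   apply_scenario(scenario(aerobic = FALSE)) |>
#'   maximize_atp()
#' sol$objective # 3.5
#' @export
maximize_atp <- function(network, parsimonious = TRUE) {
  stopifnot(inherits(network, "flux_network"))
  lp <- network_lp(network)
  if (!any(lp$obj > 0)) {
    stop("network has no ATP-drain reactions to maximize", call. = FALSE)
  }
  sol <- lp_solve(lp$obj, lp$S, lp$b, lp$lb, lp$ub, maximize = TRUE)
  if (sol$status != "optimal") {
    return(new_flux_solution(network, rep(NA_real_, ncol(lp$S)), NA_real_,
                             sol$status, violated = sol$violated))
  }
  v <- sol$x
  if (parsimonious) {
    v2 <- lp_parsimonious(lp$obj, lp$S, lp$b, lp$lb, lp$ub, sol$objective)
    if (!is.null(v2)) v <- v2
  }
  v <- stats::setNames(zap_tiny(v), colnames(lp$S))
  resid <- max(abs(lp$S %*% v))
  if (resid > 1e-9) {
    warning("steady-state residual ", format(resid), " exceeds 1e-9",
            call. = FALSE)
  }
  new_flux_solution(network, v, zap_tiny(sol$objective), "optimal")
}

zap_tiny <- function(x, tol = 1e-9) {
  x[abs(x) < tol] <- 0
  # snap to the nearest half: the curated yields are exact halves, and the
  # solver's vertices carry only tiny round-off
  half <- round(x * 2) / 2
  ifelse(abs(x - half) < 1e-7, half, x)
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> status:", x$status)
  if (!is.null(x$preset)) cat("  preset:", x$preset)
  cat("\n")
  if (x$status == "optimal") {
    cat("  ATP yield:", format(x$objective), "mol per mol glucose\n")
    nz <- x$yields[x$yields$yield > 1e-9, ]
    if (nrow(nz)) {
      cat("  end products:",
          paste(nz$product, format(nz$yield), collapse = ", "), "\n")
    }
  } else if (!is.null(x$violated)) {
    cat("  violated:", x$violated, "\n")
  }
  invisible(x)
}

#' @rdname maximize_atp
#' @param x A `flux_solution`.
#' @param ... Unused.
#' @export
tidy.flux_solution <- function(x, ...) x$fluxes

#' @rdname maximize_atp
#' @export
glance.flux_solution <- function(x, ...) {
  wide <- stats::setNames(as.list(x$yields$yield), x$yields$product)
  dplyr::bind_cols(
    tibble::tibble(objective = x$objective, status = x$status,
                   preset = x$preset %||% NA_character_,
                   n_active = sum(abs(x$fluxes$flux) > 1e-9, na.rm = TRUE)),
    tibble::as_tibble(wide)
  )
}

#' End-product yields of a flux solution
#'
#' Reads the end-product profile from the exchange fluxes only (exchanges are
#' export-positive): mol of acetate, ethanol, succinate, propionate, CO2,
#' glycerol and pyruvate formed per mol glucose. Carbon is conserved: the
#' product carbons plus excreted CO2 minus CO2 fixed by carboxylation equal
#' the six glucose carbons.
#'
#' @param solution A `flux_solution` with status `"optimal"`, or the zero
#'   vector case of a solution with all-zero fluxes.
#' @return A tibble with columns `product` and `yield`.
#' @examples
#' load_preset("vickermania") |>
#'   apply_scenario(scenario(aerobic = FALSE, block_succinate_export = TRUE)) |>
#'   maximize_atp() |>
#'   end_product_profile()
#' @export
end_product_profile <- function(solution) {
  stopifnot(inherits(solution, "flux_solution"))
  solution$yields
}

#' Exact-rational certification of the ATP optimum
#'
#' Re-solves the ATP-maximization LP from scratch in exact rational
#' arithmetic (int64 fractions, Bland-safeguarded simplex, no floating
#' point), independently of the numeric solver, and returns the optimum as an
#' exact fraction. For every curated scenario the exact optimum is a small
#' rational (halves), so agreement between [maximize_atp()] and this routine
#' certifies the numeric result to all digits.
#'
#' @param network A bounded `flux_network`.
#' @return A list with `status`, `objective` (numeric), `objective_exact`
#'   (e.g. `"7/2"`), and `fluxes` (named numeric, an exact optimal vertex).
#' @examples
#' net <- load_preset("vickermania") |> apply_scenario(scenario(aerobic = FALSE))
#' max_atp_exact(net)$objective_exact # "7/2"
#' @export
max_atp_exact <- function(network) {
  stopifnot(inherits(network, "flux_network"))
  ex <- stoichiometric_matrix(network, exact = TRUE)
  lbr <- rat_approx(network$reactions$lb)
  ubr <- rat_approx(network$reactions$ub)
  obj <- as.numeric(network$reactions$subsystem %in% "atp_drain")
  m <- nrow(ex$S)
  res <- .exact_lp(ex$num, ex$den,
                   rep(0, m), rep(1, m),
                   obj, rep(1, length(obj)),
                   lbr$num, lbr$den, ubr$num, ubr$den,
                   TRUE)
  if (res$status != "optimal") {
    return(list(status = res$status, objective = NA_real_,
                objective_exact = NA_character_, fluxes = NULL))
  }
  list(
    status = "optimal",
    objective = res$objective,
    objective_exact = rat_format(list(num = res$objective_num,
                                      den = res$objective_den)),
    fluxes = stats::setNames(res$v, colnames(ex$S))
  )
}

#' Brute-force vertex enumeration oracle
#'
#' Enumerates, in exact rational arithmetic, every vertex of the flux
#' polytope `{S v = 0, lb <= v <= ub}` by fixing each choice of
#' `n - rank(S)` variables at a bound and solving the remaining square system
#' exactly, and returns the maximal ATP-drain objective over feasible
#' vertices. Exhaustive and therefore only for small systems: the
#' combinatorial guard refuses networks whose enumeration would exceed
#' `max_combos` candidate bases. Used to certify the exact simplex on toy
#' networks; the simplex then certifies the numeric solver everywhere.
#'
#' @param network A bounded `flux_network`.
#' @param max_combos Guard on the number of candidate vertices (default
#'   200000).
#' @return A list with `objective` (numeric) and `objective_exact`.
#' @export
enumerate_yield_brute <- function(network, max_combos = 2e5) {
  stopifnot(inherits(network, "flux_network"))
  ex <- stoichiometric_matrix(network, exact = TRUE)
  n <- ncol(ex$S)
  if (n == 0) return(list(objective = 0, objective_exact = "0"))
  r <- qr(ex$S)$rank
  nfix <- n - r
  n_comb <- choose(n, nfix) * 2^nfix
  if (!is.finite(n_comb) || n_comb > max_combos) {
    stop("vertex enumeration refused: ", format(n_comb),
         " candidate bases exceed the guard of ", format(max_combos),
         call. = FALSE)
  }
  obj <- as.numeric(network$reactions$subsystem %in% "atp_drain")
  lbr <- rat_approx(network$reactions$lb)
  ubr <- rat_approx(network$reactions$ub)
  best <- NULL
  fix_sets <- if (nfix == 0) list(integer(0)) else
    utils::combn(n, nfix, simplify = FALSE)
  for (fix in fix_sets) {
    free <- setdiff(seq_len(n), fix)
    # the free square system must be solvable; rank-deficient choices skipped
    sub_num <- ex$num[, free, drop = FALSE]
    sub_den <- ex$den[, free, drop = FALSE]
    if (length(free) && qr(sub_num / sub_den)$rank < length(free)) next
    # choose rows to make it square (independent rows)
    if (length(free)) {
      qrS <- qr(t(sub_num / sub_den))
      rows <- sort(qrS$pivot[seq_len(qrS$rank)])
      if (length(rows) != length(free)) next
    } else rows <- integer(0)
    sides <- expand.grid(rep(list(c(FALSE, TRUE)), nfix))
    if (nfix == 0) sides <- data.frame(row.names = 1)
    for (s in seq_len(nrow(sides))) {
      at_ub <- if (nfix > 0) unlist(sides[s, ]) else logical(0)
      vfix <- list(num = ifelse(at_ub, ubr$num[fix], lbr$num[fix]),
                   den = ifelse(at_ub, ubr$den[fix], lbr$den[fix]))
      # rhs = -S_fix v_fix restricted to chosen rows
      if (length(free)) {
        rhs <- lapply(rows, function(i) {
          contrib <- rat_mul(list(num = ex$num[i, fix], den = ex$den[i, fix]),
                             vfix)
          r <- rat_sum(contrib)
          list(num = -r$num, den = r$den)
        })
        solved <- rat_solve(
          sub_num[rows, , drop = FALSE], sub_den[rows, , drop = FALSE],
          vapply(rhs, `[[`, numeric(1), "num"),
          vapply(rhs, `[[`, numeric(1), "den")
        )
        if (is.null(solved)) next
      } else solved <- list(num = numeric(0), den = numeric(0))
      v_num <- numeric(n); v_den <- rep(1, n)
      v_num[fix] <- vfix$num; v_den[fix] <- vfix$den
      v_num[free] <- solved$num; v_den[free] <- solved$den
      v <- v_num / v_den
      # feasibility: all rows of S v = 0 and bounds hold (checked exactly)
      ok <- TRUE
      for (i in seq_len(nrow(ex$S))) {
        resid <- rat_sum(rat_mul(list(num = ex$num[i, ], den = ex$den[i, ]),
                                 list(num = v_num, den = v_den)))
        if (!rat_is_zero(resid)) { ok <- FALSE; break }
      }
      if (ok && all(v >= lbr$num / lbr$den - 1e-12) &&
          all(v <= ubr$num / ubr$den + 1e-12)) {
        z <- rat_sum(list(num = v_num[obj > 0], den = v_den[obj > 0]))
        if (is.null(best) || rat_as_numeric(z) > rat_as_numeric(best)) best <- z
      }
    }
  }
  if (is.null(best)) stop("no feasible vertex found", call. = FALSE)
  list(objective = rat_as_numeric(best), objective_exact = rat_format(best))
}

#' Flux variability at (or off) the optimum
#'
#' For each reaction, the minimal and maximal flux compatible with steady
#' state and the bounds, optionally with the ATP objective pinned at its
#' optimum. Exposes degeneracies the single reported vertex hides - e.g.
#' whether glycosomal succinate may be excreted or must enter the propionate
#' cycle at the anaerobic optimum.
#'
#' @param network A bounded `flux_network`.
#' @param at_optimum Pin the ATP objective at its maximum (default `TRUE`).
#' @param reactions Reaction ids to analyze (default: all).
#' @return A tibble with columns `reaction`, `min`, `max`.
#' @examples
#' net <- load_preset("vickermania") |> apply_scenario(scenario(aerobic = FALSE))
#' flux_ranges(net, reactions = c("succt_ge", "pct_m"))
#' @export
flux_ranges <- function(network, at_optimum = TRUE, reactions = NULL) {
  stopifnot(inherits(network, "flux_network"))
  lp <- network_lp(network)
  ids <- reactions %||% network$reactions$id
  idx <- match(ids, network$reactions$id)
  if (anyNA(idx)) {
    stop("unknown reaction id(s): ", paste(ids[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  A <- lp$S; b <- lp$b
  if (at_optimum) {
    base <- lp_solve(lp$obj, lp$S, lp$b, lp$lb, lp$ub, maximize = TRUE)
    if (base$status != "optimal") {
      stop("cannot fix the objective: base LP status ", base$status,
           call. = FALSE)
    }
    A <- rbind(A, lp$obj)
    b <- c(b, base$objective)
  }
  out <- purrr::map_dfr(idx, function(j) {
    e <- numeric(ncol(A)); e[j] <- 1
    lo <- lp_solve(e, A, b, lp$lb, lp$ub, maximize = FALSE)
    hi <- lp_solve(e, A, b, lp$lb, lp$ub, maximize = TRUE)
    tibble::tibble(reaction = network$reactions$id[j],
                   min = zap_tiny(lo$objective), max = zap_tiny(hi$objective))
  })
  out
}

#' The packaged hand-accounting flux vector
#'
#' The per-glucose flux assignment that transcribes the organism's anaerobic
#' accounting: one PEP equivalent through pyruvate kinase and one through the
#' glycosomal succinate branch, half the pyruvate oxidized to acetate and
#' half reduced to ethanol, and full succinate-to-propionate conversion. All
#' values are exact rationals.
#'
#' @param network The network the vector is defined on (the `vickermania`
#'   preset); used to validate reaction ids.
#' @return A tibble with columns `reaction`, `flux`, `num`, `den` (zero-flux
#'   reactions included).
#' @export
accounting_vector <- function(network = load_preset("vickermania")) {
  stopifnot(inherits(network, "flux_network"))
  raw <- readr::read_tsv(vflx_extdata("accounting_vickermania.tsv"),
                         col_types = readr::cols(.default = readr::col_character()))
  unknown <- setdiff(raw$reaction_id, network$reactions$id)
  if (length(unknown)) {
    stop("accounting vector references unknown reaction(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  r <- rat_parse(raw$flux)
  all_ids <- network$reactions$id
  num <- stats::setNames(rep(0, length(all_ids)), all_ids)
  den <- stats::setNames(rep(1, length(all_ids)), all_ids)
  num[raw$reaction_id] <- r$num
  den[raw$reaction_id] <- r$den
  tibble::tibble(reaction = all_ids, flux = unname(num / den),
                 num = unname(num), den = unname(den))
}

atp_coefficients <- function(network) {
  atp_ids <- c("atp_g", "atp_c", "atp_m")
  st <- network$stoich[network$stoich$metabolite %in% atp_ids, ]
  agg <- lapply(split(st, st$reaction), function(d) {
    s <- rat_sum(list(num = d$num, den = d$den))
    tibble::tibble(reaction = d$reaction[1], num = s$num, den = s$den)
  })
  dplyr::bind_rows(agg)
}

#' Verify the hand-accounting flux vector
#'
#' Checks, in exact rational arithmetic, that a flux assignment satisfies
#' steady state (`S v = 0`, residual exactly zero) on the given network, and
#' itemizes its ATP formation: substrate-level phosphorylation of glycolysis
#' and the succinate branch (hexokinase and phosphofructokinase debits;
#' phosphoglycerate kinase, pyruvate kinase and PEP carboxykinase credits),
#' the acetate branch (succinyl-CoA ligase), the propionate cycle
#' (decarboxylating propionyl-CoA carboxylase net of any ligase reversal),
#' and oxidative phosphorylation (zero at the default P/O of 0). The item sum
#' equals the total ATP drain. End-product formation is tallied from the
#' exchange fluxes.
#'
#' @param network The `flux_network` the vector is defined on.
#' @param fluxes A flux tibble with exact `num`/`den` columns, as returned by
#'   [accounting_vector()]; a named numeric vector of small rationals is also
#'   accepted.
#' @return An object of class `accounting_report`: a list with `residual_zero`
#'   (logical), `atp_items` (tibble: item, atp, atp_exact), `atp_total`,
#'   `products` (tibble), and `fluxes`.
#' @examples
#' net <- load_preset("vickermania")
#' rep <- verify_accounting(net)
#' rep$atp_total # 3.5 = 2 + 0.5 + 1
#' @export
verify_accounting <- function(network = load_preset("vickermania"),
                              fluxes = accounting_vector(network)) {
  stopifnot(inherits(network, "flux_network"))
  if (is.numeric(fluxes) && !is.null(names(fluxes))) {
    r <- rat_approx(unname(fluxes))
    fluxes <- tibble::tibble(reaction = names(fluxes), flux = unname(fluxes),
                             num = r$num, den = r$den)
  }
  unknown <- setdiff(fluxes$reaction, network$reactions$id)
  if (length(unknown)) {
    stop("flux vector references unknown reaction(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  all_ids <- network$reactions$id
  num <- stats::setNames(rep(0, length(all_ids)), all_ids)
  den <- stats::setNames(rep(1, length(all_ids)), all_ids)
  num[fluxes$reaction] <- fluxes$num
  den[fluxes$reaction] <- fluxes$den

  ex <- stoichiometric_matrix(network, exact = TRUE)
  residual_zero <- TRUE
  for (i in seq_len(nrow(ex$S))) {
    resid <- rat_sum(rat_mul(list(num = ex$num[i, ], den = ex$den[i, ]),
                             list(num = unname(num[colnames(ex$S)]),
                                  den = unname(den[colnames(ex$S)]))))
    if (!rat_is_zero(resid)) { residual_zero <- FALSE; break }
  }

  atp <- atp_coefficients(network)
  groups <- list(
    `substrate-level phosphorylation (glycolysis + succinate branch)` =
      c("hk", "pfk", "pgk_g", "pyk_c", "pepck_g", "glyk_g", "adk_g"),
    `acetate branch (succinyl-CoA ligase)` = c("asct_m", "scl_m", "pdh_m"),
    `propionate cycle` = c("mcm_m", "mce_m", "pcc_m", "pct_m"),
    `oxidative phosphorylation` = c("atps_m", "nadh1_m", "cyc3_m", "cox_m",
                                    "aox_m", "sdh_m")
  )
  items <- purrr::imap_dfr(groups, function(ids, label) {
    sel <- atp[atp$reaction %in% ids, ]
    if (!nrow(sel)) {
      return(tibble::tibble(item = label, atp = 0, atp_exact = "0"))
    }
    contrib <- rat_mul(list(num = sel$num, den = sel$den),
                       list(num = unname(num[sel$reaction]),
                            den = unname(den[sel$reaction])))
    s <- rat_sum(contrib)
    tibble::tibble(item = label, atp = rat_as_numeric(s),
                   atp_exact = rat_format(s))
  })
  total <- rat_sum(rat_parse(items$atp_exact))

  ex_ids <- network$reactions$id[network$reactions$exchange &
                                   !network$reactions$id %in% c("ex_glc", "ex_o2")]
  products <- tibble::tibble(
    product = unname(PRODUCT_NAMES[sub("^ex_", "", ex_ids)]),
    yield = unname(num[ex_ids] / den[ex_ids])
  )
  structure(
    list(residual_zero = residual_zero,
         atp_items = items,
         atp_total = rat_as_numeric(total),
         atp_total_exact = rat_format(total),
         products = products,
         fluxes = tibble::tibble(reaction = all_ids,
                                 flux = unname(num / den))),
    class = "accounting_report"
  )
}

#' @export
print.accounting_report <- function(x, ...) {
  cat("<accounting_report> steady-state residual exactly zero:",
      x$residual_zero, "\n")
  cat("ATP tally (mol per mol glucose):\n")
  for (i in seq_len(nrow(x$atp_items))) {
    cat(sprintf("  %-58s %6s\n", x$atp_items$item[i], x$atp_items$atp_exact[i]))
  }
  cat(sprintf("  %-58s %6s\n", "total", x$atp_total_exact))
  nz <- x$products[x$products$yield != 0, ]
  if (nrow(nz)) {
    cat("end products:", paste(nz$product, format(nz$yield), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Net ATP of the propionate cycle per propionate
#'
#' Solves, in exact rational arithmetic, the unit flux distribution of the
#' mitochondrial methylmalonyl-CoA cycle (succinyl-CoA ligase running as
#' needed, mutase, epimerase, decarboxylating propionyl-CoA carboxylase, and
#' the CoA transferase that hands CoA back to succinate) for one mol of
#' propionate formed from succinate, and returns the net ATP of that cycle.
#'
#' @param network A `flux_network` containing the cycle (the `vickermania`
#'   preset).
#' @return A list with `atp` (numeric), `atp_exact`, and `fluxes` (tibble of
#'   the cycle reactions at unit propionate output).
#' @examples
#' propionate_cycle_atp(load_preset("vickermania"))$atp # 1
#' @export
propionate_cycle_atp <- function(network = load_preset("vickermania")) {
  cycle <- c("scl_m", "mcm_m", "mce_m", "pcc_m", "pct_m")
  intermediates <- c("succoa_m", "mmcoa_r_m", "mmcoa_s_m", "ppcoa_m")
  missing <- setdiff(cycle, network$reactions$id)
  if (length(missing)) {
    stop("network lacks propionate-cycle reaction(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ex <- stoichiometric_matrix(network, exact = TRUE)
  rows <- match(intermediates, rownames(ex$S))
  cols <- match(cycle, colnames(ex$S))
  # balance the four CoA intermediates and pin the CoA transferase at 1:
  # a 5x5 exact system
  Anum <- rbind(ex$num[rows, cols], as.numeric(cycle == "pct_m"))
  Aden <- rbind(ex$den[rows, cols], rep(1, length(cycle)))
  sol <- rat_solve(Anum, Aden, c(0, 0, 0, 0, 1), rep(1, 5))
  if (is.null(sol)) stop("propionate cycle system is singular", call. = FALSE)
  atp <- atp_coefficients(network)
  sel <- atp[match(cycle, atp$reaction), ]
  sel$num[is.na(sel$num)] <- 0
  sel$den[is.na(sel$den)] <- 1
  s <- rat_sum(rat_mul(list(num = sel$num, den = sel$den), sol))
  list(
    atp = rat_as_numeric(s),
    atp_exact = rat_format(s),
    fluxes = tibble::tibble(reaction = cycle, flux = sol$num / sol$den)
  )
}
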