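anaerobic_net <- function(...) {
  load_preset("vickermania") |> apply_scenario(scenario(aerobic = FALSE, ...))
}

test_that("anaerobic optimum is 3.5 ATP with the dismutation product slate", {
  sol <- maximize_atp(anaerobic_net())
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective, 3.5, tolerance = 1e-9)
  y <- stats::setNames(sol$yields$yield, sol$yields$product)
  expect_equal(y[["ethanol"]], 0.5, tolerance = 1e-9)
  expect_equal(y[["acetate"]], 0.5, tolerance = 1e-9)
  expect_equal(y[["succinate"]] + y[["propionate"]], 1, tolerance = 1e-9)
})

test_that("the exact rational route certifies the float optimum as 7/2", {
  ex <- max_atp_exact(anaerobic_net())
  expect_equal(ex$status, "optimal")
  expect_identical(ex$objective_exact, "7/2")
})

test_that("no glucose means no ATP", {
  sol <- maximize_atp(anaerobic_net(glucose_uptake = 0))
  expect_equal(sol$objective, 0)
  expect_true(all(end_product_profile(sol)$yield == 0))
})

test_that("doubling glucose uptake exactly doubles objective and yields", {
  one <- maximize_atp(anaerobic_net())
  two <- maximize_atp(anaerobic_net(glucose_uptake = 2))
  expect_equal(two$objective, 2 * one$objective, tolerance = 1e-9)
  expect_equal(two$yields$yield, 2 * one$yields$yield, tolerance = 1e-9)
})

test_that("bloodstream trypanosome yields match the classical accounting", {
  tb <- load_preset("tbrucei_bloodstream")
  aer <- maximize_atp(apply_scenario(tb, scenario(aerobic = TRUE)))
  expect_equal(aer$objective, 2, tolerance = 1e-9)
  an <- maximize_atp(apply_scenario(tb, scenario(aerobic = FALSE)))
  expect_equal(an$objective, 1, tolerance = 1e-9)
  # hand steady-state solve of the anaerobic bloodstream network: one
  # pyruvate and one glycerol per glucose
  y <- stats::setNames(an$yields$yield, an$yields$product)
  expect_equal(y[["pyruvate"]], 1, tolerance = 1e-9)
  expect_equal(y[["glycerol"]], 1, tolerance = 1e-9)
  # aerobically the shuttle reoxidizes NADH and both trioses reach pyruvate
  y2 <- stats::setNames(aer$yields$yield, aer$yields$product)
  expect_equal(y2[["pyruvate"]], 2, tolerance = 1e-9)
  expect_equal(y2[["glycerol"]], 0, tolerance = 1e-9)
})

test_that("the packaged accounting vector verifies exactly and itemizes 2 + 1/2 + 1", {
  net <- load_preset("vickermania")
  rep <- verify_accounting(net)
  expect_true(rep$residual_zero)
  items <- stats::setNames(rep$atp_items$atp_exact, NULL)
  expect_identical(items[1:3], c("2", "1/2", "1"))
  expect_identical(rep$atp_total_exact, "7/2")
  # linearity: scaling the vector by two doubles the tally, residual stays 0
  v <- accounting_vector(net)
  v$num <- 2 * v$num
  v$flux <- v$num / v$den
  rep2 <- verify_accounting(net, v)
  expect_true(rep2$residual_zero)
  expect_equal(rep2$atp_total, 7)
})

test_that("rerouting succinate to export instead of the cycle tallies 2.5", {
  net <- load_preset("vickermania")
  v <- accounting_vector(net)
  set_flux <- function(v, id, num, den = 1) {
    i <- match(id, v$reaction)
    v$num[i] <- num; v$den[i] <- den; v$flux[i] <- num / den
    v
  }
  for (id in c("mcm_m", "mce_m", "pcc_m", "pct_m", "succt_gm", "propt",
               "ex_prop")) {
    v <- set_flux(v, id, 0)
  }
  v <- set_flux(v, "succt_ge", 1)
  v <- set_flux(v, "ex_succ", 1)
  v <- set_flux(v, "atpm_m", 1, 2)
  v <- set_flux(v, "co2t_mc", 1, 2)
  v <- set_flux(v, "co2t_ce", 0)
  v <- set_flux(v, "ex_co2", 0)
  rep <- verify_accounting(net, v)
  expect_true(rep$residual_zero)
  expect_equal(rep$atp_total, 2.5)
  expect_identical(rep$atp_items$atp_exact[3], "0")
})

test_that("accounting rejects fluxes on unknown reactions", {
  net <- load_preset("vickermania")
  expect_error(verify_accounting(net, c(warp = 1)), "unknown reaction")
})

test_that("the propionate cycle nets exactly one ATP per propionate", {
  res <- propionate_cycle_atp(load_preset("vickermania"))
  expect_identical(res$atp_exact, "1")
  # the CoA transferase regenerates succinyl-CoA, so the ligase carries no
  # net flux in the unit cycle
  fx <- stats::setNames(res$fluxes$flux, res$fluxes$reaction)
  expect_equal(fx[["scl_m"]], 0)
  expect_equal(fx[["pcc_m"]], 1)
})

test_that("flux variability pins the propionate corner at the optimum", {
  fr <- flux_ranges(anaerobic_net(), reactions = c("succt_ge", "pct_m"))
  expect_equal(fr$min[fr$reaction == "succt_ge"], 0, tolerance = 1e-7)
  expect_equal(fr$max[fr$reaction == "succt_ge"], 0, tolerance = 1e-7)
  expect_equal(fr$min[fr$reaction == "pct_m"], 1, tolerance = 1e-7)
  expect_equal(fr$max[fr$reaction == "pct_m"], 1, tolerance = 1e-7)
  # with the cycle knocked out, export is the only outlet
  fr2 <- flux_ranges(anaerobic_net(knockouts = "pcc"),
                     reactions = "succt_ge")
  expect_equal(c(fr2$min, fr2$max), c(1, 1), tolerance = 1e-7)
})

test_that("a pinned linear chain has degenerate flux ranges", {
  net <- toy_linear_network()
  fr <- flux_ranges(net, at_optimum = FALSE, reactions = c("r1", "t_b"))
  expect_equal(fr$min, c(1, 1), tolerance = 1e-9)
  expect_equal(fr$max, c(1, 1), tolerance = 1e-9)
})

test_that("brute-force vertex enumeration certifies both solvers on a toy", {
  net <- toy_branched_network()
  brute <- enumerate_yield_brute(net)
  expect_identical(brute$objective_exact, "2")
  expect_equal(maximize_atp(net)$objective, brute$objective, tolerance = 1e-9)
  expect_equal(max_atp_exact(net)$objective, brute$objective)
  # the guard refuses the full curated network
  expect_error(enumerate_yield_brute(load_preset("vickermania"),
                                     max_combos = 1000),
               "refused")
})

test_that("LP and exact oracle agree across presets, oxygen and key knockouts", {
  grid <- preset_oxygen_grid()
  kos <- list(character(0), "pdc", "asct", "frd", "aox", "pepck")
  for (i in seq_len(nrow(grid))) {
    for (ko in kos) {
      net <- load_preset(grid$preset[i]) |>
        apply_scenario(scenario(aerobic = grid$aerobic[i], knockouts = ko))
      f <- maximize_atp(net, parsimonious = FALSE)
      e <- max_atp_exact(net)
      expect_equal(f$status, e$status)
      if (f$status == "optimal") {
        expect_equal(f$objective, e$objective, tolerance = 1e-9,
                     label = paste(grid$preset[i],
                                   if (grid$aerobic[i]) "aerobic" else "anaerobic",
                                   paste(ko, collapse = "+")))
      }
    }
  }
})

test_that("carbon and cofactors are conserved at every optimum", {
  grid <- preset_oxygen_grid()
  for (i in seq_len(nrow(grid))) {
    net <- load_preset(grid$preset[i]) |>
      apply_scenario(scenario(aerobic = grid$aerobic[i]))
    sol <- maximize_atp(net)
    expect_equal(exchange_carbon_flux(sol, net), 0, tolerance = 1e-9)
    expect_true(all(abs(all_cofactor_closures(sol, net)) < 1e-9))
  }
})

test_that("the dismutation ratio at the anaerobic optimum is 2:1", {
  sol <- maximize_atp(anaerobic_net(block_succinate_export = TRUE))
  y <- stats::setNames(sol$yields$yield, sol$yields$product)
  expect_equal((y[["succinate"]] + y[["propionate"]]) / y[["acetate"]], 2,
               tolerance = 1e-9)
})

test_that("infeasible bounds are reported as such", {
  net <- anaerobic_net(knockouts = "pcc", block_succinate_export = TRUE)
  # with the cycle dead and export blocked, forcing propionate production is
  # impossible
  net$reactions$lb[net$reactions$id == "ex_prop"] <- 0.5
  sol <- maximize_atp(net)
  expect_equal(sol$status, "infeasible")
  expect_match(sol$violated, "constraint")
})

test_that("networks without an ATP drain are rejected", {
  rx <- vickerflux_reactions()
  rx <- rx[rx$subsystem != "atp_drain", ]
  net <- build_network(rx)
  expect_error(maximize_atp(net), "no ATP-drain")
})

test_that("knockout monotonicity holds over seeded random scenarios", {
  base <- maximize_atp(anaerobic_net(), parsimonious = FALSE)$objective
  scns <- random_knockouts(generator_config(seed = 5, absence_rate = 0.15),
                           k = 12, aerobic = FALSE)
  for (scn in scns) {
    obj <- maximize_atp(load_preset("vickermania") |> apply_scenario(scn),
                        parsimonious = FALSE)$objective
    expect_lte(obj, base + 1e-9)
  }
})

test_that("tidiers and plots expose the solution", {
  sol <- maximize_atp(anaerobic_net())
  td <- tidy(sol)
  expect_true(all(c("reaction", "flux", "lb", "ub") %in% names(td)))
  expect_equal(nrow(td), nrow(sol$fluxes))
  gl <- glance(sol)
  expect_equal(gl$objective, 3.5)
  expect_equal(gl$status, "optimal")
  expect_equal(gl$propionate, 1)
  p <- autoplot(sol)
  expect_s3_class(p, "ggplot")
  p2 <- plot_fluxes(sol)
  expect_s3_class(p2, "ggplot")
})
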