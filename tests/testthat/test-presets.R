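test_that("the vickermania preset has no complex III/IV and no cytochrome c", {
  net <- load_preset("vickermania")
  expect_false(any(c("cyc3_m", "cox_m") %in% net$reactions$id))
  expect_false(any(grepl("^cytc", net$stoich$metabolite)))
  # glycerol kinase is absent too (the annotated gene is a xylulose kinase)
  expect_false("glyk_g" %in% net$reactions$id)
  # but complex I, II, V, AOX and the propionate cycle are present
  expect_true(all(c("nadh1_m", "sdh_m", "atps_m", "aox_m",
                    "mcm_m", "mce_m", "pcc_m", "pct_m") %in% net$reactions$id))
})

test_that("the only route from ubiquinol to oxygen in vickermania is AOX", {
  net <- load_preset("vickermania")
  consumers <- net$stoich$reaction[net$stoich$metabolite == "qh2_m" &
                                     net$stoich$coef < 0]
  expect_identical(sort(consumers), "aox_m")
})

test_that("leishmania_like carries complexes III and IV and diffs as documented", {
  leish <- load_preset("leishmania_like")
  expect_true(all(c("cyc3_m", "cox_m") %in% leish$reactions$id))
  manifest <- vickerflux:::preset_manifest()
  diff <- preset_enzyme_diff()
  expect_setequal(
    setdiff(unlist(manifest$leishmania_like$enzymes),
            unlist(manifest$vickermania$enzymes)),
    diff$enzyme_id
  )
})

test_that("every preset passes the whole-table carbon audit", {
  for (p in vickerflux_presets()) {
    audit <- check_carbon_balance(load_preset(p))
    expect_true(all(audit$pass), label = paste(p, "carbon audit"))
  }
})

test_that("unknown presets and knockouts error informatively", {
  expect_error(load_preset("martian"), "unknown preset.*vickermania")
  net <- load_preset("vickermania")
  expect_error(apply_scenario(net, scenario(knockouts = "warp_drive")),
               "valid enzyme ids")
  expect_error(scenario(inhibitors = "aspirin"), "unknown inhibitor")
})

test_that("scenario application is idempotent and controls oxygen", {
  net <- load_preset("vickermania")
  scn <- scenario(aerobic = FALSE, inhibitors = "SHAM", knockouts = "pcc")
  once <- apply_scenario(net, scn)
  twice <- apply_scenario(once, scn)
  expect_identical(once$reactions$lb, twice$reactions$lb)
  expect_identical(once$reactions$ub, twice$reactions$ub)
  o2 <- once$reactions[once$reactions$id == "ex_o2", ]
  expect_equal(c(o2$lb, o2$ub), c(0, 0))
  aer <- apply_scenario(net, scenario(aerobic = TRUE))
  expect_lt(aer$reactions$lb[aer$reactions$id == "ex_o2"], 0)
})

test_that("inhibitors zero their target reactions", {
  leish <- load_preset("leishmania_like")
  bounds_of <- function(net, id) {
    unlist(net$reactions[net$reactions$id == id, c("lb", "ub")], use.names = FALSE)
  }
  sham <- apply_scenario(leish, scenario(inhibitors = "SHAM"))
  expect_equal(bounds_of(sham, "aox_m"), c(0, 0))
  cn <- apply_scenario(leish, scenario(inhibitors = "cyanide"))
  expect_equal(bounds_of(cn, "cox_m"), c(0, 0))
  mal <- apply_scenario(leish, scenario(inhibitors = "malonate"))
  expect_equal(bounds_of(mal, "sdh_m"), c(0, 0))
  # cyanide is a no-op on vickermania: there is no complex IV to inhibit
  vick <- load_preset("vickermania")
  with_cn <- apply_scenario(vick, scenario(inhibitors = "cyanide"))
  without <- apply_scenario(vick, scenario())
  expect_identical(with_cn$reactions$ub, without$reactions$ub)
})

test_that("knocking out every enzyme leaves only non-enzymatic capacity", {
  net <- load_preset("tbrucei_bloodstream")
  all_enz <- enzyme_vocabulary()$enzyme_id
  ko <- apply_scenario(net, scenario(knockouts = all_enz))
  gated <- lengths(ko$reactions$enzymes) > 0
  expect_true(all(ko$reactions$ub[gated] == 0))
  expect_true(all(ko$reactions$lb[gated] == 0))
  # and the ATP optimum collapses to zero
  expect_equal(maximize_atp(ko)$objective, 0)
})

test_that("scenario round-trips through the key/value config format", {
  f <- withr::local_tempfile(fileext = ".json")
  scn <- scenario(aerobic = FALSE, glucose_uptake = 2,
                  inhibitors = c("SHAM", "malonate"), knockouts = "pcc",
                  block_succinate_export = TRUE)
  jsonlite::write_json(unclass(scn), f, auto_unbox = TRUE)
  back <- read_scenario(f)
  expect_equal(unclass(back), unclass(scn))
})

test_that("a positive P/O ratio adds oxidative ATP aerobically", {
  net <- load_preset("vickermania")
  base <- maximize_atp(apply_scenario(net, scenario(aerobic = TRUE)))
  coupled <- maximize_atp(apply_scenario(net, scenario(aerobic = TRUE,
                                                       po_ratio = 1)))
  expect_gt(coupled$objective, base$objective)
  # anaerobically the chain is dead and the coupling changes nothing
  an_base <- maximize_atp(apply_scenario(net, scenario(aerobic = FALSE)))
  an_coup <- maximize_atp(apply_scenario(net, scenario(aerobic = FALSE,
                                                       po_ratio = 1)))
  expect_equal(an_coup$objective, an_base$objective)
})
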