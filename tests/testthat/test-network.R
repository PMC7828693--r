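test_that("the full curated table builds and is carbon-balanced throughout", {
  net <- build_network()
  expect_s3_class(net, "flux_network")
  audit <- check_carbon_balance(net)
  expect_true(all(audit$pass))
  # exchanges exist for nutrients and every fermentation end product
  ex <- net$reactions$id[net$reactions$exchange]
  expect_true(all(c("ex_glc", "ex_o2", "ex_co2", "ex_ac", "ex_etoh",
                    "ex_succ", "ex_prop") %in% ex))
})

test_that("an empty table gives an empty network", {
  empty <- vickerflux_reactions()[0, ]
  net <- build_network(empty)
  expect_equal(nrow(net$reactions), 0)
  expect_equal(dim(stoichiometric_matrix(net)), c(0, 0))
  # and the audit is vacuously clean
  expect_equal(nrow(check_carbon_balance(net)), 0)
})

test_that("malformed and unbalanced rows are rejected with names", {
  rx <- vickerflux_reactions()
  bad <- rx
  bad$equation[bad$id == "pdc_c"] <- "pyr_c - acald_c"
  expect_error(build_network(bad), "malformed stoichiometry.*pdc_c")

  # deliberately mis-transcribed pyruvate decarboxylase: CO2 omitted leaves a
  # one-carbon deficit that the import audit must report
  bad2 <- rx
  bad2$equation[bad2$id == "pdc_c"] <- "pyr_c -> acald_c"
  err <- tryCatch(build_network(bad2), error = conditionMessage)
  expect_match(err, "carbon-unbalanced")
  expect_match(err, "pdc_c")
  expect_match(err, "-1")

  dup <- dplyr::bind_rows(rx, rx[1, ])
  expect_error(build_network(dup), "duplicate reaction ids")

  ghost <- rx
  ghost$equation[ghost$id == "hk"] <- "glc_g + atp_g -> nosuchmet + adp_g"
  expect_error(build_network(ghost), "unknown metabolite.*nosuchmet")
})

test_that("carbon balance arithmetic handles the canonical cases", {
  net <- build_network()
  # pyruvate (3C) -> acetaldehyde (2C) + CO2 (1C)
  pdc <- check_carbon_balance(net, "pdc_c")
  expect_true(pdc$pass)
  expect_identical(pdc$net_carbon_exact, "0")
  # pyruvate dehydrogenase balances because CoA is a zero-carbon carrier
  pdh <- check_carbon_balance(net, "pdh_m")
  expect_true(pdh$pass)
  # exchanges are exempt despite being one-sided
  exg <- check_carbon_balance(net, "ex_glc")
  expect_true(exg$exchange)
  expect_true(exg$pass)
  expect_error(check_carbon_balance(net, "nope"), "unknown reaction")
})

test_that("stoichiometric matrix matches a naive double-loop assembly", {
  net <- build_network()
  S <- stoichiometric_matrix(net)
  expect_equal(dim(S), c(length(vickerflux:::internal_metabolites(net)),
                         nrow(net$reactions)))
  # oracle: walk every reaction x metabolite pair independently of the
  # package's triplet construction
  oracle <- matrix(0, nrow(S), ncol(S), dimnames = dimnames(S))
  for (id in net$reactions$id) {
    eq <- net$reactions$equation[net$reactions$id == id]
    parsed <- vickerflux:::parse_equation(eq)
    for (k in seq_len(nrow(parsed))) {
      met <- parsed$metabolite[k]
      if (met %in% rownames(oracle)) {
        oracle[met, id] <- parsed$num[k] / parsed$den[k]
      }
    }
  }
  expect_identical(S, oracle)
})

test_that("matrix round-trip preserves exact rational coefficients", {
  net <- build_network()
  ex <- stoichiometric_matrix(net, exact = TRUE)
  for (id in c("pdh_m", "cox_m", "aox_m", "pepck_g")) {
    st <- net$stoich[net$stoich$reaction == id, ]
    for (k in seq_len(nrow(st))) {
      expect_identical(ex$num[st$metabolite[k], id], st$num[k])
      expect_identical(ex$den[st$metabolite[k], id], st$den[k])
    }
    # and columns carry nothing else
    col_mets <- rownames(ex$S)[ex$num[, id] != 0]
    expect_setequal(col_mets, st$metabolite)
  }
  # half-coefficients survive exactly (complex IV consumes 1/2 O2)
  expect_identical(ex$num["o2_m", "cox_m"], -1)
  expect_identical(ex$den["o2_m", "cox_m"], 2)
})

test_that("pyruvate dehydrogenase column has the expected signs", {
  net <- build_network()
  S <- stoichiometric_matrix(net)
  expect_lt(S["pyr_m", "pdh_m"], 0)
  expect_lt(S["nad_m", "pdh_m"], 0)
  expect_lt(S["coa_m", "pdh_m"], 0)
  expect_gt(S["accoa_m", "pdh_m"], 0)
  expect_gt(S["co2_m", "pdh_m"], 0)
  expect_gt(S["nadh_m", "pdh_m"], 0)
})

test_that("toy two-reaction network yields the expected 2x2-scale matrix", {
  net <- toy_linear_network()
  S <- stoichiometric_matrix(net)
  expect_equal(S["A_c", "r1"], -1)
  expect_equal(S["B_c", "r1"], 1)
  expect_equal(S["B_e", "ex_b"], -1)
  expect_equal(sum(S[, "r1"] != 0), 2)
})

test_that("cofactor closure is zero at steady state and -2 on the succinate branch", {
  net <- load_preset("vickermania")
  v <- accounting_vector(net)
  expect_equal(cofactor_closure(v, net, "glycosome", "nad"), 0)
  expect_equal(cofactor_closure(v, net, "cytosol", "nad"), 0)
  expect_equal(cofactor_closure(v, net, "mitochondrion", "nad"), 0)
  expect_equal(cofactor_closure(v, net, "mitochondrion", "q"), 0)
  # all-zero vector trivially closes
  zero <- stats::setNames(rep(0, nrow(net$reactions)), net$reactions$id)
  expect_equal(cofactor_closure(zero, net, "glycosome", "nad"), 0)
  # restricted to the succinate branch: net NADH consumption of 2 per
  # succinate, i.e. two moles of NAD+ regenerated
  branch <- c("pepck_g", "mdh_g", "fh_g", "frd_g")
  expect_equal(cofactor_closure(v, net, "glycosome", "nad", reactions = branch),
               -2)
  expect_error(cofactor_closure(v, net, "glycosome", "cytc"),
               "not present in compartment")
})
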