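# FBA, FVA, MOMA and the model quality checks.

test_that("FBA solves bottleneck chains and reports degenerate-safe optima", {
  m <- chain_model(uptake = 10)
  sol <- fba(m, "EX_b")
  expect_identical(sol$status, "optimal")
  expect_flux_equal(sol$objective_value, 10)
  # uptake bound, not capacity, is binding
  m2 <- chain_model(uptake = 10, cap = 4)
  expect_flux_equal(fba(m2, "EX_b")$objective_value, 4)
  # toy model grows on glucose
  toy <- build_toy()
  g <- fba(toy, medium = toy_medium("glucose", 10))
  expect_identical(g$status, "optimal")
  expect_gt(g$objective_value, 0)
  # S v = 0 within tolerance at the optimum
  S <- as.matrix(stoichiometric_matrix(toy))
  v <- g$fluxes[colnames(S)]
  expect_lt(max(abs(S %*% v)), 1e-6)
})

test_that("FVA brackets the FBA optimum and resolves parallel branches", {
  # unique optimum: chain at gamma = 1 pins every reaction
  m <- chain_model(uptake = 7)
  f <- fva(m, "EX_b", fraction = 1)
  expect_true(all(abs(f$min_flux - f$max_flux) < 1e-6))
  expect_flux_equal(f$max_flux[f$reaction == "EX_b"], 7)

  # two equivalent branches: each ranges [0, optimum], sum constrained
  b <- branch_model(uptake = 5)
  fb <- fva(b, "EX_b", fraction = 1, reactions = c("B1", "B2"))
  expect_flux_equal(fb$min_flux[fb$reaction == "B1"], 0)
  expect_flux_equal(fb$max_flux[fb$reaction == "B1"], 5)
  expect_flux_equal(fb$min_flux[fb$reaction == "B2"], 0)
  expect_flux_equal(fb$max_flux[fb$reaction == "B2"], 5)

  # FBA flux lies inside every FVA interval (property, toy model)
  toy <- apply_medium(build_toy(toy_options(adhe = TRUE)),
                      toy_medium("glucose", 5))
  sol <- fba(toy, "EX_etoh")
  fr <- fva(toy, "EX_etoh", fraction = 1,
            reactions = c("GAPDH", "POR", "ADHE", "EX_etoh", "MBH"))
  for (i in seq_len(nrow(fr))) {
    v <- sol$fluxes[[fr$reaction[i]]]
    expect_gte(v, fr$min_flux[i] - 1e-6)
    expect_lte(v, fr$max_flux[i] + 1e-6)
  }
  expect_error(fva(chain_model(), "EX_b", fraction = 0), "fraction")
})

test_that("MOMA returns the reference when feasible and projects when not", {
  m <- moma_triangle_model()
  vref <- c(P = 6, C1 = 3, C2 = 3)
  same <- moma(m, vref)
  expect_identical(same$status, "optimal")
  expect_lt(same$distance, 1e-6)

  # block C2: closed-form projection onto {P = C1, C2 = 0} gives (4.5, 4.5, 0)
  blocked <- apply_design(m, new_design(direction_overrides = c(C2 = "blocked")))
  proj <- moma(blocked, vref)
  expect_flux_equal(proj$fluxes[["P"]], 4.5)
  expect_flux_equal(proj$fluxes[["C1"]], 4.5)
  expect_flux_equal(proj$fluxes[["C2"]], 0)
  expect_flux_equal(proj$distance, sqrt(1.5^2 + 1.5^2 + 3^2))
  # L1 variant also satisfies the constraints
  proj1 <- moma(blocked, vref, norm = "l1")
  expect_flux_equal(proj1$fluxes[["C2"]], 0)
  expect_flux_equal(proj1$fluxes[["P"]], proj1$fluxes[["C1"]])

  # infeasible edited model reports status, not garbage
  dead <- m
  dead$reactions$P$lb <- 5; dead$reactions$P$ub <- 5
  dead$reactions$C1$ub <- 1; dead$reactions$C2$ub <- 1
  expect_identical(moma(dead, vref)$status, "infeasible")
})

test_that("MOMA on the ldh knockout redirects carbon to acetate and pyruvate", {
  med <- toy_medium("glucose", 10)
  wt <- build_toy()
  wtc <- calibrate_product_ratios(
    wt, c(EX_lac = 0.5, EX_ac = 0.35, EX_pyr = 0.15),
    products = c("EX_lac", "EX_ac", "EX_pyr", "EX_etoh", "EX_actn"))
  ref <- fba(wtc, medium = med)
  expect_gt(ref$fluxes[["EX_lac"]], 0)
  dl <- apply_design(wt, new_design(deleted_genes = "g_ldh"))
  sol <- moma(dl, ref$fluxes, medium = med)
  expect_identical(sol$status, "optimal")
  expect_flux_equal(sol$fluxes[["EX_lac"]], 0)
  expect_gt(sol$fluxes[["EX_ac"]] + sol$fluxes[["EX_pyr"]],
            ref$fluxes[["EX_ac"]] + ref$fluxes[["EX_pyr"]])
  expect_gt(sol$distance, 0)
})

test_that("stoichiometric consistency flags mass creation and excludes boundaries", {
  m <- chain_model()
  expect_equal(check_stoichiometric_consistency(m)$percent, 100)
  # A -> 2A creates mass
  bad <- m
  bad$reactions$DUP <- reaction("DUP", stoich = c("a[c]" = 1), lb = 0,
                                ub = 10)
  bad$reactions$DUP$stoich <- c("a[c]" = 1)  # net production of a
  bad$reactions$DUP$kind <- "cytosolic"
  res <- check_stoichiometric_consistency(bad)
  expect_lt(res$percent, 100)
  expect_true("a[c]" %in% res$inconsistent_compounds)
})

test_that("formula and charge balance checks report deltas and exclusions", {
  cps <- rbind(compound("co2", formula = "CO2", charge = 0),
               compound("h2o", formula = "H2O", charge = 0),
               compound("h2co3", formula = "CH2O3", charge = 0),
               compound("badh", formula = "CH3O3", charge = -1),
               compound("rgrp", formula = "C2R", charge = 0),
               compound("x", compartment = "c"))
  rxs <- list(
    reaction("CARB", equation = "co2[c] + h2o[c] <=> h2co3[c]"),
    reaction("BROKEN", equation = "h2co3[c] => badh[c]"),   # loses H, gains charge
    reaction("WITHR", equation = "rgrp[c] => co2[c] + x[c]"),
    reaction("BIO", equation = "h2co3[c] =>", kind = "biomass"))
  m <- new_model(cps, rxs, biomass_id = "BIO")
  fb <- check_formula_balance(m)
  expect_false("CARB" %in% fb$imbalanced$reaction)
  expect_true("BROKEN" %in% fb$imbalanced$reaction)
  expect_match(fb$imbalanced$delta[fb$imbalanced$reaction == "BROKEN"], "H")
  expect_true("WITHR" %in% fb$excluded$reaction)
  expect_false("BIO" %in% c(fb$imbalanced$reaction, fb$excluded$reaction))
  cb <- check_charge_balance(m)
  expect_true("BROKEN" %in% cb$imbalanced$reaction)
  # report invariant: excluded and imbalanced are disjoint
  rep <- consistency_report(m)
  expect_length(intersect(rep$excluded_reactions$reaction,
                          c(rep$imbalanced_formula_reactions,
                            rep$imbalanced_charge_reactions)), 0)
})

test_that("balance audits pass on optimal toy solutions", {
  med <- toy_medium("glucose", 10)
  m <- build_toy(toy_options(adhe = TRUE, rnf_na = TRUE))
  for (obj in c("BIOMASS", "EX_etoh", "EX_ac")) {
    sol <- fba(m, obj, medium = med)
    expect_identical(sol$status, "optimal")
    expect_true(audit_carbon_balance(m, sol)$ok, label = obj)
    expect_true(audit_electron_balance(m, sol)$ok, label = obj)
  }
})
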