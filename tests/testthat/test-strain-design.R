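# Knock-in catalog, redox economics of the engineered designs, design
# matrix, and production envelopes.

med10 <- function() toy_medium("glucose", 10)

toy_with <- function(...) build_toy(toy_options(...))

test_that("every knock-in is element- and charge-balanced", {
  m <- build_toy(toy_options(adhe = TRUE, rnf_na = TRUE, rnf_h = TRUE,
                             mrp = TRUE, sh1 = TRUE, sh2 = TRUE))
  fb <- check_formula_balance(m)
  cb <- check_charge_balance(m)
  kin <- c("ADHE", "RNF_NA", "RNF_H", "MRP", "SH1", "SH2")
  expect_length(intersect(kin, fb$imbalanced$reaction), 0)
  expect_length(intersect(kin, cb$imbalanced$reaction), 0)
  expect_length(intersect(kin, fb$excluded$reaction), 0)
  # provenance notes present
  cat <- knockin_catalog()
  expect_true(all(vapply(cat, function(e) nzchar(e$note), TRUE)))
})

test_that("ethanol production requires AdhE and POR", {
  expect_flux_equal(
    max_product(toy_with(), "EX_etoh", med10())$product_mM, 0)
  m <- toy_with(adhe = TRUE)
  expect_gt(max_product(m, "EX_etoh", med10())$product_mM, 0)
  nopor <- apply_design(m, new_design(deleted_genes = "g_por"))
  expect_flux_equal(max_product(nopor, "EX_etoh", med10())$product_mM, 0)
})

test_that("redox economics: 2.0 vs 1.0 mol ethanol per mol glucose", {
  # reversible BF-H2ase: MBH/BF-H2ase H2-recycling loop recovers Fd_red
  expect_flux_equal(
    max_product(toy_with(adhe = TRUE), "EX_etoh", med10())$mol_per_mol, 2)
  # H2-producing-only BF-H2ase and no Rnf/SH: only GAPDH NADH remains
  expect_flux_equal(
    max_product(toy_with(adhe = TRUE, bfh2ase_mode = "forward_only"),
                "EX_etoh", med10())$mol_per_mol, 1)
  # Rnf_H, Rnf_Na + Mrp, SH1 and SH2 each restore 2.0 with a
  # H2-producing-only BF-H2ase
  for (args in list(list(rnf_h = TRUE), list(rnf_na = TRUE, mrp = TRUE),
                    list(sh1 = TRUE), list(sh2 = TRUE))) {
    opts <- do.call(toy_options, c(list(adhe = TRUE,
                                        bfh2ase_mode = "forward_only"), args))
    expect_flux_equal(
      max_product(build_toy(opts), "EX_etoh", med10())$mol_per_mol, 2)
  }
})

test_that("yields are robust across ion-translocation stoichiometries", {
  for (hatp in c(3, 4)) for (pmbh in c(1, 2)) {
    o1 <- toy_options(adhe = TRUE, h_per_atp = hatp, h_pumped_mbh = pmbh)
    expect_flux_equal(
      max_product(build_toy(o1), "EX_etoh", med10())$mol_per_mol, 2)
    o2 <- toy_options(adhe = TRUE, bfh2ase_mode = "forward_only",
                      h_per_atp = hatp, h_pumped_mbh = pmbh)
    expect_flux_equal(
      max_product(build_toy(o2), "EX_etoh", med10())$mol_per_mol, 1)
  }
})

test_that("Rnf_Na without a sodium return path carries zero flux", {
  m <- toy_with(adhe = TRUE, rnf_na = TRUE, bfh2ase_mode = "forward_only")
  res <- max_product(m, "EX_etoh", med10())
  fr <- fva(local({
    mm <- apply_medium(m, med10())
    mm$reactions$EX_etoh$lb <- res$product_mM * 0.9999
    mm
  }), "EX_etoh", fraction = 0.9999, reactions = "RNF_NA")
  expect_flux_equal(fr$min_flux, 0)
  expect_flux_equal(fr$max_flux, 0)
  # and the yield equals the no-Rnf strain's
  expect_flux_equal(res$mol_per_mol, 1)
})

test_that("MBH:BF-H2ase-reverse optimal flux ratio is 2:1 in the recycling loop", {
  m <- apply_medium(toy_with(adhe = TRUE), med10())
  emax <- fba(m, "EX_etoh")$objective_value
  m$reactions$EX_etoh$lb <- emax * 0.9999
  fr <- fva(m, "EX_etoh", fraction = 0.9999, reactions = c("MBH", "BFH2"))
  mbh <- fr[fr$reaction == "MBH", ]
  bfh <- fr[fr$reaction == "BFH2", ]
  expect_lt(bfh$max_flux, 0)   # BF-H2ase runs in reverse (H2-consuming)
  expect_flux_equal(mbh$min_flux / abs(bfh$max_flux), 2, tol = 1e-3)
  expect_flux_equal(mbh$max_flux / abs(bfh$min_flux), 2, tol = 1e-3)
})

test_that("triple redox deletion abolishes growth and ethanol", {
  m <- toy_with(adhe = TRUE, rnf_na = TRUE)
  trip <- apply_design(m, new_design(deleted_genes = c("g_mbh", "g_bfh",
                                                       "g_nfn")))
  expect_flux_equal(fba(trip, medium = med10())$objective_value, 0)
  expect_flux_equal(max_product(trip, "EX_etoh", med10())$product_mM, 0)
})

test_that("design matrix is monotone and balance audits pass on each row", {
  base <- toy_with(adhe = TRUE, rnf_na = TRUE)
  med <- toy_medium("cellulose", cellulose_uptake_mM(11.8), uracil = 1)
  dm <- evaluate_designs(base, cbes_design_matrix(), "forward_only", med,
                         biomass_min = 0.41)
  expect_identical(dm$design[1], "E1M")
  e1m <- dm$ethanol_mM[1]
  # knockout-only rows never exceed the parent design
  ko_rows <- grep("^(del_|no_)", dm$design)
  expect_true(all(dm$ethanol_mM[ko_rows] <= e1m + 1e-6))
  # only the triple redox deletion is lethal
  expect_identical(dm$status[dm$design == "del_redox_triple"], "infeasible")
  expect_true(all(dm$status[dm$design != "del_redox_triple"] == "optimal"))
  # knock-in designs recover roughly double the base yield
  for (d in c("plus_mrp", "rnf_h", "sh1", "sh2"))
    expect_gt(dm$ethanol_mM[dm$design == d], 1.8 * e1m)
  # pyrE deletion has little influence (uracil salvage active)
  expect_flux_equal(dm$ethanol_mM[dm$design == "del_pyrE"], e1m, tol = 1e-4)
  # ldh deletion cannot exceed the parent (gene also carries MDH)
  expect_lte(dm$ethanol_mM[dm$design == "del_ldh"], e1m + 1e-6)
  # MBH deletion is the most damaging single redox deletion
  singles <- c("del_mbh", "del_bfh2", "del_nfn")
  vals <- dm$ethanol_mM[match(singles, dm$design)]
  expect_identical(singles[which.min(vals)], "del_mbh")

  # audits on every optimal row
  cat <- knockin_catalog()
  for (i in seq_len(nrow(dm))) {
    if (dm$status[i] != "optimal") next
    d2 <- combine_designs(
      new_design(direction_overrides = c(BFH2 = "forward_only")),
      cbes_design_matrix()[[dm$design[i]]])
    mm <- apply_design(base, d2)
    res <- max_product(mm, "EX_etoh", med, biomass_min = 0.41)
    expect_true(audit_carbon_balance(mm, res$fluxes)$ok, label = dm$design[i])
    expect_true(audit_electron_balance(mm, res$fluxes)$ok,
                label = dm$design[i])
    # stoichiometric ceiling: <= 2 ethanol per glucose-equivalent
    expect_lte(res$mol_per_mol, 2 + 1e-6)
  }
})

test_that("ATP synthase flux collapses when MBH is deleted at max ethanol", {
  med <- med10()
  e1m <- apply_medium(toy_with(adhe = TRUE, rnf_na = TRUE), med)
  emax <- fba(e1m, "EX_etoh")$objective_value
  e1m$reactions$EX_etoh$lb <- emax * 0.9999
  atps_min_base <- fva(e1m, "EX_etoh", fraction = 0.9999,
                       reactions = "ATPS")$min_flux
  dd <- apply_design(toy_with(adhe = TRUE, rnf_na = TRUE),
                     new_design(deleted_genes = "g_mbh"))
  dd <- apply_medium(dd, med)
  emax2 <- fba(dd, "EX_etoh")$objective_value
  dd$reactions$EX_etoh$lb <- emax2 * 0.9999
  atps_max_mut <- fva(dd, "EX_etoh", fraction = 0.9999,
                      reactions = "ATPS")$max_flux
  expect_gt(atps_min_base, 0)
  expect_lt(atps_max_mut, 0.02 * atps_min_base)
})

test_that("production envelopes reproduce the flux-variability structure", {
  med <- med10()
  # step 0 equals unconstrained variability
  m <- toy_with(adhe = TRUE, bfh2ase_mode = "forward_only")
  env <- production_envelope(m, steps = 10, medium = med,
                             watch = c("GAPDH", "MBH", "EX_h2"))
  s0 <- env[env$step == 0 & env$reaction == "GAPDH", ]
  m0 <- apply_medium(m, med)
  direct_max <- fba(m0, "GAPDH")$objective_value
  expect_flux_equal(s0$max_flux, direct_max)
  # final step, H2-producing-only, no Rnf/SH: GAPDH is essential
  sf <- env[env$step == 10, ]
  expect_gt(sf$min_flux[sf$reaction == "GAPDH"], 0)
  # reversible BF-H2ase: GOR can replace GAPDH even at maximum ethanol
  env_rev <- production_envelope(toy_with(adhe = TRUE), steps = 10,
                                 medium = med, watch = "GAPDH")
  expect_flux_equal(env_rev$min_flux[env_rev$step == 10], 0)
  # with Rnf_H the proton-pumping role of MBH is dispensable: MBH and H2
  # export can both be zero at maximum ethanol
  env_h <- production_envelope(
    toy_with(adhe = TRUE, rnf_h = TRUE, bfh2ase_mode = "forward_only"),
    steps = 10, medium = med, watch = c("MBH", "EX_h2"))
  fh <- env_h[env_h$step == 10, ]
  expect_flux_equal(fh$min_flux[fh$reaction == "MBH"], 0)
  expect_flux_equal(fh$min_flux[fh$reaction == "EX_h2"], 0)
})

test_that("SH designs depend on the H2-producing machinery", {
  med <- med10()
  # SH1 needs MBH (proton pumping + H2 supply)
  sh1 <- toy_with(adhe = TRUE, sh1 = TRUE, bfh2ase_mode = "forward_only")
  sh1_nombh <- apply_design(sh1, new_design(deleted_genes = "g_mbh"))
  y_full <- max_product(sh1, "EX_etoh", med)$mol_per_mol
  y_cut <- max_product(sh1_nombh, "EX_etoh", med)$mol_per_mol
  expect_flux_equal(y_full, 2)
  expect_lt(y_cut, y_full - 0.5)
  # SH2 needs MBH or BF-H2ase for H2 supply, but either suffices
  sh2 <- toy_with(adhe = TRUE, sh2 = TRUE, bfh2ase_mode = "forward_only")
  y_sh2_nombh <- max_product(
    apply_design(sh2, new_design(deleted_genes = "g_mbh")),
    "EX_etoh", med)$mol_per_mol
  expect_flux_equal(y_sh2_nombh, 2)
  y_sh2_cut <- max_product(
    apply_design(sh2, new_design(deleted_genes = c("g_mbh", "g_bfh"))),
    "EX_etoh", med)$mol_per_mol
  expect_lt(y_sh2_cut, 2 - 0.5)
})
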