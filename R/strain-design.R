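# Knock-in catalog and in-silico strain design evaluation: design matrices
# of maximum ethanol production and production-envelope sweeps.

#' Catalog of heterologous knock-in functions
#'
#' Reaction definitions for the engineering candidates considered for
#' C. bescii, with element- and charge-balanced stoichiometry including
#' translocated ions (ferredoxin as a 2-electron couple):
#'
#' * `ADHE` — bifunctional acetaldehyde/alcohol dehydrogenase
#'   (C. thermocellum): acetyl-CoA + 2 NADH + 2 H+ -> ethanol + CoA + 2 NAD+.
#' * `RNF_NA` — sodium-pumping reduced ferredoxin:NAD oxidoreductase
#'   (Thermoanaerobacter sp. X514): Fd_red oxidation to NADH coupled to
#'   Na+ export; carries no net flux without a sodium return path.
#' * `RNF_H` — proton-pumping variant of Rnf.
#' * `MRP` — multi-subunit Na+/H+ antiporter interconverting the sodium and
#'   proton gradients.
#' * `SH1` — NADPH-producing soluble hydrogenase (H2 + NADP+ -> NADPH + H+).
#' * `SH2` — NADH-producing soluble hydrogenase (H2 + NAD+ -> NADH + H+).
#'
#' @param ions_per_fd ions translocated per Fd_red oxidized by Rnf.
#' @return named list; each entry has `name`, `reaction` (a [reaction()]
#'   carrying a `compounds` attribute with any species it requires) and a
#'   provenance `note`.
#' @export
knockin_catalog <- function(ions_per_fd = 1) {
  stopifnot(ions_per_fd >= 1)
  k <- ions_per_fd
  na_cpds <- rbind(compound("na", "sodium ion", "Na", 1, "c"),
                   compound("na", "sodium ion", "Na", 1, "e"))
  mk <- function(name, eq, genes, note, compounds = NULL, kind = NA) {
    rxn <- reaction(name, equation = eq, genes = genes, kind = kind)
    if (!is.null(compounds)) attr(rxn, "compounds") <- compounds
    list(name = name, reaction = rxn, note = note)
  }
  list(
    ADHE = mk("ADHE",
              "accoa[c] + (2) nadh[c] + (2) h[c] => etoh[c] + coa[c] + (2) nad[c]",
              "g_adhE",
              "bifunctional acetaldehyde/alcohol dehydrogenase, C. thermocellum"),
    RNF_NA = mk("RNF_NA",
                sprintf("fdred[c] + nad[c] + h[c] + (%d) na[c] => fdox[c] + nadh[c] + (%d) na[e]",
                        k, k),
                "g_rnfNa",
                "sodium-pumping reduced ferredoxin:NAD oxidoreductase, Thermoanaerobacter sp. X514",
                compounds = na_cpds),
    RNF_H = mk("RNF_H",
               sprintf("fdred[c] + nad[c] + (%d) h[c] => fdox[c] + nadh[c] + (%d) h[e]",
                       k + 1, k),
               "g_rnfH",
               "proton-pumping reduced ferredoxin:NAD oxidoreductase (mesophilic homologs)"),
    MRP = mk("MRP", "na[e] + h[c] <=> na[c] + h[e]", "g_mrp",
             "multi-subunit Na+/H+ antiporter (thermostable homologs in Thermococcales)",
             compounds = na_cpds),
    SH1 = mk("SH1", "h2[c] + nadp[c] <=> nadph[c] + h[c]", "g_sh1",
             "NADPH-producing soluble hydrogenase (Thermococcales)"),
    SH2 = mk("SH2", "h2[c] + nad[c] <=> nadh[c] + h[c]", "g_sh2",
             "NADH-producing soluble hydrogenase (Thermococcales)")
  )
}

#' Maximum product formation of a strain
#'
#' FBA maximum of a product exchange flux subject to a minimum biomass
#' flux, reported both in raw flux units (mM per liter on the
#' substrate-consumed basis when the medium bounds total substrate
#' consumption in mM) and as mol product per mol substrate-equivalent
#' taken up.
#'
#' @param model a `cb_model` (already engineered).
#' @param product_exchange exchange reaction id of the product.
#' @param medium `cb_medium` bounding total substrate consumption.
#' @param biomass_min minimum biomass flux enforced during maximization.
#' @param substrate_exchange exchange id used for the mol/mol basis
#'   (default: the medium entry with the most negative lower bound).
#' @return list with `status`, `product_mM`, `mol_per_mol`, `biomass`,
#'   `fluxes`.
#' @export
max_product <- function(model, product_exchange, medium,
                        biomass_min = 0, substrate_exchange = NULL) {
  if (!product_exchange %in% names(model$reactions))
    stop("unknown product exchange: ", product_exchange)
  m <- apply_medium(model, medium)
  m$reactions[[m$biomass_id]]$lb <- biomass_min
  if (is.null(substrate_exchange)) {
    # the carbon source: carbon-bearing exchange with the most negative
    # uptake bound in the medium
    cw <- element_count(model, "C")
    has_c <- vapply(medium$reaction, function(ex) {
      st <- model$reactions[[ex]]$stoich
      isTRUE(cw[[names(st)]] > 0)
    }, TRUE)
    cand <- medium[has_c & medium$lower < 0, , drop = FALSE]
    if (!nrow(cand)) stop("medium opens no carbon-source uptake")
    substrate_exchange <- cand$reaction[which.min(cand$lower)]
  }
  sol <- fba(m, product_exchange)
  if (sol$status != "optimal")
    return(list(status = sol$status, product_mM = NA_real_,
                mol_per_mol = NA_real_, biomass = NA_real_,
                fluxes = sol$fluxes))
  # mol product per mol glucose-equivalent taken up (carbon / 6)
  cw <- element_count(m, "C")
  sub_c <- cw[[names(m$reactions[[substrate_exchange]]$stoich)]]
  uptake <- -sol$fluxes[[substrate_exchange]] * sub_c / 6
  list(status = "optimal",
       product_mM = sol$objective_value,
       mol_per_mol = if (uptake > 1e-9) sol$objective_value / uptake
                     else NA_real_,
       biomass = sol$fluxes[[m$biomass_id]],
       fluxes = sol$fluxes)
}

#' Evaluate a matrix of strain designs
#'
#' Applies each design to the base model (plus the global BF-H2ase
#' directionality mode), maximizes ethanol production under a shared
#' medium and biomass constraint, and tabulates the results.
#'
#' @param base base `cb_model` (e.g. the E1M-like strain).
#' @param designs named list of `cb_design` objects.
#' @param bfh2ase_mode `"reversible"` or `"forward_only"`; applied as a
#'   direction override on the `BFH2` reaction when present.
#' @param medium shared `cb_medium`.
#' @param biomass_min minimum biomass flux for every row.
#' @param product_exchange product exchange id (default `"EX_etoh"`).
#' @return data frame with one row per design: `design`, `status`,
#'   `ethanol_mM`, `mol_per_mol`, `biomass`.
#' @export
evaluate_designs <- function(base, designs, bfh2ase_mode = "forward_only",
                             medium, biomass_min = 0,
                             product_exchange = "EX_etoh") {
  stopifnot(bfh2ase_mode %in% c("reversible", "forward_only"))
  rows <- lapply(names(designs), function(nm) {
    d <- designs[[nm]]
    mode_ov <- if ("BFH2" %in% names(base$reactions))
      stats::setNames(bfh2ase_mode, "BFH2") else character()
    d2 <- combine_designs(new_design(direction_overrides = mode_ov), d)
    m <- tryCatch(apply_design(base, d2), error = function(e) NULL)
    if (is.null(m))
      return(data.frame(design = nm, status = "design_error",
                        ethanol_mM = NA_real_, mol_per_mol = NA_real_,
                        biomass = NA_real_))
    res <- max_product(m, product_exchange, medium, biomass_min)
    data.frame(design = nm, status = res$status,
               ethanol_mM = if (res$status == "optimal") res$product_mM else 0,
               mol_per_mol = res$mol_per_mol,
               biomass = if (res$status == "optimal") res$biomass else 0)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Standard design matrix for the synthetic E1M strain
#'
#' The combinatorial set explored for ethanol optimization: the E1M base
#' strain (AdhE + Rnf_Na), single deletions of the genetic-background loci
#' (pyrE, ldh), the Rnf_Na insertion, the ATP/GTP-production functions
#' (AckA, PCK, ATP synthase), single/pairwise/triple deletions of the
#' redox functions (MBH, BF-H2ase, BF-Nfn), and the knock-in designs
#' (+Mrp; Rnf_Na replaced by Rnf_H, SH1 or SH2).
#'
#' @param ions_per_fd ion stoichiometry passed to [knockin_catalog()].
#' @return named list of `cb_design` objects to use with
#'   [evaluate_designs()] on an E1M-like base model.
#' @export
cbes_design_matrix <- function(ions_per_fd = 1) {
  cat <- knockin_catalog(ions_per_fd)
  del_g <- function(...) new_design(deleted_genes = c(...))
  swap_rnf <- function(entry)
    new_design(deleted_reactions = "RNF_NA",
               insertions = list(cat[[entry]]$reaction))
  list(
    E1M = new_design(),
    no_rnf_na = new_design(deleted_reactions = "RNF_NA"),
    del_pyrE = del_g("g_pyrE"),
    del_ldh = del_g("g_ldh"),
    del_acka = del_g("g_acka"),
    del_pck = del_g("g_pck"),
    del_atpsyn = del_g("g_atps"),
    del_mbh = del_g("g_mbh"),
    del_bfh2 = del_g("g_bfh"),
    del_nfn = del_g("g_nfn"),
    del_mbh_bfh2 = del_g("g_mbh", "g_bfh"),
    del_mbh_nfn = del_g("g_mbh", "g_nfn"),
    del_bfh2_nfn = del_g("g_bfh", "g_nfn"),
    del_redox_triple = del_g("g_mbh", "g_bfh", "g_nfn"),
    plus_mrp = new_design(insertions = list(cat$MRP$reaction)),
    rnf_h = swap_rnf("RNF_H"),
    sh1 = swap_rnf("SH1"),
    sh2 = swap_rnf("SH2")
  )
}

#' Production envelope sweep
#'
#' Varies the product flux from zero to its maximum in `steps` steps; at
#' each step the product exchange's lower bound is raised to the target and
#' the flux variability of a watch-list of reactions is recorded (step 0
#' therefore reproduces the unconstrained variability).
#'
#' @param model engineered `cb_model`.
#' @param product_exchange product exchange id.
#' @param steps number of steps (default 100).
#' @param medium `cb_medium`.
#' @param watch reaction ids to track (default: the central redox/energy
#'   reactions present in the model).
#' @param biomass_min minimum biomass flux maintained during the sweep.
#' @return data frame with columns `step`, `product_flux`, `reaction`,
#'   `min_flux`, `max_flux`.
#' @export
production_envelope <- function(model, product_exchange = "EX_etoh",
                                steps = 100, medium, watch = NULL,
                                biomass_min = 0) {
  m <- apply_medium(model, medium)
  m$reactions[[m$biomass_id]]$lb <- biomass_min
  if (is.null(watch)) {
    watch <- intersect(c("GAPDH", "GOR", "MBH", "BFH2", "NFN", "ATPS",
                         "ACKA", "RNF_NA", "RNF_H", "SH1", "SH2", "EX_h2"),
                       names(m$reactions))
  }
  vmax <- fba(m, product_exchange)
  if (vmax$status != "optimal")
    stop("cannot establish product maximum: ", vmax$status)
  pmax <- vmax$objective_value
  out <- list()
  lp0 <- build_lp_problem(m)
  for (s in 0:steps) {
    target <- pmax * s / steps
    lb <- lp0$lb; ub <- lp0$ub
    j <- match(product_exchange, lp0$reactions)
    lb[j] <- max(lb[j], target)
    for (w in watch) {
      cobj <- as.numeric(lp0$reactions == w)
      lo <- solve_lp(lp0$A, lp0$b, cobj, lb, ub, maximize = FALSE)
      hi <- solve_lp(lp0$A, lp0$b, cobj, lb, ub, maximize = TRUE)
      out[[length(out) + 1L]] <- data.frame(
        step = s, product_flux = target, reaction = w,
        min_flux = lo$objective, max_flux = hi$objective)
    }
  }
  do.call(rbind, out)
}
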