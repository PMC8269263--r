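# Synthetic core-metabolism model of C. bescii.
#
# A reduced, fully specified central-carbon + redox network: parallel
# NAD-dependent (GAPDH/PGK) and ferredoxin-dependent (GOR) glycolytic
# branches, POR, substrate-level phosphorylation (PTA/AckA), LDH/MDH
# sharing one gene, proton-pumping MBH, electron-bifurcating BF-H2ase and
# BF-Nfn, ATP synthase, a GTP economy (GTP-forming PCK, ADP/GDP-accepting
# PGK, NDPK), a lumped pyrimidine branch giving the pyrE locus a function,
# and optional knock-ins (AdhE, Rnf_Na, Rnf_H, Mrp, SH1, SH2).
#
# Every internal reaction is element- and charge-balanced, so the network
# scores 100% on the stoichiometric consistency check and has zero
# formula/charge imbalances; ethanol yields are hand-checkable from the
# electron bookkeeping (2 NADH from GAPDH + 2 Fd_red from POR per glucose).
# Ferredoxin is modeled as a two-electron couple Fd_ox/Fd_red (one Fd_red
# carries 2 e-), so POR and GOR transfer one Fd per turnover.

#' Options for the synthetic core model
#'
#' @param substrate default carbon source for [toy_medium()]: `"glucose"`,
#'   `"cellobiose"` or `"cellulose"` (all three uptake routes are always in
#'   the network; this only selects the default medium).
#' @param adhe,rnf_na,rnf_h,mrp,sh1,sh2 logicals: include the corresponding
#'   knock-in from [knockin_catalog()].
#' @param bfh2ase_mode `"reversible"` (default) or `"forward_only"`
#'   (H2-producing direction only).
#' @param h_pumped_mbh protons pumped per H2 by the membrane-bound
#'   hydrogenase (default 1).
#' @param h_per_atp extracellular protons consumed per ATP by the ATP
#'   synthase, one of which is chemical (default 4, i.e. 3 translocated).
#' @param ions_per_fd ions translocated per Fd_red oxidized by Rnf (default 1).
#' @param biomass_atp,biomass_nadph,biomass_nadh,biomass_precursor biomass
#'   equation coefficients per unit biomass flux (defaults 30 ATP, 6 NADPH,
#'   4 NADH, 1 of each precursor); anabolism is a net consumer of both
#'   reduced pyridine cofactors.
#' @return list of validated options.
#' @export
toy_options <- function(substrate = "glucose", adhe = FALSE, rnf_na = FALSE,
                        rnf_h = FALSE, mrp = FALSE, sh1 = FALSE, sh2 = FALSE,
                        bfh2ase_mode = "reversible",
                        h_pumped_mbh = 1, h_per_atp = 4, ions_per_fd = 1,
                        biomass_atp = 30, biomass_nadph = 6,
                        biomass_nadh = 4, biomass_precursor = 1) {
  if (!substrate %in% c("glucose", "cellobiose", "cellulose"))
    stop("unknown substrate: ", substrate)
  if (!bfh2ase_mode %in% c("reversible", "forward_only"))
    stop("unknown bfh2ase_mode: ", bfh2ase_mode)
  if (h_pumped_mbh < 1 || h_per_atp < 2 || ions_per_fd < 1)
    stop("ion translocation stoichiometries must be at least 1 ",
         "(h_per_atp at least 2)")
  if (biomass_atp <= 0 || biomass_nadph <= 0 || biomass_precursor <= 0 ||
      biomass_nadh < 0)
    stop("biomass coefficients must be positive")
  list(substrate = substrate, adhe = adhe, rnf_na = rnf_na, rnf_h = rnf_h,
       mrp = mrp, sh1 = sh1, sh2 = sh2, bfh2ase_mode = bfh2ase_mode,
       h_pumped_mbh = h_pumped_mbh, h_per_atp = h_per_atp,
       ions_per_fd = ions_per_fd, biomass_atp = biomass_atp,
       biomass_nadph = biomass_nadph, biomass_nadh = biomass_nadh,
       biomass_precursor = biomass_precursor)
}

toy_compound_table <- function(include_na) {
  rows <- list(
    c("glc",  "glucose",               "C6H12O6",          0, "ce"),
    c("clb",  "cellobiose",            "C12H22O11",        0, "ce"),
    c("cel",  "cellulose (anhydroglucose unit)", "C6H10O5", 0, "e"),
    c("xyl",  "xylose",                "C5H10O5",          0, "e"),
    c("g6p",  "glucose 6-phosphate",   "C6H11O9P",        -2, "c"),
    c("gap",  "glyceraldehyde 3-phosphate", "C3H5O6P",    -2, "c"),
    c("bpg",  "1,3-bisphosphoglycerate", "C3H4O10P2",     -4, "c"),
    c("pg3",  "3-phosphoglycerate",    "C3H4O7P",         -3, "c"),
    c("pep",  "phosphoenolpyruvate",   "C3H2O6P",         -3, "c"),
    c("pyr",  "pyruvate",              "C3H3O3",          -1, "ce"),
    c("oaa",  "oxaloacetate",          "C4H2O5",          -2, "c"),
    c("mal",  "malate",                "C4H4O5",          -2, "c"),
    c("lac",  "lactate",               "C3H5O3",          -1, "ce"),
    c("accoa", "acetyl-CoA",           "C23H34N7O17P3S",  -4, "c"),
    c("coa",  "coenzyme A",            "C21H32N7O16P3S",  -4, "c"),
    c("actp", "acetyl phosphate",      "C2H3O5P",         -2, "c"),
    c("ac",   "acetate",               "C2H3O2",          -1, "ce"),
    c("etoh", "ethanol",               "C2H6O",            0, "ce"),
    c("actn", "acetoin",               "C4H8O2",           0, "ce"),
    c("btd",  "2,3-butanediol",        "C4H10O2",          0, "ce"),
    c("co2",  "carbon dioxide",        "CO2",              0, "ce"),
    c("h2",   "dihydrogen",            "H2",               0, "ce"),
    c("h2o",  "water",                 "H2O",              0, "ce"),
    c("pi",   "phosphate",             "HO4P",            -2, "ce"),
    c("ppi",  "diphosphate",           "HO7P2",           -3, "c"),
    c("nh4",  "ammonium",              "H4N",              1, "ce"),
    c("atp",  "ATP",                   "C10H12N5O13P3",   -4, "c"),
    c("adp",  "ADP",                   "C10H12N5O10P2",   -3, "c"),
    c("amp",  "AMP",                   "C10H12N5O7P",     -2, "c"),
    c("gtp",  "GTP",                   "C10H12N5O14P3",   -4, "c"),
    c("gdp",  "GDP",                   "C10H12N5O11P2",   -3, "c"),
    c("nad",  "NAD+",                  "C21H26N7O14P2",   -1, "c"),
    c("nadh", "NADH",                  "C21H27N7O14P2",   -2, "c"),
    c("nadp", "NADP+",                 "C21H25N7O17P3",   -3, "c"),
    c("nadph", "NADPH",                "C21H26N7O17P3",   -4, "c"),
    c("fdox", "oxidized ferredoxin (2e- couple)", "Fe8S8", 0, "c"),
    c("fdred", "reduced ferredoxin (2e- couple)", "Fe8S8", -2, "c"),
    c("h",    "proton",                "H",                1, "ce"),
    c("ura",  "uracil",                "C4H4N2O2",         0, "ce"),
    c("ump",  "UMP",                   "C9H11N2O9P",      -2, "c")
  )
  if (include_na)
    rows <- c(rows, list(c("na", "sodium ion", "Na", 1, "ce")))
  out <- do.call(rbind, lapply(rows, function(r) {
    comps <- strsplit(r[5], "")[[1]]
    do.call(rbind, lapply(comps, function(cc)
      compound(r[1], r[2], r[3], as.numeric(r[4]), cc)))
  }))
  out
}

#' Build the synthetic C. bescii core model
#'
#' See [toy_options()] for the knobs. The returned model grows on glucose,
#' cellobiose or cellulose once a medium is applied; without the AdhE
#' knock-in it cannot produce ethanol.
#'
#' @param options list from [toy_options()].
#' @return a `cb_model`.
#' @export
build_toy <- function(options = toy_options()) {
  p <- options$h_pumped_mbh
  k <- options$h_per_atp
  atp <- options$biomass_atp
  npd <- options$biomass_nadph
  ndh <- options$biomass_nadh
  pre <- options$biomass_precursor
  include_na <- options$rnf_na || options$mrp

  compounds <- toy_compound_table(include_na)

  rx <- function(id, eq, genes = NA, subsystem = NA)
    reaction(id, equation = eq, genes = genes, subsystem = subsystem)

  reactions <- list(
    # carbohydrate uptake and activation
    rx("CELH", "cel[e] + h2o[e] => glc[e]", "g_celH", "carbohydrate"),
    rx("CLBt", "clb[e] => clb[c]", "g_clbT", "transport"),
    rx("CLBH", "clb[c] + h2o[c] => (2) glc[c]", "g_clbH", "carbohydrate"),
    rx("GLCt", "glc[e] => glc[c]", "g_glcT", "transport"),
    rx("HEX", "glc[c] + atp[c] => g6p[c] + adp[c] + h[c]", "g_hex",
       "glycolysis"),
    rx("PFK_L", "g6p[c] + atp[c] => (2) gap[c] + adp[c] + h[c]", "g_pfk",
       "glycolysis"),
    # parallel GAP oxidation branches
    rx("GAPDH", "gap[c] + nad[c] + pi[c] => bpg[c] + nadh[c] + h[c]",
       "g_gapdh", "glycolysis"),
    rx("PGK", "bpg[c] + adp[c] => pg3[c] + atp[c]", "g_pgk", "glycolysis"),
    rx("PGK_GDP", "bpg[c] + gdp[c] => pg3[c] + gtp[c]", "g_pgk",
       "glycolysis"),
    rx("GOR", "gap[c] + fdox[c] + h2o[c] => pg3[c] + fdred[c] + (3) h[c]",
       "g_gor", "glycolysis"),
    # nonphosphorylating NADP-dependent GAP dehydrogenase: NADPH source
    # independent of BF-Nfn (bypasses PGK, so no ATP gain)
    rx("GAPN", "gap[c] + nadp[c] + h2o[c] => pg3[c] + nadph[c] + (2) h[c]",
       "g_gapn", "glycolysis"),
    rx("ENO", "pg3[c] => pep[c] + h2o[c]", "g_eno", "glycolysis"),
    rx("PK", "pep[c] + adp[c] + h[c] => pyr[c] + atp[c]", "g_pk",
       "glycolysis"),
    rx("PPDK", "pyr[c] + atp[c] + pi[c] <=> pep[c] + amp[c] + ppi[c] + h[c]",
       "g_ppdk", "glycolysis"),
    rx("AK", "atp[c] + amp[c] <=> (2) adp[c]", "g_ak", "energy"),
    rx("PPA", "ppi[c] + h2o[c] => (2) pi[c] + h[c]", "g_ppa", "energy"),
    # anaplerosis and the malate node (MDH shares its gene with LDH)
    rx("PEPC", "pep[c] + co2[c] + h2o[c] => oaa[c] + pi[c] + h[c]",
       "g_pepc", "anaplerosis"),
    rx("PCK", "oaa[c] + gtp[c] => pep[c] + co2[c] + gdp[c]", "g_pck",
       "anaplerosis"),
    rx("MDH", "oaa[c] + nadh[c] + h[c] <=> mal[c] + nad[c]", "g_ldh",
       "anaplerosis"),
    rx("ME", "mal[c] + nad[c] => pyr[c] + co2[c] + nadh[c]", "g_me",
       "anaplerosis"),
    # fermentation branches
    rx("LDH", "pyr[c] + nadh[c] + h[c] => lac[c] + nad[c]", "g_ldh",
       "fermentation"),
    rx("POR", "pyr[c] + coa[c] + fdox[c] => accoa[c] + co2[c] + fdred[c] + h[c]",
       "g_por", "fermentation"),
    rx("PTA", "accoa[c] + pi[c] <=> actp[c] + coa[c]", "g_pta",
       "fermentation"),
    rx("ACKA", "actp[c] + adp[c] => ac[c] + atp[c]", "g_acka",
       "fermentation"),
    rx("ALS", "(2) pyr[c] + (2) h[c] => actn[c] + (2) co2[c]", "g_als",
       "fermentation"),
    # NADPH-dependent acetoin reductase: carbon-bounded NADPH overflow sink
    rx("BDH", "actn[c] + nadph[c] + h[c] => btd[c] + nadp[c]", "g_bdh",
       "fermentation"),
    rx("BTDt", "btd[c] <=> btd[e]", NA, "transport"),
    # redox and energy conservation
    rx("MBH", sprintf("fdred[c] + (%d) h[c] => fdox[c] + h2[c] + (%d) h[e]",
                      2 + p, p), "g_mbh", "redox"),
    rx("BFH2", "fdred[c] + nadh[c] + (3) h[c] <=> (2) h2[c] + fdox[c] + nad[c]",
       "g_bfh", "redox"),
    rx("NFN", "fdred[c] + nadh[c] + (2) nadp[c] + h[c] <=> fdox[c] + nad[c] + (2) nadph[c]",
       "g_nfn", "redox"),
    rx("ATPS", sprintf("adp[c] + pi[c] + (%d) h[e] <=> atp[c] + h2o[c] + (%d) h[c]",
                       k, k - 1), "g_atps", "energy"),
    rx("ATPM", "atp[c] + h2o[c] => adp[c] + pi[c] + h[c]", NA, "energy"),
    rx("NDPK", "atp[c] + gdp[c] <=> adp[c] + gtp[c]", "g_ndpk", "energy"),
    # lumped pyrimidine branch: de novo (pyrE) and uracil salvage
    rx("PYRDN",
       "g6p[c] + oaa[c] + (2) nh4[c] + (2) nadp[c] => ump[c] + co2[c] + (2) nadph[c] + (3) h2o[c] + (2) h[c]",
       "g_pyrE", "pyrimidine"),
    rx("URASALV",
       "ura[c] + g6p[c] + (2) nadp[c] => ump[c] + co2[c] + (2) nadph[c] + (2) h[c]",
       "g_upp", "pyrimidine"),
    rx("URAt", "ura[e] <=> ura[c]", "g_uraT", "transport"),
    # transport
    rx("H2Ot", "h2o[e] <=> h2o[c]", NA, "transport"),
    rx("CO2t", "co2[c] <=> co2[e]", NA, "transport"),
    rx("H2t", "h2[c] <=> h2[e]", NA, "transport"),
    rx("ETOHt", "etoh[c] <=> etoh[e]", NA, "transport"),
    rx("ACTNt", "actn[c] <=> actn[e]", NA, "transport"),
    rx("NH4t", "nh4[e] <=> nh4[c]", NA, "transport"),
    rx("PIt", "pi[e] <=> pi[c]", NA, "transport"),
    rx("ACt", "ac[c] + h[c] <=> ac[e] + h[e]", "g_acT", "transport"),
    rx("LACt", "lac[c] + h[c] <=> lac[e] + h[e]", "g_lacT", "transport"),
    rx("PYRt", "pyr[c] + h[c] <=> pyr[e] + h[e]", "g_pyrT", "transport"),
    # biomass: precursors + ATP + NADPH per unit biomass (pseudo-reaction,
    # excluded from balance checks)
    reaction("BIOMASS", equation = sprintf(
      paste0("(%s) g6p[c] + (%s) pep[c] + (%s) pyr[c] + (%s) accoa[c] + ",
             "(%s) oaa[c] + (%s) ump[c] + (%s) atp[c] + (%s) nadph[c] + ",
             "(%s) nadh[c] + (%s) h2o[c] => (%s) adp[c] + (%s) pi[c] + ",
             "(%s) nadp[c] + (%s) nad[c] + (%s) coa[c] + (%s) h[c]"),
      pre, pre, pre, pre, pre, pre, atp, npd, ndh, atp, atp, atp, npd,
      ndh, pre, atp + npd), kind = "biomass")
  )

  exchange_for <- c("glc", "clb", "cel", "xyl", "etoh", "ac", "lac", "pyr",
                    "actn", "btd", "h2", "co2", "h", "h2o", "pi", "nh4",
                    "ura")
  if (include_na) exchange_for <- c(exchange_for, "na")
  for (cp in exchange_for) {
    ex <- reaction(paste0("EX_", cp),
                   equation = paste0(cp, "[e] <=>"), kind = "exchange")
    ex$lb <- 0; ex$ub <- 1000          # secretion-only until a medium opens
    ex$default_lb <- 0; ex$default_ub <- 1000
    reactions <- c(reactions, list(ex))
  }

  cat_entries <- knockin_catalog(ions_per_fd = options$ions_per_fd)
  wanted <- c(ADHE = options$adhe, RNF_NA = options$rnf_na,
              RNF_H = options$rnf_h, MRP = options$mrp,
              SH1 = options$sh1, SH2 = options$sh2)
  for (nm in names(wanted)) {
    if (!wanted[[nm]]) next
    ki <- cat_entries[[nm]]$reaction
    attr(ki, "compounds") <- NULL      # toy catalog already has the species
    reactions <- c(reactions, list(ki))
  }

  mdl <- new_model(compounds, reactions, biomass_id = "BIOMASS",
                   default_bound = 1000, name = "cbes_core")
  if (options$bfh2ase_mode == "forward_only") {
    mdl$reactions[["BFH2"]]$lb <- 0
    mdl$reactions[["BFH2"]]$default_lb <- 0
  }
  attr(mdl, "toy_options") <- options
  mdl
}

#' Default growth medium for the synthetic model
#'
#' Opens uptake for one carbon substrate plus water, phosphate, ammonium
#' and (optionally) uracil; every other exchange stays secretion-only.
#'
#' @param substrate `"glucose"`, `"cellobiose"` or `"cellulose"`.
#' @param uptake substrate uptake bound (mM-equivalent flux units).
#' @param uracil uracil uptake bound (0 disables; needed for viable
#'   pyrE-deletion strains relying on salvage).
#' @return a `cb_medium`.
#' @export
toy_medium <- function(substrate = "glucose", uptake = 25, uracil = 0) {
  ex <- switch(substrate, glucose = "EX_glc", cellobiose = "EX_clb",
               cellulose = "EX_cel",
               stop("unknown substrate: ", substrate))
  rxn <- c(ex, "EX_h2o", "EX_pi", "EX_nh4")
  lower <- c(-uptake, -1000, -1000, -1000)
  upper <- c(1000, 1000, 1000, 1000)
  if (uracil > 0) {
    rxn <- c(rxn, "EX_ura"); lower <- c(lower, -uracil); upper <- c(upper, 1000)
  }
  medium_spec(rxn, lower, upper)
}

#' Convert a cellulose load to glucose-equivalent uptake
#'
#' Cellulose is modeled per anhydroglucose unit (molar mass 162 g/mol), so
#' a load in g/liter maps to mM glucose equivalents as `load / 162 * 1000`.
#'
#' @param g_per_liter cellulose load in g/liter.
#' @param solubilized_fraction fraction of the load actually solubilized
#'   and available for uptake (default 1).
#' @return uptake bound in mM anhydroglucose equivalents.
#' @export
cellulose_uptake_mM <- function(g_per_liter, solubilized_fraction = 1) {
  stopifnot(g_per_liter >= 0, solubilized_fraction >= 0,
            solubilized_fraction <= 1)
  g_per_liter * solubilized_fraction / 162 * 1000
}

## ---- randomized LP fixtures ------------------------------------------------

#' Random small network with a closed-form optimum
#'
#' Generates chain or parallel-branch uptake->sink networks whose maximum
#' sink flux is computable from bound arithmetic, for use as LP test
#' oracles. The generator restores the caller's RNG state.
#'
#' @param seed integer seed.
#' @param n_reactions maximum number of reactions (>= 3, <= 8).
#' @return list with `model`, `objective` (reaction id to maximize) and
#'   `optimum` (the closed-form maximum).
#' @export
random_lp_fixture <- function(seed, n_reactions = 6) {
  stopifnot(n_reactions >= 3, n_reactions <= 8)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  type <- sample(c("chain", "branch"), 1)
  uptake <- sample(1:10, 1)
  mk_cpd <- function(ids, comp) do.call(rbind, lapply(ids, function(i)
    compound(i, compartment = comp)))
  if (type == "chain") {
    k <- min(n_reactions - 2L, sample(1:4, 1))   # internal chain length
    caps <- sample(1:12, k, replace = TRUE)
    ids <- paste0("m", seq_len(k + 1))
    compounds <- rbind(mk_cpd(ids[1], "e"), mk_cpd(ids[-1], "c"),
                       mk_cpd("out", "e"))
    reactions <- list()
    reactions[[1]] <- reaction("EX_in", stoich = stats::setNames(-1, cpd_key(ids[1], "e")),
                               lb = -uptake, ub = 0)
    for (i in seq_len(k)) {
      from <- if (i == 1) cpd_key(ids[1], "e") else cpd_key(ids[i], "c")
      to <- cpd_key(ids[i + 1], "c")
      reactions[[i + 1]] <- reaction(paste0("R", i),
                                     stoich = stats::setNames(c(-1, 1), c(from, to)),
                                     lb = 0, ub = caps[i])
    }
    reactions <- c(reactions, list(
      reaction("Rout", stoich = stats::setNames(c(-1, 1),
               c(cpd_key(ids[k + 1], "c"), cpd_key("out", "e"))),
               lb = 0, ub = 1000),
      reaction("EX_out", stoich = stats::setNames(-1, cpd_key("out", "e")),
               lb = 0, ub = 1000)))
    optimum <- min(uptake, caps)
  } else {
    nb <- sample(2:3, 1)
    caps <- sample(1:8, nb, replace = TRUE)
    sink_cap <- sample(2:15, 1)
    compounds <- rbind(mk_cpd("a", "e"), mk_cpd(c("a", "b"), "c"),
                       mk_cpd("out", "e"))
    reactions <- list(
      reaction("EX_in", stoich = stats::setNames(-1, "a[e]"),
               lb = -uptake, ub = 0),
      reaction("Tin", stoich = c("a[e]" = -1, "a[c]" = 1), lb = 0, ub = 1000))
    for (i in seq_len(nb))
      reactions <- c(reactions, list(
        reaction(paste0("B", i), stoich = c("a[c]" = -1, "b[c]" = 1),
                 lb = 0, ub = caps[i])))
    reactions <- c(reactions, list(
      reaction("Rout", stoich = c("b[c]" = -1, "out[e]" = 1),
               lb = 0, ub = sink_cap),
      reaction("EX_out", stoich = c("out[e]" = -1), lb = 0, ub = 1000)))
    optimum <- min(uptake, sum(caps), sink_cap)
  }
  mdl <- new_model(compounds, reactions, biomass_id = "EX_out",
                   name = paste0("fixture_", seed))
  list(model = mdl, objective = "EX_out", optimum = optimum)
}
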