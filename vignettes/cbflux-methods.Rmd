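---
title: "Constraint-based modeling of C. bescii core metabolism: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based modeling of C. bescii core metabolism: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbflux)
```

## The modeling framework

`cbflux` works with stoichiometric models of metabolism at steady state.
A model is a catalog of compartmentalized compounds, a catalog of
reactions with signed stoichiometric coefficients and flux bounds
(mmol gDW^-1 h^-1 by convention), a biomass pseudo-reaction, and boolean
gene associations linking reactions to locus tags. The feasible flux
states are $\{v : S v = 0,\ lb \le v \le ub\}$ where $S$ is the
stoichiometric matrix. On top of that polytope the package provides

* **FBA** (`fba()`): maximize or minimize one reaction's flux by linear
  programming;
* **FVA** (`fva()`): per-reaction flux minima/maxima subject to the
  objective holding at least a fraction $\gamma$ of its optimum;
* **MOMA** (`moma()`): predict a mutant's fluxes as the Euclidean
  projection of a reference (wild-type) flux vector onto the mutant's
  polytope, the usual model for the short-term response of a cell that
  has not re-optimized its regulation after a knockout. An L1 variant is
  available via `norm = "l1"`.

Media are sets of exchange-reaction bounds (`medium_spec()`,
`read_medium()`); the sign convention is that a negative lower bound on
an exchange permits uptake. Exchanges not listed in a medium are
secretion-only. Strain edits — gene deletions, reaction deletions,
knock-in insertions and directionality overrides — are declarative
`new_design()` objects applied with `apply_design()`. Deletions zero a
reaction's bounds rather than removing it, so FVA/MOMA tables keep a
stable reaction index across strains.

## The linear programming core

No LP solver package is assumed; the package carries its own dense
two-phase primal simplex with native variable bounds (`solve_lp()`),
refactorizing the basis inverse periodically and switching to Bland's
rule after runs of degenerate pivots. Two properties of the intended
workload make this appropriate: problems are small (tens of reactions)
and are solved many thousands of times (pruning searches, variability
sweeps), so a dependency-free, deterministic solver with warm
tolerances is worth more than raw speed. Correctness is audited against
an independent brute-force oracle, `enumerate_lp_optimum()`, which
enumerates candidate vertices of the polytope; the test suite and the
acceptance script check agreement on 200 seeded networks. Equality
feasibility is enforced at $10^{-9}$ and flux comparisons are made at
$10^{-6}$; objective constraints that encode "the maximum" use the
fraction 0.9999 to absorb solver tolerance. Only objective values are
contractually reproducible: flux vectors of degenerate optima are
reported but asserted only through FVA envelopes.

MOMA's quadratic program runs through `quadprog` behind an outer
active-set loop: only currently violated bounds are handed to the dense
QP solver, which keeps the problem small and avoids the numerical
failures `solve.QP` exhibits when given hundreds of redundant box
constraints. Feasibility of the mutant polytope is established by the
LP core before the QP is attempted, so `status = "infeasible"` is an
LP-certified verdict rather than a QP error code.

Stoichiometric coefficients are stored as doubles. Every coefficient
the model dialect produces is a small integer or a small-denominator
fraction, for which double arithmetic is exact; the balance checks
therefore compare totals at $10^{-9}$ rather than carrying an exact
rational type. Compound identity is the (id, compartment) pair — the
same chemical species may exist in the cytosol (`c`) and extracellular
(`e`) compartments, which is what transport chemistry requires.
Translocated ions are modeled as extracellular species, since the
membrane reactions only distinguish inside from outside.

## Model quality checks

Four checks mirror the standard quality axes of a curated
reconstruction (`consistency_report()`):

1. **Stoichiometric consistency**: an LP searches for a strictly
   positive mass per compound conserved by every non-boundary reaction;
   the reported percentage is the fraction of compounds that can carry
   such a mass. Exchange, biomass and sink reactions are excluded.
2. **Formula balance**: per-element totals of each non-boundary
   reaction, with reactions excluded (and listed with a reason) when a
   compound's formula is missing, unparsable, or contains a generic
   `R`/`X` group.
3. **Charge balance**: the same for net charge.
4. **Connectivity**: compounds referenced by no reaction.

Excluded reactions are never reported as imbalanced — the two lists are
disjoint by construction. Two audit operations extend the checks to
flux solutions: `audit_carbon_balance()` and `audit_electron_balance()`
verify that carbon and degree-of-reduction
($\gamma = 4C + H - 2O - 3N + 5P + 6S - \text{charge}$) are conserved
across the exchanges and the biomass drain of any optimal solution.

## The synthetic core network

`build_toy()` generates a fully specified core-metabolism model of
*Caldicellulosiruptor bescii* — a cellulolytic, extremely thermophilic
anaerobe whose central carbon metabolism has two unusual features that
drive everything in this package: a ferredoxin-dependent glycolytic
branch (GOR) running in parallel to the NAD-dependent GAPDH/PGK branch,
and a three-way interconversion of the Fd_red/NADH/NADPH pools by a
proton-pumping membrane hydrogenase (MBH), an electron-bifurcating
hydrogenase (BF-H2ase) and an electron-bifurcating transhydrogenase
(BF-Nfn). The network is deliberately *not* a reduction of any published
reconstruction: it is an independent didactic model (~57 compounds, ~67
reactions) whose stoichiometry is fully documented in code, so every
yield the package reports can be checked by hand. Every internal
reaction is element- and charge-balanced (ferredoxin is carried as an
Fe8S8 two-electron couple, so POR and GOR transfer one Fd per
turnover), which is why the default network scores 100% on all four
quality checks.

The hand-checkable electron bookkeeping per glucose is: upper
glycolysis costs 2 ATP and yields 2 GAP; each GAP oxidation yields
either 1 NADH (GAPDH, with 1 ATP from PGK), 1 Fd_red (GOR, no ATP) or 1
NADPH (GAPN); POR converts each pyruvate to acetyl-CoA plus CO2 and 1
Fd_red; AdhE consumes 2 NADH per ethanol. Hence:

* with a **reversible BF-H2ase**, the H2-recycling loop (MBH producing
  H2 and pumping protons, BF-H2ase consuming that H2 to reduce NAD)
  converts the 2 Fd_red from POR into 2 NADH; with the 2 NADH from
  GAPDH this supports exactly **2 ethanol per glucose**, and the
  MBH : BF-H2ase(reverse) flux ratio settles at exactly **2:1**
  (H2 balance $m = 2b$, Fd balance $2 + b = 2b$);
* with BF-H2ase constrained **H2-producing only** and no other
  Fd_red-to-NADH route, only GAPDH's 2 NADH remain: **1 ethanol per
  glucose**, the remaining acetyl-CoA leaving as acetate and Fd_red as
  H2;
* **Rnf_H**, **Rnf_Na + Mrp**, **SH1** (via MBH, SH1 and reverse
  BF-Nfn) and **SH2** (via MBH or BF-H2ase) each restore the 2 mol/mol
  ceiling under a H2-producing-only BF-H2ase;
* without AdhE, or without POR, maximum ethanol is 0; deleting MBH,
  BF-H2ase and BF-Nfn together leaves POR's Fd_red without any sink, so
  biomass is infeasible (Rnf_Na alone cannot run: with no sodium return
  path its flux is structurally zero — the reason the Mrp antiporter or
  the proton-translocating Rnf_H is needed).

These derivations are asserted verbatim in the test suite and
recomputed by `scripts/acceptance.R`.

### Generator parameters

* Ion translocation stoichiometries are not published for this
  organism, so they are configuration: MBH pumps 1 H+ per H2
  (`h_pumped_mbh`), ATP synthase consumes 4 extracellular protons per
  ATP of which one is chemical (`h_per_atp`), Rnf translocates 1 ion
  per Fd_red (`ions_per_fd`). Defaults are the smallest integers that
  balance; the qualitative yield results are asserted robust across
  `h_per_atp` 3–4 and `h_pumped_mbh` 1–2.
* Biomass coefficients default to 30 ATP, 6 NADPH, 4 NADH and 1 of each
  precursor (G6P, PEP, pyruvate, acetyl-CoA, OAA, UMP) per unit
  biomass. The NADH term reflects that anabolism is a net consumer of
  reduced pyridine cofactors; without it, growth in the model is
  obligately hydrogenase-dependent and hydrogenase-free mutants are
  spuriously lethal. Qualitative results are asserted robust across a
  ±50% sweep of these coefficients.
* The pyrE locus is carried by a lumped de novo pyrimidine reaction;
  a uracil-salvage route keeps ΔpyrE strains viable when the medium
  supplies uracil, matching the use of uracil auxotrophy as a selection
  background.
* GAPN (nonphosphorylating NADP-dependent GAP dehydrogenase) provides
  an Fd-independent NADPH supply, and an NADPH-consuming acetoin
  reductase (BDH, secreting 2,3-butanediol) provides a carbon-bounded
  NADPH overflow valve. Both are chosen so that **no** composition of
  reactions converts NADPH (or Fd_red) into NADH for free — that
  direction is what the engineered Rnf/SH modules exist to supply, and
  its absence is what makes the 1.0 mol/mol forward-only ceiling exact.
* Cellulose is modeled per anhydroglucose unit (162 g/mol), so a load
  in g/liter converts to mM glucose equivalents with
  `cellulose_uptake_mM()`; 11.8 g/liter is 72.8 mM. A batch biomass
  yield (g DW/liter) is imposed as a minimum biomass flux on the
  substrate-consumed basis; the mapping factor is deliberately
  config-level, since a batch yield has no unique steady-state
  counterpart.

### What the toy does and does not show

Passing tests on the synthetic network demonstrate that the algorithms
are implemented correctly and that the qualitative redox logic of the
organism is captured. They do not reproduce the printed flux values of
the full 714-reaction reconstruction: those depend on unpublished ion
stoichiometries and on pathways the toy omits. Three specific
divergences are known and deliberate:

* a Δldh strain (the gene also carries MDH activity) shows *equal*
  rather than strictly reduced maximum ethanol in the toy: any malate
  shunt that made MDH a net NADH source would, combined with BF-Nfn,
  create a free Fd_red-to-NADH cycle and destroy the exact yield
  ceilings;
* POR is core-essential at every ethanol level in the toy because it
  is the only acetyl-CoA source, so only AdhE (not POR) moves from the
  conditional to the core set as the ethanol constraint rises;
* acetate overflow cannot rise in an MBH deletion (every acetyl-CoA
  produces an Fd_red that has no cheap sink there), so the collapse of
  proton-motive ATP synthesis is asserted via the ATP synthase flux
  rather than an acetate kinase increase; carbon overflow is
  redirected to pyruvate export instead.

## Minimal-network analysis

`find_minimal_network()` prunes reactions in a seeded uniform random
order: each deletable reaction (anything that is not an exchange,
biomass, sink, or explicitly protected) is tentatively bound to zero
and stays blocked iff the constraints — a biomass floor and an ethanol
level of 0, 50% or 99.99% of the maximum — remain feasible. The result
is 1-minimal by construction and is audited (`audit_minimal_network()`)
by re-solving. Replicated searches (`run_sparse_study()`, seeds derived
from a master seed by increment and recorded in the manifest) are
classified by occurrence into core-essential (all networks),
conditionally essential (some) and nonessential (none); convergence is
declared when all three set sizes are unchanged over a sliding window,
by default 10% of the replicate budget — the convergence plots this
mirrors show stability long before the budget, and a 10% window makes
"unchanged" mean a substantial number of fresh random orders, not a
lucky streak. The ethanol level 0 pins the product flux to zero
(a true no-production condition) rather than merely dropping the lower
bound. An exhaustive oracle, `enumerate_minimal_networks()`, checks
every subset of the deletable universe on small fixtures; the
acceptance suite verifies that a 500-replicate random sample classifies
a 12-reaction two-pathway fixture identically to full enumeration.

## Strain design evaluation

`knockin_catalog()` carries balanced reaction definitions for AdhE,
Rnf_Na, Rnf_H, Mrp, SH1 and SH2, each annotated with its source
organism. `evaluate_designs()` applies a named list of designs to a
base strain under one medium and one BF-H2ase directionality mode and
tabulates maximum ethanol (in mM on the substrate-consumed basis, and
as mol per mol glucose-equivalent, i.e. product flux divided by carbon
uptake/6). `production_envelope()` steps the product lower bound from 0
to the maximum (100 steps by default) and records flux variability of a
watch list of central reactions, so step 0 reproduces the unconstrained
variability. Monotonicity (knockout rows never beat their parent) and
the carbon/electron audits run over every row in the tests.

## Validation stage

`growth_matrix()` predicts growth/no-growth per substrate by opening
one exchange at a time over a basal medium (growth tolerance $10^{-6}$,
the LP noise floor; substrates with no exchange reaction are flagged
rather than silently failing). `calibrate_product_ratios()` pins the
carbon-weighted secretion fluxes of measured products to their measured
relative fractions via extra equality rows in the LP — a calibration
that can only lower the biomass optimum and is removed by
`uncalibrate()`. `cells_to_biomass()` (8.2e-10 mg/cell) and
`fit_protein_dryweight()` (OLS) provide the unit conversions between
measured cell densities, protein and dry weight.

## Problem sizes and reproducibility

The shipped analyses use 150 pruning replicates per ethanol level with
a convergence window of 15, 50 envelope steps, and 200 LP oracle
fixtures; the classification converges around iteration 30 on the
synthetic network, so the replicate budget is comfortable. All
randomness flows from explicit seeds (per-replicate seeds are master
seed + increment, recorded in each run manifest), and repeated runs are
bit-identical; `analysis/01_model_checks.R` through
`analysis/05_envelopes.R` re-create every table under `results/` from
scratch.

## Known limitations

Thermodynamic (ΔG-based) directionality, enzyme kinetics and
regulation are out of scope; directionality is encoded in bounds.
Degenerate optimal flux vectors are solver-dependent; assert on
objective values or FVA ranges. The simplex is dense and intended for
networks up to a few hundred reactions; a genome-scale model with
thousands of reactions would want a sparse factorized solver behind
the same `solve_lp()` interface. Parsing the full published
reconstruction requires a one-step export of its spreadsheet
supplement to TSV (`read_table_model()`); the binary workbook itself is
not parsed.
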