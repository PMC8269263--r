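#!/usr/bin/env Rscript
# Stage 2: validation-style analyses on the synthetic network — the
# growth/no-growth phenotype matrix over the carbon substrates, the
# product-ratio-calibrated wild-type state, the ldh-knockout MOMA
# prediction, and the unit-conversion fits.
#
# Finds: phenotype predictions match the synthetic reference on all five
# substrates (dextran is flagged as lacking an uptake pathway); the Δldh
# MOMA solution abolishes lactate secretion and redirects carbon to
# acetate and pyruvate.

library(cbflux)

dir.create("results", showWarnings = FALSE)
extdata <- system.file("extdata", package = "cbflux")

wt <- build_toy()
med <- read_medium(file.path(extdata, "medium_dg25_glucose.tsv"))

## growth phenotypes ---------------------------------------------------------
ph <- read.delim(file.path(extdata, "growth_phenotypes_synthetic.tsv"),
                 na.strings = "NA")
subs <- stats::setNames(ph$exchange, ph$substrate)
basal <- medium_spec(c("EX_h2o", "EX_pi", "EX_nh4"), rep(-1000, 3),
                     rep(1000, 3))
gm <- growth_matrix(wt, subs, basal, uptake = 10,
                    experimental = stats::setNames(ph$observed_growth,
                                                   ph$substrate))
print(gm)
write.table(gm, "results/growth_matrix.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sum(gm$consistent), "of", nrow(gm), "phenotypes consistent\n")

## calibrated wild type and the ldh knockout (MOMA) --------------------------
ratios <- read.delim(file.path(extdata, "product_ratios_synthetic.tsv"))
cal <- calibrate_product_ratios(
  wt, stats::setNames(ratios$carbon_fraction, ratios$exchange),
  products = c(ratios$exchange, "EX_etoh", "EX_actn", "EX_btd"))
ref <- fba(cal, medium = med)
dl <- moma(apply_design(wt, new_design(deleted_genes = "g_ldh")),
           ref$fluxes, medium = med)
cmp <- data.frame(
  quantity = c("biomass", "lactate", "acetate", "pyruvate", "moma_distance"),
  wild_type = c(ref$objective_value, ref$fluxes[["EX_lac"]],
                ref$fluxes[["EX_ac"]], ref$fluxes[["EX_pyr"]], 0),
  ldh_knockout = c(dl$objective_value, dl$fluxes[["EX_lac"]],
                   dl$fluxes[["EX_ac"]], dl$fluxes[["EX_pyr"]],
                   dl$distance))
print(cmp, digits = 4)
write.table(cmp, "results/ldh_knockout_moma.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

## unit conversions -----------------------------------------------------------
pd <- read.delim(file.path(extdata, "protein_dryweight_synthetic.tsv"))
fit <- fit_protein_dryweight(pd$protein_g_per_l, pd$dryweight_g_per_l)
cat(sprintf("protein->dry-weight fit: slope %.4f, intercept %.4f, R2 %.4f\n",
            fit$slope, fit$intercept, fit$r_squared))
cat(sprintf("1e12 cells/liter = %.3f g DW/liter\n", cells_to_biomass(1e12)))
write.table(data.frame(slope = fit$slope, intercept = fit$intercept,
                       r_squared = fit$r_squared),
            "results/protein_dryweight_fit.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
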