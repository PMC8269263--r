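# Model validation stage: growth/no-growth phenotype matrix, unit
# conversions between cell counts / protein / dry weight, and calibration
# of secreted-product ratios against measurements.

#' Growth/no-growth phenotype matrix
#'
#' For each substrate the basal medium is applied with the corresponding
#' exchange opened for uptake; predicted growth is a biomass flux above the
#' growth tolerance. Substrates lacking an exchange reaction are recorded
#' as predicted no-growth with `missing_exchange = TRUE`.
#'
#' @param model a `cb_model`.
#' @param substrates named character vector mapping substrate name to its
#'   exchange reaction id (use `NA` for substrates without an exchange).
#' @param basal_medium `cb_medium` with everything except the carbon
#'   source (the basal medium's own carbon entries, if any, are kept).
#' @param uptake uptake bound opened for the tested substrate.
#' @param experimental optional named logical vector of observed growth.
#' @param growth_tol biomass flux above which growth is called (default
#'   1e-6, the LP noise floor).
#' @return data frame with one row per substrate: `substrate`, `exchange`,
#'   `predicted`, `missing_exchange`, and when experimental data are given
#'   `experimental` and `consistent`.
#' @export
growth_matrix <- function(model, substrates, basal_medium, uptake = 10,
                          experimental = NULL, growth_tol = 1e-6) {
  stopifnot(!is.null(names(substrates)))
  rows <- lapply(names(substrates), function(nm) {
    ex <- substrates[[nm]]
    if (is.na(ex) || !ex %in% names(model$reactions)) {
      return(data.frame(substrate = nm, exchange = NA_character_,
                        predicted = FALSE, missing_exchange = TRUE))
    }
    med <- basal_medium
    if (ex %in% med$reaction) {
      med$lower[med$reaction == ex] <- -uptake
    } else {
      med <- medium_spec(c(med$reaction, ex), c(med$lower, -uptake),
                         c(med$upper, 1000))
    }
    sol <- fba(model, medium = med)
    grew <- sol$status == "optimal" && sol$objective_value > growth_tol
    data.frame(substrate = nm, exchange = ex, predicted = grew,
               missing_exchange = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(experimental)) {
    out$experimental <- as.logical(experimental[out$substrate])
    out$consistent <- out$experimental == out$predicted
  }
  rownames(out) <- NULL
  out
}

#' Convert cell counts to dry weight
#'
#' Uses the estimated per-cell dry weight of 8.2e-10 mg/cell.
#'
#' @param cell_count cells per liter (vectorized).
#' @param mg_per_cell per-cell dry weight in mg (default 8.2e-10).
#' @return g dry weight per liter.
#' @export
cells_to_biomass <- function(cell_count, mg_per_cell = 8.2e-10) {
  if (any(cell_count < 0)) stop("cell count must be non-negative")
  cell_count * mg_per_cell * 1e-3
}

#' Fit the protein-to-dry-weight conversion line
#'
#' Ordinary least squares fit of dry weight on protein concentration; the
#' returned `convert` closure applies the fitted line to new protein
#' measurements.
#'
#' @param protein protein concentrations (g/liter).
#' @param dryweight matching cell dry weights (g/liter).
#' @return list with `slope`, `intercept`, `r_squared`, `fitted`, `convert`.
#' @export
fit_protein_dryweight <- function(protein, dryweight) {
  stopifnot(length(protein) == length(dryweight))
  if (length(protein) < 2L)
    stop("at least two calibration pairs are required")
  fit <- stats::lm(dryweight ~ protein)
  co <- stats::coef(fit)
  # summary() warns on an exactly collinear calibration set; the R^2 of 1
  # is still the right answer there
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(slope = unname(co["protein"]), intercept = unname(co["(Intercept)"]),
       r_squared = r2,
       fitted = unname(stats::fitted(fit)),
       convert = function(p) unname(co["(Intercept)"] + co["protein"] * p))
}

#' Calibrate secreted-product flux ratios
#'
#' Adds linear coupling constraints fixing the carbon-weighted fluxes of
#' secreted products to measured relative fractions: products listed in
#' `products` but absent from `ratios` (or with fraction 0) are pinned to
#' zero. The constraints live in `model$extra_constraints` and are honored
#' by [fba()], [fva()] and [moma()]; [uncalibrate()] removes them.
#'
#' @param model a `cb_model`.
#' @param ratios named numeric vector of relative carbon fractions (must
#'   sum to at most 1), named by product exchange id.
#' @param products full set of competing product exchanges considered; when
#'   the fractions sum to 1, members not named in `ratios` are pinned to 0.
#'   Defaults to `names(ratios)`.
#' @return the calibrated model.
#' @export
calibrate_product_ratios <- function(model, ratios,
                                     products = names(ratios)) {
  if (is.null(names(ratios)) || any(!nzchar(names(ratios))))
    stop("ratios must be named by product exchange id")
  if (any(ratios < 0)) stop("ratios must be non-negative")
  if (sum(ratios) > 1 + 1e-9)
    stop("ratios sum to more than 1 of secreted carbon: ", sum(ratios))
  products <- union(products, names(ratios))
  unknown <- setdiff(products, names(model$reactions))
  if (length(unknown))
    stop("unknown product exchange(s): ", paste(unknown, collapse = ", "))
  cw <- element_count(model, "C")
  carbon_of <- vapply(products, function(ex) {
    st <- model$reactions[[ex]]$stoich
    w <- cw[names(st)]
    if (is.na(w)) stop("product compound lacks a formula: ", names(st))
    abs(st) * w
  }, 0)
  f <- stats::setNames(rep(0, length(products)), products)
  f[names(ratios)] <- ratios
  anchor <- products[which(f > 0)[1]]
  if (is.na(anchor)) stop("all ratios are zero")
  cons <- list()
  for (pxx in products) {
    if (pxx == anchor) next
    if (f[[pxx]] == 0 && sum(f) >= 1 - 1e-9) {
      cons <- c(cons, list(list(
        coef = stats::setNames(1, pxx), rhs = 0,
        tag = paste0("ratio_zero:", pxx))))
    } else if (f[[pxx]] > 0) {
      cons <- c(cons, list(list(
        coef = stats::setNames(
          c(carbon_of[[pxx]] * f[[anchor]], -carbon_of[[anchor]] * f[[pxx]]),
          c(pxx, anchor)),
        rhs = 0, tag = paste0("ratio:", pxx, ":", anchor))))
    }
  }
  model$extra_constraints <- c(model$extra_constraints, cons)
  model
}

#' Remove all extra constraints from a model
#' @param model a `cb_model`.
#' @export
uncalibrate <- function(model) {
  model$extra_constraints <- list()
  model
}
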