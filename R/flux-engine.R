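# LP/QP core: flux balance analysis, flux variability analysis, MOMA, and
# the four model-quality checks (stoichiometric consistency, formula and
# charge balance, metabolite connectivity).

# assemble the steady-state LP of a model: S v = 0 plus any extra equality
# constraint rows (e.g. product-ratio calibration)
build_lp_problem <- function(model) {
  S <- as.matrix(stoichiometric_matrix(model))
  rids <- colnames(S)
  lb <- vapply(rids, function(id) model$reactions[[id]]$lb, 0)
  ub <- vapply(rids, function(id) model$reactions[[id]]$ub, 0)
  A <- S
  b <- rep(0, nrow(S))
  if (length(model$extra_constraints)) {
    for (ec in model$extra_constraints) {
      row <- stats::setNames(rep(0, length(rids)), rids)
      unknown <- setdiff(names(ec$coef), rids)
      if (length(unknown))
        stop("extra constraint references unknown reaction(s): ",
             paste(unknown, collapse = ", "))
      row[names(ec$coef)] <- ec$coef
      A <- rbind(A, row)
      b <- c(b, ec$rhs)
    }
  }
  list(A = A, b = b, lb = lb, ub = ub, reactions = rids)
}

#' Flux balance analysis
#'
#' Maximizes (or minimizes) the flux of an objective reaction subject to
#' steady state (`S v = 0`) and flux bounds. The objective value of the LP
#' is unique up to solver tolerance even when the flux vector is degenerate;
#' only the objective value is contractually reproducible.
#'
#' @param model a `cb_model`.
#' @param objective reaction id to optimize (default: the biomass reaction).
#' @param medium optional `cb_medium`, applied before solving.
#' @param maximize logical.
#' @return a `cb_flux_solution`: list with `status`, `objective_value` and
#'   `fluxes` (named by reaction id).
#' @export
fba <- function(model, objective = model$biomass_id, medium = NULL,
                maximize = TRUE) {
  model <- apply_medium(model, medium)
  if (!objective %in% names(model$reactions))
    stop("objective reaction not in model: ", objective)
  lp <- build_lp_problem(model)
  obj <- as.numeric(lp$reactions == objective)
  res <- solve_lp(lp$A, lp$b, obj, lp$lb, lp$ub, maximize = maximize)
  sol <- list(status = res$status,
              objective_value = if (res$status == "optimal") res$objective
                                else NA_real_,
              objective = objective,
              fluxes = stats::setNames(res$x, lp$reactions))
  class(sol) <- "cb_flux_solution"
  sol
}

#' @export
print.cb_flux_solution <- function(x, ...) {
  cat("<flux solution> status:", x$status, " objective (", x$objective,
      "):", signif(x$objective_value, 8), "\n")
  invisible(x)
}

#' Flux variability analysis
#'
#' For each reaction, minimizes and maximizes its flux subject to steady
#' state, bounds, and the constraint that the objective reaction achieves at
#' least `fraction` of its FBA optimum.
#'
#' @inheritParams fba
#' @param fraction objective fraction gamma in (0, 1].
#' @param reactions reaction ids to scan (default: all).
#' @return data frame with columns `reaction`, `min_flux`, `max_flux`, plus
#'   attribute `optimum` (the FBA optimum used).
#' @export
fva <- function(model, objective = model$biomass_id, fraction = 1,
                medium = NULL, reactions = NULL) {
  stopifnot(fraction > 0, fraction <= 1)
  model <- apply_medium(model, medium)
  base <- fba(model, objective)
  if (base$status != "optimal")
    stop("FVA base problem is ", base$status)
  opt <- base$objective_value
  lp <- build_lp_problem(model)
  n <- length(lp$reactions)
  # objective >= fraction * optimum, encoded with a one-sided slack variable
  orow <- as.numeric(lp$reactions == objective)
  A <- rbind(cbind(lp$A, 0), c(orow, -1))
  b <- c(lp$b, 0)
  lb <- c(lp$lb, fraction * opt)
  ub <- c(lp$ub, Inf)
  if (is.null(reactions)) reactions <- lp$reactions
  bad <- setdiff(reactions, lp$reactions)
  if (length(bad)) stop("unknown reaction(s): ", paste(bad, collapse = ", "))
  out <- data.frame(reaction = reactions,
                    min_flux = NA_real_, max_flux = NA_real_)
  for (i in seq_along(reactions)) {
    cobj <- c(as.numeric(lp$reactions == reactions[i]), 0)
    lo <- solve_lp(A, b, cobj, lb, ub, maximize = FALSE)
    hi <- solve_lp(A, b, cobj, lb, ub, maximize = TRUE)
    out$min_flux[i] <- lo$objective
    out$max_flux[i] <- hi$objective
  }
  attr(out, "optimum") <- opt
  out
}

#' Minimization of metabolic adjustment (MOMA)
#'
#' Predicts the flux state of an edited (mutant) model as the feasible flux
#' vector closest to a reference (wild-type) distribution: by default the
#' Euclidean projection (quadratic program via `quadprog`), optionally the
#' L1-nearest point (linear program) with `norm = "l1"`.
#'
#' @param edited the edited `cb_model`.
#' @param reference_fluxes named flux vector from a wild-type FBA solution
#'   on the same reaction index.
#' @param medium optional `cb_medium` applied to the edited model.
#' @param norm `"l2"` (default) or `"l1"`.
#' @return a `cb_flux_solution` whose `objective_value` is the achieved
#'   biomass flux, with an extra `distance` element.
#' @export
moma <- function(edited, reference_fluxes, medium = NULL, norm = c("l2", "l1")) {
  norm <- match.arg(norm)
  edited <- apply_medium(edited, medium)
  lp <- build_lp_problem(edited)
  if (is.null(names(reference_fluxes)))
    stop("reference_fluxes must be named by reaction id")
  missing <- setdiff(lp$reactions, names(reference_fluxes))
  if (length(missing))
    stop("reference fluxes missing for: ", paste(missing, collapse = ", "))
  vref <- reference_fluxes[lp$reactions]
  n <- length(lp$reactions)

  if (norm == "l2") {
    # confirm the edited polytope is nonempty before touching the QP
    feas <- solve_lp(lp$A, lp$b, rep(0, n), lp$lb, lp$ub)
    if (feas$status != "optimal") {
      sol <- list(status = "infeasible", objective_value = NA_real_,
                  objective = edited$biomass_id,
                  fluxes = stats::setNames(rep(NA_real_, n), lp$reactions),
                  distance = NA_real_)
      class(sol) <- "cb_flux_solution"
      return(sol)
    }
    # independent equality rows: S v = 0 (+ extras) and fixed variables
    Aeq <- lp$A
    fixed <- which(lp$lb == lp$ub)
    for (j in fixed) {
      row <- rep(0, n); row[j] <- 1
      Aeq <- rbind(Aeq, row)
    }
    beq <- c(lp$b, lp$lb[fixed])
    qrt <- qr(t(Aeq))
    keep <- qrt$pivot[seq_len(qrt$rank)]
    Aeq <- Aeq[keep, , drop = FALSE]
    beq <- beq[keep]
    # outer active-set loop: only bounds that are actually violated are
    # handed to solve.QP, which keeps the dense QP small and well scaled
    active <- integer()   # signed variable indices: +j lower, -j upper
    v <- NULL
    for (iter in 1:(2L * n + 2L)) {
      ineq <- lapply(active, function(s) {
        row <- rep(0, n); row[abs(s)] <- sign(s); row
      })
      ib <- vapply(active, function(s)
        if (s > 0) lp$lb[s] else -lp$ub[-s], 0)
      Amat <- t(rbind(Aeq, do.call(rbind, c(list(NULL), ineq))))
      qp <- tryCatch(
        quadprog::solve.QP(Dmat = diag(n), dvec = vref, Amat = Amat,
                           bvec = c(beq, ib), meq = nrow(Aeq)),
        error = function(e) NULL)
      if (is.null(qp))
        stop("MOMA quadratic program failed on a feasible model")
      v <- qp$solution
      low_viol <- which(v < lp$lb - 1e-8)
      up_viol <- which(v > lp$ub + 1e-8)
      if (!length(low_viol) && !length(up_viol)) break
      worst <- c(stats::setNames(lp$lb[low_viol] - v[low_viol], low_viol),
                 stats::setNames(v[up_viol] - lp$ub[up_viol], -as.integer(up_viol)))
      add <- as.integer(names(worst)[order(-worst)][seq_len(min(5L, length(worst)))])
      active <- union(active, add)
    }
    v <- stats::setNames(pmin(pmax(v, lp$lb), lp$ub), lp$reactions)
    dist <- sqrt(sum((v - vref)^2))
  } else {
    # minimize sum |v - vref|: v - p + q = vref with p, q >= 0
    A <- cbind(lp$A, matrix(0, nrow(lp$A), 2 * n))
    A <- rbind(A, cbind(diag(n), -diag(n), diag(n)))
    b <- c(lp$b, as.numeric(vref))
    lb <- c(lp$lb, rep(0, 2 * n))
    ub <- c(lp$ub, rep(Inf, 2 * n))
    obj <- c(rep(0, n), rep(1, 2 * n))
    res <- solve_lp(A, b, obj, lb, ub, maximize = FALSE)
    if (res$status != "optimal") {
      sol <- list(status = "infeasible", objective_value = NA_real_,
                  objective = edited$biomass_id,
                  fluxes = stats::setNames(rep(NA_real_, n), lp$reactions),
                  distance = NA_real_)
      class(sol) <- "cb_flux_solution"
      return(sol)
    }
    v <- stats::setNames(res$x[seq_len(n)], lp$reactions)
    dist <- sum(abs(v - vref))
  }
  sol <- list(status = "optimal",
              objective_value = unname(v[edited$biomass_id]),
              objective = edited$biomass_id, fluxes = v, distance = dist)
  class(sol) <- "cb_flux_solution"
  sol
}

## ---- model quality checks --------------------------------------------------

internal_reaction_ids <- function(model) {
  reaction_ids(model, c("cytosolic", "transmembrane", "extracellular"))
}

#' Stoichiometric consistency check
#'
#' Searches for a strictly positive mass assignment over compounds that is
#' conserved by every non-boundary reaction (exchange, biomass and sink
#' reactions are excluded): maximize the number of compounds whose mass can
#' reach 1 subject to `S_int' m = 0`, `m >= 0`. A compound that cannot carry
#' positive mass indicates mass creation/destruction in the network.
#'
#' @param model a `cb_model`.
#' @return list with `percent` (percent of compounds assignable a strictly
#'   positive mass), `inconsistent_compounds` and the mass vector `mass`.
#' @export
check_stoichiometric_consistency <- function(model) {
  S <- as.matrix(stoichiometric_matrix(model))
  int <- intersect(colnames(S), internal_reaction_ids(model))
  nc <- nrow(S)
  Sint <- S[, int, drop = FALSE]
  big <- 1e6
  # variables: m (nc), z (nc), s (nc);  S_int' m = 0;  m - z - s = 0
  A <- rbind(cbind(t(Sint), matrix(0, length(int), 2 * nc)),
             cbind(diag(nc), -diag(nc), -diag(nc)))
  b <- rep(0, length(int) + nc)
  lb <- rep(0, 3 * nc)
  ub <- c(rep(big, nc), rep(1, nc), rep(big, nc))
  obj <- c(rep(0, nc), rep(1, nc), rep(0, nc))
  res <- solve_lp(A, b, obj, lb, ub, maximize = TRUE)
  if (res$status != "optimal") stop("consistency LP failed: ", res$status)
  z <- res$x[nc + seq_len(nc)]
  consistent <- z > 1 - 1e-6
  list(percent = 100 * mean(consistent),
       inconsistent_compounds = rownames(S)[!consistent],
       mass = stats::setNames(res$x[seq_len(nc)], rownames(S)))
}

# shared exclusion logic for formula/charge checks
balance_exclusions <- function(model, need = c("formula", "charge")) {
  need <- match.arg(need)
  keys <- cpd_key(model$compounds$id, model$compounds$compartment)
  info <- model$compounds
  status <- character(nrow(info))   # "", "missing", "unparsable", "generic"
  for (i in seq_len(nrow(info))) {
    f <- info$formula[i]
    if (need == "charge" && is.na(info$charge[i])) { status[i] <- "missing"; next }
    if (is.na(f) || !nzchar(f)) {
      if (need == "formula") status[i] <- "missing"
      next
    }
    pf <- tryCatch(parse_formula(f), error = function(e) NULL)
    if (is.null(pf)) status[i] <- "unparsable"
    else if (any(names(pf) %in% c("R", "X"))) status[i] <- "generic"
  }
  stats::setNames(status, keys)
}

balance_check <- function(model, what = c("formula", "charge")) {
  what <- match.arg(what)
  status <- balance_exclusions(model, what)
  keys <- names(status)
  ckeys <- cpd_key(model$compounds$id, model$compounds$compartment)
  charge <- stats::setNames(model$compounds$charge, ckeys)
  formulas <- stats::setNames(model$compounds$formula, ckeys)
  imbalanced <- list()
  excluded <- list()
  for (id in internal_reaction_ids(model)) {
    st <- model$reactions[[id]]$stoich
    stat <- status[names(st)]
    if (any(stat != "")) {
      reason <- paste0(what, " ", stat[stat != ""][1], " for ",
                       names(st)[stat != ""][1])
      excluded[[id]] <- reason
      next
    }
    if (what == "formula") {
      tot <- numeric()
      for (k in names(st)) {
        f <- parse_formula(formulas[[k]])
        for (el in names(f)) {
          tot[el] <- (if (el %in% names(tot)) tot[el] else 0) +
            st[[k]] * f[[el]]
        }
      }
      bad <- tot[abs(tot) > 1e-9]
      if (length(bad))
        imbalanced[[id]] <- paste0(names(bad), ":", signif(bad, 6),
                                   collapse = ",")
    } else {
      delta <- sum(st * charge[names(st)])
      if (abs(delta) > 1e-9)
        imbalanced[[id]] <- as.character(signif(delta, 6))
    }
  }
  as_df <- function(lst, col) {
    if (!length(lst))
      return(stats::setNames(data.frame(character(), character(),
                                        stringsAsFactors = FALSE),
                             c("reaction", col)))
    stats::setNames(data.frame(names(lst), unlist(lst), row.names = NULL,
                               stringsAsFactors = FALSE),
                    c("reaction", col))
  }
  list(imbalanced = as_df(imbalanced, "delta"),
       excluded = as_df(excluded, "reason"))
}

#' Formula (mass) balance check
#'
#' Compares, element by element, substrate and product totals of every
#' non-boundary reaction. Reactions touching compounds whose formula is
#' missing, unparsable or contains a generic `R`/`X` group are excluded and
#' listed with the reason rather than reported as imbalanced.
#'
#' @param model a `cb_model`.
#' @return list with data frames `imbalanced` (reaction, element deltas) and
#'   `excluded` (reaction, reason).
#' @export
check_formula_balance <- function(model) balance_check(model, "formula")

#' Charge balance check
#'
#' Like [check_formula_balance()] but for the net charge of each reaction;
#' compounds lacking a charge exclude their reactions.
#'
#' @param model a `cb_model`.
#' @return list with data frames `imbalanced` and `excluded`.
#' @export
check_charge_balance <- function(model) balance_check(model, "charge")

#' Metabolite connectivity check
#'
#' @param model a `cb_model`.
#' @return list with `percent` of compounds referenced by at least one
#'   reaction and the `unconnected` compound keys.
#' @export
check_connectivity <- function(model) {
  keys <- cpd_key(model$compounds$id, model$compounds$compartment)
  used <- unique(unlist(lapply(model$reactions, function(r) names(r$stoich))))
  unconnected <- setdiff(keys, used)
  list(percent = 100 * (1 - length(unconnected) / length(keys)),
       unconnected = unconnected)
}

#' Combined model quality report
#'
#' Runs the stoichiometric consistency, formula balance, charge balance and
#' connectivity checks and assembles them into one report.
#'
#' @param model a `cb_model`.
#' @return object of class `cb_consistency_report`.
#' @export
consistency_report <- function(model) {
  sc <- check_stoichiometric_consistency(model)
  fb <- check_formula_balance(model)
  cb <- check_charge_balance(model)
  cn <- check_connectivity(model)
  excluded <- unique(rbind(fb$excluded, cb$excluded))
  rep <- list(percent_stoichiometrically_consistent = sc$percent,
              inconsistent_compounds = sc$inconsistent_compounds,
              imbalanced_formula_reactions = fb$imbalanced$reaction,
              imbalanced_charge_reactions = cb$imbalanced$reaction,
              unconnected_compounds = cn$unconnected,
              connectivity_percent = cn$percent,
              excluded_reactions = excluded)
  stopifnot(!length(intersect(excluded$reaction,
                              c(fb$imbalanced$reaction,
                                cb$imbalanced$reaction))))
  class(rep) <- "cb_consistency_report"
  rep
}

#' @export
print.cb_consistency_report <- function(x, ...) {
  cat("Stoichiometric consistency: ",
      signif(x$percent_stoichiometrically_consistent, 4), "%\n",
      "Formula-imbalanced reactions: ",
      length(x$imbalanced_formula_reactions), "\n",
      "Charge-imbalanced reactions: ",
      length(x$imbalanced_charge_reactions), "\n",
      "Metabolite connectivity: ", signif(x$connectivity_percent, 4), "%\n",
      "Excluded from balance checks: ", nrow(x$excluded_reactions), "\n",
      sep = "")
  invisible(x)
}

## ---- balance audits on flux solutions -------------------------------------

element_count <- function(model, element) {
  keys <- cpd_key(model$compounds$id, model$compounds$compartment)
  out <- stats::setNames(rep(NA_real_, length(keys)), keys)
  for (i in seq_along(keys)) {
    f <- model$compounds$formula[i]
    if (is.na(f)) next
    pf <- tryCatch(parse_formula(f), error = function(e) NULL)
    if (is.null(pf)) next
    out[keys[i]] <- if (element %in% names(pf)) pf[[element]] else 0
  }
  out
}

reaction_weight <- function(model, weights) {
  vapply(model$reactions, function(rx) {
    w <- weights[names(rx$stoich)]
    if (any(is.na(w))) return(NA_real_)
    sum(rx$stoich * w)
  }, 0)
}

#' Carbon balance audit of a flux solution
#'
#' Since every internal reaction should be element-balanced, the total
#' carbon flux over all reactions (which reduces to exchanges plus biomass)
#' must vanish at steady state. Reports the net carbon flux.
#'
#' @param model a `cb_model`.
#' @param solution a `cb_flux_solution` or named flux vector.
#' @param tol audit tolerance.
#' @return list with `net` (carbon flux residual) and `ok`.
#' @export
audit_carbon_balance <- function(model, solution, tol = 1e-6) {
  v <- if (inherits(solution, "cb_flux_solution")) solution$fluxes
       else solution
  cw <- element_count(model, "C")
  rw <- reaction_weight(model, cw)
  rw[is.na(rw)] <- 0   # reactions with formula-less compounds are audited
                       # by the balance checks instead
  net <- sum(rw[names(v)] * v)
  list(net = net, ok = abs(net) < tol)
}

#' Degree-of-reduction (electron) balance audit
#'
#' Audits a flux solution with the generalized degree of reduction
#' gamma = 4C + H - 2O - 3N + 5P + 6S - charge, which must be conserved by
#' every balanced reaction; the total over the solution (effectively
#' substrates vs. secreted products, H2 included) must vanish.
#'
#' @inheritParams audit_carbon_balance
#' @return list with `net` and `ok`.
#' @export
audit_electron_balance <- function(model, solution, tol = 1e-6) {
  v <- if (inherits(solution, "cb_flux_solution")) solution$fluxes
       else solution
  keys <- cpd_key(model$compounds$id, model$compounds$compartment)
  gamma <- stats::setNames(rep(NA_real_, length(keys)), keys)
  wts <- c(C = 4, H = 1, O = -2, N = -3, P = 5, S = 6)
  for (i in seq_along(keys)) {
    f <- model$compounds$formula[i]
    if (is.na(f)) next
    pf <- tryCatch(parse_formula(f), error = function(e) NULL)
    if (is.null(pf) || any(names(pf) %in% c("R", "X"))) next
    g <- sum(wts[names(pf)] * pf, na.rm = TRUE)
    ch <- model$compounds$charge[i]
    gamma[keys[i]] <- g - if (is.na(ch)) 0 else ch
  }
  rw <- reaction_weight(model, gamma)
  rw[is.na(rw)] <- 0
  net <- sum(rw[names(v)] * v)
  list(net = net, ok = abs(net) < tol)
}
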