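# Randomized minimal-network analysis: seeded random-order reaction pruning
# under biomass + product constraints, replicate classification into
# core-essential / conditionally essential / nonessential sets, and
# convergence diagnostics.

#' Constraints for minimal-network searches
#'
#' @param biomass_min minimum biomass flux every pruned network must keep.
#' @param ethanol_level product constraint as a fraction of the maximum
#'   product flux: 0 pins the product to zero (no-production condition),
#'   a value in (0, 1] becomes a lower bound of `level * max`.
#' @param product_exchange product exchange reaction id, or `NULL` for a
#'   biomass-only study.
#' @param protected reaction ids never pruned (exchanges, biomass and sink
#'   reactions are always protected in addition).
#' @return list of class `cb_sparse_constraints`.
#' @export
sparse_constraints <- function(biomass_min = 0, ethanol_level = 0,
                               product_exchange = "EX_etoh",
                               protected = character()) {
  if (is.null(product_exchange))
    return(structure(list(biomass_min = biomass_min, ethanol_level = 0,
                          product_exchange = NULL, protected = protected),
                     class = "cb_sparse_constraints"))
  stopifnot(biomass_min >= 0, ethanol_level >= 0, ethanol_level <= 1)
  out <- list(biomass_min = biomass_min, ethanol_level = ethanol_level,
              product_exchange = product_exchange, protected = protected)
  class(out) <- "cb_sparse_constraints"
  out
}

#' Map a named ethanol level to its fraction
#'
#' `"none"` -> 0, `"half"` -> 0.5, `"max"` -> 0.9999 (the maximum condition
#' uses 99.99% of the optimum to absorb LP solver tolerance).
#'
#' @param level `"none"`, `"half"`, `"max"`, or a numeric fraction.
#' @return numeric fraction.
#' @export
sparse_level <- function(level) {
  if (is.numeric(level)) return(level)
  switch(level, none = 0, half = 0.5, max = 0.9999,
         stop("unknown level: ", level))
}

# prepare a model for pruning: biomass floor + product level constraint.
# Returns the constrained model; errors if the starting constraints are
# infeasible.
prepare_sparse_model <- function(model, constraints, product_max = NULL) {
  m <- model
  m$reactions[[m$biomass_id]]$lb <- constraints$biomass_min
  pex <- constraints$product_exchange
  if (is.null(pex)) return(m)
  if (!pex %in% names(m$reactions))
    stop("product exchange not in model: ", pex)
  if (constraints$ethanol_level == 0) {
    m$reactions[[pex]]$lb <- 0
    m$reactions[[pex]]$ub <- 0
  } else {
    if (is.null(product_max)) {
      sol <- fba(m, pex)
      if (sol$status != "optimal")
        stop("cannot establish product maximum: ", sol$status)
      product_max <- sol$objective_value
    }
    m$reactions[[pex]]$lb <- constraints$ethanol_level * product_max
  }
  attr(m, "product_max") <- product_max
  m
}

sparse_feasible <- function(lp, blocked_idx) {
  lb <- lp$lb; ub <- lp$ub
  lb[blocked_idx] <- 0; ub[blocked_idx] <- 0
  res <- solve_lp(lp$A, lp$b, rep(0, length(lb)), lb, ub)
  res$status == "optimal"
}

deletable_universe <- function(model, constraints) {
  cand <- reaction_ids(model, c("cytosolic", "transmembrane",
                                "extracellular"))
  cand <- setdiff(cand, c(constraints$protected, model$biomass_id))
  # reactions already bound to zero carry no information
  zero <- vapply(model$reactions[cand],
                 function(r) r$lb == 0 && r$ub == 0, TRUE)
  cand[!zero]
}

#' Find one random minimal network
#'
#' Iterates the deletable reactions in a seeded uniform random permutation;
#' each is tentatively bound to zero and stays blocked iff the biomass and
#' product constraints remain feasible. The result is 1-minimal: no single
#' retained deletable reaction can be removed without breaking the
#' constraints.
#'
#' @param model a `cb_model` with the medium already applied.
#' @param constraints a [sparse_constraints()].
#' @param seed integer seed controlling the pruning order.
#' @param product_max optional precomputed product maximum (saves one FBA).
#' @return list of class `cb_minimal_network`: `retained` (reaction ids),
#'   `seed`, `order` (the permutation used), `blocked`.
#' @export
find_minimal_network <- function(model, constraints, seed,
                                 product_max = NULL) {
  m <- prepare_sparse_model(model, constraints, product_max)
  lp <- build_lp_problem(m)
  if (!sparse_feasible(lp, integer()))
    stop("starting constraints are infeasible; nothing to prune")
  universe <- deletable_universe(m, constraints)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ord <- sample(universe)
  blocked <- integer()
  for (r in ord) {
    idx <- match(r, lp$reactions)
    trial <- c(blocked, idx)
    if (sparse_feasible(lp, trial)) blocked <- trial
  }
  blocked_ids <- lp$reactions[blocked]
  out <- list(retained = setdiff(names(m$reactions), blocked_ids),
              seed = seed, order = ord, blocked = blocked_ids)
  class(out) <- "cb_minimal_network"
  out
}

#' Audit a minimal network
#'
#' Re-solves the constraints on the retained set and exhaustively confirms
#' 1-minimality (no retained deletable reaction can be singly removed).
#'
#' @inheritParams find_minimal_network
#' @param network a `cb_minimal_network`.
#' @return list with `feasible` and `one_minimal` logicals.
#' @export
audit_minimal_network <- function(model, constraints, network,
                                  product_max = NULL) {
  m <- prepare_sparse_model(model, constraints, product_max)
  lp <- build_lp_problem(m)
  blocked <- match(network$blocked, lp$reactions)
  feasible <- sparse_feasible(lp, blocked)
  universe <- deletable_universe(m, constraints)
  retained_del <- intersect(network$retained, universe)
  one_minimal <- all(vapply(retained_del, function(r) {
    !sparse_feasible(lp, c(blocked, match(r, lp$reactions)))
  }, TRUE))
  list(feasible = feasible, one_minimal = one_minimal)
}

#' Classify reactions by occurrence across minimal networks
#'
#' Partitions the deletable universe into core-essential (present in every
#' network), conditionally essential (present in some but not all) and
#' nonessential (present in none), and records the three set sizes after
#' each added network.
#'
#' @param networks list of `cb_minimal_network` (or plain retained-id
#'   character vectors).
#' @param universe the deletable reaction id set the networks were pruned
#'   over.
#' @return list of class `cb_classification`: `core_essential`,
#'   `conditionally_essential`, `nonessential`, `occurrence` (named counts),
#'   `trace` (data frame of set sizes per iteration).
#' @export
classify <- function(networks, universe) {
  if (!length(networks)) stop("no networks to classify")
  retained_sets <- lapply(networks, function(nw) {
    r <- if (inherits(nw, "cb_minimal_network")) nw$retained else nw
    intersect(r, universe)
  })
  occ <- stats::setNames(rep(0L, length(universe)), universe)
  core <- universe
  un <- character()
  trace <- data.frame(iteration = seq_along(retained_sets),
                      core = NA_integer_, conditional = NA_integer_,
                      nonessential = NA_integer_)
  for (i in seq_along(retained_sets)) {
    s <- retained_sets[[i]]
    occ[s] <- occ[s] + 1L
    core <- intersect(core, s)
    un <- union(un, s)
    trace$core[i] <- length(core)
    trace$nonessential[i] <- length(universe) - length(un)
    trace$conditional[i] <- length(un) - length(core)
  }
  out <- list(core_essential = sort(core),
              conditionally_essential = sort(setdiff(un, core)),
              nonessential = sort(setdiff(universe, un)),
              occurrence = occ, n = length(networks), trace = trace)
  class(out) <- "cb_classification"
  out
}

#' @export
print.cb_classification <- function(x, ...) {
  cat("<classification over ", x$n, " minimal networks> core-essential: ",
      length(x$core_essential), ", conditionally essential: ",
      length(x$conditionally_essential), ", nonessential: ",
      length(x$nonessential), "\n", sep = "")
  invisible(x)
}

#' Convergence of a classification trace
#'
#' The classification has converged when all three set sizes are unchanged
#' for `window` consecutive additions; reports the first iteration at which
#' that holds.
#'
#' @param trace data frame with columns `core`, `conditional`,
#'   `nonessential` (as produced by [classify()]).
#' @param window number of consecutive unchanged additions required.
#' @return list with `converged` and `iteration` (NA when not converged).
#' @export
convergence <- function(trace, window) {
  stopifnot(window >= 1)
  n <- nrow(trace)
  if (window > n) return(list(converged = FALSE, iteration = NA_integer_))
  cols <- c("core", "conditional", "nonessential")
  for (t in window:n) {
    w <- trace[(t - window + 1L):t, cols, drop = FALSE]
    if (all(vapply(w, function(col) length(unique(col)) == 1L, TRUE)))
      return(list(converged = TRUE, iteration = t))
  }
  list(converged = FALSE, iteration = NA_integer_)
}

#' Run a replicated minimal-network study
#'
#' `n` independent [find_minimal_network()] calls with seeds
#' `base_seed .. base_seed + n - 1`, followed by classification and
#' convergence analysis. Identical `base_seed` gives bit-identical results.
#'
#' @param model a `cb_model`.
#' @param level `"none"`, `"half"`, `"max"` or a numeric fraction (see
#'   [sparse_level()]).
#' @param n number of replicates.
#' @param base_seed master seed; per-replicate seeds are derived by
#'   increment and recorded in the manifest.
#' @param medium `cb_medium` applied before the study.
#' @param biomass_min minimum biomass flux.
#' @param product_exchange product exchange id.
#' @param protected extra protected reaction ids.
#' @param window convergence window (default `max(10, n %/% 10)`).
#' @return list of class `cb_sparse_study`: `classification`, `networks`,
#'   `convergence`, `universe`, `manifest`.
#' @export
run_sparse_study <- function(model, level, n, base_seed, medium = NULL,
                             biomass_min = 0, product_exchange = "EX_etoh",
                             protected = character(), window = NULL) {
  stopifnot(n >= 1)
  if (is.null(window)) window <- max(10L, n %/% 10L)
  lv <- sparse_level(level)
  m <- apply_medium(model, medium)
  constraints <- sparse_constraints(biomass_min = biomass_min,
                                    ethanol_level = lv,
                                    product_exchange = product_exchange,
                                    protected = protected)
  prepared <- prepare_sparse_model(m, constraints)
  pmax <- attr(prepared, "product_max")
  seeds <- base_seed + seq_len(n) - 1L
  networks <- lapply(seeds, function(s)
    find_minimal_network(m, constraints, seed = s, product_max = pmax))
  universe <- deletable_universe(prepared, constraints)
  cls <- classify(networks, universe)
  conv <- convergence(cls$trace, window)
  out <- list(classification = cls, networks = networks,
              convergence = conv, universe = universe,
              manifest = list(level = lv, n = n, base_seed = base_seed,
                              seeds = seeds, biomass_min = biomass_min,
                              product_exchange = product_exchange,
                              product_max = pmax, window = window))
  class(out) <- "cb_sparse_study"
  out
}

#' @export
print.cb_sparse_study <- function(x, ...) {
  cat("<sparse study> level ", x$manifest$level, ", n = ", x$manifest$n,
      "\n", sep = "")
  print(x$classification)
  cat("converged:", x$convergence$converged, "at iteration",
      x$convergence$iteration, "\n")
  invisible(x)
}

#' Export a sparse study as TSV + JSON manifest
#'
#' @param study a `cb_sparse_study`.
#' @param tsv_path path for the per-reaction classification table.
#' @param manifest_path optional path for the JSON run manifest.
#' @export
write_sparse_study <- function(study, tsv_path, manifest_path = NULL) {
  cls <- study$classification
  class_of <- function(id) {
    if (id %in% cls$core_essential) "core_essential"
    else if (id %in% cls$conditionally_essential) "conditionally_essential"
    else "nonessential"
  }
  tb <- data.frame(reaction = study$universe,
                   class = vapply(study$universe, class_of, ""),
                   occurrence = as.integer(cls$occurrence[study$universe]),
                   n = cls$n, row.names = NULL)
  tb <- tb[order(tb$reaction), ]
  utils::write.table(tb, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(manifest_path))
    jsonlite::write_json(study$manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA)
  invisible(tsv_path)
}

#' Exhaustively enumerate all minimal networks
#'
#' Independent oracle for the randomized search: enumerates every subset of
#' the deletable universe, tests feasibility of the constraints with the
#' complement blocked, and returns all 1-minimal feasible subsets.
#' Exponential in the universe size; intended for fixtures of at most ~12
#' deletable reactions.
#'
#' @inheritParams find_minimal_network
#' @return list with `minimal_networks` (list of retained deletable-id
#'   sets) and `classification` (a [classify()] result over all of them).
#' @export
enumerate_minimal_networks <- function(model, constraints,
                                       product_max = NULL) {
  m <- prepare_sparse_model(model, constraints, product_max)
  lp <- build_lp_problem(m)
  universe <- deletable_universe(m, constraints)
  d <- length(universe)
  if (d > 16L) stop("universe too large for exhaustive enumeration: ", d)
  uidx <- match(universe, lp$reactions)
  feas <- logical(2^d)
  for (code in 0:(2^d - 1)) {
    keep <- bitwAnd(code, 2^(seq_len(d) - 1L)) > 0
    feas[code + 1L] <- sparse_feasible(lp, uidx[!keep])
  }
  minimal <- list()
  for (code in 0:(2^d - 1)) {
    if (!feas[code + 1L]) next
    bits <- which(bitwAnd(code, 2^(seq_len(d) - 1L)) > 0)
    is_min <- all(vapply(bits, function(b)
      !feas[code - 2^(b - 1L) + 1L], TRUE))
    if (is_min) minimal <- c(minimal, list(universe[bits]))
  }
  list(minimal_networks = minimal,
       classification = classify(minimal, universe))
}
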