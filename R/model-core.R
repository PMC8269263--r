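# Domain types for stoichiometric models: compounds, reactions, models,
# media, strain designs, and the operations that edit/constrain them.

cpd_key <- function(id, compartment) paste0(id, "[", compartment, "]")

split_cpd_key <- function(key) {
  mt <- regmatches(key, regexec("^([^][]+)\\[([^][]+)\\]$", key))[[1]]
  if (length(mt) != 3L) stop("malformed compound key: ", key)
  list(id = mt[2], compartment = mt[3])
}

#' Create a compound catalog entry
#'
#' @param id short compound token (unique per compartment).
#' @param name free-text name.
#' @param formula chemical formula string (e.g. `"C6H12O6"`), `NA` if
#'   unknown; may contain generic `R`/`X` groups.
#' @param charge integer charge, `NA` if unknown.
#' @param compartment `"c"` (cytosol) or `"e"` (extracellular).
#' @return one-row data frame.
#' @export
compound <- function(id, name = id, formula = NA_character_,
                     charge = NA_real_, compartment = "c") {
  stopifnot(nzchar(id), compartment %in% c("c", "e"))
  data.frame(id = id, name = name, formula = as.character(formula),
             charge = as.numeric(charge), compartment = compartment,
             stringsAsFactors = FALSE)
}

#' Create a reaction
#'
#' Stoichiometry may be given directly as a named numeric vector (names are
#' `"cpd[compartment]"` keys, negative coefficients are substrates) or as an
#' equation string understood by [parse_equation()].
#'
#' @param id reaction id.
#' @param equation equation string; alternative to `stoich`/`reversible`.
#' @param stoich named numeric vector of signed coefficients.
#' @param lb,ub flux bounds (mmol gDW^-1 h^-1 by convention). Defaults come
#'   from reversibility: `(-default_bound, default_bound)` for reversible,
#'   `(0, default_bound)` for irreversible.
#' @param reversible logical, used when bounds are not given.
#' @param genes gene association string (`"and"`/`"or"`, parentheses), or NA.
#' @param subsystem free-text subsystem label.
#' @param kind one of cytosolic, transmembrane, extracellular, exchange,
#'   biomass, sink; inferred from the stoichiometry when `NA`.
#' @param default_bound bound magnitude used for unstated bounds.
#' @return object of class `cb_reaction`.
#' @export
reaction <- function(id, equation = NULL, stoich = NULL, lb = NA, ub = NA,
                     reversible = FALSE, genes = NA_character_,
                     subsystem = NA_character_, kind = NA_character_,
                     default_bound = 1000) {
  stopifnot(nzchar(id))
  if (!is.null(equation)) {
    eq <- parse_equation(equation)
    stoich <- eq$stoich
    reversible <- eq$reversible
  }
  if (is.null(stoich) || !length(stoich))
    stop("reaction ", id, ": stoichiometry must be nonempty")
  if (any(stoich == 0)) stop("reaction ", id, ": zero coefficient")
  if (is.null(names(stoich)) || any(!nzchar(names(stoich))))
    stop("reaction ", id, ": stoichiometry must be named by compound key")
  if (is.na(lb)) lb <- if (reversible) -default_bound else 0
  if (is.na(ub)) ub <- default_bound
  if (lb > ub) stop("reaction ", id, ": lower bound exceeds upper bound")
  rx <- list(id = id, stoich = stoich, lb = lb, ub = ub,
             genes = if (is.na(genes) || !nzchar(genes)) NA_character_ else genes,
             subsystem = subsystem, kind = kind,
             default_lb = lb, default_ub = ub)
  class(rx) <- "cb_reaction"
  rx
}

infer_kind <- function(rx, biomass_id = NULL) {
  if (!is.na(rx$kind)) return(rx$kind)
  if (!is.null(biomass_id) && rx$id == biomass_id) return("biomass")
  if (grepl("^sink_", rx$id)) return("sink")
  comps <- vapply(names(rx$stoich),
                  function(k) split_cpd_key(k)$compartment, "")
  if (length(rx$stoich) == 1L) return("exchange")
  if (all(comps == "e")) return("extracellular")
  if (length(unique(comps)) > 1L) return("transmembrane")
  "cytosolic"
}

#' Assemble a stoichiometric model
#'
#' Validates the model invariants: unique (id, compartment) compound pairs,
#' unique reaction ids, every referenced compound present in the catalog,
#' biomass reaction present, and exchange reactions touching exactly one
#' compound.
#'
#' @param compounds data frame of [compound()] rows.
#' @param reactions list of [reaction()] objects.
#' @param biomass_id id of the biomass reaction.
#' @param default_bound positive flux magnitude applied where bounds are
#'   unstated.
#' @param name model name.
#' @return object of class `cb_model`.
#' @export
new_model <- function(compounds, reactions, biomass_id,
                      default_bound = 1000, name = "model") {
  stopifnot(is.data.frame(compounds), default_bound > 0)
  keys <- cpd_key(compounds$id, compounds$compartment)
  if (anyDuplicated(keys))
    stop("duplicate compounds: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  ids <- vapply(reactions, function(r) r$id, "")
  if (anyDuplicated(ids))
    stop("duplicate reaction ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(reactions) <- ids
  if (!biomass_id %in% ids) stop("biomass reaction not found: ", biomass_id)
  for (rx in reactions) {
    missing <- setdiff(names(rx$stoich), keys)
    if (length(missing))
      stop("reaction ", rx$id, " references unknown compounds: ",
           paste(missing, collapse = ", "))
  }
  reactions <- lapply(reactions, function(rx) {
    rx$kind <- infer_kind(rx, biomass_id)
    rx
  })
  for (rx in reactions)
    if (rx$kind == "exchange" && length(rx$stoich) != 1L)
      stop("exchange reaction ", rx$id, " must touch exactly one compound")
  mdl <- list(name = name, compounds = compounds[order(keys), , drop = FALSE],
              reactions = reactions[order(ids)], biomass_id = biomass_id,
              default_bound = default_bound, extra_constraints = list())
  class(mdl) <- "cb_model"
  mdl
}

#' @export
print.cb_model <- function(x, ...) {
  kinds <- vapply(x$reactions, function(r) r$kind, "")
  cat("<cb_model> ", x$name, ": ", nrow(x$compounds), " compounds, ",
      length(x$reactions), " reactions (",
      paste(names(table(kinds)), as.integer(table(kinds)),
            sep = ":", collapse = ", "),
      "); biomass = ", x$biomass_id, "\n", sep = "")
  invisible(x)
}

#' Reaction ids of a model, optionally filtered by kind
#' @param model a `cb_model`.
#' @param kind optional character vector of kinds to keep.
#' @export
reaction_ids <- function(model, kind = NULL) {
  ids <- names(model$reactions)
  if (is.null(kind)) return(ids)
  kinds <- vapply(model$reactions, function(r) r$kind, "")
  ids[kinds %in% kind]
}

#' Distinct gene loci referenced by a model
#' @param model a `cb_model`.
#' @export
model_genes <- function(model) {
  gs <- lapply(model$reactions, function(r) {
    if (is.na(r$genes)) character() else gene_leaves(parse_gene_association(r$genes))
  })
  sort(unique(unlist(gs)))
}

## ---- gene associations -----------------------------------------------------

gpr_tokenize <- function(s) {
  pat <- "\\(|\\)|[A-Za-z0-9_.:-]+"
  toks <- regmatches(s, gregexpr(pat, s))[[1]]
  rest <- gsub(pat, "", s)
  if (grepl("[^[:space:]]", rest))
    stop("malformed gene association: ", s)
  toks
}

#' Parse a boolean gene-association expression
#'
#' Grammar: identifiers combined with case-insensitive `and`/`or` keywords
#' and parentheses; `and` binds tighter than `or`.
#'
#' @param s association string, e.g. `"(gA and gB) or gC"`.
#' @return expression tree: a leaf is a locus-tag string, an inner node is
#'   `list(op = "and"|"or", args = list(...))`.
#' @export
parse_gene_association <- function(s) {
  if (is.na(s) || !nzchar(trimws(s))) stop("empty gene association")
  toks <- gpr_tokenize(s)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  is_kw <- function(t, kw) !is.na(t) && tolower(t) == kw
  parse_or <- function() {
    args <- list(parse_and())
    while (is_kw(peek(), "or")) { advance(); args <- c(args, list(parse_and())) }
    if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
  }
  parse_and <- function() {
    args <- list(parse_atom())
    while (is_kw(peek(), "and")) { advance(); args <- c(args, list(parse_atom())) }
    if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
  }
  parse_atom <- function() {
    t <- peek()
    if (is.na(t)) stop("malformed gene association: ", s)
    if (t == "(") {
      advance()
      e <- parse_or()
      if (!identical(peek(), ")")) stop("unbalanced parentheses in: ", s)
      advance()
      return(e)
    }
    if (t == ")" || tolower(t) %in% c("and", "or"))
      stop("malformed gene association: ", s)
    advance()
  }
  out <- parse_or()
  if (pos <= length(toks)) stop("trailing tokens in gene association: ", s)
  out
}

gene_leaves <- function(expr) {
  if (is.character(expr)) return(expr)
  unlist(lapply(expr$args, gene_leaves))
}

render_gene_association <- function(expr) {
  if (is.character(expr)) return(expr)
  parts <- vapply(expr$args, function(a) {
    s <- render_gene_association(a)
    if (is.list(a)) paste0("(", s, ")") else s
  }, "")
  paste(parts, collapse = paste0(" ", expr$op, " "))
}

#' Evaluate a gene association under a set of deletions
#'
#' Deleted loci evaluate to `FALSE`, all others to `TRUE`; the boolean tree
#' is then evaluated recursively. A reaction whose association evaluates
#' `FALSE` has lost its enzyme.
#'
#' @param expr parsed tree from [parse_gene_association()] or a string.
#' @param deleted character vector of deleted locus tags.
#' @return logical scalar.
#' @export
evaluate_gene_association <- function(expr, deleted = character()) {
  if (is.character(expr)) expr <- parse_gene_association(expr)
  eval_node <- function(e) {
    if (is.character(e)) return(!(e %in% deleted))
    vals <- vapply(e$args, eval_node, logical(1))
    if (e$op == "and") all(vals) else any(vals)
  }
  eval_node(expr)
}

## ---- strain designs --------------------------------------------------------

#' Create a strain design
#'
#' @param deleted_genes locus tags to delete (reactions whose association
#'   evaluates false are bound to zero).
#' @param deleted_reactions reaction ids to bound to zero directly.
#' @param insertions list of [reaction()] objects (knock-ins); each may carry
#'   a `compounds` attribute with new catalog rows it requires.
#' @param direction_overrides named character vector mapping reaction id to
#'   `"reversible"`, `"forward_only"`, `"reverse_only"` or `"blocked"`.
#' @return object of class `cb_design`.
#' @export
new_design <- function(deleted_genes = character(),
                       deleted_reactions = character(),
                       insertions = list(),
                       direction_overrides = character()) {
  ins_ids <- vapply(insertions, function(r) r$id, "")
  if (anyDuplicated(ins_ids)) stop("duplicate insertion ids")
  if (length(direction_overrides)) {
    bad <- setdiff(direction_overrides,
                   c("reversible", "forward_only", "reverse_only", "blocked"))
    if (length(bad)) stop("unknown direction override mode: ",
                          paste(bad, collapse = ", "))
    if (is.null(names(direction_overrides)))
      stop("direction_overrides must be named by reaction id")
  }
  d <- list(deleted_genes = unique(deleted_genes),
            deleted_reactions = unique(deleted_reactions),
            insertions = insertions,
            direction_overrides = direction_overrides)
  class(d) <- "cb_design"
  d
}

#' Combine two strain designs
#' @param a,b `cb_design` objects; `b`'s direction overrides win on clash.
#' @export
combine_designs <- function(a, b) {
  ov <- c(a$direction_overrides, b$direction_overrides)
  ov <- ov[!duplicated(names(ov), fromLast = TRUE)]
  new_design(deleted_genes = union(a$deleted_genes, b$deleted_genes),
             deleted_reactions = union(a$deleted_reactions,
                                       b$deleted_reactions),
             insertions = c(a$insertions, b$insertions),
             direction_overrides = ov)
}

#' Apply a strain design to a model
#'
#' Gene deletions zero the bounds of every reaction whose gene association
#' evaluates false (the reaction stays in the model so downstream FVA/MOMA
#' reports keep a stable reaction index); explicit reaction deletions are
#' bound to zero likewise; insertions are appended (with any new compounds
#' they declare); direction overrides clamp or restore bounds
#' (`forward_only` raises the lower bound to at least 0, `reverse_only`
#' lowers the upper bound to at most 0, `blocked` zeroes both, `reversible`
#' restores the catalog defaults).
#'
#' @param model a `cb_model`.
#' @param design a `cb_design`.
#' @return the edited `cb_model` (the input is not modified).
#' @export
apply_design <- function(model, design) {
  stopifnot(inherits(model, "cb_model"), inherits(design, "cb_design"))
  known_genes <- model_genes(model)
  unknown <- setdiff(design$deleted_genes, known_genes)
  if (length(unknown))
    stop("unknown gene(s) in design: ", paste(unknown, collapse = ", "))
  unknown_rx <- setdiff(design$deleted_reactions, names(model$reactions))
  if (length(unknown_rx))
    stop("unknown reaction(s) in design: ", paste(unknown_rx, collapse = ", "))

  reactions <- model$reactions
  if (length(design$deleted_genes)) {
    for (id in names(reactions)) {
      g <- reactions[[id]]$genes
      if (!is.na(g) &&
          !evaluate_gene_association(g, design$deleted_genes)) {
        reactions[[id]]$lb <- 0
        reactions[[id]]$ub <- 0
      }
    }
  }
  for (id in design$deleted_reactions) {
    reactions[[id]]$lb <- 0
    reactions[[id]]$ub <- 0
  }

  compounds <- model$compounds
  if (length(design$insertions)) {
    ins_ids <- vapply(design$insertions, function(r) r$id, "")
    clash <- intersect(ins_ids, names(reactions))
    if (length(clash))
      stop("insertion duplicates existing reaction id: ",
           paste(clash, collapse = ", "))
    for (rx in design$insertions) {
      extra <- attr(rx, "compounds")
      if (!is.null(extra)) {
        have <- cpd_key(compounds$id, compounds$compartment)
        add <- extra[!cpd_key(extra$id, extra$compartment) %in% have, ,
                     drop = FALSE]
        if (nrow(add)) compounds <- rbind(compounds, add)
      }
      rx2 <- rx
      attr(rx2, "compounds") <- NULL
      reactions[[rx$id]] <- rx2
    }
  }

  if (length(design$direction_overrides)) {
    unknown_ov <- setdiff(names(design$direction_overrides), names(reactions))
    if (length(unknown_ov))
      stop("direction override for unknown reaction: ",
           paste(unknown_ov, collapse = ", "))
    for (id in names(design$direction_overrides)) {
      mode <- design$direction_overrides[[id]]
      rx <- reactions[[id]]
      if (mode == "forward_only") {
        rx$lb <- max(0, rx$lb)
      } else if (mode == "reverse_only") {
        rx$ub <- min(0, rx$ub)
      } else if (mode == "blocked") {
        rx$lb <- 0; rx$ub <- 0
      } else if (mode == "reversible") {
        rx$lb <- rx$default_lb; rx$ub <- rx$default_ub
      }
      reactions[[id]] <- rx
    }
  }

  out <- new_model(compounds, unname(reactions), model$biomass_id,
                   default_bound = model$default_bound, name = model$name)
  out$extra_constraints <- model$extra_constraints
  for (a in setdiff(names(attributes(model)), c("names", "class")))
    attr(out, a) <- attr(model, a)
  out
}

## ---- stoichiometric matrix -------------------------------------------------

#' Stoichiometric matrix of a model
#'
#' Sparse matrix with one row per compartmentalized compound and one column
#' per reaction, both in lexicographic id order; entry (i, j) is the signed
#' coefficient of compound i in reaction j.
#'
#' @param model a `cb_model`.
#' @return a `Matrix::sparseMatrix` with dimnames.
#' @export
stoichiometric_matrix <- function(model) {
  keys <- sort(cpd_key(model$compounds$id, model$compounds$compartment))
  rids <- sort(names(model$reactions))
  triplets <- lapply(seq_along(rids), function(j) {
    st <- model$reactions[[rids[j]]]$stoich
    cbind(match(names(st), keys), j, st)
  })
  tr <- do.call(rbind, triplets)
  Matrix::sparseMatrix(i = tr[, 1], j = tr[, 2], x = tr[, 3],
                       dims = c(length(keys), length(rids)),
                       dimnames = list(keys, rids))
}

## ---- media -----------------------------------------------------------------

#' Create a medium specification
#'
#' @param reaction character vector of exchange reaction ids.
#' @param lower,upper bound vectors; a negative lower bound permits uptake.
#' @return object of class `cb_medium` (a data frame).
#' @export
medium_spec <- function(reaction = character(), lower = numeric(),
                        upper = numeric()) {
  stopifnot(length(reaction) == length(lower),
            length(reaction) == length(upper))
  if (any(lower > upper))
    stop("medium bound pair with lower > upper for: ",
         paste(reaction[lower > upper], collapse = ", "))
  m <- data.frame(reaction = reaction, lower = lower, upper = upper,
                  stringsAsFactors = FALSE)
  class(m) <- c("cb_medium", "data.frame")
  m
}

#' Apply a medium to a model
#'
#' Every exchange reaction not listed in the medium becomes secretion-only
#' `(0, default_bound)`; listed exchanges get the stated bounds.
#'
#' @param model a `cb_model`.
#' @param medium a `cb_medium` (or NULL for no change).
#' @return the constrained model.
#' @export
apply_medium <- function(model, medium) {
  if (is.null(medium)) return(model)
  ex <- reaction_ids(model, "exchange")
  unknown <- setdiff(medium$reaction, names(model$reactions))
  if (length(unknown))
    stop("medium references unknown exchange reaction(s): ",
         paste(unknown, collapse = ", "))
  not_ex <- setdiff(medium$reaction, ex)
  if (length(not_ex))
    stop("medium references non-exchange reaction(s): ",
         paste(not_ex, collapse = ", "))
  for (id in ex) {
    model$reactions[[id]]$lb <- 0
    model$reactions[[id]]$ub <- model$default_bound
  }
  for (i in seq_len(nrow(medium))) {
    id <- medium$reaction[i]
    model$reactions[[id]]$lb <- medium$lower[i]
    model$reactions[[id]]$ub <- medium$upper[i]
  }
  model
}
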