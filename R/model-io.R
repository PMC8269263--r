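# Readers and writers for the YAML model dialect and tabular model sheets.
#
# The YAML dialect follows common conventions for constraint-based models:
# a central document naming the biomass reaction, default flux limit and
# compartments, with compounds / reactions / limits either inline or in
# included sub-documents. Equations use the grammar of parse_equation().

resolve_section <- function(doc, section, dir) {
  entries <- doc[[section]]
  if (is.null(entries)) return(list())
  out <- list()
  for (e in entries) {
    if (!is.null(e$include)) {
      f <- file.path(dir, e$include)
      if (!file.exists(f))
        stop("included file not found for section '", section, "': ", f)
      out <- c(out, yaml::read_yaml(f))
    } else {
      out <- c(out, list(e))
    }
  }
  out
}

#' Read a model from the YAML dialect
#'
#' @param path path to the central model document; `include:` entries are
#'   resolved relative to its directory.
#' @return a `cb_model`.
#' @export
read_yaml_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  doc <- yaml::read_yaml(path)
  dir <- dirname(path)
  if (is.null(doc$biomass)) stop("model document lacks a 'biomass' key")
  default_bound <- if (!is.null(doc$default_flux_limit))
    as.numeric(doc$default_flux_limit) else 1000

  cps <- resolve_section(doc, "compounds", dir)
  if (!length(cps)) stop("model document lists no compounds")
  compounds <- do.call(rbind, lapply(cps, function(e) {
    if (is.null(e$id)) stop("compound entry without id")
    compound(id = e$id,
             name = if (is.null(e$name)) e$id else e$name,
             formula = if (is.null(e$formula)) NA_character_ else e$formula,
             charge = if (is.null(e$charge)) NA_real_ else as.numeric(e$charge),
             compartment = if (is.null(e$compartment)) "c" else e$compartment)
  }))
  dup <- duplicated(cpd_key(compounds$id, compounds$compartment))
  if (any(dup))
    stop("duplicate compound entries: ",
         paste(cpd_key(compounds$id, compounds$compartment)[dup],
               collapse = ", "))

  rxs <- resolve_section(doc, "reactions", dir)
  if (!length(rxs)) stop("model document lists no reactions")
  seen <- character()
  reactions <- lapply(rxs, function(e) {
    if (is.null(e$id)) stop("reaction entry without id")
    if (e$id %in% seen) stop("duplicate reaction id: ", e$id)
    seen <<- c(seen, e$id)
    if (is.null(e$equation)) stop("reaction ", e$id, " lacks an equation")
    eq <- tryCatch(parse_equation(e$equation), error = function(err)
      stop("reaction ", e$id, ": ", conditionMessage(err), call. = FALSE))
    reaction(id = e$id, stoich = eq$stoich, reversible = eq$reversible,
             genes = if (is.null(e$genes)) NA_character_ else e$genes,
             subsystem = if (is.null(e$subsystem)) NA_character_
                         else e$subsystem,
             default_bound = default_bound)
  })

  limits <- resolve_section(doc, "limits", dir)
  mdl <- new_model(compounds, reactions, biomass_id = doc$biomass,
                   default_bound = default_bound,
                   name = if (is.null(doc$name)) "model" else doc$name)
  for (lm in limits) {
    id <- lm$reaction
    if (is.null(id) || !id %in% names(mdl$reactions))
      stop("limits entry for unknown reaction: ", id)
    if (!is.null(lm$lower)) mdl$reactions[[id]]$lb <- as.numeric(lm$lower)
    if (!is.null(lm$upper)) mdl$reactions[[id]]$ub <- as.numeric(lm$upper)
    if (mdl$reactions[[id]]$lb > mdl$reactions[[id]]$ub)
      stop("limits for ", id, ": lower > upper")
    mdl$reactions[[id]]$default_lb <- mdl$reactions[[id]]$lb
    mdl$reactions[[id]]$default_ub <- mdl$reactions[[id]]$ub
  }
  mdl
}

#' Write a model in the YAML dialect
#'
#' Emits the central document plus `<stem>_compounds.yaml`,
#' `<stem>_reactions.yaml` and `<stem>_limits.yaml` next to it, all in
#' lexicographic id order so output is deterministic. Limits are written
#' only for reactions whose bounds differ from the equation-derived
#' defaults.
#'
#' @param model a `cb_model`.
#' @param path path of the central document to create.
#' @export
write_yaml_model <- function(model, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  stem <- sub("\\.ya?ml$", "", basename(path))
  cfile <- paste0(stem, "_compounds.yaml")
  rfile <- paste0(stem, "_reactions.yaml")
  lfile <- paste0(stem, "_limits.yaml")

  cps <- model$compounds
  cps <- cps[order(cpd_key(cps$id, cps$compartment)), , drop = FALSE]
  cpd_entries <- lapply(seq_len(nrow(cps)), function(i) {
    e <- list(id = cps$id[i], name = cps$name[i],
              compartment = cps$compartment[i])
    if (!is.na(cps$formula[i])) e$formula <- cps$formula[i]
    if (!is.na(cps$charge[i])) e$charge <- cps$charge[i]
    e
  })

  rids <- sort(names(model$reactions))
  rx_entries <- lapply(rids, function(id) {
    rx <- model$reactions[[id]]
    reversible <- rx$default_lb < 0
    e <- list(id = id,
              equation = render_equation(rx$stoich, reversible))
    if (!is.na(rx$genes)) e$genes <- rx$genes
    if (!is.na(rx$subsystem)) e$subsystem <- rx$subsystem
    e
  })

  lim_entries <- list()
  for (id in rids) {
    rx <- model$reactions[[id]]
    reversible <- rx$default_lb < 0
    eq_lb <- if (reversible) -model$default_bound else 0
    eq_ub <- model$default_bound
    if (rx$lb != eq_lb || rx$ub != eq_ub)
      lim_entries <- c(lim_entries,
                       list(list(reaction = id, lower = rx$lb,
                                 upper = rx$ub)))
  }

  yaml::write_yaml(cpd_entries, file.path(dir, cfile))
  yaml::write_yaml(rx_entries, file.path(dir, rfile))
  yaml::write_yaml(lim_entries, file.path(dir, lfile))
  central <- list(name = model$name, biomass = model$biomass_id,
                  default_flux_limit = model$default_bound,
                  compartments = list(list(id = "c", name = "cytosol"),
                                      list(id = "e", name = "extracellular")),
                  compounds = list(list(include = cfile)),
                  reactions = list(list(include = rfile)),
                  limits = list(list(include = lfile)))
  yaml::write_yaml(central, path)
  invisible(path)
}

#' Read a model from tabular (TSV) sheets
#'
#' Ingestion path for reconstructions exported from spreadsheet
#' supplementary material: one reaction sheet and one compound sheet,
#' UTF-8, tab-delimited, with a header row.
#'
#' @param reaction_sheet TSV with mandatory columns `id`, `equation` and
#'   optional `genes`, `subsystem`.
#' @param compound_sheet TSV with mandatory columns `id`, `compartment` and
#'   optional `name`, `formula`, `charge`.
#' @param biomass_id biomass reaction id (default: a reaction whose id
#'   contains "biomass", case-insensitively).
#' @param default_bound default flux magnitude.
#' @return a `cb_model`.
#' @export
read_table_model <- function(reaction_sheet, compound_sheet,
                             biomass_id = NULL, default_bound = 1000) {
  rt <- utils::read.delim(reaction_sheet, stringsAsFactors = FALSE,
                          check.names = FALSE, quote = "")
  ct <- utils::read.delim(compound_sheet, stringsAsFactors = FALSE,
                          check.names = FALSE, quote = "")
  for (col in c("id", "equation"))
    if (!col %in% names(rt))
      stop("reaction sheet lacks mandatory column '", col, "'")
  for (col in c("id", "compartment"))
    if (!col %in% names(ct))
      stop("compound sheet lacks mandatory column '", col, "'")
  compounds <- do.call(rbind, lapply(seq_len(nrow(ct)), function(i) {
    compound(id = ct$id[i],
             name = if ("name" %in% names(ct)) ct$name[i] else ct$id[i],
             formula = if ("formula" %in% names(ct) && nzchar(ct$formula[i]))
               ct$formula[i] else NA_character_,
             charge = if ("charge" %in% names(ct)) suppressWarnings(
               as.numeric(ct$charge[i])) else NA_real_,
             compartment = ct$compartment[i])
  }))
  reactions <- lapply(seq_len(nrow(rt)), function(i) {
    eq <- parse_equation(rt$equation[i])
    g <- if ("genes" %in% names(rt) && nzchar(rt$genes[i])) rt$genes[i]
         else NA_character_
    reaction(id = rt$id[i], stoich = eq$stoich, reversible = eq$reversible,
             genes = g,
             subsystem = if ("subsystem" %in% names(rt)) rt$subsystem[i]
                         else NA_character_,
             default_bound = default_bound)
  })
  if (is.null(biomass_id)) {
    hit <- grep("biomass", rt$id, ignore.case = TRUE, value = TRUE)
    if (!length(hit))
      stop("no biomass reaction found; pass biomass_id explicitly")
    biomass_id <- hit[1]
  }
  new_model(compounds, reactions, biomass_id, default_bound = default_bound)
}

#' Count reactions per category
#'
#' @param model a `cb_model`.
#' @return named integer vector over the reaction kinds present.
#' @export
reaction_counts <- function(model) {
  kinds <- vapply(model$reactions, function(r) r$kind, "")
  table(factor(kinds, levels = c("cytosolic", "transmembrane",
                                 "extracellular", "exchange", "biomass",
                                 "sink")))
}

#' Read a medium specification
#'
#' Accepts a TSV file (columns `reaction`, `lower`, `upper`) or a YAML file
#' (list of `{reaction, lower, upper}` entries). An empty file yields an
#' empty medium, i.e. every exchange secretion-only once applied.
#'
#' @param path file path, format chosen by extension (`.yaml`/`.yml` vs
#'   anything else = TSV).
#' @return a `cb_medium`.
#' @export
read_medium <- function(path) {
  if (!file.exists(path)) stop("medium file not found: ", path)
  if (grepl("\\.ya?ml$", path)) {
    entries <- yaml::read_yaml(path)
    if (is.null(entries) || !length(entries))
      return(medium_spec())
    return(medium_spec(
      reaction = vapply(entries, function(e) e$reaction, ""),
      lower = vapply(entries, function(e) as.numeric(e$lower), 0),
      upper = vapply(entries, function(e) as.numeric(e$upper), 0)))
  }
  tb <- tryCatch(utils::read.delim(path, stringsAsFactors = FALSE),
                 error = function(e) NULL)
  if (is.null(tb) || nrow(tb) == 0L) return(medium_spec())
  for (col in c("reaction", "lower", "upper"))
    if (!col %in% names(tb)) stop("medium sheet lacks column '", col, "'")
  medium_spec(tb$reaction, as.numeric(tb$lower), as.numeric(tb$upper))
}

#' Write a medium specification as TSV
#' @param medium a `cb_medium`.
#' @param path output path.
#' @export
write_medium <- function(medium, path) {
  utils::write.table(as.data.frame(medium), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
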