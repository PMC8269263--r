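# Reaction equation grammar and chemical formula parsing.
#
# Equation grammar:
#   equation := side ARROW side
#   side     := [ term (" + " term)* ]          (empty side allowed for
#                                                exchange reactions)
#   term     := [ "(" coef ")" ] compoundId compartmentRef
#   coef     := integer | decimal | integer "/" integer   (positive)
#   ARROW    := "=>" (irreversible) | "<=>" (reversible)
#   compartmentRef := "[" compartment "]"  |  "_c" / "_e" suffix
# An omitted coefficient is 1. Duplicate compounds on a side are summed;
# a compound on both sides nets out.

coef_pat <- "[0-9]+(\\.[0-9]+)?(/[0-9]+)?"
id_pat <- "[A-Za-z][A-Za-z0-9.-]*"

parse_coef <- function(s) {
  if (grepl("/", s, fixed = TRUE)) {
    parts <- strsplit(s, "/", fixed = TRUE)[[1]]
    as.numeric(parts[1]) / as.numeric(parts[2])
  } else as.numeric(s)
}

parse_term <- function(s, context) {
  pat <- paste0("^\\s*(\\(\\s*(", coef_pat, ")\\s*\\)\\s*)?(", id_pat,
                ")(\\[([A-Za-z0-9]+)\\]|_([ce]))\\s*$")
  mt <- regmatches(s, regexec(pat, s))[[1]]
  if (!length(mt))
    stop("cannot parse equation term '", trimws(s), "' in: ", context)
  # groups: [2] coef wrapper, [3] coef, [6] compound id, [8] bracketed
  # compartment, [9] suffix compartment
  coef <- if (nzchar(mt[2])) parse_coef(mt[3]) else 1
  if (coef <= 0) stop("non-positive coefficient in: ", context)
  comp <- if (nzchar(mt[8])) mt[8] else mt[9]
  stats::setNames(coef, cpd_key(mt[6], comp))
}

parse_side <- function(s, context) {
  if (!nzchar(trimws(s))) return(numeric())
  terms <- strsplit(s, "+", fixed = TRUE)[[1]]
  if (any(!nzchar(trimws(terms))))
    stop("empty term in equation: ", context)
  out <- lapply(terms, parse_term, context = context)
  v <- unlist(out)
  tapply(v, names(v), sum)[unique(names(v))]
}

#' Parse a reaction equation string
#'
#' @param s equation such as `"(2) h[c] + fdred[c] => h2[e] + fdox[c]"`.
#' @return list with `stoich` (named signed coefficients, negative =
#'   substrate) and `reversible` (logical).
#' @export
parse_equation <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  n_rev <- length(gregexpr("<=>", s, fixed = TRUE)[[1]])
  if (gregexpr("<=>", s, fixed = TRUE)[[1]][1] == -1L) n_rev <- 0L
  n_fwd <- length(gregexpr("=>", s, fixed = TRUE)[[1]])
  if (gregexpr("=>", s, fixed = TRUE)[[1]][1] == -1L) n_fwd <- 0L
  if (n_rev == 1L && n_fwd == 1L) {
    reversible <- TRUE
    arrow <- "<=>"
  } else if (n_rev == 0L && n_fwd == 1L) {
    reversible <- FALSE
    arrow <- "=>"
  } else stop("equation must contain exactly one '=>' or '<=>': ", s)
  at <- regexpr(arrow, s, fixed = TRUE)
  sides <- c(substr(s, 1L, at - 1L),
             substr(s, at + attr(at, "match.length"), nchar(s)))
  lhs <- parse_side(sides[1], s)
  rhs <- parse_side(sides[2], s)
  if (!length(lhs) && !length(rhs)) stop("empty equation: ", s)
  st <- c(-lhs, rhs)
  st <- tapply(st, names(st), sum)
  st <- st[st != 0]
  if (!length(st)) stop("equation nets to nothing: ", s)
  list(stoich = stats::setNames(as.numeric(st), names(st)),
       reversible = reversible)
}

format_coef <- function(x) {
  if (abs(x - round(x)) < 1e-12) return(format(round(x)))
  # try small-denominator fraction for exact rendering
  for (d in 2:64) {
    if (abs(x * d - round(x * d)) < 1e-12)
      return(paste0(round(x * d), "/", d))
  }
  format(x, digits = 15)
}

#' Render a reaction equation string
#'
#' Inverse of [parse_equation()]: substrates and products in lexicographic
#' compound-key order, coefficient 1 omitted, other coefficients in
#' parentheses, `"<=>"` for reversible reactions.
#'
#' @param stoich named signed coefficient vector.
#' @param reversible logical.
#' @return equation string.
#' @export
render_equation <- function(stoich, reversible = FALSE) {
  fmt_side <- function(v) {
    if (!length(v)) return("")
    v <- v[order(names(v))]
    paste(vapply(seq_along(v), function(i) {
      cf <- v[i]
      if (abs(cf - 1) < 1e-12) names(v)[i]
      else paste0("(", format_coef(cf), ") ", names(v)[i])
    }, ""), collapse = " + ")
  }
  lhs <- -stoich[stoich < 0]
  rhs <- stoich[stoich > 0]
  arrow <- if (reversible) "<=>" else "=>"
  trimws(paste(fmt_side(lhs), arrow, fmt_side(rhs)))
}

## ---- chemical formulas -----------------------------------------------------

#' Parse a chemical formula string
#'
#' Formulas are flat element sequences such as `"C6H12O6"` or `"Fe8S8"`;
#' the pseudo-elements `R` and `X` denote generic groups (used to flag
#' compounds with undefined structure).
#'
#' @param s formula string.
#' @return named numeric vector of element counts.
#' @export
parse_formula <- function(s) {
  if (is.na(s) || !nzchar(s)) stop("empty formula")
  pat <- "([A-Z][a-z]?)([0-9]*)"
  mt <- gregexpr(pat, s)[[1]]
  consumed <- sum(attr(mt, "match.length"))
  if (consumed != nchar(s) || mt[1] != 1L)
    stop("unparsable formula: ", s)
  pieces <- regmatches(s, gregexpr(pat, s))[[1]]
  els <- sub("[0-9]*$", "", pieces)
  cnt <- as.numeric(ifelse(grepl("[0-9]$", pieces),
                           sub("^[A-Za-z]+", "", pieces), "1"))
  tapply(stats::setNames(cnt, els), els, sum)
}

formula_has_generic <- function(s) {
  f <- tryCatch(parse_formula(s), error = function(e) NULL)
  if (is.null(f)) return(NA)
  any(names(f) %in% c("R", "X"))
}
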