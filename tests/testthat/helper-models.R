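# Fixture builders and independent oracles shared across the test files.
# All fixtures are built in code; none are stored on disk.

# linear chain: EX_A (uptake u) -> A -> B -> EX_B; bottleneck = min(u, cap)
chain_model <- function(uptake = 10, cap = 1000) {
  compounds <- rbind(compound("a", compartment = "e"),
                     compound("a", compartment = "c"),
                     compound("b", compartment = "c"),
                     compound("b", compartment = "e"))
  reactions <- list(
    reaction("EX_a", stoich = c("a[e]" = -1), lb = -uptake, ub = 0),
    reaction("T1", stoich = c("a[e]" = -1, "a[c]" = 1), lb = 0, ub = 1000),
    reaction("R1", stoich = c("a[c]" = -1, "b[c]" = 1), lb = 0, ub = cap),
    reaction("T2", stoich = c("b[c]" = -1, "b[e]" = 1), lb = 0, ub = 1000),
    reaction("EX_b", stoich = c("b[e]" = -1), lb = 0, ub = 1000))
  new_model(compounds, reactions, biomass_id = "EX_b", name = "chain")
}

# two equivalent parallel branches feeding one sink
branch_model <- function(uptake = 5, caps = c(1000, 1000)) {
  compounds <- rbind(compound("a", compartment = "e"),
                     compound("a", compartment = "c"),
                     compound("b", compartment = "c"),
                     compound("b", compartment = "e"))
  reactions <- list(
    reaction("EX_a", stoich = c("a[e]" = -1), lb = -uptake, ub = 0),
    reaction("T1", stoich = c("a[e]" = -1, "a[c]" = 1), lb = 0, ub = 1000),
    reaction("B1", stoich = c("a[c]" = -1, "b[c]" = 1), lb = 0, ub = caps[1]),
    reaction("B2", stoich = c("a[c]" = -1, "b[c]" = 1), lb = 0, ub = caps[2]),
    reaction("T2", stoich = c("b[c]" = -1, "b[e]" = 1), lb = 0, ub = 1000),
    reaction("EX_b", stoich = c("b[e]" = -1), lb = 0, ub = 1000))
  new_model(compounds, reactions, biomass_id = "EX_b", name = "branch")
}

# 12-reaction two-pathway fixture for exhaustive minimal-network work:
# two alternative A->B routes, two alternative B->D routes, and two
# never-needed reactions (a dead end and a pointless back-edge)
two_path_fixture <- function(uptake = 10) {
  cpd <- function(id, comp) compound(id, compartment = comp)
  compounds <- rbind(cpd("a", "e"), cpd("a", "c"), cpd("b", "c"),
                     cpd("c", "c"), cpd("d", "c"), cpd("f", "c"),
                     cpd("g", "c"), cpd("out", "e"))
  rx <- function(id, from, to, ub = 1000)
    reaction(id, stoich = stats::setNames(c(-1, 1), c(from, to)),
             lb = 0, ub = ub)
  reactions <- list(
    reaction("EX_a", stoich = c("a[e]" = -1), lb = -uptake, ub = 0),
    rx("Tin", "a[e]", "a[c]"),
    rx("P1", "a[c]", "b[c]"),
    rx("P2a", "a[c]", "c[c]"),
    rx("P2b", "c[c]", "b[c]"),
    rx("Q1", "b[c]", "d[c]"),
    rx("Q2a", "b[c]", "f[c]"),
    rx("Q2b", "f[c]", "d[c]"),
    rx("U1", "b[c]", "g[c]"),      # dead end, never carries flux
    rx("U2", "d[c]", "a[c]"),      # pointless back-edge
    rx("Rout", "d[c]", "out[e]"),
    reaction("EX_out", stoich = c("out[e]" = -1), lb = 0, ub = 1000))
  new_model(compounds, reactions, biomass_id = "EX_out", name = "twopath")
}

# ground truth for two_path_fixture minimal networks (hand enumeration):
# {Tin, Rout} core; one of {P1} / {P2a,P2b}; one of {Q1} / {Q2a,Q2b}
two_path_truth <- list(
  core = c("Rout", "Tin"),
  conditional = c("P1", "P2a", "P2b", "Q1", "Q2a", "Q2b"),
  nonessential = c("U1", "U2"))

# 3-reaction triangle for the closed-form MOMA projection: P produces A,
# C1/C2 drain it; blocking C2 projects vref onto {vP = vC1, vC2 = 0}
moma_triangle_model <- function() {
  compounds <- compound("a", compartment = "c")
  reactions <- list(
    reaction("P", stoich = c("a[c]" = 1), lb = 0, ub = 10),
    reaction("C1", stoich = c("a[c]" = -1), lb = 0, ub = 10),
    reaction("C2", stoich = c("a[c]" = -1), lb = 0, ub = 10))
  new_model(compounds, reactions, biomass_id = "C1", name = "triangle")
}

# independent gene-association oracle: translate to an R logical expression
# and evaluate with each leaf bound to its truth value
gpr_oracle <- function(s, deleted) {
  toks <- regmatches(s, gregexpr("\\(|\\)|[A-Za-z0-9_.:-]+", s))[[1]]
  leaves <- setdiff(toks, c("(", ")"))
  leaves <- leaves[!tolower(leaves) %in% c("and", "or")]
  expr <- s
  expr <- gsub("\\band\\b", "&&", expr, ignore.case = TRUE)
  expr <- gsub("\\bor\\b", "||", expr, ignore.case = TRUE)
  env <- new.env()
  for (g in unique(leaves)) assign(g, !(g %in% deleted), envir = env)
  eval(parse(text = expr), envir = env)
}

# random gene-association tree of at most `n_leaves` leaves, returned as a
# string, for property tests against the truth-table oracle
random_gpr <- function(n_leaves, genes = paste0("g", 1:5)) {
  build <- function(k) {
    if (k == 1) return(sample(genes, 1))
    left <- sample(seq_len(k - 1), 1)
    op <- sample(c("and", "or"), 1)
    paste0("(", build(left), " ", op, " ", build(k - left), ")")
  }
  build(n_leaves)
}

# random valid equation string plus its expected stoichiometry
random_equation <- function(seed) {
  set.seed(seed)
  cpds <- paste0("m", 1:6)
  n_l <- sample(1:3, 1); n_r <- sample(1:3, 1)
  pick <- sample(cpds, n_l + n_r)
  comp <- sample(c("c", "e"), n_l + n_r, replace = TRUE)
  coef <- sample(c(1, 2, 3, 0.5), n_l + n_r, replace = TRUE)
  term <- function(i) {
    cf <- if (coef[i] == 1) "" else paste0("(", ifelse(coef[i] == 0.5, "1/2",
                                                       coef[i]), ") ")
    paste0(cf, pick[i], "[", comp[i], "]")
  }
  lhs <- paste(vapply(seq_len(n_l), term, ""), collapse = " + ")
  rhs <- paste(vapply(n_l + seq_len(n_r), term, ""), collapse = " + ")
  rev <- sample(c(TRUE, FALSE), 1)
  eq <- paste(lhs, if (rev) "<=>" else "=>", rhs)
  keys <- cpd_key(pick, comp)
  stoich <- stats::setNames(c(-coef[seq_len(n_l)], coef[n_l + seq_len(n_r)]),
                            keys)
  list(equation = eq, stoich = stoich, reversible = rev)
}

expect_flux_equal <- function(x, y, tol = 1e-6) {
  expect_true(abs(x - y) < tol,
              label = sprintf("|%.9g - %.9g| < %g", x, y, tol))
}
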