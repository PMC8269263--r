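# Equation grammar, YAML round trips, tabular sheets and media files.

test_that("equation grammar parses coefficients, compartments and arrows", {
  eq <- parse_equation("(2) h[c] + fdred[c] => h2[e] + fdox[c]")
  expect_false(eq$reversible)
  expect_equal(eq$stoich[["h[c]"]], -2)
  expect_equal(eq$stoich[["fdred[c]"]], -1)
  expect_equal(eq$stoich[["h2[e]"]], 1)
  expect_equal(eq$stoich[["fdox[c]"]], 1)

  expect_true(parse_equation("a[c] <=> b[c]")$reversible)
  # suffix compartment notation accepted on read
  expect_equal(parse_equation("glc_c => g6p_c")$stoich[["glc[c]"]], -1)
  # fraction coefficients
  expect_equal(parse_equation("(1/2) o[c] => w[c]")$stoich[["o[c]"]], -0.5)
  # one-sided exchange equations
  expect_equal(parse_equation("glc[e] <=>")$stoich[["glc[e]"]], -1)

  for (bad in c("a[c] -> b[c]", "a[c] => b[c] => c[c]", "a => b",
                "a[c] + => b[c]", "(0) a[c] => b[c]", "(x) a[c] => b[c]",
                "a[c] b[c] => c[c]", ""))
    expect_error(parse_equation(bad), label = bad)
})

test_that("parse and render are mutually inverse on random equations", {
  for (seed in 1:50) {
    re <- random_equation(seed)
    parsed <- parse_equation(re$equation)
    expect_equal(parsed$reversible, re$reversible, label = re$equation)
    expect_equal(parsed$stoich[sort(names(parsed$stoich))],
                 re$stoich[sort(names(re$stoich))], label = re$equation)
    rendered <- render_equation(parsed$stoich, parsed$reversible)
    reparsed <- parse_equation(rendered)
    expect_equal(reparsed$stoich[sort(names(reparsed$stoich))],
                 parsed$stoich[sort(names(parsed$stoich))],
                 label = rendered)
  }
  # rendering conventions
  expect_identical(render_equation(c("a[c]" = -1, "b[c]" = 2)),
                   "a[c] => (2) b[c]")
  expect_match(render_equation(c("a[c]" = -1, "b[c]" = 1), TRUE), "<=>",
               fixed = TRUE)
})

test_that("YAML model round trip is the identity", {
  dir <- withr::local_tempdir()
  m <- build_toy(toy_options(adhe = TRUE, rnf_na = TRUE))
  p <- file.path(dir, "toy.yaml")
  write_yaml_model(m, p)
  m2 <- read_yaml_model(p)
  expect_identical(sort(names(m2$reactions)), sort(names(m$reactions)))
  keyf <- function(x) cpd_key(x$compounds$id, x$compounds$compartment)
  expect_identical(sort(keyf(m2)), sort(keyf(m)))
  for (id in names(m$reactions)) {
    a <- m$reactions[[id]]; b <- m2$reactions[[id]]
    expect_equal(b$stoich[sort(names(b$stoich))],
                 a$stoich[sort(names(a$stoich))], label = id)
    expect_equal(b$lb, a$lb, label = id)
    expect_equal(b$ub, a$ub, label = id)
    expect_identical(b$genes, a$genes, label = id)
    expect_identical(b$kind, a$kind, label = id)
  }
  expect_identical(m2$biomass_id, m$biomass_id)
  # write -> read -> write is byte-stable
  p2 <- file.path(dir, "toy2.yaml")
  write_yaml_model(m2, p2)
  expect_identical(readLines(file.path(dir, "toy2_reactions.yaml")),
                   readLines(file.path(dir, "toy_reactions.yaml")))
  # the round-tripped model solves identically
  med <- toy_medium("glucose", 10)
  expect_flux_equal(fba(m2, "EX_etoh", medium = med)$objective_value,
                    fba(m, "EX_etoh", medium = med)$objective_value)
})

test_that("YAML reader reports missing files, duplicates and bad equations", {
  dir <- withr::local_tempdir()
  writeLines(c("biomass: B", "compounds:", "- include: nope.yaml",
               "reactions:", "- include: nope2.yaml"),
             file.path(dir, "m.yaml"))
  expect_error(read_yaml_model(file.path(dir, "m.yaml")), "not found")

  yaml::write_yaml(list(
    name = "bad", biomass = "R1",
    compounds = list(list(id = "a", compartment = "c")),
    reactions = list(list(id = "R1", equation = "a[c] =>"),
                     list(id = "R1", equation = "a[c] =>"))),
    file.path(dir, "dup.yaml"))
  expect_error(read_yaml_model(file.path(dir, "dup.yaml")), "duplicate")

  yaml::write_yaml(list(
    name = "bad2", biomass = "R1",
    compounds = list(list(id = "a", compartment = "c")),
    reactions = list(list(id = "R1", equation = "a[c] -> b[c]"))),
    file.path(dir, "badeq.yaml"))
  expect_error(read_yaml_model(file.path(dir, "badeq.yaml")), "R1")
})

test_that("tabular model sheets are read with category counts", {
  dir <- withr::local_tempdir()
  rs <- file.path(dir, "reactions.tsv")
  cs <- file.path(dir, "compounds.tsv")
  writeLines(c("id\tequation\tgenes\tsubsystem",
               "R1\ta[c] => b[c]\tgA\tcore",
               "EX_a\ta[c] <=>\t\t",
               "biomass\tb[c] =>\t\t"), rs)
  writeLines(c("id\tname\tformula\tcharge\tcompartment",
               "a\tA\tC2H4O2\t0\tc",
               "b\tB\tC2H4O2\t0\tc"), cs)
  m <- read_table_model(rs, cs)
  expect_s3_class(m, "cb_model")
  cnt <- reaction_counts(m)
  expect_equal(unname(cnt[["cytosolic"]]), 1L)
  expect_equal(unname(cnt[["exchange"]]), 1L)
  expect_equal(unname(cnt[["biomass"]]), 1L)
  expect_identical(model_genes(m), "gA")

  writeLines(c("id\tgenes", "R1\tgA"), rs)
  expect_error(read_table_model(rs, cs), "equation")
})

test_that("round trip through TSV sheets preserves the toy model", {
  dir <- withr::local_tempdir()
  m <- build_toy()
  rs <- file.path(dir, "rx.tsv"); cs <- file.path(dir, "cp.tsv")
  rxdf <- data.frame(
    id = names(m$reactions),
    equation = vapply(m$reactions, function(r)
      render_equation(r$stoich, r$default_lb < 0), ""),
    genes = vapply(m$reactions, function(r)
      if (is.na(r$genes)) "" else r$genes, ""),
    subsystem = vapply(m$reactions, function(r)
      if (is.na(r$subsystem)) "" else r$subsystem, ""))
  utils::write.table(rxdf, rs, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(m$compounds, cs, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  m2 <- read_table_model(rs, cs, biomass_id = "BIOMASS")
  expect_identical(sort(names(m2$reactions)), sort(names(m$reactions)))
  expect_equal(length(model_genes(m2)), length(model_genes(m)))
  med <- toy_medium("glucose", 10)
  expect_flux_equal(fba(m2, medium = med)$objective_value,
                    fba(m, medium = med)$objective_value)
})

test_that("media are read from TSV and YAML with validation", {
  dir <- withr::local_tempdir()
  tsv <- file.path(dir, "med.tsv")
  writeLines(c("reaction\tlower\tupper", "EX_glc\t-25\t1000"), tsv)
  med <- read_medium(tsv)
  expect_equal(med$lower[med$reaction == "EX_glc"], -25)

  # empty file: all exchanges secretion-only once applied
  empty <- file.path(dir, "empty.tsv")
  writeLines("reaction\tlower\tupper", empty)
  med0 <- read_medium(empty)
  expect_equal(nrow(med0), 0)
  m <- apply_medium(build_toy(), med0)
  ex <- reaction_ids(m, "exchange")
  expect_true(all(vapply(m$reactions[ex], function(r) r$lb == 0, TRUE)))

  yml <- file.path(dir, "med.yaml")
  yaml::write_yaml(list(list(reaction = "EX_glc", lower = -10, upper = 0)),
                   yml)
  expect_equal(read_medium(yml)$lower, -10)

  expect_error(medium_spec("EX_glc", 5, -5), "lower > upper")
  expect_error(apply_medium(build_toy(), medium_spec("NOPE", -1, 0)),
               "unknown")
  expect_error(apply_medium(build_toy(), medium_spec("GAPDH", -1, 0)),
               "non-exchange")
})

test_that("cellulose loads convert to glucose-equivalent uptake", {
  expect_equal(cellulose_uptake_mM(11.8), 11.8 / 162 * 1000)
  expect_equal(cellulose_uptake_mM(0), 0)
  expect_equal(cellulose_uptake_mM(50, solubilized_fraction = 0.2),
               10 / 162 * 1000)
})
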