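# Randomized minimal networks: pruning, classification, convergence, and
# agreement with exhaustive enumeration.

two_path_constraints <- function() {
  sparse_constraints(biomass_min = 1, product_exchange = NULL)
}

test_that("each run retains exactly one of two redundant paths; both occur", {
  m <- two_path_fixture()
  cons <- two_path_constraints()
  seen <- character()
  for (seed in 1:12) {
    nw <- find_minimal_network(m, cons, seed)
    aud <- audit_minimal_network(m, cons, nw)
    expect_true(aud$feasible, label = paste("seed", seed))
    expect_true(aud$one_minimal, label = paste("seed", seed))
    has_p1 <- "P1" %in% nw$retained
    has_p2 <- all(c("P2a", "P2b") %in% nw$retained)
    expect_true(xor(has_p1, has_p2), label = paste("seed", seed))
    expect_false(any(c("U1", "U2") %in% nw$retained))
    seen <- c(seen, if (has_p1) "P1" else "P2")
  }
  expect_setequal(unique(seen), c("P1", "P2"))
})

test_that("no deletable reactions means the full set is retained", {
  m <- chain_model()
  cons <- sparse_constraints(biomass_min = 1, product_exchange = NULL,
                             protected = c("T1", "R1", "T2"))
  nw <- find_minimal_network(m, cons, seed = 1)
  expect_setequal(nw$retained, names(m$reactions))
  expect_length(nw$blocked, 0)
})

test_that("infeasible starting constraints error before pruning", {
  m <- chain_model(uptake = 2)
  cons <- sparse_constraints(biomass_min = 5, product_exchange = NULL)
  expect_error(find_minimal_network(m, cons, 1), "infeasible")
})

test_that("classification matches exhaustive enumeration on the fixture", {
  m <- two_path_fixture()
  cons <- two_path_constraints()
  enum <- enumerate_minimal_networks(m, cons)
  # hand-derived ground truth: 4 minimal networks from 2 x 2 path choices
  expect_length(enum$minimal_networks, 4)
  expect_identical(enum$classification$core_essential, two_path_truth$core)
  expect_identical(enum$classification$conditionally_essential,
                   two_path_truth$conditional)
  expect_identical(enum$classification$nonessential,
                   two_path_truth$nonessential)

  study <- run_sparse_study(m, level = 0, n = 60, base_seed = 500,
                            biomass_min = 1, product_exchange = NULL)
  expect_identical(study$classification$core_essential,
                   enum$classification$core_essential)
  expect_identical(study$classification$conditionally_essential,
                   enum$classification$conditionally_essential)
  expect_identical(study$classification$nonessential,
                   enum$classification$nonessential)
})

test_that("classification set algebra and trivial cases", {
  uni <- c("a", "b", "c", "d")
  single <- classify(list(c("a", "b")), uni)
  expect_identical(single$core_essential, c("a", "b"))
  expect_length(single$conditionally_essential, 0)
  expect_identical(single$nonessential, c("c", "d"))
  multi <- classify(list(c("a", "b"), c("a", "c")), uni)
  expect_identical(multi$core_essential, "a")
  expect_identical(multi$conditionally_essential, c("b", "c"))
  expect_identical(multi$nonessential, "d")
  # the three sets partition the universe
  expect_setequal(c(multi$core_essential, multi$conditionally_essential,
                    multi$nonessential), uni)
  expect_error(classify(list(), uni), "no networks")
})

test_that("convergence detects stability windows", {
  const_trace <- data.frame(core = rep(5, 20), conditional = rep(3, 20),
                            nonessential = rep(2, 20))
  cv <- convergence(const_trace, window = 7)
  expect_true(cv$converged)
  expect_equal(cv$iteration, 7)
  growing <- data.frame(core = rep(5, 20), conditional = 1:20,
                        nonessential = rep(2, 20))
  expect_false(convergence(growing, window = 5)$converged)
  expect_false(convergence(const_trace, window = 50)$converged)
  # stabilizes after iteration 4
  late <- data.frame(core = c(9, 8, 7, 6, rep(6, 10)),
                     conditional = c(1, 2, 3, 4, rep(4, 10)),
                     nonessential = rep(0, 14))
  cv2 <- convergence(late, window = 5)
  expect_true(cv2$converged)
  expect_equal(cv2$iteration, 8)
})

test_that("studies are reproducible and reduce to a single search at n = 1", {
  m <- two_path_fixture()
  s1 <- run_sparse_study(m, 0, n = 1, base_seed = 42, biomass_min = 1,
                         product_exchange = NULL)
  nw <- find_minimal_network(m, two_path_constraints(), seed = 42)
  expect_identical(sort(s1$networks[[1]]$retained), sort(nw$retained))
  s2 <- run_sparse_study(m, 0, n = 15, base_seed = 42, biomass_min = 1,
                         product_exchange = NULL)
  s3 <- run_sparse_study(m, 0, n = 15, base_seed = 42, biomass_min = 1,
                         product_exchange = NULL)
  expect_identical(s2$classification, s3$classification)
  expect_equal(s2$manifest$seeds, 42 + 0:14)
  # serialization is deterministic
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_sparse_study(s2, f1); write_sparse_study(s3, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("toy max-ethanol networks always contain AdhE and POR", {
  med <- toy_medium("glucose", 10)
  m <- apply_medium(build_toy(toy_options(adhe = TRUE, rnf_na = TRUE)), med)
  cons <- sparse_constraints(biomass_min = 0.1, ethanol_level = 0.9999,
                             product_exchange = "EX_etoh")
  pmax <- attr(prepare_sparse_model(m, cons), "product_max")
  for (seed in 1:6) {
    nw <- find_minimal_network(m, cons, seed, product_max = pmax)
    expect_true(all(c("ADHE", "POR") %in% nw$retained),
                label = paste("seed", seed))
  }
})

test_that("core sets grow and conditional sets shrink with ethanol demand", {
  med <- toy_medium("glucose", 10)
  m <- build_toy(toy_options(adhe = TRUE, rnf_na = TRUE))
  st <- lapply(c(0, 0.5, 0.9999), function(lv)
    run_sparse_study(m, lv, n = 25, base_seed = 900, medium = med,
                     biomass_min = 0.1))
  core_sizes <- vapply(st, function(s)
    length(s$classification$core_essential), 1L)
  cond_sizes <- vapply(st, function(s)
    length(s$classification$conditionally_essential), 1L)
  expect_true(all(diff(core_sizes) >= 0))
  expect_gt(core_sizes[3], core_sizes[1])
  expect_lt(cond_sizes[3], cond_sizes[1])
  # AdhE moves into the core when ethanol production is required
  expect_true("ADHE" %in% setdiff(st[[3]]$classification$core_essential,
                                  st[[1]]$classification$core_essential))
  # every network re-audits clean (post-hoc pass on a sample)
  cons <- sparse_constraints(biomass_min = 0.1, ethanol_level = 0.9999,
                             product_exchange = "EX_etoh")
  m2 <- apply_medium(m, med)
  for (nw in st[[3]]$networks[1:3]) {
    aud <- audit_minimal_network(m2, cons, nw)
    expect_true(aud$feasible && aud$one_minimal)
  }
})
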