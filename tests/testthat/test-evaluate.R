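test_that("reference mapping honors L/I equivalence and deamidation classes", {
  m <- map_to_reference("PEPTLDE", "PEPTIDE")
  expect_equal(m$identity, 1)
  m <- map_to_reference("PEPTIDE", "PEPTIDE")
  expect_equal(m$identity, 1)
  expect_true(all(m$column_classes == "match"))

  m <- map_to_reference("ADEA", "ANQA")
  expect_equal(m$identity, 0.5)
  expect_equal(unname(m$column_classes),
               c("match", "deamidation_sub", "deamidation_sub", "match"))
  expect_equal(m$n_deamidation, 2)
  # the reverse substitutions (ref D vs scaffold N) are plain mismatches
  m <- map_to_reference("ANQA", "ADEA")
  expect_equal(m$n_deamidation, 0)
})

test_that("reference coverage is a span union with an identity gate", {
  mk <- function(start, end, identity) {
    list(start = start, end = end, identity = identity, n_aligned = 1)
  }
  expect_equal(reference_coverage(list(mk(1, 100, 1)), 100), 1)
  expect_equal(reference_coverage(list(mk(1, 50, 1), mk(26, 75, 1)), 100),
               0.75)
  expect_equal(reference_coverage(list(mk(1, 100, 0.5)), 100,
                                  min_identity = 0.9), 0)
  # loosening the identity gate cannot lower coverage
  maps <- list(mk(1, 40, 0.95), mk(30, 80, 0.7), mk(70, 100, 0.45))
  covs <- sapply(c(0.9, 0.7, 0.4), function(t) {
    reference_coverage(maps, 100, min_identity = t)
  })
  expect_true(all(diff(covs) >= 0))
})

test_that("N50 returns the shortest length covering half the total", {
  expect_equal(n50(c(5, 4, 3, 2, 1)), 4)
  expect_equal(n50(10), 10)
  expect_equal(n50(c(2, 2, 2, 2)), 2)
  expect_error(n50(numeric(0)), "empty")
})

test_that("precision and mean identity use their identity thresholds", {
  maps <- lapply(c(0.95, 0.75, 0.45, 0.30), function(i) list(identity = i))
  expect_equal(precision(maps, 4), 0.75)
  expect_equal(precision(maps[1:2], 2), 1)
  expect_equal(precision(maps[4], 1), 0)

  maps <- lapply(c(0.95, 0.75, 0.30), function(i) list(identity = i))
  expect_equal(mean_identity(maps), mean(c(0.95, 0.75)))
  expect_equal(mean_identity(list(list(identity = 1))), 1)
  expect_equal(mean_identity(lapply(c(0.6, 0.5), function(i) {
    list(identity = i)
  })), 0)
})

test_that("min-max normalization maps to [0,1] with the degenerate rule", {
  expect_equal(min_max_normalize(c(1, 3, 5)), c(0, 0.5, 1))
  expect_equal(min_max_normalize(c(4, 4)), c(1, 1))
  expect_equal(min_max_normalize(c(0, 1)), c(0, 1))
})

test_that("composite score weights and bounds behave as specified", {
  expect_equal(composite_score(1, 1, 0, 1), 1)
  expect_equal(composite_score(1, 0.5, 0.5, 0.5) -
                 composite_score(0, 0.5, 0.5, 0.5), 0.35)
  expect_equal(composite_score(0, 0, 1, 0), 0)
  expect_error(composite_score(1.2, 0, 0, 0), "normalized")
  expect_error(composite_weights(coverage = 0.5), "sum to 1")
  # bounded in [0,1] over random inputs
  set.seed(31)
  for (i in 1:50) {
    v <- runif(4)
    s <- composite_score(v[1], v[2], v[3], v[4])
    expect_gte(s, 0)
    expect_lte(s, 1)
  }
})

test_that("AQS matches its closed form and decreases with fragmentation", {
  expect_equal(aqs(1, 1, 1, 1), 100)
  expect_equal(aqs(1, 1, 1, 91), 50)
  expect_equal(aqs(0, 1, 1, 5), 0)
  expect_error(aqs(1, 1, 1, 0), "N must be")
  ns <- c(1, 2, 5, 10, 50, 200)
  vals <- sapply(ns, function(n) aqs(0.9, 0.95, 0.8, n))
  expect_true(all(diff(vals) < 0))
})

test_that("a perfect single-scaffold reconstruction earns perfect metrics", {
  set.seed(37)
  ref <- random_protein(150, 6)
  m <- evaluate_assembly(ref, ref)
  expect_equal(m$coverage, 1)
  expect_equal(m$high_conf_coverage, 1)
  expect_equal(m$precision, 1)
  expect_equal(m$mean_identity, 1)
  expect_equal(m$aqs, 100)
  expect_equal(m$n50, 150)
})

test_that("cross-assembly comparison attaches composite scores", {
  set.seed(41)
  ref <- random_protein(100, 6)
  good <- evaluate_assembly(ref, ref)
  frag <- evaluate_assembly(c(substr(ref, 1, 40), substr(ref, 45, 80)), ref)
  both <- compare_assemblies(list(good = good, frag = frag))
  expect_gt(both[[1]]$composite, both[[2]]$composite)
  expect_equal(both[[1]]$composite, 1)  # best on every axis
})
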