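test_that("graph construction counts spanning (k+1)-mer occurrences", {
  g <- build_kmer_graph(c("ACDEFGH", "DEFGHIK"), k = 4)
  expect_setequal(g$nodes, c("ACDE", "CDEF", "DEFG", "EFGH", "FGHI", "GHIK"))
  expect_equal(g$edges$weight[g$edges$from == "DEFG"], 2L)
  expect_equal(sort(g$edges$weight), c(1L, 1L, 1L, 1L, 2L))

  single <- build_kmer_graph("ACDEFGH", k = 7)
  expect_equal(single$nodes, "ACDEFGH")
  expect_equal(nrow(single$edges), 0)

  dup <- build_kmer_graph(rep(c("ACDEFGH", "DEFGHIK"), each = 2), k = 4)
  expect_equal(dup$edges$weight, 2L * g$edges$weight)
})

test_that("edge weights conserve total (k+1)-mer occurrences", {
  set.seed(5)
  for (rep in 1:10) {
    peps <- replicate(15, paste(sample(LETTERS[1:20], sample(5:14, 1),
                                       replace = TRUE), collapse = ""))
    k <- sample(3:6, 1)
    g <- build_kmer_graph(peps, k)
    occurrences <- sum(pmax(nchar(peps) - k, 0))
    expect_equal(sum(g$edges$weight), occurrences)
  }
})

test_that("short peptides are skipped with a message, empty graph allowed", {
  expect_message(g <- build_kmer_graph(c("ACD", "EFG"), k = 7), "skipped")
  expect_equal(length(g$nodes), 0)
  expect_equal(nrow(extract_unitigs(g, 1)), 0)
})

test_that("unitig extraction spells unambiguous paths with weight stats", {
  g <- build_kmer_graph(c("ACDEFGH", "DEFGHIK"), k = 4)
  u <- extract_unitigs(g, 1)
  expect_equal(u$sequence, "ACDEFGHIK")
  expect_equal(u$w_mean, 1.2)
  expect_equal(u$w_min, 1)

  # a branch (out-degree 2) splits the path
  gb <- build_kmer_graph(c("ACDEFGH", "CDEFGW"), k = 4)
  ub <- extract_unitigs(gb, 1)
  expect_true(all(nchar(ub$sequence) < 9))
  expect_false(any(grepl("ACDEFGH", ub$sequence, fixed = TRUE) &
                     grepl("W", ub$sequence, fixed = TRUE)))
})

test_that("cycles terminate traversal instead of looping", {
  # AB->BA->AB cycle plus an entry edge
  g <- build_kmer_graph(c("CABAB"), k = 2)
  expect_silent(u <- extract_unitigs(g, 1))
  expect_true(all(nchar(u$sequence) <= 6))
})

test_that("edge filtering never increases assembled graph content", {
  set.seed(9)
  peps <- unlist(lapply(1:3, function(i) {
    src <- random_protein(60, 5)
    starts <- sample(1:50, 40, replace = TRUE)
    p <- substring(src, starts, pmin(starts + 9, 60))
    rep(p, times = sample(1:3, length(p), replace = TRUE))
  }))
  prev <- Inf
  for (mew in c(1, 2, 3, 5)) {
    g <- filter_edges(build_kmer_graph(peps, 5), mew)
    u <- extract_unitigs(g, 1)
    # unitigs partition the surviving edges: total traversed edges equals
    # the filtered edge count and shrinks as the weight floor rises
    total <- sum(lengths(attr(u, "weights")))
    expect_equal(total, nrow(g$edges))
    expect_lte(total, prev)
    prev <- total
  }
})

test_that("OLC refinement chains contigs and aggregates weight lists", {
  u <- pepnexus:::.new_dbg_contigs(c("ACDEFGHIK", "EFGHIKLMN", "IKLMNPQRS"),
                                   list(c(3, 2, 4, 2, 2), c(2, 2, 5, 1, 3),
                                        c(4, 4, 2, 6, 2)))
  sc <- olc_refine(u, 5)
  expect_equal(sc$sequence, "ACDEFGHIKLMNPQRS")
  expect_equal(sc$w_min, 1)
  expect_equal(sc$w_mean, mean(c(3, 2, 4, 2, 2, 2, 2, 5, 1, 3, 4, 4, 2, 6, 2)))

  none <- olc_refine(pepnexus:::.new_dbg_contigs(c("ACDEFGHIK", "WWWWYYYYT"),
                                                 list(1, 1)), 5)
  expect_setequal(none$sequence, c("ACDEFGHIK", "WWWWYYYYT"))
})

test_that("scaffold scoring follows the linear form with 0.2 w_min penalty", {
  expect_equal(score_scaffold(1, 2, 1), 2.2)
  expect_equal(score_scaffold(10, 3, 2) - score_scaffold(10, 3, 1), 0.2)
  expect_equal(score_scaffold(50, 4, 2, alpha = 0, beta = 0), 0.4)
  expect_error(score_scaffold(0, 1, 1), "L must be")
  # strictly increasing in each argument with positive coefficients
  expect_gt(score_scaffold(11, 3, 2), score_scaffold(10, 3, 2))
  expect_gt(score_scaffold(10, 3.5, 2), score_scaffold(10, 3, 2))
  expect_gt(score_scaffold(10, 3, 2.5), score_scaffold(10, 3, 2))
})

test_that("ranking is by score, then length, then sequence", {
  sc <- structure(data.frame(sequence = c("AAA", "CCCCCCCCCC", "GG"),
                             L = c(3, 10, 2), w_mean = 0, w_min = 0,
                             score = c(2.2, 5.0, 0.3),
                             stringsAsFactors = FALSE),
                  class = c("pn_scaffolds", "data.frame"))
  expect_equal(rank_scaffolds(sc)$score, c(5.0, 2.2, 0.3))
  tie <- structure(data.frame(sequence = c("AAAAAAAA", "CCCCCCCCCC"),
                              L = c(8, 10), w_mean = 0, w_min = 0,
                              score = c(1, 1), stringsAsFactors = FALSE),
                   class = c("pn_scaffolds", "data.frame"))
  expect_equal(rank_scaffolds(tie)$L, c(10, 8))
  empty <- structure(data.frame(sequence = character(0), L = numeric(0),
                                w_mean = numeric(0), w_min = numeric(0),
                                score = numeric(0), stringsAsFactors = FALSE),
                     class = c("pn_scaffolds", "data.frame"))
  expect_equal(nrow(rank_scaffolds(empty)), 0)
})

test_that("a tiling noiseless digest reconstructs the reference at k = 6 and 7", {
  for (k in c(6, 7)) {
    panel <- protease_panel(c("elastase", "thermolysin", "chymotrypsin",
                              "trypsin"))
    set.seed(300 + k)
    ref <- random_tiled_protein(sample(100:300, 1), panel, k = k)
    frags <- unlist(lapply(panel, function(r) digest(ref, r, 2)))
    frags <- frags[nchar(frags) >= 7 & nchar(frags) <= 20]
    sc <- dbg_assemble(frags, dbg_params(k = k))
    expect_equal(sc$sequence[1], ref)
  }
})
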