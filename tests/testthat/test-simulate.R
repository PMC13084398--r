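test_that("tryptic digestion respects specificity and missed cleavages", {
  trypsin <- protease_panel("trypsin")[[1]]
  expect_setequal(digest("AAKRPCCK", trypsin, 0), c("AAK", "RPCCK"))
  expect_setequal(digest("AAKRPCCK", trypsin, 1),
                  c("AAK", "RPCCK", "AAKRPCCK"))
  # no cleavable residues: the protein comes back whole
  norule <- protease_rule("x", cleave_after = "W")
  expect_equal(digest("AAAAAA", norule, 0), "AAAAAA")
  # cleave_before rules cut on the N-terminal side
  thermo <- protease_panel("thermolysin")[[1]]
  expect_setequal(digest("GGGLGG", thermo, 0), c("GGG", "LGG"))
})

test_that("digest fragments are exact substrings at their coordinates", {
  set.seed(43)
  prot <- random_protein(80, 6)
  for (rule in protease_panel(c("trypsin", "gluc", "elastase"))) {
    d <- digest(prot, rule, 2, with_positions = TRUE)
    expect_equal(d$peptide, substring(prot, d$start, d$end))
  }
})

test_that("noiseless simulation emits only exact reference substrings", {
  set.seed(47)
  ref <- random_protein(100, 6)
  sim <- simulate_psm_table(
    c(p1 = ref), proteases = protease_panel(c("trypsin", "elastase")),
    noise = noise_model(substitution_rate = 0, deamidation_rate = 0,
                        false_psm_rate = 0, mod_token_rate = 0, seed = 47),
    psms_per_protease = 100)
  expect_true(all(vapply(sim$psms$peptide, grepl, logical(1), x = ref,
                         fixed = TRUE)))
  expect_false(any(sim$truth$is_false))
})

test_that("the same seed reproduces the table byte for byte", {
  ref <- c(p1 = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQAPILSRVGDGTQDNLSGAEKAVQ")
  a <- simulate_psm_table(ref, noise = noise_model(seed = 99),
                          psms_per_protease = 50)
  b <- simulate_psm_table(ref, noise = noise_model(seed = 99),
                          psms_per_protease = 50)
  expect_identical(a$psms, b$psms)
  expect_identical(a$truth, b$truth)
  c <- simulate_psm_table(ref, noise = noise_model(seed = 100),
                          psms_per_protease = 50)
  expect_false(identical(a$psms$peptide, c$psms$peptide))
})

test_that("false PSM fraction concentrates on its nominal rate", {
  set.seed(53)
  ref <- c(p1 = random_protein(150, 6))
  sim <- simulate_psm_table(
    ref, proteases = protease_panel(c("trypsin", "chymotrypsin", "elastase",
                                      "gluc")),
    noise = noise_model(false_psm_rate = 0.5, seed = 53),
    psms_per_protease = 2500)
  expect_equal(mean(sim$truth$is_false), 0.5, tolerance = 0.03)
})

test_that("q-values are calibrated: realized FDR below any threshold", {
  set.seed(59)
  ref <- c(p1 = random_protein(150, 6))
  sim <- simulate_psm_table(ref, noise = noise_model(seed = 59),
                            psms_per_protease = 200)
  joined <- merge(sim$psms, sim$truth, by = "spectrum_id")
  for (thr in c(0.01, 0.05, 0.10, 0.25)) {
    kept <- joined[joined$q_value <= thr, ]
    if (nrow(kept)) expect_lte(mean(kept$is_false), thr + 1e-9)
  }
  # q-values are monotone non-increasing in confidence
  o <- order(-joined$log_confidence)
  expect_true(all(diff(joined$q_value[o]) >= -1e-12))
})

test_that("recorded mutations match the emitted peptide residues", {
  set.seed(61)
  ref_seq <- random_protein(120, 6)
  sim <- simulate_psm_table(c(p1 = ref_seq),
                            noise = noise_model(deamidation_rate = 0.3,
                                                seed = 61),
                            psms_per_protease = 50)
  stripped <- strip_modifications(sim$psms$peptide)
  for (i in seq_len(nrow(sim$mutations))) {
    mu <- sim$mutations[i, ]
    row <- which(sim$truth$spectrum_id == mu$spectrum_id)
    offset <- mu$ref_pos - sim$truth$start[row] + 1
    expect_equal(substring(stripped[row], offset, offset), mu$to)
    expect_equal(substring(ref_seq, mu$ref_pos, mu$ref_pos), mu$from)
  }
  deam <- sim$mutations[sim$mutations$type == "deamidation", ]
  expect_true(all(paste0(deam$from, deam$to) %in% c("ND", "QE")))
})

test_that("tiled reference generation yields a tiling digest", {
  panel <- protease_panel(c("elastase", "thermolysin", "chymotrypsin",
                            "trypsin"))
  set.seed(67)
  ref <- random_tiled_protein(150, panel, k = 7)
  frags <- unlist(lapply(panel, function(r) digest(ref, r, 2)))
  frags <- frags[nchar(frags) >= 7 & nchar(frags) <= 20]
  expect_true(tiles_reference(frags, ref, 7))
  expect_false(tiles_reference("ACDEFGHI", ref, 7))
})
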