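test_that("log-confidence exponentiation matches closed-form values", {
  expect_equal(exponentiate_confidence(0), 1)
  expect_equal(exponentiate_confidence(-0.2231435513), 0.8, tolerance = 1e-9)
  res <- exponentiate_confidence(-709)
  expect_gte(res, 0)
  expect_lt(res, 1e-300)
  expect_warning(out <- exponentiate_confidence(c(-1, 1e-7)),
                 "clamping")
  expect_equal(out[2], 1)
  expect_error(exponentiate_confidence("x"), "not numeric")
})

test_that("modification stripping removes both delimiter dialects", {
  expect_equal(strip_modifications("SEQM(ox)K"), "SEQMK")
  expect_equal(strip_modifications("PEPTIDE"), "PEPTIDE")
  expect_equal(strip_modifications("M(ox)N(+.98)K"), "MNK")
  expect_equal(strip_modifications("M[+15.99]K"), "MK")
  expect_equal(strip_modifications(c("A(x)C", "D[y]E")), c("AC", "DE"))
  expect_error(strip_modifications("SEQ(oxK"), "unbalanced")
})

make_psms <- function(peptide, q_value = 0.01, log_confidence = -0.1) {
  data.frame(peptide = peptide, q_value = q_value,
             log_confidence = log_confidence, stringsAsFactors = FALSE)
}

test_that("filtering applies length window, FDR gate and keeps order", {
  peps <- c("ACDEFG", "ACDEFGH", strrep("AC", 10), paste0(strrep("AC", 10), "D"))
  stopifnot(nchar(peps) == c(6, 7, 20, 21))
  out <- filter_psms(make_psms(peps))
  expect_equal(out$peptide, peps[c(2, 3)])

  qs <- make_psms(rep("ACDEFGH", 3), q_value = c(0.005, 0.09, 0.2))
  out <- filter_psms(qs, filter_config(fdr_threshold = 0.10))
  expect_equal(nrow(out), 2)
  expect_equal(out$q_value, c(0.005, 0.09))

  empty <- data.frame(peptide = character(0), q_value = numeric(0),
                      log_confidence = numeric(0), stringsAsFactors = FALSE)
  expect_equal(nrow(filter_psms(empty)), 0)
})

test_that("contaminant exclusion is substring-based and L/I-insensitive", {
  contam <- c(decoy = "AAACDEFGHIKAAA")
  psms <- make_psms(c("CDEFGHIK",  # exact substring
                      "CDEFGHLK",  # substring after I->L folding
                      "CDEFGHWK")) # no hit
  out <- filter_psms(psms, filter_config(contaminants = contam))
  expect_equal(out$peptide, "CDEFGHWK")
})

test_that("filtering is idempotent and monotone in its thresholds", {
  set.seed(7)
  n <- 120
  psms <- data.frame(
    peptide = replicate(n, paste(sample(c(LETTERS[1:20]), sample(4:24, 1),
                                        replace = TRUE), collapse = "")),
    q_value = runif(n, 0, 0.3),
    log_confidence = -rexp(n, 5),
    stringsAsFactors = FALSE)
  cfg <- filter_config()
  once <- filter_psms(psms, cfg)
  twice <- filter_psms(once, cfg)
  expect_identical(once, twice)

  loose <- nrow(filter_psms(psms, filter_config(fdr_threshold = 0.2)))
  tight <- nrow(filter_psms(psms, filter_config(fdr_threshold = 0.05)))
  expect_lte(tight, loose)
  wide <- nrow(filter_psms(psms, filter_config(min_len = 5, max_len = 22)))
  narrow <- nrow(filter_psms(psms, filter_config(min_len = 8, max_len = 15)))
  expect_lte(narrow, wide)

  kept <- filter_psms(psms, cfg)$peptide_stripped
  expect_true(all(grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", kept)))
})

test_that("PSM table round-trips through CSV with derived confidence", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  psms <- make_psms(c("ACDEFGH", "MNPQRST"), q_value = c(0.01, 0.02),
                    log_confidence = c(-0.1, -0.5))
  write.csv(psms, tmp, row.names = FALSE)
  back <- read_psm_table(tmp)
  expect_equal(back$confidence, exp(back$log_confidence))
  expect_error(read_psm_table(tmp2 <- {
    t2 <- withr::local_tempfile(fileext = ".csv")
    write.csv(psms[, c("peptide", "log_confidence")], t2, row.names = FALSE)
    t2
  }), "q_value")
  expect_silent(read_psm_table(tmp2, no_fdr = TRUE))
})

test_that("bundled contaminant set loads and screens peptides", {
  contam <- read_contaminants()
  expect_gt(length(contam), 0)
  pep <- substr(contam[[1]], 10, 22)
  out <- filter_psms(make_psms(pep), filter_config(contaminants = contam))
  expect_equal(nrow(out), 0)
})
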