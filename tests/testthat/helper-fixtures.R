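# Shared fixtures and independent oracles, built in code at test time.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Fraction of `source` covered by exact occurrences of `seqs`.
coverage_of <- function(seqs, source) {
  covered <- logical(nchar(source))
  for (s in seqs) {
    mt <- gregexpr(s, source, fixed = TRUE)[[1]]
    if (mt[1] != -1) {
      for (p in mt) covered[p:(p + nchar(s) - 1)] <- TRUE
    }
  }
  mean(covered)
}

# Exhaustive-merge-order assembler: explores every sequence of containment
# absorptions and suffix-prefix merges and returns the best source coverage
# reachable. Independent of the greedy implementation (only the shared
# low-level overlap-length primitive is reused).
oracle_best_coverage <- function(peps, source, min_ov = 3) {
  sp <- pepnexus:::.sp_overlap
  best <- 0
  seen <- new.env(hash = TRUE)
  rec <- function(seqs) {
    key <- paste(sort(seqs), collapse = "|")
    if (!is.null(seen[[key]])) return()
    seen[[key]] <- TRUE
    best <<- max(best, coverage_of(seqs, source))
    n <- length(seqs)
    if (n < 2) return()
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        if (i < j && grepl(seqs[j], seqs[i], fixed = TRUE)) {
          rec(seqs[-j])
          next
        }
        l <- sp(seqs[i], seqs[j], min_ov)
        if (l > 0) {
          rec(c(seqs[-c(i, j)], paste0(seqs[i], substring(seqs[j], l + 1))))
        }
      }
    }
  }
  rec(unique(peps))
  best
}

# The 4-protease noiseless reconstruction fixture: a repeat-free reference
# whose pooled digest tiles it at k, plus the exhaustive digest PSM table.
noiseless_fixture <- function(seed, ref_len = 150, k = 7) {
  panel <- protease_panel(c("elastase", "thermolysin", "chymotrypsin",
                            "trypsin"))
  set.seed(seed)
  ref <- random_tiled_protein(ref_len, panel, k = k)
  sim <- simulate_psm_table(
    c(target = ref), proteases = panel,
    noise = noise_model(substitution_rate = 0, deamidation_rate = 0,
                        false_psm_rate = 0, mod_token_rate = 0, seed = seed),
    psms_per_protease = NULL)
  list(ref = ref, sim = sim, panel = panel)
}

# The 10-protease noisy fixture used for robustness checks (simulator
# defaults: substitution 0.01, deamidation 0.05, false PSMs 0.10).
noisy_fixture <- function(seed, ref_len = 120, psms_per_protease = 300) {
  panel <- protease_panel()
  set.seed(seed)
  ref <- random_tiled_protein(ref_len, panel, k = 7)
  sim <- simulate_psm_table(c(nb = ref), proteases = panel,
                            noise = noise_model(seed = seed),
                            psms_per_protease = psms_per_protease)
  list(ref = ref, sim = sim, panel = panel)
}

# DBG configuration selected by the package's grid search on the noisy
# fixture (deep simulated coverage rewards a high edge-weight floor).
noisy_dbg_params <- function() {
  dbg_params(k = 7, min_edge_weight = 9, olc_min_overlap = 5,
             size_threshold = 15)
}
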