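#' Define a protease cleavage rule
#'
#' A rule cleaves the backbone C-terminally of residues in
#' \code{cleave_after} (unless the next residue is in \code{blocked_next})
#' and N-terminally of residues in \code{cleave_before}. Low-specificity
#' enzymes are modeled by \code{nonspecific_rate}, the probability that any
#' additional inter-residue position is cleaved.
#'
#' @param name enzyme label.
#' @param cleave_after,cleave_before,blocked_next residue sets (character
#'   vectors of one-letter codes).
#' @param nonspecific_rate probability of an extra random cleavage per
#'   position.
#' @return a \code{protease_rule} list.
#' @export
protease_rule <- function(name, cleave_after = character(0),
                          cleave_before = character(0),
                          blocked_next = character(0),
                          nonspecific_rate = 0) {
  if (!length(cleave_after) && !length(cleave_before) &&
      nonspecific_rate <= 0) {
    stop("rule '", name, "' would never cleave")
  }
  structure(list(name = name, cleave_after = cleave_after,
                 cleave_before = cleave_before, blocked_next = blocked_next,
                 nonspecific_rate = nonspecific_rate),
            class = "protease_rule")
}

#' Standard multiprotease panel
#'
#' Ten proteases spanning a broad specificity range, with standard cleavage
#' specificities: trypsin (after K/R, not before P), LysC (after K), GluC
#' (after E), chymotrypsin (after F/W/Y), elastase (after A/V/S/G/L/I),
#' thermolysin (before I/L/V/A/M/F), pepsin (after F/L), and papain,
#' proteinase K and legumain modeled as low-specificity enzymes via a
#' nonspecific cleavage rate. All rules are overridable by constructing
#' [protease_rule()] objects directly.
#'
#' @param names optional subset of panel members to return.
#' @return named list of \code{protease_rule}s.
#' @export
protease_panel <- function(names = NULL) {
  panel <- list(
    trypsin = protease_rule("trypsin", cleave_after = c("K", "R"),
                            blocked_next = "P"),
    lysc = protease_rule("lysc", cleave_after = "K"),
    gluc = protease_rule("gluc", cleave_after = "E"),
    chymotrypsin = protease_rule("chymotrypsin",
                                 cleave_after = c("F", "W", "Y")),
    elastase = protease_rule("elastase",
                             cleave_after = c("A", "V", "S", "G", "L", "I")),
    thermolysin = protease_rule("thermolysin",
                                cleave_before = c("I", "L", "V", "A", "M",
                                                  "F")),
    pepsin = protease_rule("pepsin", cleave_after = c("F", "L")),
    papain = protease_rule("papain", cleave_after = c("K", "R"),
                           nonspecific_rate = 0.05),
    proteinase_k = protease_rule("proteinase_k", nonspecific_rate = 0.15),
    legumain = protease_rule("legumain", cleave_after = "N",
                             nonspecific_rate = 0.05)
  )
  if (is.null(names)) panel else panel[names]
}

#' In-silico digestion of a protein
#'
#' Determines cleavage sites from the rule (respecting blocked residues and
#' any nonspecific rate, which draws from the current RNG) and returns every
#' fragment spanning at most \code{missed_cleavages} internal sites.
#' Deterministic when \code{nonspecific_rate} is 0.
#'
#' @param protein non-empty amino-acid string.
#' @param rule a [protease_rule()].
#' @param missed_cleavages maximum internal cleavage sites per fragment
#'   (default 2, the usual search-engine setting).
#' @param with_positions also return 1-based start/end coordinates.
#' @return character vector of peptides, or a data.frame
#'   (peptide, start, end) when \code{with_positions = TRUE}.
#' @examples
#' digest("AAKRPCCK", protease_panel("trypsin")[[1]], missed_cleavages = 0)
#' @export
digest <- function(protein, rule, missed_cleavages = 2L,
                   with_positions = FALSE) {
  stopifnot(nzchar(protein))
  n <- nchar(protein)
  res <- strsplit(protein, "")[[1]]
  pos <- seq_len(n - 1L)
  site <- logical(n - 1L)
  if (length(pos)) {
    site <- (res[pos] %in% rule$cleave_after &
               !(res[pos + 1L] %in% rule$blocked_next)) |
      (res[pos + 1L] %in% rule$cleave_before)
    if (rule$nonspecific_rate > 0) {
      extra <- stats::runif(n - 1L) < rule$nonspecific_rate
      site <- site | extra
    }
  }
  bounds <- c(0L, which(site), n)
  nb <- length(bounds)
  out <- list()
  for (s in seq_len(nb - 1L)) {
    for (e in seq.int(s + 1L, min(nb, s + 1L + missed_cleavages))) {
      out[[length(out) + 1L]] <- c(bounds[s] + 1L, bounds[e])
    }
  }
  starts <- vapply(out, `[`, integer(1), 1L)
  ends <- vapply(out, `[`, integer(1), 2L)
  peps <- substring(protein, starts, ends)
  if (with_positions) {
    data.frame(peptide = peps, start = starts, end = ends,
               stringsAsFactors = FALSE)
  } else {
    peps
  }
}

#' Noise model for the PSM simulator
#'
#' @param substitution_rate per-residue probability of a random substitution
#'   (default 0.01).
#' @param deamidation_rate probability that each N becomes D and each Q
#'   becomes E (default 0.05) -- the systematic mass-shift substitutions
#'   seen in real MS data.
#' @param false_psm_rate fraction of emitted PSMs that are random spurious
#'   sequences (default 0.10).
#' @param mod_token_rate probability that a peptide containing M gains an
#'   "(ox)" annotation token (default 0.05), to exercise modification
#'   stripping.
#' @param true_conf_shape,false_conf_shape Beta shape pairs for confidences
#'   of true and false PSMs (high- and low-centered respectively).
#' @param seed RNG seed for reproducibility.
#' @return a \code{noise_model} list.
#' @export
noise_model <- function(substitution_rate = 0.01, deamidation_rate = 0.05,
                        false_psm_rate = 0.10, mod_token_rate = 0.05,
                        true_conf_shape = c(12, 2),
                        false_conf_shape = c(2, 8), seed = 1L) {
  rates <- c(substitution_rate, deamidation_rate, false_psm_rate,
             mod_token_rate)
  stopifnot(all(rates >= 0 & rates <= 1))
  structure(list(substitution_rate = substitution_rate,
                 deamidation_rate = deamidation_rate,
                 false_psm_rate = false_psm_rate,
                 mod_token_rate = mod_token_rate,
                 true_conf_shape = true_conf_shape,
                 false_conf_shape = false_conf_shape,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Random protein sequence, repeat-free at a given k
#'
#' Uniform over the 20 canonical residues, redrawn until no k-mer occurs
#' twice, so that de Bruijn graphs built at that k are branch-free for a
#' noiseless digest. Uses the current RNG state.
#'
#' @param length sequence length in residues.
#' @param k_unique k at which all k-mers must be unique (default 6, which
#'   also guarantees uniqueness at any larger k).
#' @return an amino-acid string.
#' @export
random_protein <- function(length, k_unique = 6L) {
  repeat {
    s <- paste(sample(AA_ALPHABET, length, replace = TRUE), collapse = "")
    n <- nchar(s)
    if (n < k_unique) return(s)
    starts <- seq_len(n - k_unique + 1L)
    if (!anyDuplicated(substring(s, starts, starts + k_unique - 1L))) {
      return(s)
    }
  }
}

.random_peptide <- function(len) {
  paste(sample(AA_ALPHABET, len, replace = TRUE), collapse = "")
}

#' Do peptides tile a reference at a given k?
#'
#' Checks whether every (k+1)-mer of the reference occurs in at least one
#' peptide, i.e. whether the peptide set carries every edge of the
#' reference's de Bruijn path at k-mer size k. When this fails, no
#' assembler can reconstruct the reference from the peptides alone: the
#' missing junctions are not present in the data.
#'
#' @param peptides character vector of peptides.
#' @param reference reference sequence.
#' @param k k-mer size.
#' @return logical.
#' @export
tiles_reference <- function(peptides, reference, k = 7L) {
  n <- nchar(reference)
  if (n <= k) return(TRUE)
  starts <- seq_len(n - k)
  windows <- substring(reference, starts, starts + k)
  covered <- unique(unlist(lapply(peptides, function(p) {
    np <- nchar(p)
    if (np < k + 1L) return(character(0))
    s <- seq_len(np - k)
    substring(p, s, s + k)
  })))
  all(windows %in% covered)
}

#' Random protein whose digest supports exact reconstruction
#'
#' Draws repeat-free random proteins (see [random_protein()]) until the
#' pooled digest of the given protease panel -- after the standard peptide
#' length filter -- tiles the sequence at k ([tiles_reference()]). Exact
#' assembly of a reference is only defined for proteins whose digest
#' retains every sequence junction, so conditioning the draw on tiling
#' separates "assembler correctness" from "digest informativeness". Uses
#' the current RNG state.
#'
#' @param length protein length in residues.
#' @param proteases list of [protease_rule()]s.
#' @param k k-mer size the digest must tile.
#' @param missed_cleavages digestion allowance (default 2).
#' @param min_len,max_len peptide length filter window applied to the
#'   digest before the tiling check (defaults 7 and 20, matching the PSM
#'   filter).
#' @param max_tries draw limit before giving up with an error.
#' @return an amino-acid string.
#' @export
random_tiled_protein <- function(length, proteases, k = 7L,
                                 missed_cleavages = 2L, min_len = 7L,
                                 max_len = 20L, max_tries = 1000L) {
  for (i in seq_len(max_tries)) {
    ref <- random_protein(length, k_unique = min(k, 6L))
    frags <- unlist(lapply(proteases, function(r) {
      digest(ref, r, missed_cleavages)
    }))
    frags <- frags[nchar(frags) >= min_len & nchar(frags) <= max_len]
    if (tiles_reference(frags, ref, k)) return(ref)
  }
  stop("no tiling reference found in ", max_tries, " draws; ",
       "use a denser protease panel or smaller k")
}

#' Simulate a multiprotease PSM table with ground truth
#'
#' Digests each reference with every protease in the panel (allowing missed
#' cleavages), pools fragments in a 5-25 residue window (so the downstream
#' 7-20 length filter is exercised), and samples \code{psms_per_protease}
#' peptides per protease with replacement -- replacement creates the
#' spectral multiplicity that weighted de Bruijn graph edges rely on. Noise
#' is then applied per PSM: random substitutions, N->D / Q->E deamidation,
#' spurious random-sequence PSMs at \code{false_psm_rate}, and occasional
#' "(ox)" modification tokens. Confidences are drawn from high (true) or
#' low (false) Beta distributions; q-values are oracle q-values derived
#' from the realized false/true mix along the confidence ranking (running
#' false fraction, made monotone), so FDR filtering at threshold t retains
#' a set whose realized false fraction is at most t by construction.
#'
#' @param references named character vector of reference protein sequences.
#' @param proteases list of [protease_rule()]s (default: the 10-enzyme
#'   panel).
#' @param noise a [noise_model()].
#' @param psms_per_protease PSMs sampled per protease (default 300), or
#'   \code{NULL} for exhaustive mode: every digest fragment in the length
#'   window is emitted exactly once per protease (the complete noiseless
#'   digest, useful for reconstruction fixtures).
#' @param missed_cleavages digestion missed-cleavage allowance (default 2).
#' @return list with \code{psms} (data.frame: spectrum_id, peptide,
#'   log_confidence, q_value, protease, source_file), \code{truth}
#'   (data.frame: spectrum_id, protein, start, end, is_false,
#'   n_substitutions, n_deamidations) and \code{mutations} (data.frame:
#'   spectrum_id, ref_pos, type, from, to).
#' @export
simulate_psm_table <- function(references, proteases = protease_panel(),
                               noise = noise_model(),
                               psms_per_protease = 300L,
                               missed_cleavages = 2L) {
  stopifnot(length(references) >= 1, all(nzchar(references)))
  if (is.null(names(references))) {
    names(references) <- sprintf("ref_%d", seq_along(references))
  }
  if (!is.null(noise$seed)) set.seed(noise$seed)

  rows <- list()
  mut_rows <- list()
  psm_i <- 0L
  for (rule in proteases) {
    # pooled digest of all references for this protease
    frag <- do.call(rbind, lapply(names(references), function(pn) {
      d <- digest(references[[pn]], rule, missed_cleavages,
                  with_positions = TRUE)
      if (nrow(d)) d$protein <- pn
      d
    }))
    frag <- frag[nchar(frag$peptide) >= 5 & nchar(frag$peptide) <= 25, ,
                 drop = FALSE]
    if (!nrow(frag)) next
    pick <- if (is.null(psms_per_protease)) {
      seq_len(nrow(frag))
    } else {
      sample.int(nrow(frag), psms_per_protease, replace = TRUE)
    }
    for (fi in pick) {
      psm_i <- psm_i + 1L
      sid <- sprintf("spec_%06d", psm_i)
      is_false <- stats::runif(1) < noise$false_psm_rate
      if (is_false) {
        pep <- .random_peptide(sample(5:25, 1))
        origin <- list(protein = NA_character_, start = NA_integer_,
                       end = NA_integer_)
        nsub <- 0L; ndeam <- 0L
      } else {
        pep_chars <- strsplit(frag$peptide[fi], "")[[1]]
        origin <- list(protein = frag$protein[fi], start = frag$start[fi],
                       end = frag$end[fi])
        nsub <- 0L; ndeam <- 0L
        for (p in seq_along(pep_chars)) {
          ref_pos <- origin$start + p - 1L
          ch <- pep_chars[p]
          if (ch %in% c("N", "Q") &&
              stats::runif(1) < noise$deamidation_rate) {
            new_ch <- if (ch == "N") "D" else "E"
            mut_rows[[length(mut_rows) + 1L]] <-
              data.frame(spectrum_id = sid, ref_pos = ref_pos,
                         type = "deamidation", from = ch, to = new_ch,
                         stringsAsFactors = FALSE)
            pep_chars[p] <- new_ch
            ndeam <- ndeam + 1L
          } else if (stats::runif(1) < noise$substitution_rate) {
            new_ch <- sample(setdiff(AA_ALPHABET, ch), 1)
            mut_rows[[length(mut_rows) + 1L]] <-
              data.frame(spectrum_id = sid, ref_pos = ref_pos,
                         type = "substitution", from = ch, to = new_ch,
                         stringsAsFactors = FALSE)
            pep_chars[p] <- new_ch
            nsub <- nsub + 1L
          }
        }
        pep <- paste(pep_chars, collapse = "")
      }
      shape <- if (is_false) noise$false_conf_shape else noise$true_conf_shape
      conf <- stats::rbeta(1, shape[1], shape[2])
      conf <- min(max(conf, 1e-12), 1 - 1e-12)
      # occasionally annotate an oxidized methionine
      pep_out <- pep
      if (grepl("M", pep, fixed = TRUE) &&
          stats::runif(1) < noise$mod_token_rate) {
        mpos <- which(strsplit(pep, "")[[1]] == "M")[1]
        pep_out <- paste0(substr(pep, 1, mpos), "(ox)",
                          substring(pep, mpos + 1))
      }
      rows[[psm_i]] <- data.frame(
        spectrum_id = sid, peptide = pep_out,
        log_confidence = log(conf),
        protease = rule$name,
        source_file = paste0(rule$name, "_run1.mzML"),
        is_false = is_false, protein = origin$protein,
        start = origin$start, end = origin$end,
        n_substitutions = nsub, n_deamidations = ndeam,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab)) stop("no peptides produced; check references and rules")

  # oracle q-values: running false fraction along the confidence ranking,
  # then the minimum over all equal-or-looser thresholds (monotone)
  ord <- order(-tab$log_confidence)
  fdr <- cumsum(tab$is_false[ord]) / seq_len(nrow(tab))
  qv <- rev(cummin(rev(fdr)))
  tab$q_value <- NA_real_
  tab$q_value[ord] <- qv

  psms <- tab[, c("spectrum_id", "peptide", "log_confidence", "q_value",
                  "protease", "source_file")]
  truth <- tab[, c("spectrum_id", "protein", "start", "end", "is_false",
                   "n_substitutions", "n_deamidations")]
  mutations <- if (length(mut_rows)) {
    do.call(rbind, mut_rows)
  } else {
    data.frame(spectrum_id = character(0), ref_pos = integer(0),
               type = character(0), from = character(0), to = character(0),
               stringsAsFactors = FALSE)
  }
  rownames(psms) <- rownames(truth) <- NULL
  list(psms = psms, truth = truth, mutations = mutations)
}
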