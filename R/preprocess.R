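AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Convert natural-log confidence scores to probabilities
#'
#' De novo sequencing engines report per-PSM confidence as a natural-log
#' probability (a value \eqn{\le 0}). This converts it to the probability
#' scale \eqn{[0, 1]} for interpretability and downstream filtering.
#'
#' Small positive inputs (rounding artifacts in upstream exports) raise a
#' warning, not an error; the result is clamped to \eqn{[0, 1]}.
#'
#' @param log_confidence numeric vector of ln-probabilities.
#' @return numeric vector of probabilities in \eqn{[0, 1]}.
#' @examples
#' exponentiate_confidence(c(0, -0.2231435513, -709))
#' @export
exponentiate_confidence <- function(log_confidence) {
  if (!is.numeric(log_confidence)) {
    bad <- which(is.na(suppressWarnings(as.numeric(log_confidence))))
    stop("log_confidence is not numeric (first offending row: ",
         if (length(bad)) bad[1] else 1, ")")
  }
  pos <- which(!is.na(log_confidence) & log_confidence > 0)
  if (length(pos)) {
    warning(length(pos), " log-confidence value(s) > 0 (e.g. row ", pos[1],
            "); clamping to probability 1")
  }
  pmin(pmax(exp(log_confidence), 0), 1)
}

#' Strip modification tokens from peptide strings
#'
#' Removes parenthesized and bracketed modification annotations (e.g.
#' \code{"(ox)"}, \code{"[+.98]"}) attached to residues, leaving the plain
#' amino-acid sequence. Both \code{(...)} and \code{[...]} dialects are
#' handled, including nested tokens.
#'
#' @param peptide character vector of possibly modified peptide strings.
#' @return character vector of plain sequences; residue order unchanged.
#' @examples
#' strip_modifications(c("SEQM(ox)K", "M(ox)N(+.98)K", "PEPTIDE"))
#' @export
strip_modifications <- function(peptide) {
  out <- peptide
  repeat {
    nxt <- gsub("\\([^][()]*\\)|\\[[^][()]*\\]", "", out)
    if (identical(nxt, out)) break
    out <- nxt
  }
  bad <- grepl("[][()]", out)
  if (any(bad)) {
    stop("unbalanced modification delimiters in peptide '",
         peptide[which(bad)[1]], "'")
  }
  out
}

#' Filtering configuration for PSM tables
#'
#' @param min_len,max_len retained peptide length window in residues
#'   (defaults 7 and 20).
#' @param fdr_threshold maximum q-value retained (default 0.10).
#' @param contaminants character vector of contaminant protein sequences;
#'   peptides contained in any of them (L/I-insensitively) are removed.
#'   \code{NULL} disables contaminant screening.
#' @param min_confidence optional minimum confidence in \eqn{[0,1]};
#'   \code{NULL} (default) disables the confidence gate.
#' @return a \code{filter_config} list.
#' @export
filter_config <- function(min_len = 7L, max_len = 20L, fdr_threshold = 0.10,
                          contaminants = NULL, min_confidence = NULL) {
  stopifnot(min_len >= 1, min_len <= max_len,
            fdr_threshold > 0, fdr_threshold <= 1)
  structure(list(min_len = as.integer(min_len), max_len = as.integer(max_len),
                 fdr_threshold = fdr_threshold,
                 contaminants = contaminants,
                 min_confidence = min_confidence),
            class = "filter_config")
}

#' Read a PSM table from CSV/TSV
#'
#' The delimiter is chosen from the file extension (\code{.csv} comma,
#' anything else tab). Required columns: \code{peptide} and at least one of
#' \code{log_confidence} / \code{confidence}; \code{q_value} is required
#' unless \code{no_fdr = TRUE}. Optional columns \code{protease},
#' \code{spectrum_id} and \code{source_file} are carried through. A
#' \code{confidence} column is derived from \code{log_confidence} when
#' absent.
#'
#' @param path path to the table.
#' @param no_fdr allow a missing \code{q_value} column (the FDR filter is
#'   then skipped downstream). Defaults to \code{FALSE}: a missing q-value
#'   column is an error, because silently skipping FDR control would change
#'   results.
#' @return a data.frame of PSM records.
#' @export
read_psm_table <- function(path, no_fdr = FALSE) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  if (!"peptide" %in% names(df)) stop("PSM table lacks a 'peptide' column")
  if (!"confidence" %in% names(df)) {
    if (!"log_confidence" %in% names(df)) {
      stop("PSM table needs a 'log_confidence' or 'confidence' column")
    }
    df$confidence <- exponentiate_confidence(df$log_confidence)
  }
  if (!"q_value" %in% names(df) && !no_fdr) {
    stop("PSM table has no 'q_value' column; pass no_fdr = TRUE to ",
         "deliberately skip FDR filtering")
  }
  df
}

#' Path to the bundled synthetic contaminant FASTA
#'
#' A small, clearly synthetic stand-in for the albumin/collagen-style
#' contaminant screens used in proteomics (collagen-like Gly-X-Y repeats and
#' generic carry-over sequences). Users with a real contaminant database
#' should pass their own FASTA instead.
#'
#' @return path to \code{contaminants_synthetic.fasta}.
#' @export
default_contaminant_fasta <- function() {
  system.file("extdata", "contaminants_synthetic.fasta", package = "pepnexus",
              mustWork = TRUE)
}

#' Read contaminant sequences from a FASTA file
#' @param path FASTA path; defaults to the bundled synthetic set.
#' @return named character vector of sequences.
#' @export
read_contaminants <- function(path = default_contaminant_fasta()) {
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Filter a PSM table for assembly
#'
#' Applies, in order: removal of rows with missing mandatory fields
#' (peptide, confidence, q-value when present), the peptide length window,
#' the FDR (q-value) threshold, the optional minimum-confidence gate, and
#' contaminant exclusion. Contaminant matching asks whether the stripped
#' peptide occurs as a substring of any contaminant sequence, treating L and
#' I as equivalent (they are isobaric and indistinguishable by standard MS).
#' Row order is preserved; an empty result is valid.
#'
#' Lengths and residue checks are computed on the stripped peptide; the
#' returned table gains \code{peptide_stripped} and \code{confidence}
#' columns if absent.
#'
#' @param psms data.frame as returned by [read_psm_table()].
#' @param cfg a [filter_config()].
#' @return the filtered data.frame.
#' @export
filter_psms <- function(psms, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  if (nrow(psms) == 0) {
    psms$peptide_stripped <- character(0)
    return(psms)
  }
  if (!"confidence" %in% names(psms)) {
    psms$confidence <- exponentiate_confidence(psms$log_confidence)
  }
  psms$peptide_stripped <- strip_modifications(psms$peptide)

  keep <- !is.na(psms$peptide) & nzchar(psms$peptide_stripped) &
    !is.na(psms$confidence)
  canonical <- vapply(
    strsplit(psms$peptide_stripped, ""),
    function(ch) all(ch %in% AA_ALPHABET), logical(1))
  keep <- keep & canonical
  len <- nchar(psms$peptide_stripped)
  keep <- keep & len >= cfg$min_len & len <= cfg$max_len
  if ("q_value" %in% names(psms)) {
    keep <- keep & !is.na(psms$q_value) & psms$q_value <= cfg$fdr_threshold
  }
  if (!is.null(cfg$min_confidence)) {
    keep <- keep & psms$confidence >= cfg$min_confidence
  }
  if (!is.null(cfg$contaminants) && length(cfg$contaminants)) {
    # L/I-insensitive substring containment against each contaminant
    pep_li <- chartr("I", "L", psms$peptide_stripped)
    cont_li <- chartr("I", "L", toupper(cfg$contaminants))
    hit <- rep(FALSE, nrow(psms))
    idx <- which(keep)
    for (cs in cont_li) {
      if (!length(idx)) break
      hit[idx] <- hit[idx] | vapply(pep_li[idx], grepl, logical(1),
                                    x = cs, fixed = TRUE)
      idx <- idx[!hit[idx]]
    }
    keep <- keep & !hit
  }
  psms[keep, , drop = FALSE]
}

#' Write unique filtered peptides to FASTA
#' @param psms filtered PSM table (needs \code{peptide_stripped}).
#' @param path output FASTA path.
#' @return \code{path}, invisibly.
#' @export
write_peptide_fasta <- function(psms, path) {
  seqs <- unique(psms$peptide_stripped)
  x <- Biostrings::AAStringSet(seqs)
  names(x) <- sprintf("peptide_%d", seq_along(seqs))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
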