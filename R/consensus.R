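# Amino-acid substitution matrices for the internal aligners. Deamidation
# pairs (N/D, Q/E) may be scored neutrally because the N->D and Q->E mass
# shifts are systematic chemical artifacts in MS data, not sequencing errors.
aa_substitution_matrix <- function(match = 2, mismatch = -1,
                                   li_equivalent = FALSE,
                                   deamidation_score = NULL) {
  m <- matrix(mismatch, 20, 20, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  diag(m) <- match
  if (li_equivalent) m["L", "I"] <- m["I", "L"] <- match
  if (!is.null(deamidation_score)) {
    m["N", "D"] <- m["D", "N"] <- deamidation_score
    m["Q", "E"] <- m["E", "Q"] <- deamidation_score
  }
  m
}

# Gap costs are affine: the first gap residue costs gap_open + gap_extend.
.align <- function(pattern, subject, type, submat, gap_open = 3,
                   gap_extend = 1) {
  Biostrings::pairwiseAlignment(pattern, subject, type = type,
                                substitutionMatrix = submat,
                                gapOpening = gap_open,
                                gapExtension = gap_extend)
}

.aligned_chars <- function(al) {
  list(pattern = strsplit(as.character(Biostrings::alignedPattern(al)),
                          "")[[1]],
       subject = strsplit(as.character(Biostrings::alignedSubject(al)),
                          "")[[1]])
}

#' Pairwise identity and target coverage
#'
#' Aligns query against target globally with free end gaps. Identity is the
#' fraction of matching columns among aligned (non-gap-pair) columns;
#' coverage is the fraction of the target sequence that is aligned.
#'
#' @param query,target non-empty amino-acid strings.
#' @return list with \code{identity} and \code{coverage}, both fractions.
#' @export
pairwise_identity_and_coverage <- function(query, target) {
  stopifnot(nzchar(query), nzchar(target))
  submat <- aa_substitution_matrix()
  al <- .align(query, target, "overlap", submat)
  ch <- .aligned_chars(al)
  aligned <- ch$pattern != "-" & ch$subject != "-"
  n_aligned <- sum(aligned)
  identity <- if (n_aligned) {
    sum(ch$pattern[aligned] == ch$subject[aligned]) / n_aligned
  } else 0
  coverage <- sum(ch$subject != "-") / nchar(target)
  list(identity = identity, coverage = min(coverage, 1))
}

#' Clustering parameters
#' @param identity_threshold minimum pairwise identity over the aligned
#'   region for a scaffold to join a cluster (default 0.85).
#' @param coverage_threshold minimum aligned fraction of the shorter of the
#'   two sequences (default 0.8), so that partially assembled scaffolds
#'   merge with their near-identical superstrings.
#' @return a \code{cluster_params} list.
#' @export
cluster_params <- function(identity_threshold = 0.85,
                           coverage_threshold = 0.8) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1,
            coverage_threshold >= 0, coverage_threshold <= 1)
  structure(list(identity_threshold = identity_threshold,
                 coverage_threshold = coverage_threshold),
            class = "cluster_params")
}

#' Greedy centroid clustering of scaffolds
#'
#' Scaffolds are processed in descending length (ties lexicographic). Each
#' joins the first existing cluster whose representative (its longest
#' member) it matches at identity >= \code{identity_threshold} with
#' coverage >= \code{coverage_threshold} of the shorter sequence; otherwise
#' it founds a new cluster. The procedure is deterministic and partitions
#' the input.
#'
#' @param scaffolds character vector of scaffold sequences or a
#'   \code{pn_scaffolds} data.frame.
#' @param params a [cluster_params()].
#' @return list of clusters, each a list with \code{members} (indices into
#'   the input), \code{sequences} and \code{representative}.
#' @export
cluster_scaffolds <- function(scaffolds, params = cluster_params()) {
  seqs <- if (is.data.frame(scaffolds)) scaffolds$sequence else scaffolds
  if (!length(seqs)) return(list())
  ord <- order(-nchar(seqs), seqs)
  # 4-mer prefilter: two sequences meeting the identity and coverage
  # thresholds necessarily share a sizable fraction of the shorter one's
  # 4-mers, so pairs sharing fewer than 15% are rejected without the
  # expense of an alignment (the same idea as the prefilter stages of
  # production clustering tools).
  kmer_set <- function(s) {
    n <- nchar(s)
    if (n < 4L) return(s)
    st <- seq_len(n - 3L)
    unique(substring(s, st, st + 3L))
  }
  ksets <- lapply(seqs, kmer_set)
  prefilter_pass <- function(i, j) {
    a <- ksets[[i]]; b <- ksets[[j]]
    short <- if (length(a) <= length(b)) a else b
    other <- if (length(a) <= length(b)) b else a
    mean(short %in% other) >= 0.15
  }
  clusters <- list()
  for (idx in ord) {
    s <- seqs[idx]
    placed <- FALSE
    for (ci in seq_along(clusters)) {
      rep_idx <- clusters[[ci]]$members[1]
      if (!prefilter_pass(idx, rep_idx)) next
      rep_seq <- clusters[[ci]]$representative
      target <- if (nchar(s) <= nchar(rep_seq)) s else rep_seq
      query <- if (nchar(s) <= nchar(rep_seq)) rep_seq else s
      r <- pairwise_identity_and_coverage(query, target)
      if (r$identity >= params$identity_threshold &&
          r$coverage >= params$coverage_threshold) {
        clusters[[ci]]$members <- c(clusters[[ci]]$members, idx)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      clusters[[length(clusters) + 1L]] <-
        list(members = idx, representative = s)
    }
  }
  lapply(clusters, function(cl) {
    list(members = cl$members, sequences = seqs[cl$members],
         representative = cl$representative)
  })
}

#' Align a cluster of near-identical sequences
#'
#' Representative-anchored progressive multiple alignment: every member is
#' aligned globally to the cluster representative (its longest member) and
#' the pairwise alignments are merged positionally, inserting the maximal
#' gap run observed after each representative position. Deterministic;
#' adequate for the near-identical (>= 85\% identity) members a cluster
#' contains. Singleton clusters are returned unchanged.
#'
#' @param sequences character vector; first element (or longest) is used as
#'   the anchor.
#' @return character vector of gapped rows of equal width, in input order.
#' @export
align_cluster <- function(sequences) {
  stopifnot(length(sequences) >= 1)
  if (length(sequences) == 1L) return(sequences)
  rep_idx <- order(-nchar(sequences), sequences)[1]
  rep_seq <- sequences[rep_idx]
  L <- nchar(rep_seq)
  submat <- aa_substitution_matrix()

  others <- setdiff(seq_along(sequences), rep_idx)
  # per member: residue (or gap) at each representative position, plus
  # insertion strings after representative positions 0..L
  parses <- lapply(others, function(i) {
    al <- .align(sequences[i], rep_seq, "global", submat)
    ch <- .aligned_chars(al)
    at <- character(L)
    ins <- vector("list", L + 1L)
    for (p0 in seq_len(L + 1L)) ins[[p0]] <- character(0)
    p <- 0L
    for (c in seq_along(ch$subject)) {
      if (ch$subject[c] != "-") {
        p <- p + 1L
        at[p] <- ch$pattern[c]
      } else {
        ins[[p + 1L]] <- c(ins[[p + 1L]], ch$pattern[c])
      }
    }
    list(at = at, ins = ins)
  })

  max_ins <- vapply(seq_len(L + 1L), function(p0) {
    if (!length(parses)) 0L else
      max(vapply(parses, function(pr) length(pr$ins[[p0]]), integer(1)))
  }, integer(1))

  pad <- function(chars, n) {
    c(chars, rep("-", n - length(chars)))
  }
  build_row <- function(at, ins) {
    parts <- character(0)
    for (p0 in seq_len(L + 1L)) {
      parts <- c(parts, pad(ins[[p0]], max_ins[p0]))
      if (p0 <= L) parts <- c(parts, at[p0])
    }
    paste(parts, collapse = "")
  }
  rep_row <- build_row(strsplit(rep_seq, "")[[1]],
                       rep(list(character(0)), L + 1L))
  rows <- character(length(sequences))
  rows[rep_idx] <- rep_row
  for (k in seq_along(others)) {
    rows[others[k]] <- build_row(parses[[k]]$at, parses[[k]]$ins)
  }
  rows
}

#' Build a position-specific scoring matrix from an alignment
#'
#' Per column, the relative frequency of each canonical residue among the
#' non-gap characters; gaps are excluded from the denominator. Columns
#' containing only gaps are marked empty (all-NA column).
#'
#' @param msa character vector of equal-length gapped rows.
#' @return a \code{pn_pssm}: list with \code{frequencies} (20 x ncol matrix,
#'   rows alphabetically named) and \code{n_sequences}.
#' @export
build_pssm <- function(msa) {
  stopifnot(length(msa) >= 1)
  widths <- nchar(msa)
  if (length(unique(widths)) != 1L) stop("alignment rows have unequal length")
  ncol <- widths[1]
  chars <- do.call(rbind, strsplit(msa, ""))
  freqs <- matrix(NA_real_, nrow = 20, ncol = ncol,
                  dimnames = list(AA_ALPHABET, NULL))
  for (j in seq_len(ncol)) {
    col <- chars[, j]
    res <- col[col != "-"]
    if (length(res)) {
      tab <- table(factor(res, levels = AA_ALPHABET))
      freqs[, j] <- as.numeric(tab) / length(res)
    }
  }
  structure(list(frequencies = freqs, n_sequences = length(msa)),
            class = "pn_pssm")
}

#' @export
print.pn_pssm <- function(x, ...) {
  cat("pn_pssm:", ncol(x$frequencies), "positions from", x$n_sequences,
      "sequence(s)\n")
  invisible(x)
}

#' Consensus sequence from a PSSM
#'
#' Per position, the residue with the highest frequency; all-gap columns are
#' omitted. Ties break by residue alphabetical order.
#'
#' @param pssm a \code{pn_pssm}.
#' @return consensus amino-acid string.
#' @export
consensus_from_pssm <- function(pssm) {
  f <- pssm$frequencies
  if (!ncol(f)) return("")
  picks <- vapply(seq_len(ncol(f)), function(j) {
    col <- f[, j]
    if (all(is.na(col))) return(NA_character_)
    rownames(f)[which.max(col)]  # rows are alphabetical; first max wins
  }, character(1))
  paste(picks[!is.na(picks)], collapse = "")
}

#' Cluster scaffolds and derive ranked consensus sequences
#'
#' Clusters scaffolds at the identity threshold, aligns each cluster, builds
#' its PSSM and emits the argmax consensus. Clusters are ranked by member
#' count, then by summed scaffold score when scores are available, then by
#' consensus sequence.
#'
#' @param scaffolds character vector or scored \code{pn_scaffolds}.
#' @param params a [cluster_params()].
#' @return data.frame (consensus, n_members, support_score) in rank order,
#'   with the cluster list in attribute \code{clusters}.
#' @export
consensus_pipeline <- function(scaffolds, params = cluster_params()) {
  seqs <- if (is.data.frame(scaffolds)) scaffolds$sequence else scaffolds
  scores <- if (is.data.frame(scaffolds) && "score" %in% names(scaffolds)) {
    scaffolds$score
  } else rep(0, length(seqs))
  clusters <- cluster_scaffolds(seqs, params)
  if (!length(clusters)) {
    return(structure(data.frame(consensus = character(0),
                                n_members = integer(0),
                                support_score = numeric(0),
                                stringsAsFactors = FALSE),
                     clusters = clusters))
  }
  cons <- vapply(clusters, function(cl) {
    consensus_from_pssm(build_pssm(align_cluster(cl$sequences)))
  }, character(1))
  n_members <- vapply(clusters, function(cl) length(cl$members), integer(1))
  support <- vapply(clusters, function(cl) sum(scores[cl$members]),
                    numeric(1))
  ord <- order(-n_members, -support, cons)
  structure(data.frame(consensus = cons[ord], n_members = n_members[ord],
                       support_score = support[ord],
                       stringsAsFactors = FALSE),
            clusters = clusters[ord])
}
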