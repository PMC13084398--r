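#' Parameters for the greedy overlap assembler
#'
#' @param min_overlap minimum exact suffix-prefix overlap, in residues,
#'   required to merge two sequences. The default of 3 is a deliberate floor:
#'   shorter overlaps routinely arise by chance between unrelated peptides
#'   and generate chimeric contigs. Setting a smaller value warns.
#' @param max_scaffold_rounds maximum assemble/deduplicate rounds for
#'   [iterative_scaffold()] (default 10).
#' @return a \code{greedy_params} list.
#' @export
greedy_params <- function(min_overlap = 3L, max_scaffold_rounds = 10L) {
  min_overlap <- as.integer(min_overlap)
  if (min_overlap < 3L) {
    warning("min_overlap < 3 invites spurious merges between unrelated peptides")
  }
  stopifnot(min_overlap >= 1L, max_scaffold_rounds >= 1L)
  structure(list(min_overlap = min_overlap,
                 max_scaffold_rounds = as.integer(max_scaffold_rounds)),
            class = "greedy_params")
}

#' Longest exact overlap between two sequences
#'
#' Detects, in order of precedence, containment (one sequence a substring of
#' the other, reported with the shorter sequence's length) and the longest
#' exact suffix-prefix overlap of at least \code{min_overlap} residues in
#' either orientation. Matching is exact character equality; L and I are
#' distinct here (their isobaric equivalence applies only when mapping
#' against a reference).
#'
#' @param a,b non-empty amino-acid strings.
#' @param min_overlap minimum qualifying overlap length.
#' @return a list with \code{kind} (one of \code{"contain_b_in_a"},
#'   \code{"contain_a_in_b"}, \code{"ab"} for suffix of \code{a} matching
#'   prefix of \code{b}, \code{"ba"}, \code{"none"}) and \code{length}.
#' @examples
#' find_overlap("ACDEFG", "EFGHIK", 3)  # suffix-prefix a->b, length 3
#' find_overlap("ACDEFG", "CDEF", 3)    # containment of b in a, length 4
#' @export
find_overlap <- function(a, b, min_overlap = 3L) {
  stopifnot(nzchar(a), nzchar(b))
  na <- nchar(a); nb <- nchar(b)
  if (nb <= na && grepl(b, a, fixed = TRUE)) {
    return(list(kind = "contain_b_in_a", length = nb))
  }
  if (na < nb && grepl(a, b, fixed = TRUE)) {
    return(list(kind = "contain_a_in_b", length = na))
  }
  m <- min(na, nb) - 1L
  best_len <- 0L; best_kind <- "none"
  if (m >= min_overlap) {
    ls <- seq.int(min_overlap, m)
    ok_ab <- substring(a, na - ls + 1L, na) == substring(b, 1L, ls)
    ok_ba <- substring(b, nb - ls + 1L, nb) == substring(a, 1L, ls)
    lab <- if (any(ok_ab)) max(ls[ok_ab]) else 0L
    lba <- if (any(ok_ba)) max(ls[ok_ba]) else 0L
    if (lab >= lba && lab > 0L) { best_len <- lab; best_kind <- "ab" }
    else if (lba > 0L) { best_len <- lba; best_kind <- "ba" }
  }
  list(kind = best_kind, length = best_len)
}

# Longest suffix(a)/prefix(b) overlap length (directed), 0 if < min_overlap.
.sp_overlap <- function(a, b, min_overlap) {
  na <- nchar(a); nb <- nchar(b)
  m <- min(na, nb) - 1L
  if (m < min_overlap) return(0L)
  ls <- seq.int(min_overlap, m)
  ok <- substring(a, na - ls + 1L, na) == substring(b, 1L, ls)
  if (any(ok)) max(ls[ok]) else 0L
}

.new_contigs <- function(sequence, n_peptides, support) {
  structure(data.frame(sequence = sequence, n_peptides = as.integer(n_peptides),
                       stringsAsFactors = FALSE),
            support = support, class = c("pn_contigs", "data.frame"))
}

#' @export
print.pn_contigs <- function(x, ...) {
  cat("pn_contigs:", nrow(x), "contig(s)\n")
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  invisible(x)
}

contig_support <- function(x) attr(x, "support", exact = TRUE)

# Absorb sequences fully contained in another; merge support. Keeps the
# longest representative of every containment chain.
.absorb_containments <- function(seqs, npep, supp) {
  ord <- order(-nchar(seqs), seqs)
  seqs <- seqs[ord]; npep <- npep[ord]; supp <- supp[ord]
  keep <- rep(TRUE, length(seqs))
  for (i in seq_along(seqs)) {
    if (!keep[i]) next
    if (i < length(seqs)) {
      js <- which(keep & seq_along(seqs) > i)
      for (j in js) {
        if (grepl(seqs[j], seqs[i], fixed = TRUE)) {
          npep[i] <- npep[i] + npep[j]
          supp[[i]] <- c(supp[[i]], supp[[j]])
          keep[j] <- FALSE
        }
      }
    }
  }
  list(seqs = seqs[keep], npep = npep[keep], supp = supp[keep])
}

#' Greedy longest-overlap-first assembly of peptides into contigs
#'
#' Exact duplicates are collapsed first (multiplicity recorded), sequences
#' contained in a longer sequence are absorbed, and then the pair with the
#' current longest suffix-prefix overlap is merged repeatedly until no pair
#' overlaps by at least \code{min_overlap} residues. Ties on overlap length
#' prefer the merge producing the longest result, then lexicographic order
#' of the two sequences, making the result independent of input order.
#'
#' @param peptides character vector of peptide sequences (names, if set, are
#'   used as support identifiers), or a \code{pn_contigs} object.
#' @param params a [greedy_params()].
#' @return a \code{pn_contigs} data.frame (sequence, n_peptides) with a
#'   \code{support} attribute listing contributing identifiers per contig.
#' @examples
#' greedy_assemble(c("ACDEFG", "EFGHIK"))$sequence  # "ACDEFGHIK"
#' @export
greedy_assemble <- function(peptides, params = greedy_params()) {
  if (inherits(peptides, "pn_contigs")) {
    seqs <- peptides$sequence
    npep <- peptides$n_peptides
    supp <- contig_support(peptides)
  } else {
    ids <- if (!is.null(names(peptides))) names(peptides) else
      sprintf("p%d", seq_along(peptides))
    tab <- split(ids, factor(peptides, levels = unique(peptides)))
    seqs <- names(tab)
    npep <- lengths(tab)
    supp <- unname(tab)
  }
  if (!length(seqs)) return(.new_contigs(character(0), integer(0), list()))
  min_ov <- params$min_overlap

  st <- .absorb_containments(seqs, npep, supp)
  # state keyed by stable integer ids so the overlap table survives merges
  seqs <- st$seqs; npep <- st$npep; supp <- st$supp
  ids <- seq_along(seqs)
  names(seqs) <- names(npep) <- names(supp) <- ids
  next_id <- length(seqs) + 1L

  ov_rows <- function(i, js) {
    # directed overlaps between id i and ids js, both orientations
    out <- vector("list", 2L * length(js))
    k <- 0L
    for (j in js) {
      l1 <- .sp_overlap(seqs[[as.character(i)]], seqs[[as.character(j)]], min_ov)
      if (l1 > 0L) { k <- k + 1L; out[[k]] <- c(i, j, l1) }
      l2 <- .sp_overlap(seqs[[as.character(j)]], seqs[[as.character(i)]], min_ov)
      if (l2 > 0L) { k <- k + 1L; out[[k]] <- c(j, i, l2) }
    }
    if (k) do.call(rbind, out[seq_len(k)]) else NULL
  }

  ov <- NULL
  if (length(ids) > 1L) {
    rows <- lapply(ids[-length(ids)],
                   function(i) ov_rows(i, ids[ids > i]))
    rows <- rows[!vapply(rows, is.null, logical(1))]
    ov <- if (length(rows)) do.call(rbind, rows) else NULL
  }

  while (!is.null(ov) && nrow(ov)) {
    sa <- seqs[as.character(ov[, 1])]
    sb <- seqs[as.character(ov[, 2])]
    len_merged <- nchar(sa) + nchar(sb) - ov[, 3]
    o <- order(-ov[, 3], -len_merged, sa, sb)
    pick <- ov[o[1], ]
    i <- pick[1]; j <- pick[2]; l <- pick[3]
    a <- seqs[[as.character(i)]]; b <- seqs[[as.character(j)]]
    merged <- paste0(a, substring(b, l + 1L))
    new_np <- npep[[as.character(i)]] + npep[[as.character(j)]]
    new_supp <- c(supp[[as.character(i)]], supp[[as.character(j)]])

    dropped <- c(i, j)
    # absorb anything now contained in the merged sequence
    others <- setdiff(as.integer(names(seqs)), dropped)
    if (length(others)) {
      contained <- others[vapply(seqs[as.character(others)], grepl, logical(1),
                                 x = merged, fixed = TRUE)]
      for (cid in contained) {
        new_np <- new_np + npep[[as.character(cid)]]
        new_supp <- c(new_supp, supp[[as.character(cid)]])
      }
      dropped <- c(dropped, contained)
    }
    keep_names <- setdiff(names(seqs), as.character(dropped))
    seqs <- seqs[keep_names]; npep <- npep[keep_names]; supp <- supp[keep_names]

    mid <- next_id; next_id <- next_id + 1L
    seqs[[as.character(mid)]] <- merged
    npep[[as.character(mid)]] <- new_np
    supp[[as.character(mid)]] <- new_supp

    ov <- ov[!(ov[, 1] %in% dropped | ov[, 2] %in% dropped), , drop = FALSE]
    rest <- setdiff(as.integer(names(seqs)), mid)
    if (length(rest)) {
      new_rows <- ov_rows(mid, rest)
      ov <- rbind(ov, new_rows)
    }
    if (is.null(ov) || !nrow(ov)) break
  }

  seqs <- unname(unlist(seqs))
  npep <- unname(unlist(npep))
  supp <- unname(supp)
  ord <- order(-nchar(seqs), seqs)
  .new_contigs(seqs[ord], npep[ord], supp[ord])
}

#' Remove duplicate and contained contigs
#'
#' Drops exact duplicates and any contig fully contained in a longer one
#' (support is merged into the surviving contig). Output is sorted by
#' descending length, ties broken lexicographically.
#'
#' @param contigs a \code{pn_contigs} object or character vector.
#' @return a \code{pn_contigs} object.
#' @export
deduplicate_contigs <- function(contigs) {
  if (!inherits(contigs, "pn_contigs")) {
    contigs <- .new_contigs(contigs, rep(1L, length(contigs)),
                            as.list(sprintf("c%d", seq_along(contigs))))
  }
  st <- .absorb_containments(contigs$sequence, contigs$n_peptides,
                             contig_support(contigs))
  ord <- order(-nchar(st$seqs), st$seqs)
  .new_contigs(st$seqs[ord], st$npep[ord], st$supp[ord])
}

#' Iterative scaffolding of contigs
#'
#' Alternates greedy assembly and deduplication over the current contig set
#' until the set no longer changes (a fixed point) or
#' \code{max_scaffold_rounds} is reached.
#'
#' @param contigs a \code{pn_contigs} object or character vector.
#' @param params a [greedy_params()].
#' @return a \code{pn_contigs} object with attributes \code{rounds} (rounds
#'   actually run) and \code{converged} (logical).
#' @export
iterative_scaffold <- function(contigs, params = greedy_params()) {
  cur <- deduplicate_contigs(contigs)
  converged <- FALSE
  rounds <- 0L
  for (r in seq_len(params$max_scaffold_rounds)) {
    rounds <- r
    nxt <- deduplicate_contigs(greedy_assemble(cur, params))
    if (identical(nxt$sequence, cur$sequence)) {
      converged <- TRUE
      cur <- nxt
      break
    }
    cur <- nxt
  }
  attr(cur, "rounds") <- rounds
  attr(cur, "converged") <- converged
  cur
}
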