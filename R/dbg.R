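#' Parameters for the weighted de Bruijn graph assembler
#'
#' @param k k-mer size for graph construction (default 7; 6 behaves
#'   similarly, other sizes markedly worse on peptide-scale data).
#' @param min_edge_weight minimum number of supporting (k+1)-mer occurrences
#'   for an edge to survive filtering (default 1, i.e. no filtering).
#' @param size_threshold minimum contig length (residues) retained after
#'   unitig extraction (default 15).
#' @param olc_min_overlap minimum exact suffix-prefix overlap for the
#'   overlap-layout-consensus refinement of contigs into scaffolds
#'   (default 5).
#' @param alpha,beta coefficients of the scaffold score
#'   \eqn{S = \alpha \ln(L) + \beta \bar{w} + 0.2\, w_{min}} on the length
#'   and mean-weight terms (defaults 1; the 0.2 minimum-weight penalty
#'   coefficient is fixed).
#' @param olc_rounds maximum refinement rounds (default 10).
#' @return a \code{dbg_params} list.
#' @export
dbg_params <- function(k = 7L, min_edge_weight = 1L, size_threshold = 15L,
                       olc_min_overlap = 5L, alpha = 1, beta = 1,
                       olc_rounds = 10L) {
  stopifnot(k >= 2L, min_edge_weight >= 1L, size_threshold >= 1L,
            olc_min_overlap >= 1L, olc_rounds >= 1L)
  structure(list(k = as.integer(k), min_edge_weight = as.integer(min_edge_weight),
                 size_threshold = as.integer(size_threshold),
                 olc_min_overlap = as.integer(olc_min_overlap),
                 alpha = alpha, beta = beta, w_min_coeff = 0.2,
                 olc_rounds = as.integer(olc_rounds)),
            class = "dbg_params")
}

#' Build a weighted de Bruijn graph from peptides
#'
#' Nodes are the k-mers observed across the peptides; a directed edge joins
#' two k-mers overlapping by k-1 residues, weighted by the number of
#' occurrences of the spanning (k+1)-mer over all peptides (duplicate
#' peptides therefore contribute their full multiplicity to edge weights).
#' Peptides shorter than k are skipped and counted in \code{n_skipped}.
#'
#' @param peptides character vector of peptide sequences (with duplicates
#'   representing spectral multiplicity).
#' @param k k-mer size.
#' @return a \code{kmer_graph}: list with \code{k}, \code{nodes},
#'   \code{edges} (data.frame from/to/weight) and \code{n_skipped}.
#' @examples
#' g <- build_kmer_graph(c("ACDEFGH", "DEFGHIK"), k = 4)
#' g$edges  # the DEFG -> EFGH edge carries weight 2
#' @export
build_kmer_graph <- function(peptides, k = 7L) {
  k <- as.integer(k)
  stopifnot(k >= 2L)
  len <- nchar(peptides)
  skipped <- sum(len < k)
  if (skipped > 0) {
    message(skipped, " peptide(s) shorter than k = ", k, " skipped")
  }
  use <- peptides[len >= k]
  if (!length(use)) {
    return(structure(list(k = k, nodes = character(0),
                          edges = data.frame(from = character(0),
                                             to = character(0),
                                             weight = integer(0),
                                             stringsAsFactors = FALSE),
                          n_skipped = skipped),
                     class = "kmer_graph"))
  }
  kmers_of <- function(p, w) {
    n <- nchar(p)
    if (n < w) return(character(0))
    starts <- seq_len(n - w + 1L)
    substring(p, starts, starts + w - 1L)
  }
  nodes <- sort(unique(unlist(lapply(use, kmers_of, w = k))))
  spans <- unlist(lapply(use, kmers_of, w = k + 1L))
  if (length(spans)) {
    tab <- table(spans)
    edges <- data.frame(from = substr(names(tab), 1L, k),
                        to = substr(names(tab), 2L, k + 1L),
                        weight = as.integer(tab),
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(from = character(0), to = character(0),
                        weight = integer(0), stringsAsFactors = FALSE)
  }
  structure(list(k = k, nodes = nodes, edges = edges, n_skipped = skipped),
            class = "kmer_graph")
}

#' @export
print.kmer_graph <- function(x, ...) {
  cat("kmer_graph: k =", x$k, "|", length(x$nodes), "nodes |",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Drop weakly supported edges from a k-mer graph
#' @param graph a \code{kmer_graph}.
#' @param min_edge_weight minimum retained edge weight.
#' @return the filtered \code{kmer_graph} (nodes are kept even if isolated).
#' @export
filter_edges <- function(graph, min_edge_weight = 1L) {
  graph$edges <- graph$edges[graph$edges$weight >= min_edge_weight, ,
                             drop = FALSE]
  rownames(graph$edges) <- NULL
  graph
}

.new_dbg_contigs <- function(sequence, weights) {
  w_mean <- vapply(weights, function(w) if (length(w)) mean(w) else 0,
                   numeric(1))
  w_min <- vapply(weights, function(w) if (length(w)) min(w) else 0,
                  numeric(1))
  structure(data.frame(sequence = sequence, length = nchar(sequence),
                       w_mean = w_mean, w_min = w_min,
                       stringsAsFactors = FALSE),
            weights = weights, class = c("pn_dbg_contigs", "data.frame"))
}

contig_weights <- function(x) attr(x, "weights", exact = TRUE)

#' Extract unitigs (maximal unambiguous paths) from a k-mer graph
#'
#' Traverses maximal non-branching paths: extension continues only through
#' nodes with in-degree and out-degree exactly 1, so no contig spans an
#' ambiguous branch. Traversal stops at the first revisited node, which
#' terminates cleanly inside repeats (cycles). Each contig of p nodes spells
#' a sequence of p + k - 1 residues and carries the weights of its traversed
#' edges; contigs shorter than \code{size_threshold} are dropped.
#'
#' @param graph a \code{kmer_graph}, already edge-filtered if desired.
#' @param size_threshold minimum contig length in residues.
#' @return a \code{pn_dbg_contigs} data.frame (sequence, length, w_mean,
#'   w_min) with the per-contig edge-weight lists in attribute
#'   \code{weights}.
#' @export
extract_unitigs <- function(graph, size_threshold = 1L) {
  k <- graph$k
  e <- graph$edges
  nodes <- graph$nodes
  if (!length(nodes)) return(.new_dbg_contigs(character(0), list()))

  out_adj <- split(seq_len(nrow(e)), factor(e$from, levels = nodes))
  indeg <- table(factor(e$to, levels = nodes))
  outdeg <- lengths(out_adj)
  simple <- indeg == 1L & outdeg == 1L  # interior-eligible nodes

  spell <- function(path_nodes) {
    paste0(path_nodes[1], paste(substr(path_nodes[-1], k, k), collapse = ""))
  }

  used_edge <- rep(FALSE, nrow(e))
  seqs <- character(0); wts <- list()

  walk_from <- function(eidx) {
    # follow a chain of edges starting with edge eidx
    path <- c(e$from[eidx], e$to[eidx])
    ws <- e$weight[eidx]
    used_edge[eidx] <<- TRUE
    cur <- e$to[eidx]
    seen <- path
    while (simple[[cur]]) {
      nxt_e <- out_adj[[cur]][1]
      if (used_edge[nxt_e]) break
      nxt <- e$to[nxt_e]
      if (nxt %in% seen) {  # cycle: stop at first revisited node
        used_edge[nxt_e] <<- TRUE
        ws <- c(ws, e$weight[nxt_e])
        path <- c(path, nxt)
        break
      }
      used_edge[nxt_e] <<- TRUE
      ws <- c(ws, e$weight[nxt_e])
      path <- c(path, nxt)
      seen <- c(seen, nxt)
      cur <- nxt
    }
    list(seq = spell(path), w = ws)
  }

  # paths start on edges leaving a non-simple node
  starts <- nodes[outdeg >= 1L & !simple]
  for (v in starts) {
    for (eidx in out_adj[[v]]) {
      if (used_edge[eidx]) next
      r <- walk_from(eidx)
      seqs <- c(seqs, r$seq); wts <- c(wts, list(r$w))
    }
  }
  # leftover edges belong to isolated cycles; start at the smallest node
  remaining <- which(!used_edge)
  while (length(remaining)) {
    eidx <- remaining[order(e$from[remaining])][1]
    r <- walk_from(eidx)
    seqs <- c(seqs, r$seq); wts <- c(wts, list(r$w))
    remaining <- which(!used_edge)
  }
  # isolated nodes (no incident surviving edge) spell themselves
  touched <- unique(c(e$from, e$to))
  iso <- setdiff(nodes, touched)
  if (length(iso)) {
    seqs <- c(seqs, iso)
    wts <- c(wts, rep(list(numeric(0)), length(iso)))
  }

  keep <- nchar(seqs) >= size_threshold
  seqs <- seqs[keep]; wts <- wts[keep]
  ord <- order(-nchar(seqs), seqs)
  .new_dbg_contigs(seqs[ord], wts[ord])
}

#' Overlap-layout-consensus refinement of contigs into scaffolds
#'
#' Contigs become nodes of a higher-order overlap layout and are iteratively
#' merged on exact suffix-prefix overlaps of at least
#' \code{olc_min_overlap} residues, with the same longest-overlap-first
#' mechanics and tie-breaks as the greedy assembler, until a fixed point or
#' \code{rounds} is reached. Contained contigs are absorbed (the container's
#' weight list is kept); merged scaffolds concatenate their constituents'
#' edge-weight lists, and \code{w_mean}/\code{w_min} are recomputed over the
#' combined list.
#'
#' @param contigs a \code{pn_dbg_contigs} object (or character vector, in
#'   which case empty weight lists are assumed).
#' @param olc_min_overlap minimum qualifying overlap (residues).
#' @param rounds maximum merge rounds.
#' @return a \code{pn_scaffolds} data.frame (sequence, L, w_mean, w_min)
#'   without scores; see [score_scaffolds()].
#' @export
olc_refine <- function(contigs, olc_min_overlap = 5L, rounds = 10L) {
  if (!inherits(contigs, "pn_dbg_contigs")) {
    contigs <- .new_dbg_contigs(contigs,
                                rep(list(numeric(0)), length(contigs)))
  }
  seqs <- contigs$sequence
  wts <- contig_weights(contigs)

  absorb <- function(seqs, wts) {
    ord <- order(-nchar(seqs), seqs)
    seqs <- seqs[ord]; wts <- wts[ord]
    keep <- rep(TRUE, length(seqs))
    for (i in seq_along(seqs)) {
      if (!keep[i]) next
      js <- which(keep & seq_along(seqs) > i)
      for (j in js) {
        if (grepl(seqs[j], seqs[i], fixed = TRUE)) keep[j] <- FALSE
      }
    }
    list(seqs = seqs[keep], wts = wts[keep])
  }

  best_pair <- function(seqs) {
    n <- length(seqs)
    best <- NULL
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        l <- .sp_overlap(seqs[i], seqs[j], olc_min_overlap)
        if (l > 0L) {
          cand <- c(l, nchar(seqs[i]) + nchar(seqs[j]) - l, i, j)
          if (is.null(best) ||
              cand[1] > best[1] ||
              (cand[1] == best[1] && (cand[2] > best[2] ||
                (cand[2] == best[2] &&
                 (seqs[i] < seqs[best[3]] ||
                  (seqs[i] == seqs[best[3]] && seqs[j] < seqs[best[4]])))))) {
            best <- cand
          }
        }
      }
    }
    best
  }

  for (r in seq_len(rounds)) {
    before <- sort(seqs)
    st <- absorb(seqs, wts)
    seqs <- st$seqs; wts <- st$wts
    # merge to exhaustion within the round
    repeat {
      if (length(seqs) < 2L) break
      best <- best_pair(seqs)
      if (is.null(best)) break
      i <- best[3]; j <- best[4]; l <- best[1]
      merged <- paste0(seqs[i], substring(seqs[j], l + 1L))
      mw <- c(wts[[i]], wts[[j]])
      keep <- setdiff(seq_along(seqs), c(i, j))
      seqs <- c(seqs[keep], merged)
      wts <- c(wts[keep], list(mw))
      st <- absorb(seqs, wts)
      seqs <- st$seqs; wts <- st$wts
    }
    if (identical(sort(seqs), before)) break
  }
  st <- absorb(seqs, wts)
  scaffolds_from_contigs(.new_dbg_contigs(st$seqs, st$wts))
}

scaffolds_from_contigs <- function(contigs) {
  structure(data.frame(sequence = contigs$sequence, L = contigs$length,
                       w_mean = contigs$w_mean, w_min = contigs$w_min,
                       stringsAsFactors = FALSE),
            weights = contig_weights(contigs),
            class = c("pn_scaffolds", "data.frame"))
}

#' Post-assembly scaffold score
#'
#' \deqn{S = \alpha \ln(L) + \beta \bar{w} + 0.2\, w_{min}}
#'
#' The log-length term makes the marginal reward of added length decrease as
#' the assembly grows (contiguity without rewarding chimeric over-extension),
#' the mean path weight rewards scaffolds backed by frequent spectral
#' observations, and the minimum edge weight, at a fixed penalty coefficient
#' of 0.2, demands continuous support with no tenuous low-frequency link.
#'
#' @param L scaffold length in residues (\eqn{\ge 1}).
#' @param w_mean mean edge weight along the scaffold's path.
#' @param w_min minimum edge weight along the path.
#' @param alpha,beta coefficients of the length and mean-weight terms.
#' @return the score S (vectorized).
#' @examples
#' score_scaffold(1, 2, 1)               # 2.2
#' score_scaffold(10, 3, 2) - score_scaffold(10, 3, 1)  # 0.2
#' @export
score_scaffold <- function(L, w_mean, w_min, alpha = 1, beta = 1) {
  if (any(L < 1)) stop("scaffold length L must be >= 1")
  alpha * log(L) + beta * w_mean + 0.2 * w_min
}

#' Attach scores to a scaffold table
#' @param scaffolds a \code{pn_scaffolds} data.frame.
#' @param alpha,beta score coefficients.
#' @return the same table with a \code{score} column.
#' @export
score_scaffolds <- function(scaffolds, alpha = 1, beta = 1) {
  scaffolds$score <- if (nrow(scaffolds)) {
    score_scaffold(scaffolds$L, scaffolds$w_mean, scaffolds$w_min,
                   alpha, beta)
  } else numeric(0)
  scaffolds
}

#' Rank scaffolds by score
#'
#' Descending score; ties broken by descending length, then lexicographic
#' sequence, so the ranking is deterministic.
#'
#' @param scaffolds a scored \code{pn_scaffolds} data.frame.
#' @return the reordered table with a \code{rank} column.
#' @export
rank_scaffolds <- function(scaffolds) {
  if (!nrow(scaffolds)) {
    scaffolds$rank <- integer(0)
    return(scaffolds)
  }
  w <- attr(scaffolds, "weights", exact = TRUE)
  ord <- order(-scaffolds$score, -scaffolds$L, scaffolds$sequence)
  out <- scaffolds[ord, , drop = FALSE]
  rownames(out) <- NULL
  out$rank <- seq_len(nrow(out))
  if (!is.null(w)) attr(out, "weights") <- w[ord]
  out
}

#' Full de Bruijn graph assembly of a peptide set
#'
#' Convenience wrapper: graph construction, edge filtering, unitig
#' extraction, OLC refinement, scoring and ranking.
#'
#' @param peptides character vector of peptides (duplicates carry
#'   multiplicity into edge weights).
#' @param params a [dbg_params()].
#' @return a ranked, scored \code{pn_scaffolds} data.frame.
#' @export
dbg_assemble <- function(peptides, params = dbg_params()) {
  g <- build_kmer_graph(peptides, params$k)
  g <- filter_edges(g, params$min_edge_weight)
  contigs <- extract_unitigs(g, params$size_threshold)
  sc <- olc_refine(contigs, params$olc_min_overlap, params$olc_rounds)
  rank_scaffolds(score_scaffolds(sc, params$alpha, params$beta))
}

#' Write a k-mer graph as a GFA-like TSV (from, to, weight)
#' @param graph a \code{kmer_graph}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_graph_tsv <- function(graph, path) {
  utils::write.table(graph$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
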