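#' Alignment scoring constants for reference mapping
#'
#' Fixed, documented defaults: match +2 (with L and I treated as equivalent,
#' since they are isobaric and indistinguishable in standard MS
#' fragmentation), mismatch -1, deamidation pairs (reference N vs D,
#' reference Q vs E) 0, and affine gaps costing 4 for the first gap residue
#' and 1 for each additional one.
#'
#' @param match,mismatch,deamidation substitution scores.
#' @param gap_open,gap_extend affine gap costs (positive numbers; a gap of
#'   length g costs \code{gap_open + g * gap_extend}).
#' @return a \code{mapping_scoring} list.
#' @export
mapping_scoring <- function(match = 2, mismatch = -1, deamidation = 0,
                            gap_open = 3, gap_extend = 1) {
  structure(list(match = match, mismatch = mismatch,
                 deamidation = deamidation,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "mapping_scoring")
}

#' Map a scaffold to a reference sequence
#'
#' Best local alignment of the scaffold against the reference under the
#' scoring of [mapping_scoring()]. Each aligned (non-gap-pair) column is
#' classified as \code{match} (including L/I equivalence), \code{mismatch},
#' or \code{deamidation_sub} (reference N aligned to scaffold D, or
#' reference Q to scaffold E). Deamidation columns count as mismatches for
#' identity but are reported separately. Coordinates on the reference are
#' 1-based and inclusive.
#'
#' @param scaffold,reference non-empty amino-acid strings.
#' @param scoring a [mapping_scoring()].
#' @return list with \code{start}, \code{end} (aligned span on the
#'   reference), \code{identity}, \code{n_aligned}, \code{column_classes}
#'   (named by reference position for reference-consuming columns), and
#'   \code{n_deamidation}.
#' @examples
#' map_to_reference("PEPTLDE", "PEPTIDE")$identity  # 1 (L/I equivalent)
#' @export
map_to_reference <- function(scaffold, reference,
                             scoring = mapping_scoring()) {
  stopifnot(nzchar(scaffold), nzchar(reference))
  submat <- aa_substitution_matrix(match = scoring$match,
                                   mismatch = scoring$mismatch,
                                   li_equivalent = TRUE,
                                   deamidation_score = scoring$deamidation)
  al <- .align(scaffold, reference, "local", submat,
               gap_open = scoring$gap_open, gap_extend = scoring$gap_extend)
  ch <- .aligned_chars(al)
  ref_start <- Biostrings::start(Biostrings::subject(al))
  ref_end <- Biostrings::end(Biostrings::subject(al))

  aligned <- ch$pattern != "-" & ch$subject != "-"
  refpos <- ref_start - 1L + cumsum(ch$subject != "-")
  classes <- character(0)
  if (any(aligned)) {
    s <- ch$pattern[aligned]  # scaffold residues
    r <- ch$subject[aligned]  # reference residues
    is_match <- s == r | (s == "L" & r == "I") | (s == "I" & r == "L")
    is_deam <- (r == "N" & s == "D") | (r == "Q" & s == "E")
    classes <- ifelse(is_match, "match",
                      ifelse(is_deam, "deamidation_sub", "mismatch"))
    names(classes) <- refpos[aligned]
  }
  n_aligned <- length(classes)
  identity <- if (n_aligned) sum(classes == "match") / n_aligned else 0
  list(start = ref_start, end = ref_end, identity = identity,
       n_aligned = n_aligned, column_classes = classes,
       n_deamidation = sum(classes == "deamidation_sub"))
}

#' Reference coverage by qualifying mappings
#'
#' Fraction of the reference covered by the union of the aligned spans of
#' mappings whose identity meets \code{min_identity}.
#'
#' @param mappings list of results from [map_to_reference()].
#' @param reference_length reference length in residues.
#' @param min_identity minimum mapping identity for a span to qualify.
#' @return coverage fraction in \eqn{[0, 1]}.
#' @export
reference_coverage <- function(mappings, reference_length,
                               min_identity = 0.9) {
  covered <- logical(reference_length)
  for (m in mappings) {
    if (m$identity >= min_identity && m$n_aligned > 0) {
      covered[m$start:m$end] <- TRUE
    }
  }
  sum(covered) / reference_length
}

#' N50 of a set of sequence lengths
#'
#' The shortest length needed to cover 50\% of the total assembled length:
#' lengths are sorted descending and the first length at which the
#' cumulative sum reaches half the total is returned.
#'
#' @param lengths non-empty numeric vector of sequence lengths.
#' @return the N50 length.
#' @examples
#' n50(c(5, 4, 3, 2, 1))  # 4
#' @export
n50 <- function(lengths) {
  if (!length(lengths)) stop("n50 of an empty length set is undefined")
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' Assembly precision
#'
#' Fraction of scaffolds mapping to the reference with identity of at least
#' \code{min_identity} (default 0.40, chosen to exclude spurious noise
#' alignments while retaining homologous segments).
#'
#' @param mappings list of mapping results.
#' @param n_scaffolds total scaffold count (\eqn{\ge 1}).
#' @param min_identity qualifying identity threshold.
#' @return precision fraction.
#' @export
precision <- function(mappings, n_scaffolds = length(mappings),
                      min_identity = 0.40) {
  stopifnot(n_scaffolds >= 1)
  ids <- vapply(mappings, `[[`, numeric(1), "identity")
  sum(ids >= min_identity) / n_scaffolds
}

#' Mean identity of reliably mapped scaffolds
#'
#' Mean mapping identity over scaffolds with identity of at least
#' \code{min_identity} (default 0.70), focusing the metric on reliably
#' identified regions. Defined as 0 when no mapping qualifies.
#'
#' @param mappings list of mapping results.
#' @param min_identity qualifying identity threshold.
#' @return mean identity fraction.
#' @export
mean_identity <- function(mappings, min_identity = 0.70) {
  ids <- vapply(mappings, `[[`, numeric(1), "identity")
  ids <- ids[ids >= min_identity]
  if (!length(ids)) 0 else mean(ids)
}

#' Min-Max normalization to [0, 1]
#'
#' Linear rescaling \eqn{(v - min) / (max - min)}. When all values are
#' equal the scale is degenerate and every value maps to 1.
#'
#' @param values non-empty numeric vector.
#' @return numeric vector in \eqn{[0, 1]}.
#' @export
min_max_normalize <- function(values) {
  stopifnot(length(values) >= 1)
  rng <- range(values)
  if (rng[1] == rng[2]) return(rep(1, length(values)))
  (values - rng[1]) / (rng[2] - rng[1])
}

#' Composite score weights
#'
#' Coverage carries the highest weight (0.35) as the primary indicator of
#' how much of the target the data support; N50 (0.25) captures contiguity;
#' scaffold count (0.25) penalizes fragmentation via inverted normalization;
#' mean identity (0.15) reflects accuracy. Weights must sum to 1.
#'
#' @param coverage,n50,scaffold_count,mean_identity metric weights.
#' @return a \code{composite_weights} list.
#' @export
composite_weights <- function(coverage = 0.35, n50 = 0.25,
                              scaffold_count = 0.25, mean_identity = 0.15) {
  w <- list(coverage = coverage, n50 = n50, scaffold_count = scaffold_count,
            mean_identity = mean_identity)
  if (abs(sum(unlist(w)) - 1) > 1e-9) stop("composite weights must sum to 1")
  structure(w, class = "composite_weights")
}

#' Weighted composite assembly score
#'
#' Dot product of the normalized metric vector with the weight vector,
#' using an inverted normalization (1 - value) for scaffold count so that
#' less fragmented assemblies score higher:
#' \deqn{0.35\,C + 0.25\,N50 + 0.25\,(1 - S) + 0.15\,I}
#'
#' All inputs must already be Min-Max normalized to \eqn{[0, 1]}.
#'
#' @param coverage,n50,scaffold_count,mean_identity normalized metrics.
#' @param weights a [composite_weights()].
#' @return composite score in \eqn{[0, 1]} (vectorized).
#' @export
composite_score <- function(coverage, n50, scaffold_count, mean_identity,
                            weights = composite_weights()) {
  vals <- c(coverage, n50, scaffold_count, mean_identity)
  if (any(vals < 0 | vals > 1)) {
    stop("composite_score inputs must be normalized to [0, 1]")
  }
  unname(weights$coverage * coverage + weights$n50 * n50 +
           weights$scaffold_count * (1 - scaffold_count) +
           weights$mean_identity * mean_identity)
}

#' Assembly quality score (AQS)
#'
#' \deqn{AQS = 100 \times \frac{C_{norm} \times I_{norm} \times
#'   P_{norm}}{\log_{10}(N + 9)}}
#'
#' where \eqn{C_{norm}}, \eqn{I_{norm}}, \eqn{P_{norm}} are the normalized
#' (0-1) coverage, mean identity and precision, and N is the total scaffold
#' count. The +9 regularization makes the fragmentation penalty equal 1 for
#' an ideal single-scaffold assembly, so a perfect one-scaffold
#' reconstruction scores exactly 100.
#'
#' @param c_norm,i_norm,p_norm normalized coverage, mean identity,
#'   precision, each in \eqn{[0, 1]}.
#' @param n total scaffold count (\eqn{\ge 1}).
#' @return the AQS value.
#' @examples
#' aqs(1, 1, 1, 1)   # 100
#' aqs(1, 1, 1, 91)  # 50
#' @export
aqs <- function(c_norm, i_norm, p_norm, n) {
  if (any(n < 1)) stop("scaffold count N must be >= 1")
  vals <- c(c_norm, i_norm, p_norm)
  if (any(vals < 0 | vals > 1)) stop("AQS inputs must be in [0, 1]")
  100 * (c_norm * i_norm * p_norm) / log10(n + 9)
}

#' Evaluate an assembly against a reference
#'
#' Maps every scaffold to the reference and assembles the full metric set:
#' high-confidence coverage (spans at >= 90\% identity), permissive coverage
#' (>= 40\%), N50 of scaffold lengths, precision (>= 40\% identity), mean
#' identity (over >= 70\% identity mappings), scaffold count, and the AQS
#' (computed from high-confidence coverage, mean identity and precision,
#' which are already 0-1 fractions). The composite score requires a
#' comparison set and is added by [compare_assemblies()].
#'
#' @param scaffolds character vector of scaffold sequences (or a
#'   \code{pn_scaffolds} data.frame).
#' @param reference reference protein sequence.
#' @param scoring a [mapping_scoring()].
#' @param high_conf_identity identity threshold for high-confidence
#'   coverage (default 0.9).
#' @return an \code{assembly_metrics} list; the per-scaffold mappings are
#'   kept in its \code{mappings} element.
#' @export
evaluate_assembly <- function(scaffolds, reference,
                              scoring = mapping_scoring(),
                              high_conf_identity = 0.9) {
  seqs <- if (is.data.frame(scaffolds)) scaffolds$sequence else scaffolds
  stopifnot(nzchar(reference))
  if (!length(seqs)) {
    return(structure(list(n_scaffolds = 0L, coverage = 0,
                          high_conf_coverage = 0, n50 = 0,
                          precision = 0, mean_identity = 0, aqs = 0,
                          mappings = list()),
                     class = "assembly_metrics"))
  }
  maps <- lapply(seqs, map_to_reference, reference = reference,
                 scoring = scoring)
  rl <- nchar(reference)
  n <- length(seqs)
  prec <- precision(maps, n)
  mid <- mean_identity(maps)
  hicov <- reference_coverage(maps, rl, min_identity = high_conf_identity)
  structure(list(
    n_scaffolds = n,
    coverage = reference_coverage(maps, rl, min_identity = 0.40),
    high_conf_coverage = hicov,
    n50 = n50(nchar(seqs)),
    precision = prec,
    mean_identity = mid,
    aqs = aqs(hicov, mid, prec, n),
    mappings = maps
  ), class = "assembly_metrics")
}

#' @export
print.assembly_metrics <- function(x, ...) {
  cat(sprintf(paste0("assembly_metrics: %d scaffold(s) | coverage %.3f ",
                     "(high-conf %.3f) | N50 %d | precision %.3f | ",
                     "mean identity %.3f | AQS %.2f\n"),
              x$n_scaffolds, x$coverage, x$high_conf_coverage, x$n50,
              x$precision, x$mean_identity, x$aqs))
  if (!is.null(x$composite)) cat(sprintf("  composite %.4f\n", x$composite))
  invisible(x)
}

#' Add composite scores across a set of assemblies
#'
#' Min-Max normalizes coverage, N50, scaffold count and mean identity across
#' the assemblies being compared in this call and computes each assembly's
#' weighted composite score (inverted normalization for scaffold count).
#'
#' @param metrics_list list of \code{assembly_metrics}.
#' @param weights a [composite_weights()].
#' @return the list with a \code{composite} element added to each entry.
#' @export
compare_assemblies <- function(metrics_list, weights = composite_weights()) {
  stopifnot(length(metrics_list) >= 1)
  get <- function(f) vapply(metrics_list, `[[`, numeric(1), f)
  cov_n <- min_max_normalize(get("coverage"))
  n50_n <- min_max_normalize(get("n50"))
  cnt_n <- min_max_normalize(get("n_scaffolds"))
  id_n <- min_max_normalize(get("mean_identity"))
  for (i in seq_along(metrics_list)) {
    metrics_list[[i]]$composite <-
      composite_score(cov_n[i], n50_n[i], cnt_n[i], id_n[i], weights)
  }
  metrics_list
}
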