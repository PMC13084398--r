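#' Hyperparameter grid definition
#'
#' Finite candidate lists for the six tunable assembly parameters: k-mer
#' size, minimum OLC overlap, minimum contig size threshold, minimum edge
#' weight, FDR threshold, and refinement rounds. The total number of
#' configurations is the product of the list lengths.
#'
#' @param k_values,min_overlap_values,size_threshold_values numeric vectors.
#' @param min_edge_weight_values,fdr_values,refinement_round_values numeric
#'   vectors.
#' @return a \code{param_grid} list.
#' @export
param_grid <- function(k_values = c(6, 7),
                       min_overlap_values = c(4, 5),
                       size_threshold_values = c(10, 15),
                       min_edge_weight_values = c(1, 2),
                       fdr_values = 0.10,
                       refinement_round_values = 10) {
  g <- list(k = k_values, min_overlap = min_overlap_values,
            size_threshold = size_threshold_values,
            min_edge_weight = min_edge_weight_values,
            fdr = fdr_values, refinement_rounds = refinement_round_values)
  if (any(!lengths(g))) stop("every grid dimension needs at least one value")
  structure(g, class = "param_grid")
}

#' Enumerate all grid configurations
#'
#' Full Cartesian product in lexicographic order of the field lists (the
#' first field varies slowest).
#'
#' @param grid a [param_grid()].
#' @return data.frame with one row per configuration.
#' @export
enumerate_configs <- function(grid) {
  stopifnot(inherits(grid, "param_grid"))
  df <- expand.grid(rev(unclass(grid)), KEEP.OUT.ATTRS = FALSE,
                    stringsAsFactors = FALSE)
  df <- df[, rev(names(df)), drop = FALSE]
  rownames(df) <- NULL
  df
}

.run_one_config <- function(cfg, psms, reference, contaminants) {
  fc <- filter_config(fdr_threshold = cfg$fdr, contaminants = contaminants)
  clean <- filter_psms(psms, fc)
  dp <- dbg_params(k = cfg$k, min_edge_weight = cfg$min_edge_weight,
                   size_threshold = cfg$size_threshold,
                   olc_min_overlap = cfg$min_overlap,
                   olc_rounds = cfg$refinement_rounds)
  scaffolds <- dbg_assemble(clean$peptide_stripped, dp)
  evaluate_assembly(scaffolds, reference)
}

#' Exhaustive grid search over assembly hyperparameters
#'
#' Runs the full filter-assemble-evaluate pipeline (de Bruijn graph method)
#' for every configuration in the grid and ranks configurations by the
#' composite score, normalized across all configurations of the grid. The
#' pipeline is deterministic, so results are identical for any number of
#' workers; a failing configuration records its error and is ranked last.
#'
#' @param psms PSM data.frame (as read by [read_psm_table()]).
#' @param reference reference protein sequence for evaluation.
#' @param grid a [param_grid()].
#' @param workers parallel workers (forked; execution detail only).
#' @param contaminants optional contaminant sequences for filtering.
#' @return data.frame of configurations with metric columns, composite
#'   score and \code{rank}; failed configs carry the error message.
#' @export
run_grid <- function(psms, reference, grid = param_grid(), workers = 1L,
                     contaminants = NULL) {
  configs <- enumerate_configs(grid)
  runner <- function(i) {
    tryCatch(.run_one_config(as.list(configs[i, ]), psms, reference,
                             contaminants),
             error = function(e) structure(list(message = conditionMessage(e)),
                                           class = "grid_error"))
  }
  results <- if (workers > 1L) {
    parallel::mclapply(seq_len(nrow(configs)), runner,
                       mc.cores = workers, mc.preschedule = TRUE)
  } else {
    lapply(seq_len(nrow(configs)), runner)
  }
  ok <- !vapply(results, inherits, logical(1), "grid_error")

  out <- configs
  out$n_scaffolds <- out$coverage <- out$high_conf_coverage <- out$n50 <-
    out$precision <- out$mean_identity <- out$aqs <- out$composite <- NA_real_
  out$error <- NA_character_
  if (any(ok)) {
    scored <- compare_assemblies(results[ok])
    fields <- c("n_scaffolds", "coverage", "high_conf_coverage", "n50",
                "precision", "mean_identity", "aqs", "composite")
    for (f in fields) {
      out[[f]][ok] <- vapply(scored, `[[`, numeric(1), f)
    }
  }
  if (any(!ok)) {
    out$error[!ok] <- vapply(results[!ok], `[[`, character(1), "message")
  }
  # rank: composite desc, ties by fewer scaffolds, then higher coverage;
  # failed configs sink to the bottom
  key <- order(!ok, -ifelse(ok, out$composite, -Inf),
               ifelse(ok, out$n_scaffolds, Inf),
               -ifelse(ok, out$coverage, -Inf))
  out <- out[key, , drop = FALSE]
  rownames(out) <- NULL
  out$rank <- seq_len(nrow(out))
  out
}

#' Mean of each parameter over the top-ranked configurations
#'
#' Convenience summary for transferring tuned settings across samples.
#'
#' @param grid_results output of [run_grid()].
#' @param top number of top configurations to average (default 10).
#' @return named numeric vector of per-parameter means.
#' @export
summarize_top_configs <- function(grid_results, top = 10L) {
  ok <- is.na(grid_results$error)
  use <- utils::head(grid_results[ok, , drop = FALSE], top)
  colMeans(use[, c("k", "min_overlap", "size_threshold", "min_edge_weight",
                   "fdr", "refinement_rounds")])
}
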