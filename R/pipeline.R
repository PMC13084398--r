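#' Build a run configuration
#'
#' @param psms path to a PSM table (CSV/TSV) or a data.frame.
#' @param reference optional reference protein (FASTA path or sequence
#'   string); identity-bearing metrics require it.
#' @param method \code{"greedy"}, \code{"dbg"} or \code{"both"} (both
#'   assemblers run and are evaluated jointly, so composite normalization
#'   spans both).
#' @param filter a [filter_config()].
#' @param greedy a [greedy_params()].
#' @param dbg a [dbg_params()].
#' @param cluster a [cluster_params()].
#' @param out_dir output directory for run artifacts.
#' @return a \code{run_config} list.
#' @export
run_config <- function(psms, reference = NULL, method = c("dbg", "greedy",
                                                          "both"),
                       filter = filter_config(), greedy = greedy_params(),
                       dbg = dbg_params(), cluster = cluster_params(),
                       out_dir = tempfile("pepnexus_run_")) {
  method <- match.arg(method)
  structure(list(psms = psms, reference = reference, method = method,
                 filter = filter, greedy = greedy, dbg = dbg,
                 cluster = cluster, out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Recognized top-level keys: \code{psms}, \code{reference}, \code{method},
#' \code{out_dir}, and parameter blocks \code{filter}, \code{greedy},
#' \code{dbg}, \code{cluster} whose entries are passed to the matching
#' constructors.
#'
#' @param path YAML file path.
#' @return a \code{run_config}.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list(psms = y$psms)
  if (!is.null(y$reference)) args$reference <- y$reference
  if (!is.null(y$method)) args$method <- y$method
  if (!is.null(y$out_dir)) args$out_dir <- y$out_dir
  if (!is.null(y$filter)) args$filter <- do.call(filter_config, y$filter)
  if (!is.null(y$greedy)) args$greedy <- do.call(greedy_params, y$greedy)
  if (!is.null(y$dbg)) args$dbg <- do.call(dbg_params, y$dbg)
  if (!is.null(y$cluster)) args$cluster <- do.call(cluster_params, y$cluster)
  do.call(run_config, args)
}

.read_reference <- function(reference) {
  if (is.null(reference)) return(NULL)
  if (file.exists(reference)) {
    x <- Biostrings::readAAStringSet(reference)
    as.character(x[[1]])
  } else {
    reference
  }
}

.write_fasta <- function(seqs, names, path) {
  x <- Biostrings::AAStringSet(seqs)
  names(x) <- names
  Biostrings::writeXStringSet(x, path)
  path
}

.assemble_greedy <- function(peptides, params) {
  contigs <- greedy_assemble(peptides, params)
  iterative_scaffold(contigs, params)
}

#' Run the end-to-end assembly pipeline
#'
#' Executes the fixed stage order: PSM filtering, assembly into contigs
#' (greedy and/or de Bruijn graph), scaffold formation, clustering and
#' consensus generation, and (when a reference is supplied) evaluation.
#' Every stage writes plain-text artifacts (CSV/FASTA/JSON) into the run
#' directory together with a manifest of input checksums and the
#' configuration, so any stage can be inspected or rerun independently, and
#' reruns of the same configuration are byte-identical.
#'
#' @param config a [run_config()].
#' @return list with elements \code{out_dir}, per-method \code{scaffolds},
#'   \code{consensus} and \code{metrics}, and \code{manifest}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  od <- config$out_dir

  psms <- if (is.character(config$psms)) {
    read_psm_table(config$psms)
  } else {
    config$psms
  }
  clean <- filter_psms(psms, config$filter)
  utils::write.csv(clean, file.path(od, "psms_clean.csv"), row.names = FALSE)

  methods <- if (config$method == "both") c("greedy", "dbg") else config$method
  reference <- .read_reference(config$reference)

  scaffolds <- list(); consensus <- list(); metrics <- list()
  for (m in methods) {
    sc <- if (m == "greedy") {
      s <- .assemble_greedy(clean$peptide_stripped, config$greedy)
      data.frame(sequence = s$sequence, L = nchar(s$sequence),
                 stringsAsFactors = FALSE)
    } else {
      dbg_assemble(clean$peptide_stripped, config$dbg)
    }
    scaffolds[[m]] <- sc
    if (nrow(sc)) {
      hdr <- if ("score" %in% names(sc)) {
        sprintf("%s_scaffold_%d score=%.4f", m, seq_len(nrow(sc)), sc$score)
      } else {
        sprintf("%s_scaffold_%d", m, seq_len(nrow(sc)))
      }
      .write_fasta(sc$sequence, hdr, file.path(od, paste0("scaffolds_", m,
                                                          ".fasta")))
    }
    cons <- consensus_pipeline(sc, config$cluster)
    consensus[[m]] <- cons
    if (nrow(cons)) {
      .write_fasta(cons$consensus,
                   sprintf("%s_consensus_%d members=%d", m,
                           seq_len(nrow(cons)), cons$n_members),
                   file.path(od, paste0("consensus_", m, ".fasta")))
    }
    if (!is.null(reference)) {
      metrics[[m]] <- evaluate_assembly(sc, reference)
    }
  }
  if (!is.null(reference) && length(metrics)) {
    metrics <- stats::setNames(compare_assemblies(metrics), names(metrics))
    mj <- lapply(metrics, function(x) {
      x$mappings <- NULL
      unclass(x)
    })
    jsonlite::write_json(mj, file.path(od, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  cfg_dump <- config
  cfg_dump$out_dir <- NULL  # keep reruns into different directories identical
  if (is.data.frame(cfg_dump$psms)) cfg_dump$psms <- "<in-memory>"
  cfg_repr <- utils::capture.output(utils::str(cfg_dump, give.attr = FALSE))
  writeLines(cfg_repr, file.path(od, "config.txt"))
  files <- sort(setdiff(list.files(od), "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("pepnexus")),
    method = config$method,
    n_psms_in = nrow(psms), n_psms_clean = nrow(clean),
    files = as.list(tools::md5sum(file.path(od, files)))
  )
  names(manifest$files) <- files
  jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  list(out_dir = od, scaffolds = scaffolds, consensus = consensus,
       metrics = metrics, manifest = manifest)
}
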