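#' Run the ceRNA inference on in-memory inputs
#'
#' The full analysis behind [run_pipeline()], operating on loaded objects:
#' per-class differential expression, seed-match target prediction for the
#' DE miRNAs, Spearman-gated miRNA-target edges, Pearson + sponge-test
#' triplet assembly, and network construction.
#'
#' @param counts named list of [count_matrix()] objects, one per RNA class
#'   (`mRNA`, `miRNA`, `lncRNA`, `circRNA`), sample columns aligned.
#' @param sequences named character vector covering the miRNAs and the
#'   candidate targets (ids matching the count matrices).
#' @param min_site_type weakest seed-site type accepted (default
#'   `"7mer-m8"`).
#' @param lfc_threshold absolute log2 fold-change gate (default 1, i.e.
#'   fold change >= 2).
#' @param alpha FDR gate, strict (default 0.05).
#' @param scc_threshold Spearman gate, strict < (default -0.7).
#' @param pcc_threshold Pearson gate, strict > (default 0.9).
#' @param sponge_alpha sponge-test p-value gate, strict < (default 0.05).
#' @param universe_u miRNA universe for the sponge test; `NULL` (default)
#'   uses the number of differentially expressed miRNAs.
#' @param pseudocount fold-change pseudocount (default 1).
#' @return List with `de` (all DE records), `target_map`, `edges`,
#'   `triplets`, `network` and the `universe_u` used.
#' @export
run_cerna_analysis <- function(counts, sequences,
                               min_site_type = "7mer-m8",
                               lfc_threshold = 1, alpha = 0.05,
                               scc_threshold = -0.7, pcc_threshold = 0.9,
                               sponge_alpha = 0.05, universe_u = NULL,
                               pseudocount = 1) {
  stopifnot(all(RNA_CLASSES %in% names(counts)))
  de <- do.call(rbind, lapply(RNA_CLASSES, function(class) {
    call_de(counts[[class]], pseudocount, lfc_threshold, alpha)
  }))
  rownames(de) <- NULL
  de_mirnas <- de$feature_id[de$rna_class == "miRNA" & de$status != "ns"]
  target_ids <- de$feature_id[de$rna_class != "miRNA"]

  mirna_ids <- de$feature_id[de$rna_class == "miRNA"]
  target_map <- build_target_map(
    de_mirnas,
    sequences[intersect(names(sequences), mirna_ids)],
    sequences[intersect(names(sequences), target_ids)],
    min_site_type)

  expr <- expression_matrix(counts[RNA_CLASSES])
  edges <- candidate_pairs(target_map, de, expr, scc_threshold)
  u <- if (is.null(universe_u)) length(de_mirnas) else universe_u
  triplets <- if (nrow(edges) && any(edges$passes) && u >= 1L) {
    assemble_triplets(edges, expr, u, pcc_threshold, sponge_alpha)
  } else {
    assemble_triplets(edges[0L, , drop = FALSE], expr, max(u, 1L),
                      pcc_threshold, sponge_alpha)
  }
  list(de = de, target_map = target_map, edges = edges, triplets = triplets,
       network = build_network(triplets, de), universe_u = u)
}

#' Run the end-to-end pipeline from a config file
#'
#' Reads a YAML config naming the inputs (four count tables, condition
#' map, FASTA sequences, optional GTF and association table) and the
#' thresholds, then executes load -> DE -> target prediction -> ceRNA
#' filtering -> network assembly -> export. Outputs under `output_dir`:
#' `de_<class>.tsv`, `sites.tsv`, `triplets.tsv`, `network_edges.tsv`,
#' `network.graphml`, `lncrna_classes.tsv` (when a GTF is given) and
#' `run_log.txt` with the thresholds and per-stage record counts. The run
#' is a pure function of (inputs, config): identical inputs give
#' byte-identical outputs.
#'
#' Config layout (defaults shown):
#' \preformatted{
#' inputs:
#'   counts: {mRNA: ..., miRNA: ..., lncRNA: ..., circRNA: ...}
#'   condition_map: ...
#'   sequences: ...        # FASTA
#'   transcripts: ...      # optional GTF
#' thresholds:
#'   fold_change: 2        # inclusive, both directions
#'   fdr: 0.05             # strict <
#'   scc: -0.7             # strict <
#'   pcc: 0.9              # strict >
#'   sponge_p: 0.05        # strict <
#'   min_site_type: 7mer-m8
#'   bidirectional_window: 1000
#' output_dir: ...
#' }
#'
#' @param config_path path to the YAML config.
#' @return Invisibly, the [run_cerna_analysis()] result list, with the
#'   output directory attached as `output_dir`.
#' @export
run_pipeline <- function(config_path) {
  cfg <- yaml::read_yaml(config_path)
  if (is.null(cfg$inputs) || is.null(cfg$output_dir)) {
    stop("config must name 'inputs' and 'output_dir'")
  }
  thr <- utils::modifyList(
    list(fold_change = 2, fdr = 0.05, scc = -0.7, pcc = 0.9,
         sponge_p = 0.05, min_site_type = "7mer-m8",
         bidirectional_window = 1000),
    if (is.null(cfg$thresholds)) list() else cfg$thresholds)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  counts <- stage("load", {
    lapply(stats::setNames(RNA_CLASSES, RNA_CLASSES), function(class) {
      load_counts(cfg$inputs$counts[[class]], cfg$inputs$condition_map, class)
    })
  })
  sequences <- stage("load", {
    fa <- Biostrings::readDNAStringSet(cfg$inputs$sequences)
    stats::setNames(as.character(fa), names(fa))
  })

  res <- stage("analysis", run_cerna_analysis(
    counts, sequences,
    min_site_type = thr$min_site_type,
    lfc_threshold = log2(thr$fold_change),
    alpha = thr$fdr, scc_threshold = thr$scc, pcc_threshold = thr$pcc,
    sponge_alpha = thr$sponge_p))

  out <- cfg$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stage("export", {
    for (class in RNA_CLASSES) {
      utils::write.table(res$de[res$de$rna_class == class, , drop = FALSE],
                         file.path(out, paste0("de_", class, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    utils::write.table(res$target_map$sites, file.path(out, "sites.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$triplets, file.path(out, "triplets.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    export_network(res$network, out)
  })

  lnc_classes <- NULL
  if (!is.null(cfg$inputs$transcripts)) {
    lnc_classes <- stage("lncrna_classification", {
      tx <- load_transcripts(cfg$inputs$transcripts)
      cl <- classify_lncrnas(tx, thr$bidirectional_window)
      utils::write.table(cl, file.path(out, "lncrna_classes.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      cl
    })
  }

  log_lines <- c(
    "ceRNAsponge pipeline run",
    sprintf("threshold %s = %s", names(thr), unlist(lapply(thr, format))),
    sprintf("stage counts: de_total=%d de_significant=%d de_mirna=%d",
            nrow(res$de), sum(res$de$status != "ns"),
            sum(res$de$rna_class == "miRNA" & res$de$status != "ns")),
    sprintf("stage counts: sites=%d pairs=%d passing_pairs=%d",
            nrow(res$target_map$sites), nrow(res$edges),
            sum(res$edges$passes)),
    sprintf("stage counts: universe_u=%d triplets=%d nodes=%d edges=%d",
            res$universe_u, nrow(res$triplets), nrow(res$network$nodes),
            nrow(res$network$edges)))
  if (!is.null(lnc_classes)) {
    log_lines <- c(log_lines,
                   sprintf("stage counts: lncrna_candidates=%d",
                           nrow(lnc_classes)))
  }
  writeLines(log_lines, file.path(out, "run_log.txt"))

  res$output_dir <- out
  invisible(res)
}
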