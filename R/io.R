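#' Load a count table with its condition map
#'
#' Count tables are tab-separated with a header: the first column holds
#' feature ids, remaining columns one sample each. The condition map is a
#' two-column tab-separated file (`sample`, `condition`) naming every
#' sample's group. Malformed input is rejected, never coerced.
#'
#' @param path count table path.
#' @param condition_map_path condition map path.
#' @param rna_class RNA class of the table.
#' @return A [count_matrix()]; samples keep the header order.
#' @export
load_counts <- function(path, condition_map_path, rna_class) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("count table needs a feature column and samples: ",
                           path)
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicate feature id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- colnames(mat)[!vapply(seq_len(ncol(mat)),
                                 function(j) is.numeric(tab[[j + 1L]]),
                                 logical(1))]
    stop("non-numeric counts in column(s): ", paste(bad, collapse = ", "))
  }
  rownames(mat) <- ids
  cmap <- utils::read.delim(condition_map_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  if (ncol(cmap) < 2L) stop("condition map needs two columns")
  condition <- stats::setNames(as.character(cmap[[2L]]),
                               as.character(cmap[[1L]]))
  count_matrix(mat, rna_class, condition)
}

write_counts <- function(x, path) {
  tab <- data.frame(feature_id = rownames(x$counts), x$counts,
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Load transcript models from a GTF file
#'
#' Reads the exon features of a GTF (1-based closed coordinates) and
#' builds one [transcript_model()] per `transcript_id`, with exons merged
#' and sorted. The transcript biotype is taken from a `gene_biotype`
#' attribute when present (values other than `protein_coding` map to
#' `lncRNA_candidate`).
#'
#' @param path GTF file path.
#' @return Named list of [transcript_model()] objects.
#' @export
load_transcripts <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) stop("GTF format error in ", path, ": ",
                                          conditionMessage(e)))
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) return(list())
  if (is.null(gr$transcript_id) || anyNA(gr$transcript_id)) {
    stop("GTF exon without transcript_id in ", path)
  }
  out <- list()
  for (txid in unique(gr$transcript_id)) {
    sub <- gr[gr$transcript_id == txid]
    merged <- GenomicRanges::reduce(sub)
    biotype_raw <- if (!is.null(sub$gene_biotype)) sub$gene_biotype[1L] else
      "protein_coding"
    out[[txid]] <- transcript_model(
      transcript_id = txid,
      gene_id = if (!is.null(sub$gene_id)) sub$gene_id[1L] else txid,
      chrom = as.character(GenomicRanges::seqnames(sub))[1L],
      strand = as.character(GenomicRanges::strand(sub))[1L],
      exons = cbind(GenomicRanges::start(merged), GenomicRanges::end(merged)),
      biotype = if (identical(biotype_raw, "protein_coding"))
        "protein_coding" else "lncRNA_candidate")
  }
  out
}

write_gtf <- function(transcripts, path) {
  lines <- character(0)
  for (tx in transcripts) {
    for (k in seq_len(nrow(tx$exons))) {
      attrs <- sprintf(
        'gene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
        tx$gene_id, tx$transcript_id, tx$biotype)
      lines <- c(lines, paste(tx$chrom, "synthetic", "exon",
                              format(tx$exons[k, "start"], scientific = FALSE),
                              format(tx$exons[k, "end"], scientific = FALSE),
                              ".", tx$strand, ".", attrs, sep = "\t"))
    }
  }
  writeLines(lines, path)
}

#' Load the candidate-gene association table
#'
#' Reads a tab-separated table with columns `gene`, `pathway`, `mirnas`,
#' `lncrnas`, `circrnas`; the three list columns are comma-separated (any
#' residual whitespace-separated ids are also split) and may be empty.
#' The packaged fixture transcribing the 25 broodiness candidate genes is
#' at `system.file("extdata", "broodiness_candidate_genes.tsv",
#' package = "ceRNAsponge")`.
#'
#' @param path table path.
#' @return data.frame with character columns `gene`, `pathway` and
#'   list-columns `mirnas`, `lncrnas`, `circrnas`.
#' @export
load_association_table <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!"gene" %in% names(tab)) stop("association table lacks a gene column")
  for (col in c("pathway", "mirnas", "lncrnas", "circrnas")) {
    if (!col %in% names(tab)) tab[[col]] <- ""
  }
  if (any(!nzchar(tab$gene))) stop("empty gene symbol in association table")
  split_list <- function(cell) {
    if (is.na(cell) || !nzchar(cell)) return(character(0))
    parts <- unlist(strsplit(unlist(strsplit(cell, ",", fixed = TRUE)),
                             "[[:space:]]+"))
    parts <- trimws(parts)
    parts[nzchar(parts)]
  }
  out <- data.frame(gene = tab$gene, pathway = tab$pathway,
                    stringsAsFactors = FALSE)
  out$mirnas <- lapply(tab$mirnas, split_list)
  out$lncrnas <- lapply(tab$lncrnas, split_list)
  out$circrnas <- lapply(tab$circrnas, split_list)
  out
}

#' Export a ceRNA network for visualization
#'
#' Writes (a) `network_edges.tsv`, a Cytoscape-importable edge table with
#' columns `source`, `interaction`, `target` plus any edge attributes, and
#' (b) `network.graphml`, a GraphML graph whose nodes carry `rna_class`
#' and `de_direction` attributes. miRNA repression edges are directed;
#' co-expression edges are stored once (ceRNA to mRNA) and are
#' semantically undirected.
#'
#' @param network a [cerna_network()].
#' @param directory output directory (created if absent).
#' @return Invisibly, the two file paths.
#' @export
export_network <- function(network, directory) {
  stopifnot(inherits(network, "cerna_network"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  edge_path <- file.path(directory, "network_edges.tsv")
  graph_path <- file.path(directory, "network.graphml")

  edges <- network$edges
  tab <- data.frame(source = edges$source, interaction = edges$kind,
                    target = edges$target,
                    edges[setdiff(names(edges), c("source", "target", "kind"))],
                    check.names = FALSE)
  utils::write.table(tab, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  nodes <- network$nodes
  nodes$de_direction[is.na(nodes$de_direction)] <- "unknown"
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = edges$source, to = edges$target,
                   edges[setdiff(names(edges), c("source", "target"))],
                   check.names = FALSE),
    directed = TRUE, vertices = nodes)
  igraph::write_graph(g, graph_path, format = "graphml")
  invisible(c(edges = edge_path, graphml = graph_path))
}

#' Write a scenario to disk as plain-text fixtures
#'
#' Emits, under `directory`: one count table per RNA class
#' (`counts_<class>.tsv`), the condition map (`condition_map.tsv`), all
#' sequences as DNA FASTA (`sequences.fasta`; miRNA sequences are stored
#' with T for U), the transcript models (`transcripts.gtf`) and the ground
#' truth (`truth_de.tsv`, `truth_triplets.tsv`, `truth_target_pairs.tsv`).
#' Rereading with [load_scenario()] reproduces the matrices, sequences and
#' truth exactly.
#'
#' @param scenario a [generate_scenario()] result.
#' @param directory output directory (created if absent).
#' @return Invisibly, the directory.
#' @export
write_scenario <- function(scenario, directory) {
  stopifnot(inherits(scenario, "cerna_scenario"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  for (class in names(scenario$counts)) {
    write_counts(scenario$counts[[class]],
                 file.path(directory, paste0("counts_", class, ".tsv")))
  }
  utils::write.table(
    data.frame(sample = names(scenario$condition),
               condition = as.character(scenario$condition)),
    file.path(directory, "condition_map.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  seqs <- Biostrings::DNAStringSet(vapply(scenario$sequences, as_dna,
                                          character(1)))
  Biostrings::writeXStringSet(seqs, file.path(directory, "sequences.fasta"))
  write_gtf(scenario$transcripts, file.path(directory, "transcripts.gtf"))
  for (part in names(scenario$truth)) {
    utils::write.table(scenario$truth[[part]],
                       file.path(directory, paste0("truth_",
                                                   sub("planted_", "", part),
                                                   ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(directory)
}

#' Reload a scenario fixture written by [write_scenario()]
#'
#' @param directory fixture directory.
#' @return List with `counts` (per-class [count_matrix()]), `condition`,
#'   `sequences` (named character), `transcripts` and `truth`.
#' @export
load_scenario <- function(directory) {
  cmap_path <- file.path(directory, "condition_map.tsv")
  counts <- list()
  for (class in RNA_CLASSES) {
    counts[[class]] <- load_counts(
      file.path(directory, paste0("counts_", class, ".tsv")),
      cmap_path, class)
  }
  fa <- Biostrings::readDNAStringSet(file.path(directory, "sequences.fasta"))
  sequences <- stats::setNames(as.character(fa), names(fa))
  truth <- list()
  for (part in c("de", "triplets", "target_pairs")) {
    truth[[paste0("planted_", if (part == "de") "de" else part)]] <-
      utils::read.delim(file.path(directory, paste0("truth_", part, ".tsv")),
                        stringsAsFactors = FALSE,
                        colClasses = "character")
  }
  list(counts = counts, condition = counts[[1L]]$condition,
       sequences = sequences,
       transcripts = load_transcripts(file.path(directory, "transcripts.gtf")),
       truth = truth)
}
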