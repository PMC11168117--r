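#' Typed ceRNA network
#'
#' @param nodes data.frame with columns `id`, `rna_class`, `de_direction`.
#' @param edges data.frame with columns `source`, `target`, `kind` and any
#'   further attribute columns.
#' @return Object of class `cerna_network`.
#' @export
cerna_network <- function(nodes, edges) {
  stopifnot(all(c("id", "rna_class", "de_direction") %in% names(nodes)),
            all(c("source", "target", "kind") %in% names(edges)))
  if (anyDuplicated(nodes$id)) stop("duplicate node id")
  if (!all(nodes$rna_class %in% RNA_CLASSES)) stop("invalid rna_class")
  loose <- setdiff(c(edges$source, edges$target), nodes$id)
  if (length(loose)) {
    stop("edge endpoint(s) not in nodes: ", paste(loose, collapse = ", "))
  }
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "cerna_network")
}

#' @export
print.cerna_network <- function(x, ...) {
  cat(sprintf("<cerna_network> %d node(s), %d edge(s)\n",
              nrow(x$nodes), nrow(x$edges)))
  if (nrow(x$nodes)) print(summarize_nodes(x))
  invisible(x)
}

empty_network <- function() {
  cerna_network(
    data.frame(id = character(0), rna_class = character(0),
               de_direction = character(0)),
    data.frame(source = character(0), target = character(0),
               kind = character(0)))
}

#' Build the ceRNA network from accepted triplets
#'
#' Nodes are the union of triplet members, typed by RNA class; edges are
#' miRNA -> ceRNA and miRNA -> mRNA repression edges (`mirna_represses`,
#' carrying the SCC) and ceRNA -- mRNA co-expression edges
#' (`cerna_coexpression`, carrying PCC and the sponge test), deduplicated.
#'
#' @param triplets data.frame from [assemble_triplets()].
#' @param de_records optional DE table used to annotate nodes with their
#'   up/down direction.
#' @return A [cerna_network()].
#' @export
build_network <- function(triplets, de_records = NULL) {
  if (nrow(triplets) == 0L) return(empty_network())
  nodes <- unique(rbind(
    data.frame(id = triplets$ce_id, rna_class = triplets$ce_class),
    data.frame(id = triplets$mirna_id, rna_class = "miRNA"),
    data.frame(id = triplets$mrna_id, rna_class = "mRNA")))
  dir_of <- if (!is.null(de_records)) {
    stats::setNames(de_records$status, de_records$feature_id)
  } else c()
  nodes$de_direction <- ifelse(nodes$id %in% names(dir_of),
                               unname(dir_of[nodes$id]), NA_character_)

  repress <- unique(rbind(
    data.frame(source = triplets$mirna_id, target = triplets$ce_id,
               kind = "mirna_represses", rho = triplets$scc_ce_mirna,
               sponge_pvalue = NA_real_),
    data.frame(source = triplets$mirna_id, target = triplets$mrna_id,
               kind = "mirna_represses", rho = triplets$scc_mrna_mirna,
               sponge_pvalue = NA_real_)))
  coexpr <- unique(data.frame(
    source = triplets$ce_id, target = triplets$mrna_id,
    kind = "cerna_coexpression", rho = triplets$pcc_ce_mrna,
    sponge_pvalue = triplets$sponge_pvalue))
  cerna_network(nodes, rbind(repress, coexpr))
}

#' Candidate-gene subnetwork from an association table
#'
#' Rebuilds the regulatory neighbourhood of selected candidate genes from
#' a gene/pathway/miRNA/lncRNA/circRNA association table (the printed
#' candidate-gene table), rather than from expression: nodes are the
#' selected genes plus the union of their listed partners (deduplicated
#' across genes, verbatim id matching), edges connect each gene to each of
#' its listed partners.
#'
#' @param associations data.frame from [load_association_table()].
#' @param genes character vector of gene symbols to extract; every symbol
#'   must appear in the table.
#' @return A [cerna_network()] with `mirna_represses` edges miRNA -> gene
#'   and `cerna_coexpression` edges lncRNA/circRNA -- gene.
#' @export
subnetwork_for_genes <- function(associations, genes) {
  if (length(genes) == 0L) return(empty_network())
  unknown <- setdiff(genes, associations$gene)
  if (length(unknown)) {
    stop("gene symbol(s) not in association table: ",
         paste(unknown, collapse = ", "))
  }
  rows <- associations[match(genes, associations$gene), , drop = FALSE]
  nodes <- data.frame(id = genes, rna_class = "mRNA")
  edges <- list()
  partner_class <- c(mirnas = "miRNA", lncrnas = "lncRNA", circrnas = "circRNA")
  for (field in names(partner_class)) {
    partners <- unique(unlist(rows[[field]], use.names = FALSE))
    if (length(partners)) {
      nodes <- rbind(nodes,
                     data.frame(id = partners, rna_class = partner_class[[field]]))
    }
    for (i in seq_len(nrow(rows))) {
      for (p in rows[[field]][[i]]) {
        edges[[length(edges) + 1L]] <- data.frame(
          source = p,
          target = rows$gene[i],
          kind = if (field == "mirnas") "mirna_represses" else
            "cerna_coexpression",
          stringsAsFactors = FALSE)
      }
    }
  }
  nodes <- unique(nodes)  # a partner listed under several genes counts once
  if (anyDuplicated(nodes$id)) {
    stop("identifier(s) appear with conflicting classes: ",
         paste(nodes$id[duplicated(nodes$id)], collapse = ", "))
  }
  nodes$de_direction <- NA_character_
  edges <- if (length(edges)) unique(do.call(rbind, edges)) else
    data.frame(source = character(0), target = character(0),
               kind = character(0))
  cerna_network(nodes, edges)
}

#' Node counts per RNA class
#'
#' @param network a [cerna_network()].
#' @return Named integer vector over `mRNA`, `miRNA`, `lncRNA`, `circRNA`;
#'   sums to the total node count.
#' @export
summarize_nodes <- function(network) {
  stopifnot(inherits(network, "cerna_network"))
  counts <- table(factor(network$nodes$rna_class, levels = RNA_CLASSES))
  stats::setNames(as.integer(counts), RNA_CLASSES)
}
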