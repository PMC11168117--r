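#' Transcript model
#'
#' Exon-level model of one transcript on 1-based closed genomic coordinates.
#' Exons are sorted and must not overlap.
#'
#' @param transcript_id,gene_id identifiers.
#' @param chrom chromosome/scaffold name.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column matrix (start, end) of 1-based closed intervals.
#' @param biotype `"protein_coding"` or `"lncRNA_candidate"`.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons,
                             biotype = c("protein_coding", "lncRNA_candidate")) {
  biotype <- match.arg(biotype)
  strand <- match.arg(strand, c("+", "-"))
  exons <- matrix(as.numeric(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (any(exons[, "end"] < exons[, "start"])) {
    stop("exon with end < start in transcript ", transcript_id)
  }
  exons <- exons[order(exons[, "start"]), , drop = FALSE]
  if (nrow(exons) > 1L &&
      any(exons[-1L, "start"] <= exons[-nrow(exons), "end"])) {
    stop("overlapping exons in transcript ", transcript_id)
  }
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 chrom = chrom, strand = strand, exons = exons,
                 biotype = biotype),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s) %s:%d-%d(%s), %d exon(s)\n",
              x$transcript_id, x$biotype, x$chrom,
              tx_span(x)[1], tx_span(x)[2], x$strand, nrow(x$exons)))
  invisible(x)
}

# genomic span = min(start)..max(end) over exons
tx_span <- function(tx) c(min(tx$exons[, "start"]), max(tx$exons[, "end"]))

# transcription start site: start on +, end on -
tx_tss <- function(tx) {
  sp <- tx_span(tx)
  if (tx$strand == "+") sp[1] else sp[2]
}

ranges_overlap <- function(s1, e1, s2, e2) s1 <= e2 & s2 <= e1
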