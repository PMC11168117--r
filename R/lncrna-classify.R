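#' Positional classification of a candidate lncRNA
#'
#' Assigns one of five positional categories relative to protein-coding
#' transcripts, by strict precedence:
#' \enumerate{
#'   \item `sense_overlapping` — same strand, at least 1 bp of exonic
#'     overlap with a coding exon;
#'   \item `intronic` — same strand, genomic span fully inside a single
#'     intron of one coding transcript (hence no exon overlap);
#'   \item `antisense` — opposite strand, any genomic-span overlap;
#'   \item `bidirectional` — no span overlap with any coding transcript,
#'     but a coding TSS on the opposite strand lies within
#'     `bidirectional_window` bp of the candidate's TSS;
#'   \item `intergenic` — otherwise.
#' }
#' The TSS is the span start on `+` and the span end on `-`. Only coding
#' models on the candidate's chromosome are consulted; an empty coding set
#' yields `intergenic`. The result never depends on the order of `coding`.
#'
#' @param candidate a [transcript_model()] with biotype `lncRNA_candidate`.
#' @param coding list of [transcript_model()] objects (protein_coding).
#' @param bidirectional_window divergent-promoter window in bp (default
#'   1000).
#' @return One of `"sense_overlapping"`, `"intronic"`, `"antisense"`,
#'   `"bidirectional"`, `"intergenic"`.
#' @export
classify_lncrna <- function(candidate, coding, bidirectional_window = 1000) {
  stopifnot(inherits(candidate, "transcript_model"))
  if (candidate$biotype != "lncRNA_candidate") {
    stop("candidate must have biotype lncRNA_candidate")
  }
  assert_scalar_number(bidirectional_window, "bidirectional_window", 0)
  coding <- Filter(function(tx) {
    stopifnot(inherits(tx, "transcript_model"))
    tx$biotype == "protein_coding" && tx$chrom == candidate$chrom
  }, coding)
  if (length(coding) == 0L) return("intergenic")

  sp <- tx_span(candidate)
  same <- vapply(coding, function(tx) tx$strand == candidate$strand, logical(1))

  # 1. sense_overlapping: exon-level overlap on the same strand
  for (tx in coding[same]) {
    for (k in seq_len(nrow(tx$exons))) {
      if (any(ranges_overlap(candidate$exons[, "start"], candidate$exons[, "end"],
                             tx$exons[k, "start"], tx$exons[k, "end"]))) {
        return("sense_overlapping")
      }
    }
  }

  # 2. intronic: contained in one intron of a same-strand coding transcript
  for (tx in coding[same]) {
    if (nrow(tx$exons) < 2L) next
    intron_start <- tx$exons[-nrow(tx$exons), "end"] + 1
    intron_end <- tx$exons[-1L, "start"] - 1
    if (any(sp[1] >= intron_start & sp[2] <= intron_end)) {
      return("intronic")
    }
  }

  # 3. antisense: span overlap on the opposite strand
  for (tx in coding[!same]) {
    spc <- tx_span(tx)
    if (ranges_overlap(sp[1], sp[2], spc[1], spc[2])) return("antisense")
  }

  # 4. bidirectional: divergent promoters, no span overlap at all
  any_span_overlap <- any(vapply(coding, function(tx) {
    spc <- tx_span(tx)
    ranges_overlap(sp[1], sp[2], spc[1], spc[2])
  }, logical(1)))
  if (!any_span_overlap) {
    tss <- tx_tss(candidate)
    for (tx in coding[!same]) {
      if (abs(tss - tx_tss(tx)) <= bidirectional_window) return("bidirectional")
    }
  }

  "intergenic"
}

#' Classify every candidate lncRNA in a transcript set
#'
#' @param transcripts list of [transcript_model()] objects; the
#'   protein-coding members form the reference, the lncRNA candidates are
#'   classified.
#' @inheritParams classify_lncrna
#' @return data.frame with columns `transcript_id` and `category`.
#' @export
classify_lncrnas <- function(transcripts, bidirectional_window = 1000) {
  coding <- Filter(function(tx) tx$biotype == "protein_coding", transcripts)
  cands <- Filter(function(tx) tx$biotype == "lncRNA_candidate", transcripts)
  data.frame(
    transcript_id = vapply(cands, `[[`, character(1), "transcript_id"),
    category = vapply(cands, classify_lncrna, character(1),
                      coding = coding,
                      bidirectional_window = bidirectional_window),
    stringsAsFactors = FALSE
  )
}
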