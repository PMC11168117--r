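#' Small-RNA tag annotation categories, in priority order
#'
#' The annotation priority used when a sequenced tag matches several
#' reference sets: `rRNA_like` (bundling rRNA/scRNA/snoRNA/snRNA/tRNA) >
#' `exist_miRNA` > `exist_miRNA_edit` > `known_miRNA` > `repeat` > `exon` >
#' `novel_miRNA` > `intron`; a tag matching none is recorded as `unann`.
#'
#' @return Character vector of the eight categories, highest priority first.
#' @export
tag_categories <- function() {
  c("rRNA_like", "exist_miRNA", "exist_miRNA_edit", "known_miRNA",
    "repeat", "exon", "novel_miRNA", "intron")
}

#' Resolve a tag's annotation by priority
#'
#' @param membership character vector of categories the tag matched (any
#'   subset of [tag_categories()]; must not contain `"unann"`).
#' @return The highest-priority member, or `"unann"` for an empty set.
#' @export
annotate_tag <- function(membership) {
  cats <- tag_categories()
  membership <- unique(as.character(membership))
  if (length(membership) == 0L) return("unann")
  bad <- setdiff(membership, cats)
  if (length(bad)) stop("unknown categories: ", paste(bad, collapse = ", "))
  cats[min(match(membership, cats))]
}

#' Filter raw small-RNA tags
#'
#' Applies the read-level cleanup rules for small-RNA libraries: discard
#' tags with low quality (mean phred <= 20, tested only when quality is
#' available), tags carrying an adapter, tags shorter than 18 nt, and polyA
#' tags. Each rejection reports the first failing rule in that order.
#'
#' @param tags data.frame with columns `sequence` (A/C/G/T/U/N), optional
#'   `mean_quality` (NA when unknown) and optional `has_adapter` (default
#'   FALSE).
#' @param polya_fraction fraction of A at or above which a tag counts as
#'   polyA (default 0.8; the rule targets homopolymer artifacts, not A-rich
#'   miRNAs).
#' @return List with data.frames `kept` and `rejected`, the latter with a
#'   `reason` column (`low_quality`, `adapter`, `too_short`, `polyA`).
#' @export
filter_small_rna_tags <- function(tags, polya_fraction = 0.8) {
  stopifnot(is.data.frame(tags), "sequence" %in% names(tags))
  seqs <- toupper(as.character(tags$sequence))
  if (any(nchar(seqs) == 0L)) stop("empty tag sequence")
  if (any(grepl("[^ACGTUN]", seqs))) stop("tag alphabet must be A/C/G/T/U/N")
  qual <- if ("mean_quality" %in% names(tags)) tags$mean_quality else
    rep(NA_real_, nrow(tags))
  adapter <- if ("has_adapter" %in% names(tags)) isTRUE_vec(tags$has_adapter) else
    rep(FALSE, nrow(tags))

  n_a <- vapply(strsplit(chartr("U", "T", seqs), "", fixed = TRUE),
                function(ch) sum(ch == "A"), integer(1))
  polya <- n_a / nchar(seqs) >= polya_fraction

  reason <- rep(NA_character_, nrow(tags))
  reason[is.na(reason) & !is.na(qual) & qual <= 20] <- "low_quality"
  reason[is.na(reason) & adapter] <- "adapter"
  reason[is.na(reason) & nchar(seqs) < 18L] <- "too_short"
  reason[is.na(reason) & polya] <- "polyA"

  kept <- tags[is.na(reason), , drop = FALSE]
  rejected <- tags[!is.na(reason), , drop = FALSE]
  rejected$reason <- reason[!is.na(reason)]
  rownames(kept) <- rownames(rejected) <- NULL
  list(kept = kept, rejected = rejected)
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)
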