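SITE_TYPES <- c("6mer", "7mer-A1", "7mer-m8", "8mer")  # weakest to strongest

#' Canonical miRNA seed sites on a target sequence
#'
#' Scans a target for matches to the miRNA seed (miRNA nucleotides 2-7,
#' read 5' to 3'). A locus is the occurrence of the 6mer core — the
#' reverse complement of positions 2-7 — on the target; each locus is
#' reported once, as its strongest canonical type:
#' `8mer` (match extends to position 8 and the target has an A opposite
#' position 1), `7mer-m8` (position-8 match only), `7mer-A1` (A opposite
#' position 1 only), or `6mer`. U and T are equivalent on both inputs.
#'
#' @param mirna_seq miRNA sequence, 5'->3', length >= 8 (RNA or DNA).
#' @param target_seq target sequence, 5'->3' (RNA or DNA; N never matches).
#' @return data.frame with columns `site_type` and `position` (1-based
#'   start of the reported site on the target: the m8-pairing base for
#'   `8mer`/`7mer-m8`, the core start otherwise). Zero rows when no site.
#' @export
find_seed_sites <- function(mirna_seq, target_seq) {
  m <- as_dna(mirna_seq)
  t <- as_dna(target_seq)
  if (grepl("[^ACGTN]", m) || grepl("[^ACGTN]", t)) {
    stop("sequences must be over A/C/G/T/U/N")
  }
  if (nchar(m) < 8L) stop("miRNA sequence must be at least 8 nt")
  mch <- strsplit(m, "", fixed = TRUE)[[1]]
  core <- revcomp_dna(paste(mch[2:7], collapse = ""))      # pairs miRNA 2-7
  m8c <- DNA_COMPLEMENT[[mch[8]]]                          # pairs miRNA 8
  tch <- strsplit(t, "", fixed = TRUE)[[1]]

  hits <- gregexpr(core, t, fixed = TRUE)[[1]]
  if (hits[1] == -1L) {
    return(data.frame(site_type = character(0), position = integer(0)))
  }
  site_type <- character(length(hits))
  position <- integer(length(hits))
  for (j in seq_along(hits)) {
    i <- hits[j]
    has_m8 <- i > 1L && tch[i - 1L] == m8c
    has_a1 <- (i + 6L) <= length(tch) && tch[i + 6L] == "A"
    site_type[j] <- if (has_m8 && has_a1) "8mer"
      else if (has_m8) "7mer-m8"
      else if (has_a1) "7mer-A1"
      else "6mer"
    position[j] <- if (has_m8) i - 1L else i
  }
  data.frame(site_type = site_type, position = position,
             stringsAsFactors = FALSE)
}

#' Predict targets for a set of differential miRNAs
#'
#' Scans every supplied target sequence (mRNA, lncRNA and circRNA alike —
#' whole transcripts, since non-coding "targets" carry no UTR annotation)
#' for canonical seed sites of each differential miRNA, and keeps sites at
#' least as strong as `min_site_type`.
#'
#' @param de_mirnas character vector of miRNA ids to consider.
#' @param mirna_seqs named character vector of miRNA sequences (5'->3').
#'   A DE miRNA without a sequence is skipped with a warning.
#' @param target_seqs named character vector of candidate target sequences.
#' @param min_site_type weakest site type retained: one of `"6mer"`,
#'   `"7mer-A1"`, `"7mer-m8"` (default), `"8mer"`.
#' @return An object of class `target_map`: list with `targets_by_mirna`
#'   (named list of target-id vectors; entries exist only for miRNAs with
#'   at least one retained site) and `sites` (data.frame `mirna`, `target`,
#'   `site_type`, `position`).
#' @export
build_target_map <- function(de_mirnas, mirna_seqs, target_seqs,
                             min_site_type = "7mer-m8") {
  min_site_type <- match.arg(min_site_type, SITE_TYPES)
  min_rank <- match(min_site_type, SITE_TYPES)
  missing_seq <- setdiff(de_mirnas, names(mirna_seqs))
  if (length(missing_seq)) {
    warning("no sequence for miRNA(s), skipped: ",
            paste(missing_seq, collapse = ", "))
  }
  rows <- list()
  for (mir in intersect(de_mirnas, names(mirna_seqs))) {
    for (tgt in names(target_seqs)) {
      sites <- find_seed_sites(mirna_seqs[[mir]], target_seqs[[tgt]])
      sites <- sites[match(sites$site_type, SITE_TYPES) >= min_rank, ,
                     drop = FALSE]
      if (nrow(sites)) {
        rows[[length(rows) + 1L]] <- data.frame(
          mirna = mir, target = tgt, site_type = sites$site_type,
          position = sites$position, stringsAsFactors = FALSE)
      }
    }
  }
  sites <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mirna = character(0), target = character(0),
               site_type = character(0), position = integer(0))
  structure(list(
    targets_by_mirna = lapply(split(sites$target, sites$mirna), unique),
    sites = sites
  ), class = "target_map")
}

#' @export
print.target_map <- function(x, ...) {
  cat(sprintf("<target_map> %d miRNA(s), %d site(s), %d unique pair(s)\n",
              length(x$targets_by_mirna), nrow(x$sites),
              nrow(unique(x$sites[c("mirna", "target")]))))
  invisible(x)
}
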