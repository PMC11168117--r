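# Shared low-level helpers (not exported).

RNA_CLASSES <- c("mRNA", "miRNA", "lncRNA", "circRNA")

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", U = "A", N = "N")

#' Reverse-complement a nucleotide string (DNA output)
#' @noRd
revcomp_dna <- function(seq) {
  chars <- rev(strsplit(toupper(seq), "", fixed = TRUE)[[1]])
  bad <- !chars %in% names(DNA_COMPLEMENT)
  if (any(bad)) {
    stop("invalid nucleotide(s): ", paste(unique(chars[bad]), collapse = ", "))
  }
  paste(DNA_COMPLEMENT[chars], collapse = "")
}

#' Normalize a nucleotide string to uppercase DNA (U -> T)
#' @noRd
as_dna <- function(seq) {
  chartr("u", "T", chartr("U", "T", toupper(seq)))
}

assert_scalar_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(name, " must be a single finite number")
  }
  if ((strict && x <= lower) || (!strict && x < lower)) {
    stop(name, " must be ", if (strict) "> " else ">= ", lower, " (got ", x, ")")
  }
  invisible(x)
}

assert_count <- function(x, name, lower = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x)) {
    stop(name, " must be a single integer")
  }
  if (x < lower) stop(name, " must be >= ", lower, " (got ", x, ")")
  invisible(as.integer(x))
}
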