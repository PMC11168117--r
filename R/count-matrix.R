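#' Expression count matrix for one RNA class
#'
#' A validated container for non-negative integer counts of one RNA class
#' (mRNA, miRNA, lncRNA or circRNA) over labelled samples split into two
#' conditions ("groupA" = laying/normal ovary, "groupB" = broody/atrophic
#' ovary in the motivating design).
#'
#' @param counts integer matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids).
#' @param rna_class one of `"mRNA"`, `"miRNA"`, `"lncRNA"`, `"circRNA"`.
#' @param condition named character/factor mapping every sample id to
#'   `"groupA"` or `"groupB"`; both conditions need at least two samples.
#' @return An object of class `count_matrix`: a list with elements `counts`,
#'   `rna_class` and `condition` (a factor named by sample).
#' @export
count_matrix <- function(counts, rna_class, condition) {
  if (!is.matrix(counts)) stop("counts must be a matrix")
  rna_class <- match.arg(rna_class, RNA_CLASSES)
  fid <- rownames(counts)
  sid <- colnames(counts)
  if (is.null(fid) || is.null(sid)) stop("counts must have row and column names")
  if (anyDuplicated(fid)) {
    stop("duplicate feature id(s): ",
         paste(unique(fid[duplicated(fid)]), collapse = ", "))
  }
  if (anyDuplicated(sid)) {
    stop("duplicate sample id(s): ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "))
  }
  if (!is.numeric(counts) || any(!is.finite(counts)) ||
      any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  missing <- setdiff(sid, names(condition))
  if (length(missing)) {
    stop("sample(s) missing from condition map: ", paste(missing, collapse = ", "))
  }
  cond <- factor(as.character(condition[sid]), levels = c("groupA", "groupB"))
  if (any(is.na(cond))) {
    stop("condition labels must be 'groupA' or 'groupB'")
  }
  names(cond) <- sid
  if (any(table(cond) < 2L)) {
    stop("each condition needs at least 2 samples")
  }
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, rna_class = rna_class, condition = cond),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %s: %d features x %d samples (%d groupA, %d groupB)\n",
              x$rna_class, nrow(x$counts), ncol(x$counts),
              sum(x$condition == "groupA"), sum(x$condition == "groupB")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Counts-per-million normalization
#'
#' Scales each sample (column) to a library size of one million:
#' `cpm[f, s] = counts[f, s] / sum(counts[, s]) * 1e6`.
#'
#' @param x a [count_matrix()].
#' @return Numeric matrix of CPM values, same dimnames as the counts.
#' @export
cpm_normalize <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  libsize <- colSums(x$counts)
  zero <- libsize == 0
  if (any(zero)) {
    stop("zero library size for sample(s): ",
         paste(colnames(x$counts)[zero], collapse = ", "))
  }
  sweep(x$counts, 2L, libsize, "/") * 1e6
}

#' Stack per-class log2(CPM + 1) matrices into one expression matrix
#'
#' Correlation filters operate on a single features-by-samples matrix that
#' spans all RNA classes. Samples must agree (same ids, same order) across
#' classes; each class is CPM-normalized against its own library.
#'
#' @param counts_list list of [count_matrix()] objects.
#' @return Numeric matrix of log2(CPM + 1) values.
#' @export
expression_matrix <- function(counts_list) {
  stopifnot(length(counts_list) >= 1L)
  ref <- colnames(counts_list[[1L]]$counts)
  for (cm in counts_list) {
    stopifnot(inherits(cm, "count_matrix"))
    if (!identical(colnames(cm$counts), ref)) {
      stop("sample columns are not aligned across RNA classes")
    }
  }
  do.call(rbind, lapply(counts_list, function(cm) log2(cpm_normalize(cm) + 1)))
}
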