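#' Log2 fold change with a pseudocount
#'
#' `log2((mean_b + pseudocount) / (mean_a + pseudocount))`, reported as
#' condition B versus condition A.
#'
#' @param mean_a,mean_b non-negative mean expression values (vectorized).
#' @param pseudocount positive stabilizer added to both means (default 1).
#' @return Numeric vector of log2 fold changes.
#' @export
log2_fold_change <- function(mean_a, mean_b, pseudocount = 1) {
  assert_scalar_number(pseudocount, "pseudocount", 0, strict = TRUE)
  if (any(mean_a < 0) || any(mean_b < 0)) stop("means must be >= 0")
  log2((mean_b + pseudocount) / (mean_a + pseudocount))
}

#' Per-feature Welch t-test on log2(CPM + 1)
#'
#' A transparent two-group test: each feature is compared between conditions
#' with Welch's unequal-variance t statistic on the log2(CPM + 1) scale.
#' Features with zero variance in both groups and equal means get p = 1.
#'
#' @param x a [count_matrix()] with at least two replicates per condition.
#' @return Named numeric vector of two-sided p-values.
#' @export
de_test <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  expr <- log2(cpm_normalize(x) + 1)
  welch_rows(expr, x$condition == "groupA")
}

# vectorized Welch t over rows; `in_a` is the logical group-A mask
welch_rows <- function(expr, in_a) {
  a <- expr[, in_a, drop = FALSE]
  b <- expr[, !in_a, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  if (na < 2L || nb < 2L) stop("need >= 2 replicates in each condition")
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  tt <- (mb - ma) / sqrt(se2)
  df <- se2^2 / (va^2 / (na^2 * (na - 1)) + vb^2 / (nb^2 * (nb - 1)))
  p <- 2 * stats::pt(-abs(tt), df)
  # degenerate rows: no variance anywhere
  flat <- se2 == 0
  p[flat & (ma == mb)] <- 1
  p[flat & (ma != mb)] <- 0
  names(p) <- rownames(expr)
  p
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, monotone in p-rank and capped at 1.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same length and order as the input.
#' @export
bh_fdr <- function(pvalues) {
  if (!is.numeric(pvalues) || any(is.na(pvalues)) ||
      any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

# the workflow's significance gate: |log2FC| >= 1 (fold change >= 2,
# inclusive) and FDR < 0.05 (strict)
de_status <- function(log2fc, fdr, lfc_threshold = 1, alpha = 0.05) {
  status <- rep("ns", length(log2fc))
  status[log2fc >= lfc_threshold & fdr < alpha] <- "up"
  status[log2fc <= -lfc_threshold & fdr < alpha] <- "down"
  status
}

#' Call differential expression for one RNA class
#'
#' Composes CPM normalization, per-feature Welch tests on log2(CPM + 1),
#' BH-FDR adjustment and the fold-change/FDR significance gate: a feature is
#' `up` iff log2FC >= `lfc_threshold` (fold change >= 2 by default,
#' inclusive) with FDR < `alpha` (strict), `down` symmetrically, `ns`
#' otherwise. Fold changes are condition B versus condition A.
#'
#' @param x a [count_matrix()].
#' @param pseudocount pseudocount for the fold change (default 1).
#' @param lfc_threshold absolute log2 fold-change threshold (default 1).
#' @param alpha FDR threshold, strict (default 0.05).
#' @return A data.frame of DE records: `feature_id`, `rna_class`,
#'   `mean_cpm_A`, `mean_cpm_B`, `log2fc`, `pvalue`, `fdr`, `status`.
#' @export
call_de <- function(x, pseudocount = 1, lfc_threshold = 1, alpha = 0.05) {
  stopifnot(inherits(x, "count_matrix"))
  cpm <- cpm_normalize(x)
  in_a <- x$condition == "groupA"
  mean_a <- rowMeans(cpm[, in_a, drop = FALSE])
  mean_b <- rowMeans(cpm[, !in_a, drop = FALSE])
  lfc <- log2_fold_change(mean_a, mean_b, pseudocount)
  p <- de_test(x)
  fdr <- bh_fdr(p)
  data.frame(
    feature_id = rownames(cpm),
    rna_class = x$rna_class,
    mean_cpm_A = unname(mean_a),
    mean_cpm_B = unname(mean_b),
    log2fc = unname(lfc),
    pvalue = unname(p),
    fdr = unname(fdr),
    status = de_status(lfc, fdr, lfc_threshold, alpha),
    stringsAsFactors = FALSE
  )
}

#' Relative RT-qPCR quantification (2^-ddCt)
#'
#' Fold change of a target transcript in a sample condition relative to a
#' control condition, each normalized against a reference gene:
#' `2^-((ct_target_s - ct_ref_s) - (ct_target_c - ct_ref_c))`.
#'
#' @param ct_target_s,ct_ref_s Ct of target and reference gene in the sample.
#' @param ct_target_c,ct_ref_c Ct of target and reference gene in the control.
#' @return The relative fold change (1 when nothing differs).
#' @export
ddct_fold_change <- function(ct_target_s, ct_ref_s, ct_target_c, ct_ref_c) {
  2^-((ct_target_s - ct_ref_s) - (ct_target_c - ct_ref_c))
}
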