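#' Spearman rank correlation
#'
#' Pearson correlation of average-fractional ranks (ties receive mean
#' ranks). A zero-variance input has no defined rank correlation and
#' returns `NA` — which never passes a threshold filter.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return Correlation in \[-1, 1\], or `NA_real_` for degenerate input.
#' @export
spearman_rho <- function(x, y) {
  check_corr_input(x, y)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' Pearson linear correlation
#'
#' @inheritParams spearman_rho
#' @return Correlation in \[-1, 1\], or `NA_real_` for zero-variance input.
#' @export
pearson_r <- function(x, y) {
  check_corr_input(x, y)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "pearson")
}

check_corr_input <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y)) stop("inputs must be numeric")
  if (length(x) != length(y)) stop("inputs must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("inputs must be finite")
  invisible(NULL)
}

#' Hypergeometric shared-sponge test
#'
#' Tests whether two transcripts share more regulator miRNAs than expected
#' by chance. With a universe of `U` miRNAs, of which `M` regulate gene A
#' (set C) and `N` regulate gene B (set D), and `x` regulating both, the
#' p-value is the upper tail of the hypergeometric distribution:
#' \deqn{P(X \ge x) = \sum_{k=x}^{\min(M,N)}
#'       \binom{M}{k}\binom{U-M}{N-k} / \binom{U}{N}.}
#' Terms are accumulated as log-binomial coefficients so the sum is exact
#' to double precision for any practical universe size.
#'
#' @param x shared miRNA count, `0 <= x <= min(M, N)`.
#' @param m,n sizes of the two regulator sets, each `<= u`.
#' @param u miRNA universe size (all miRNAs in the analysis).
#' @return Upper-tail p-value; `x = 0` gives exactly 1.
#' @export
sponge_pvalue <- function(x, m, n, u) {
  x <- assert_count(x, "x"); m <- assert_count(m, "m")
  n <- assert_count(n, "n"); u <- assert_count(u, "u")
  if (m > u || n > u) stop("m and n must not exceed the universe size u")
  if (x > min(m, n)) stop("x must not exceed min(m, n)")
  if (x == 0L) return(1)
  k <- x:min(m, n)
  num <- choose(m, k) * choose(u - m, n - k)
  den <- choose(u, n)
  if (is.finite(den) && all(is.finite(num))) {
    # binomial coefficients fit in double precision: the ratio is the
    # exactly-rounded rational tail probability
    return(min(sum(num) / den, 1))
  }
  logp <- lchoose(m, k) + lchoose(u - m, n - k) - lchoose(u, n)
  top <- max(logp)
  min(exp(top) * sum(exp(logp - top)), 1)
}

#' miRNA-target co-expression edges
#'
#' For every (miRNA, target) pair in the target map whose two members are
#' both differentially expressed, computes the Spearman correlation of
#' their expression across all samples and flags the negatively
#' co-expressed pairs (`rho < scc_threshold`, strict).
#'
#' @param target_map a [build_target_map()] result.
#' @param de_records data.frame of DE records (rbind of [call_de()] over
#'   the RNA classes).
#' @param expression features-by-samples matrix from
#'   [expression_matrix()]; must cover every DE miRNA and target.
#' @param scc_threshold Spearman cutoff (default -0.7; pairs strictly
#'   below pass).
#' @return data.frame of edges: `mirna`, `target`, `target_class`, `rho`,
#'   `passes`.
#' @export
candidate_pairs <- function(target_map, de_records, expression,
                            scc_threshold = -0.7) {
  stopifnot(inherits(target_map, "target_map"))
  de <- de_records[de_records$status != "ns", , drop = FALSE]
  class_of <- stats::setNames(de$rna_class, de$feature_id)
  rows <- list()
  for (mir in intersect(names(target_map$targets_by_mirna), de$feature_id)) {
    if (!mir %in% rownames(expression)) {
      stop("miRNA ", mir, " absent from the expression matrix")
    }
    for (tgt in intersect(target_map$targets_by_mirna[[mir]], de$feature_id)) {
      if (!tgt %in% rownames(expression)) {
        stop("target ", tgt, " absent from the expression matrix")
      }
      rho <- spearman_rho(expression[mir, ], expression[tgt, ])
      rows[[length(rows) + 1L]] <- data.frame(
        mirna = mir, target = tgt, target_class = unname(class_of[tgt]),
        rho = rho, passes = !is.na(rho) && rho < scc_threshold,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(mirna = character(0), target = character(0),
               target_class = character(0), rho = numeric(0),
               passes = logical(0))
}

#' Assemble ceRNA triplets
#'
#' Composes the three acceptance rules for a competing-endogenous pair:
#' for every (ceRNA, mRNA) pair — the ceRNA a lncRNA or circRNA — that
#' shares at least one negatively co-expressed regulator miRNA, the pair
#' must additionally show positive co-expression (Pearson
#' `> pcc_threshold`, strict) and a significant shared-sponge test
#' (`sponge_pvalue < sponge_alpha`, strict; no multiple-testing
#' correction, matching the raw-p selection rule). One triplet is emitted
#' per (ceRNA, miRNA, mRNA) combination; the sponge test is computed once
#' per (ceRNA, mRNA) pair and attached to each of its triplets. Output is
#' ordered lexicographically by (ceRNA, miRNA, mRNA).
#'
#' @param edges passing-and-failing edge table from [candidate_pairs()];
#'   only rows with `passes = TRUE` are used.
#' @param expression matrix from [expression_matrix()].
#' @param universe_u miRNA universe size for the sponge test; by
#'   convention the number of miRNAs in the analysis after DE filtering.
#' @param pcc_threshold Pearson cutoff (default 0.9, strict >).
#' @param sponge_alpha sponge p-value cutoff (default 0.05, strict <).
#' @return data.frame of triplets: `ce_id`, `ce_class`, `mirna_id`,
#'   `mrna_id`, `scc_ce_mirna`, `scc_mrna_mirna`, `pcc_ce_mrna`, `x`, `m`,
#'   `n`, `u`, `sponge_pvalue`.
#' @export
assemble_triplets <- function(edges, expression, universe_u,
                              pcc_threshold = 0.9, sponge_alpha = 0.05) {
  universe_u <- assert_count(universe_u, "universe_u", 1L)
  keep <- edges[edges$passes, , drop = FALSE]
  empty <- data.frame(
    ce_id = character(0), ce_class = character(0), mirna_id = character(0),
    mrna_id = character(0), scc_ce_mirna = numeric(0),
    scc_mrna_mirna = numeric(0), pcc_ce_mrna = numeric(0),
    x = integer(0), m = integer(0), n = integer(0), u = integer(0),
    sponge_pvalue = numeric(0))
  if (nrow(keep) == 0L) return(empty)

  # per-gene sets of passing regulator miRNAs (set C for the ceRNA, D for
  # the mRNA), and the SCC attached to each edge
  mirnas_of <- split(keep$mirna, keep$target)
  rho_of <- stats::setNames(keep$rho, paste(keep$mirna, keep$target))
  ces <- unique(keep$target[keep$target_class %in% c("lncRNA", "circRNA")])
  mrnas <- unique(keep$target[keep$target_class == "mRNA"])
  ce_class <- stats::setNames(keep$target_class, keep$target)
  if (max(lengths(mirnas_of)) > universe_u) {
    stop("universe_u is smaller than a per-gene miRNA set")
  }

  rows <- list()
  for (ce in ces) {
    set_c <- unique(mirnas_of[[ce]])
    for (mrna in mrnas) {
      set_d <- unique(mirnas_of[[mrna]])
      shared <- intersect(set_c, set_d)
      if (length(shared) == 0L) next
      pcc <- pearson_r(expression[ce, ], expression[mrna, ])
      if (is.na(pcc) || pcc <= pcc_threshold) next
      p <- sponge_pvalue(length(shared), length(set_c), length(set_d),
                         universe_u)
      if (p >= sponge_alpha) next
      for (mir in shared) {
        rows[[length(rows) + 1L]] <- data.frame(
          ce_id = ce, ce_class = unname(ce_class[ce]), mirna_id = mir,
          mrna_id = mrna,
          scc_ce_mirna = unname(rho_of[paste(mir, ce)]),
          scc_mrna_mirna = unname(rho_of[paste(mir, mrna)]),
          pcc_ce_mrna = pcc, x = length(shared), m = length(set_c),
          n = length(set_d), u = universe_u, sponge_pvalue = p,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$ce_id, out$mirna_id, out$mrna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
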