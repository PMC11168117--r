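# Independent oracles the implementation is checked against. These are
# deliberately naive: textbook formulas and exhaustive enumeration.

# Pearson correlation straight from the sum formulation
textbook_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  num / den
}

# Spearman = Pearson on average-fractional ranks
textbook_spearman <- function(x, y) {
  textbook_pearson(rank(x, ties.method = "average"),
                   rank(y, ties.method = "average"))
}

# O(m^2) Benjamini-Hochberg step-up: adj_(k) = min_{j >= k} m p_(j) / j
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (k in seq_len(m)) {
    adj[k] <- min(1, min(m * ps[k:m] / (k:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# exhaustive-enumeration hypergeometric upper tail: draw every N-subset of
# a universe whose first M elements are "successes"
enum_sponge_tail <- function(x, M, N, U) {
  if (N == 0L) return(as.numeric(x <= 0))
  sets <- utils::combn(U, N)
  overlap <- colSums(matrix(sets <= M, nrow = N))
  mean(overlap >= x)
}

# scenario configurations used by the stochastic suites; the recovery and
# null designs are the scaled-up study conditions (20 replicates per
# group, dispersion 0.05)
recovery_config <- function(seed) {
  scenario_config(
    n_replicates_per_group = 20, n_mirna = 90, n_mrna = 110,
    n_lncrna = 95, n_circrna = 95, n_planted_triplets = 30,
    n_planted_de_per_class = 0, nb_dispersion = 0.05,
    coupling_strength = 2.0, seed = seed)
}

null_config <- function(seed) {
  scenario_config(
    n_replicates_per_group = 20, n_mirna = 100, n_mrna = 1000,
    n_lncrna = 500, n_circrna = 400, n_planted_triplets = 0,
    n_planted_de_per_class = 0, nb_dispersion = 0.05,
    coupling_strength = 0, de_log2fc = 0, seed = seed)
}

triplet_key <- function(df) paste(df$ce_id, df$mirna_id, df$mrna_id)

# hand-constructed positional fixture: two coding genes, ten candidates,
# two per designed category (coordinates drawn out on paper)
lnc_fixture <- function() {
  g1 <- transcript_model("G1.t1", "G1", "chr1", "+",
                         rbind(c(1000, 1400), c(1600, 2000)),
                         "protein_coding")
  g2 <- transcript_model("G2.t1", "G2", "chr1", "-",
                         rbind(c(50000, 50400), c(50600, 51000)),
                         "protein_coding")
  cand <- function(id, strand, start, end) {
    transcript_model(id, id, "chr1", strand, rbind(c(start, end)),
                     "lncRNA_candidate")
  }
  list(
    coding = list(g1, g2),
    candidates = list(
      cand("so1", "+", 1200, 1300),    # inside G1 exon 1, same strand
      cand("so2", "-", 50700, 50800),  # inside G2 exon 2, same strand
      cand("in1", "+", 1450, 1550),    # inside G1 intron, same strand
      cand("in2", "-", 50450, 50550),  # inside G2 intron, same strand
      cand("as1", "-", 1100, 1700),    # across G1 span, opposite strand
      cand("as2", "+", 50100, 50200),  # inside G2 span, opposite strand
      cand("bi1", "-", 200, 900),      # TSS 900 vs G1 TSS 1000 (100 bp)
      cand("bi2", "+", 51500, 51900),  # TSS 51500 vs G2 TSS 51000 (500 bp)
      cand("ig1", "+", 20000, 20400),
      cand("ig2", "-", 30000, 30400)),
    expected = c(so1 = "sense_overlapping", so2 = "sense_overlapping",
                 in1 = "intronic", in2 = "intronic",
                 as1 = "antisense", as2 = "antisense",
                 bi1 = "bidirectional", bi2 = "bidirectional",
                 ig1 = "intergenic", ig2 = "intergenic"))
}

# build a target_map object directly for correlation-filter tests
manual_target_map <- function(pairs) {
  sites <- data.frame(mirna = pairs$mirna, target = pairs$target,
                      site_type = "8mer", position = 1L,
                      stringsAsFactors = FALSE)
  structure(list(
    targets_by_mirna = lapply(split(sites$target, sites$mirna), unique),
    sites = sites), class = "target_map")
}

assoc_fixture_path <- function() {
  system.file("extdata", "broodiness_candidate_genes.tsv",
              package = "ceRNAsponge")
}
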