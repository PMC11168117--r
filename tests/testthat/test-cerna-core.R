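test_that("correlations match hand values and validate input", {
  expect_identical(spearman_rho(1:4, 4:1), -1)
  expect_identical(spearman_rho(1:3, 1:3), 1)
  expect_equal(spearman_rho(c(1, 1, 2), 1:3), 1.5 / sqrt(3))
  expect_equal(pearson_r(1:5, 2 * (1:5) + 1), 1, tolerance = 1e-12)
  expect_equal(pearson_r(1:5, -(1:5)), -1, tolerance = 1e-12)
  expect_true(is.na(spearman_rho(c(2, 2, 2), 1:3)))
  expect_true(is.na(pearson_r(c(2, 2, 2), 1:3)))
  expect_error(spearman_rho(1:4, 1:5), "equal length")
  expect_error(pearson_r(1:2, 1:2), "3 observations")
  expect_error(spearman_rho(c(1, NA, 3), 1:3), "finite")
})

test_that("correlations agree with textbook formulas on random vectors", {
  set.seed(10)
  for (i in 1:1000) {
    n <- sample(3:40, 1)
    x <- rnorm(n)
    y <- rnorm(n) + 0.3 * x
    expect_equal(pearson_r(x, y), textbook_pearson(x, y), tolerance = 1e-12)
    expect_equal(spearman_rho(x, y), textbook_spearman(x, y),
                 tolerance = 1e-12)
  }
})

test_that("rank correlation is invariant under strictly monotone transforms", {
  set.seed(11)
  for (i in 1:50) {
    x <- rnorm(20); y <- rnorm(20)
    rho <- spearman_rho(x, y)
    expect_equal(spearman_rho(exp(x), y), rho, tolerance = 1e-12)
    expect_equal(spearman_rho(x, y^3 + 5 * y), rho, tolerance = 1e-12)
    expect_equal(spearman_rho(-x, y), -rho, tolerance = 1e-12)
  }
})

test_that("sponge p-values match exact enumeration spot values", {
  expect_identical(sponge_pvalue(0, 4, 5, 10), 1)
  expect_identical(sponge_pvalue(1, 1, 1, 2), 0.5)
  expect_identical(sponge_pvalue(3, 4, 5, 10), 66 / 252)
  expect_error(sponge_pvalue(3, 2, 5, 10), "min\\(m, n\\)")
  expect_error(sponge_pvalue(1, 11, 5, 10), "universe")
})

test_that("sponge p-values agree with phyper and are monotone in x", {
  set.seed(12)
  for (i in 1:200) {
    u <- sample(2:400, 1)
    m <- sample(0:u, 1); n <- sample(0:u, 1)
    x <- sample(0:min(m, n), 1)
    expect_equal(sponge_pvalue(x, m, n, u),
                 phyper(x - 1, m, u - m, n, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
  for (u in c(10, 30)) {
    p <- vapply(0:5, sponge_pvalue, numeric(1), m = 6, n = 7, u = u)
    expect_true(all(diff(p) <= 0))
  }
})

test_that("the Spearman filter is strictly below -0.7", {
  # ranks engineered so Spearman(m1, t1) = -0.7 exactly (sum d^2 = 34) and
  # Spearman(m1, t2) = -0.9 (sum d^2 = 38)
  expr <- rbind(m1 = c(1, 2, 3, 4, 5),
                t1 = c(5, 3, 2, 4, 1),
                t2 = c(5, 4, 2, 3, 1))
  colnames(expr) <- paste0("s", 1:5)
  de <- data.frame(feature_id = c("m1", "t1", "t2"),
                   rna_class = c("miRNA", "mRNA", "mRNA"),
                   status = c("up", "down", "down"))
  map <- manual_target_map(data.frame(mirna = "m1", target = c("t1", "t2")))
  edges <- candidate_pairs(map, de, expr)
  expect_identical(stats::setNames(edges$passes, edges$target),
                   c(t1 = FALSE, t2 = TRUE))
  expect_equal(edges$rho[edges$target == "t2"], -0.9)
})

test_that("triplet assembly enforces strict PCC and sponge thresholds", {
  # one shared miRNA between a lncRNA and an mRNA whose expressions are
  # affinely identical (PCC = 1) and anticorrelated with the miRNA
  expr <- rbind(m1 = c(5, 4, 3, 2, 1),
                ce = c(1, 2, 3, 4, 5),
                g1 = c(2, 4, 6, 8, 10))
  colnames(expr) <- paste0("s", 1:5)
  de <- data.frame(feature_id = c("m1", "ce", "g1"),
                   rna_class = c("miRNA", "lncRNA", "mRNA"),
                   status = c("down", "up", "up"))
  map <- manual_target_map(data.frame(mirna = "m1", target = c("ce", "g1")))
  edges <- candidate_pairs(map, de, expr)
  expect_true(all(edges$passes))

  # x=1, M=1, N=1: U = 20 puts the sponge p at exactly 0.05 -> rejected;
  # U = 21 puts it below -> accepted
  expect_identical(nrow(assemble_triplets(edges, expr, 20)), 0L)
  trip <- assemble_triplets(edges, expr, 21)
  expect_identical(nrow(trip), 1L)
  expect_identical(trip$ce_id, "ce")
  expect_identical(trip$mrna_id, "g1")
  expect_equal(trip$sponge_pvalue, 1 / 21)
  expect_equal(trip$pcc_ce_mrna, 1)

  # PCC boundary: threshold set to the pair's own PCC must exclude it
  expect_identical(nrow(assemble_triplets(edges, expr, 21,
                                          pcc_threshold = 1)), 0L)
  # sponge boundary: alpha equal to the p-value must exclude it
  expect_identical(nrow(assemble_triplets(edges, expr, 21,
                                          sponge_alpha = 1 / 21)), 0L)
})

test_that("emitted triplets re-validate and ignore input order", {
  sc <- generate_scenario(recovery_config(3))
  res <- run_cerna_analysis(sc$counts, sc$sequences)
  trip <- res$triplets
  expect_gt(nrow(trip), 0L)
  expect_true(all(trip$scc_ce_mirna < -0.7))
  expect_true(all(trip$scc_mrna_mirna < -0.7))
  expect_true(all(trip$pcc_ce_mrna > 0.9))
  expect_true(all(trip$sponge_pvalue < 0.05))
  expect_true(all(trip$x <= pmin(trip$m, trip$n)))
  expect_true(all(trip$u >= pmax(trip$m, trip$n)))

  expr <- expression_matrix(sc$counts)
  shuffled <- res$edges[rev(seq_len(nrow(res$edges))), ]
  trip2 <- assemble_triplets(shuffled, expr, res$universe_u)
  expect_identical(trip, trip2)
  # output is lexicographically ordered
  expect_identical(order(trip$ce_id, trip$mirna_id, trip$mrna_id),
                   seq_len(nrow(trip)))
})
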