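toy_matrix <- function(counts, n_a = 2, n_b = 2, class = "mRNA") {
  sid <- c(paste0("a", seq_len(n_a)), paste0("b", seq_len(n_b)))
  colnames(counts) <- sid
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("f", seq_len(nrow(counts)))
  }
  count_matrix(counts, class,
               stats::setNames(rep(c("groupA", "groupB"), c(n_a, n_b)), sid))
}

test_that("CPM columns sum to one million and match hand arithmetic", {
  cm <- toy_matrix(matrix(c(1, 9, 3, 7, 2, 8, 5, 5), nrow = 2))
  cpm <- cpm_normalize(cm)
  expect_equal(unname(colSums(cpm)), rep(1e6, 4))
  expect_equal(unname(cpm[, 1]), c(1e5, 9e5))
  expect_equal(unname(cpm[, 2]), c(3e5, 7e5))

  set.seed(1)
  cm2 <- toy_matrix(matrix(rpois(40, 50), nrow = 10))
  expect_equal(unname(colSums(cpm_normalize(cm2))), rep(1e6, 4),
               tolerance = 1e-12)

  z <- matrix(c(0, 0, 1, 1, 1, 1, 1, 1), nrow = 2)
  expect_error(cpm_normalize(toy_matrix(z)), "a1")
})

test_that("log2 fold change matches hand arithmetic and is antisymmetric", {
  expect_identical(log2_fold_change(10, 10), 0)
  expect_equal(log2_fold_change(50, 200), log2(201 / 51))
  expect_equal(log2_fold_change(50, 200), 1.9786, tolerance = 1e-4)
  set.seed(2)
  a <- runif(50, 0, 1e3); b <- runif(50, 0, 1e3)
  expect_equal(log2_fold_change(a, b), -log2_fold_change(b, a))
})

test_that("identical groups give p = 1; a massive shift gives tiny p", {
  flat <- toy_matrix(matrix(rep(c(5L, 7L, 9L), each = 4), nrow = 3,
                            byrow = TRUE), n_a = 2, n_b = 2)
  expect_true(all(de_test(flat) == 1))

  set.seed(3)
  counts <- rbind(c(rnbinom(20, mu = 10, size = 20),
                    rnbinom(20, mu = 10000, size = 20)),
                  matrix(rnbinom(40 * 20, mu = 100, size = 20), nrow = 20))
  cm <- toy_matrix(counts, n_a = 20, n_b = 20)
  expect_lt(de_test(cm)[["f1"]], 1e-6)
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_identical(bh_fdr(0.5), 0.5)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(c(0.01, 0.04, 0.9)), c(0.03, 0.06, 0.9))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(4)
  for (i in 1:1000) {
    p <- runif(sample(1:60, 1))
    expect_equal(bh_fdr(p), bh_brute(p), tolerance = 1e-12)
  }
})

test_that("the significance gate is inclusive on FC and strict on FDR", {
  gate <- ceRNAsponge:::de_status
  expect_identical(gate(1.0, 0.049), "up")
  expect_identical(gate(0.99, 0.001), "ns")
  expect_identical(gate(-1.2, 0.05), "ns")
  expect_identical(gate(-1.0, 0.0499), "down")
})

test_that("swapping conditions swaps the up and down calls exactly", {
  set.seed(5)
  counts <- matrix(rnbinom(200 * 8, mu = 120, size = 10), nrow = 200)
  counts[1:20, 5:8] <- rnbinom(20 * 4, mu = 700, size = 10)
  cm <- toy_matrix(counts, n_a = 4, n_b = 4)
  swapped <- cm
  swapped$condition <- factor(
    ifelse(cm$condition == "groupA", "groupB", "groupA"),
    levels = c("groupA", "groupB"))
  names(swapped$condition) <- names(cm$condition)
  de1 <- call_de(cm)
  de2 <- call_de(swapped)
  expect_identical(sum(de1$status == "up"), sum(de2$status == "down"))
  expect_identical(sum(de1$status == "down"), sum(de2$status == "up"))
  expect_identical(which(de1$status == "up"), which(de2$status == "down"))
  expect_false(any(de1$status == "up" & de1$status == "down"))
})

test_that("2^-ddCt matches its definition", {
  expect_identical(ddct_fold_change(20, 20, 20, 20), 1)
  expect_identical(ddct_fold_change(21, 20, 20, 20), 0.5)
  expect_identical(ddct_fold_change(20, 15, 22, 15), 4)
})
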