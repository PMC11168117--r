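toy_triplet <- function(ce, mir, gene, ce_class = "lncRNA") {
  data.frame(ce_id = ce, ce_class = ce_class, mirna_id = mir,
             mrna_id = gene, scc_ce_mirna = -0.9, scc_mrna_mirna = -0.8,
             pcc_ce_mrna = 0.95, x = 1L, m = 1L, n = 1L, u = 30L,
             sponge_pvalue = 1 / 30, stringsAsFactors = FALSE)
}

test_that("one triplet yields a 3-node, 3-edge network", {
  net <- build_network(toy_triplet("lnc-1", "miR-1", "gene-1"))
  expect_identical(nrow(net$nodes), 3L)
  expect_identical(nrow(net$edges), 3L)
  expect_identical(summarize_nodes(net),
                   c(mRNA = 1L, miRNA = 1L, lncRNA = 1L, circRNA = 0L))
  expect_identical(sum(net$edges$kind == "mirna_represses"), 2L)
  expect_identical(sum(net$edges$kind == "cerna_coexpression"), 1L)
})

test_that("shared miRNA and mRNA deduplicate into 4 nodes and 5 edges", {
  trip <- rbind(toy_triplet("lnc-1", "miR-1", "gene-1"),
                toy_triplet("lnc-2", "miR-1", "gene-1"))
  net <- build_network(trip)
  expect_identical(nrow(net$nodes), 4L)
  expect_identical(nrow(net$edges), 5L)
})

test_that("empty triplets give an empty network; edge count is bounded", {
  expect_identical(nrow(build_network(toy_triplet("a", "b", "c")[0, ])$nodes),
                   0L)
  expect_identical(summarize_nodes(build_network(toy_triplet("a", "b",
                                                             "c")[0, ])),
                   c(mRNA = 0L, miRNA = 0L, lncRNA = 0L, circRNA = 0L))
  set.seed(20)
  trip <- do.call(rbind, lapply(1:20, function(i) {
    toy_triplet(paste0("lnc-", sample(5, 1)), paste0("miR-", sample(3, 1)),
                paste0("gene-", sample(4, 1)))
  }))
  trip <- trip[!duplicated(trip[c("ce_id", "mirna_id", "mrna_id")]), ]
  net <- build_network(trip)
  expect_lte(nrow(net$edges), 3L * nrow(trip))
})

test_that("node DE directions are annotated from the DE table", {
  de <- data.frame(feature_id = c("lnc-1", "miR-1", "gene-1"),
                   rna_class = c("lncRNA", "miRNA", "mRNA"),
                   status = c("up", "down", "up"))
  net <- build_network(toy_triplet("lnc-1", "miR-1", "gene-1"), de)
  expect_identical(
    stats::setNames(net$nodes$de_direction, net$nodes$id)[c("miR-1", "gene-1")],
    c(`miR-1` = "down", `gene-1` = "up"))
})

test_that("the THBS1/MYLK candidate subnetwork matches the printed counts", {
  assoc <- load_association_table(assoc_fixture_path())
  net <- subnetwork_for_genes(assoc, c("THBS1", "MYLK"))
  expect_identical(summarize_nodes(net),
                   c(mRNA = 2L, miRNA = 5L, lncRNA = 18L, circRNA = 4L))
  expect_identical(nrow(net$nodes), 29L)
  # gene order does not matter
  net2 <- subnetwork_for_genes(assoc, c("MYLK", "THBS1"))
  expect_identical(summarize_nodes(net2), summarize_nodes(net))
})

test_that("single-gene and empty selections behave as printed", {
  assoc <- load_association_table(assoc_fixture_path())
  expect_identical(summarize_nodes(subnetwork_for_genes(assoc, "COMP")),
                   c(mRNA = 1L, miRNA = 1L, lncRNA = 1L, circRNA = 0L))
  expect_identical(nrow(subnetwork_for_genes(assoc, character(0))$nodes), 0L)
  expect_error(subnetwork_for_genes(assoc, "NOSUCHGENE"), "NOSUCHGENE")
})

test_that("subnetwork node counts are order-invariant over all 25 genes", {
  assoc <- load_association_table(assoc_fixture_path())
  all_genes <- assoc$gene
  n1 <- summarize_nodes(subnetwork_for_genes(assoc, all_genes))
  set.seed(21)
  n2 <- summarize_nodes(subnetwork_for_genes(assoc, sample(all_genes)))
  expect_identical(n1, n2)
  expect_identical(unname(n1["mRNA"]), 25L)
})
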