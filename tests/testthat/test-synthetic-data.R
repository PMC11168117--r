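test_that("invalid configurations are rejected", {
  expect_error(scenario_config(n_replicates_per_group = 1), ">= 2")
  expect_error(scenario_config(n_mrna = 0), ">= 1")
  expect_error(scenario_config(base_mean = -5), "> 0")
  expect_error(scenario_config(n_planted_triplets = 200, n_lncrna = 50,
                               n_mrna = 50), "min")
})

test_that("a fixed seed reproduces the scenario bit for bit", {
  a <- generate_scenario(scenario_config(seed = 1))
  b <- generate_scenario(scenario_config(seed = 1))
  expect_identical(a$counts, b$counts)
  expect_identical(a$sequences, b$sequences)
  expect_identical(a$truth, b$truth)
  c <- generate_scenario(scenario_config(seed = 2))
  expect_false(identical(a$counts$mRNA$counts, c$counts$mRNA$counts))
})

test_that("truth set is internally consistent and counts are sound", {
  sc <- generate_scenario(scenario_config(seed = 4, n_planted_triplets = 8))
  for (cm in sc$counts) {
    expect_true(all(cm$counts >= 0))
    expect_identical(storage.mode(cm$counts), "integer")
  }
  tr <- sc$truth
  de_ids <- tr$planted_de$feature_id
  expect_true(all(tr$planted_triplets$ce_id %in% de_ids))
  expect_true(all(tr$planted_triplets$mirna_id %in% de_ids))
  expect_true(all(tr$planted_triplets$mrna_id %in% de_ids))
  pair_key <- paste(tr$planted_target_pairs$mirna_id,
                    tr$planted_target_pairs$target_id)
  expect_true(all(paste(tr$planted_triplets$mirna_id,
                        tr$planted_triplets$ce_id) %in% pair_key))
  expect_true(all(paste(tr$planted_triplets$mirna_id,
                        tr$planted_triplets$mrna_id) %in% pair_key))
})

test_that("null configuration plants nothing and decorrelates planted pairs", {
  cfg <- scenario_config(n_replicates_per_group = 5, n_mirna = 50,
                         n_mrna = 260, n_lncrna = 260, n_circrna = 150,
                         n_planted_triplets = 260,
                         n_planted_de_per_class = 0,
                         coupling_strength = 0, de_log2fc = 0, seed = 5)
  sc <- generate_scenario(cfg)
  expect_identical(nrow(sc$truth$planted_de), 0L)
  expr <- expression_matrix(sc$counts)
  pp <- sc$truth$planted_target_pairs
  expect_gte(nrow(pp), 500L)
  rho <- mapply(function(m, t) spearman_rho(expr[m, ], expr[t, ]),
                pp$mirna_id, pp$target_id)
  expect_lt(abs(mean(rho)), 0.1)
})

test_that("strong coupling yields strongly negative planted correlations", {
  # Monte-Carlo check on the generator itself, at the scaled-up design
  sc <- generate_scenario(scenario_config(
    n_replicates_per_group = 20, nb_dispersion = 0.05,
    coupling_strength = 2.0, seed = 7))
  expr <- expression_matrix(sc$counts)
  tr <- sc$truth$planted_triplets
  scc <- mapply(function(m, g) spearman_rho(expr[m, ], expr[g, ]),
                tr$mirna_id, tr$mrna_id)
  expect_lt(mean(scc), -0.7)
})

test_that("planted targets carry their seed site and decoys carry none", {
  sc <- generate_scenario(scenario_config(seed = 9, n_planted_triplets = 10))
  pp <- sc$truth$planted_target_pairs
  for (i in seq_len(nrow(pp))) {
    sites <- find_seed_sites(sc$sequences[[pp$mirna_id[i]]],
                             sc$sequences[[pp$target_id[i]]])
    expect_gte(nrow(sites), 1L)
  }
  planted_mirs <- unique(pp$mirna_id)
  target_ids <- setdiff(names(sc$sequences),
                        rownames(sc$counts$miRNA$counts))
  decoys <- setdiff(target_ids, pp$target_id)
  for (mir in planted_mirs) {
    for (tgt in decoys) {
      expect_identical(
        nrow(find_seed_sites(sc$sequences[[mir]], sc$sequences[[tgt]])), 0L)
    }
  }
})

test_that("generated transcript models cover all five positional classes", {
  sc <- generate_scenario(scenario_config(seed = 2))
  cl <- classify_lncrnas(sc$transcripts)
  expect_setequal(unique(cl$category),
                  c("intergenic", "bidirectional", "intronic", "antisense",
                    "sense_overlapping"))
  expect_identical(stats::setNames(cl$category, cl$transcript_id),
                   sc$lnc_design[cl$transcript_id])
})

test_that("scenario fixtures round-trip and are byte-stable", {
  sc <- generate_scenario(scenario_config(seed = 3))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_scenario(sc, d1)
  re <- load_scenario(d1)
  for (class in names(sc$counts)) {
    expect_identical(re$counts[[class]]$counts, sc$counts[[class]]$counts)
    expect_identical(re$counts[[class]]$condition, sc$counts[[class]]$condition)
  }
  expect_identical(re$sequences,
                   vapply(sc$sequences, ceRNAsponge:::as_dna, character(1)))
  expect_identical(length(re$transcripts), length(sc$transcripts))
  expect_identical(re$truth$planted_triplets$ce_id,
                   sc$truth$planted_triplets$ce_id)

  # writing the same seed twice gives byte-identical files
  write_scenario(generate_scenario(scenario_config(seed = 3)), d2)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- file.path(d2, basename(f1))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("an empty scenario still writes valid fixtures", {
  sc <- generate_scenario(scenario_config(seed = 6, n_planted_triplets = 0,
                                          n_planted_de_per_class = 0))
  d <- withr::local_tempdir()
  write_scenario(sc, d)
  re <- load_scenario(d)
  expect_identical(nrow(re$truth$planted_triplets), 0L)
  expect_identical(nrow(re$truth$planted_de), 0L)
})
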