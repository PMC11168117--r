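#!/usr/bin/env Rscript
# Stage 1: simulate a fully self-contained two-condition experiment.
#
# The scenario emulates the broody-vs-laying ovary design at a size where
# correlation filters are informative: 10 replicates per condition, 30
# planted ceRNA triplets (miRNA up or down, both targets pushed the
# opposite way through exp(-2 z)), and a 300-feature decoy background
# across the four RNA classes. Everything downstream reads the plain-text
# fixtures this stage writes.

library(ceRNAsponge)

cfg <- scenario_config(
  n_replicates_per_group = 10,
  n_mirna = 90, n_mrna = 110, n_lncrna = 95, n_circrna = 95,
  n_planted_triplets = 30, n_planted_de_per_class = 0,
  base_mean = 200, nb_dispersion = 0.05,
  coupling_strength = 2.0, de_log2fc = 2.0,
  seed = 7)

scenario <- generate_scenario(cfg)
write_scenario(scenario, "results/scenario")

print(scenario)
tr <- scenario$truth
cat(sprintf("planted DE features: %d (%d miRNA, %d mRNA, %d lncRNA, %d circRNA)\n",
            nrow(tr$planted_de),
            sum(tr$planted_de$class == "miRNA"),
            sum(tr$planted_de$class == "mRNA"),
            sum(tr$planted_de$class == "lncRNA"),
            sum(tr$planted_de$class == "circRNA")))
cat(sprintf("planted triplets: %d (%d lncRNA-ce, %d circRNA-ce); target pairs: %d\n",
            nrow(tr$planted_triplets),
            sum(tr$planted_triplets$ce_class == "lncRNA"),
            sum(tr$planted_triplets$ce_class == "circRNA"),
            nrow(tr$planted_target_pairs)))
cat("fixtures written to results/scenario/\n")
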