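#!/usr/bin/env Rscript
# Stage 4: ceRNA triplet inference and network assembly.
#
# The three acceptance rules in sequence: (1) seed-matched miRNA-target
# pairs, both DE, with Spearman < -0.7; (2) ceRNA-mRNA Pearson > 0.9;
# (3) hypergeometric shared-sponge test p < 0.05 with the universe U set
# to the number of DE miRNAs. Accepted triplets become the typed network.

library(ceRNAsponge)

scenario <- load_scenario("results/scenario")

res <- run_cerna_analysis(scenario$counts, scenario$sequences)

write.table(res$edges, "results/mirna_target_edges.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(res$triplets, "results/triplets.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
export_network(res$network, "results")

cat(sprintf("DE miRNAs (universe U): %d\n", res$universe_u))
cat(sprintf("miRNA-target edges: %d computed, %d pass SCC < -0.7\n",
            nrow(res$edges), sum(res$edges$passes)))
cat(sprintf("accepted triplets: %d (%d lncRNA-ce, %d circRNA-ce)\n",
            nrow(res$triplets),
            sum(res$triplets$ce_class == "lncRNA"),
            sum(res$triplets$ce_class == "circRNA")))
print(res$network)

found <- paste(res$triplets$ce_id, res$triplets$mirna_id, res$triplets$mrna_id)
truth <- paste(scenario$truth$planted_triplets$ce_id,
               scenario$truth$planted_triplets$mirna_id,
               scenario$truth$planted_triplets$mrna_id)
cat(sprintf("recall of planted triplets: %.2f; precision: %.2f\n",
            mean(truth %in% found),
            if (length(found)) mean(found %in% truth) else NA))
cat("network written to results/network.graphml and results/network_edges.tsv\n")
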