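#!/usr/bin/env Rscript
# Stage 5: candidate-gene subnetworks from the packaged association table.
#
# The 25-gene broodiness association table ships with the package; the
# THBS1/MYLK neighbourhood is the worked example whose node composition
# (2 mRNA, 5 miRNA, 18 lncRNA, 4 circRNA) the table determines exactly.

library(ceRNAsponge)

assoc <- load_association_table(
  system.file("extdata", "broodiness_candidate_genes.tsv",
              package = "ceRNAsponge"))
cat(sprintf("association records: %d genes\n", nrow(assoc)))

net <- subnetwork_for_genes(assoc, c("THBS1", "MYLK"))
counts <- summarize_nodes(net)
cat("THBS1/MYLK subnetwork node composition:\n")
print(counts)
cat(sprintf("total nodes: %d, edges: %d\n", nrow(net$nodes), nrow(net$edges)))

shared <- intersect(net$edges$source[net$edges$target == "THBS1"],
                    net$edges$source[net$edges$target == "MYLK"])
cat(sprintf("regulators shared by THBS1 and MYLK: %s\n",
            paste(shared, collapse = ", ")))

export_network(net, "results/candidate_subnetwork")
full <- subnetwork_for_genes(assoc, assoc$gene)
cat("all-candidate network node composition:\n")
print(summarize_nodes(full))
export_network(full, "results/candidate_network_all")
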