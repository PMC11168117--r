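#!/usr/bin/env Rscript
# Stage 3: canonical seed-match target prediction for the DE miRNAs.
#
# Whole transcripts are scanned for seed sites (miRNA positions 2-7 plus
# the m8/A1 extensions); sites weaker than 7mer-m8 are dropped to limit
# false positives.

library(ceRNAsponge)

scenario <- load_scenario("results/scenario")
de <- read.delim("results/de_all.tsv")

de_mirnas <- de$feature_id[de$rna_class == "miRNA" & de$status != "ns"]
mirna_ids <- rownames(scenario$counts$miRNA$counts)

map <- build_target_map(
  de_mirnas,
  scenario$sequences[intersect(names(scenario$sequences), mirna_ids)],
  scenario$sequences[setdiff(names(scenario$sequences), mirna_ids)],
  min_site_type = "7mer-m8")

write.table(map$sites, "results/seed_sites.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(map)
cat(sprintf("site types: %s\n",
            paste(names(table(map$sites$site_type)),
                  table(map$sites$site_type), collapse = ", ")))

pp <- scenario$truth$planted_target_pairs
covered <- mapply(function(m, t) t %in% map$targets_by_mirna[[m]],
                  pp$mirna_id, pp$target_id)
cat(sprintf("planted (miRNA, target) pairs with a detected site: %d / %d\n",
            sum(covered), nrow(pp)))
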