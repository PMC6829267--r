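#!/usr/bin/env Rscript
# Stage 4: neighbor-joining tree of the accepted family members from
# pairwise-alignment p-distances, with 1000 bootstrap replicates.

library(cbfsurvey)

proteins <- read_fasta("results/fixtures/proteins.faa", alphabet = "protein")
fam <- read.delim("results/family.tsv")
members <- proteins[fam$protein_id[fam$accepted]]

d <- pairwise_distance(members)
write.table(data.frame(taxon = rownames(d), round(d, 4)),
            "results/distances.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

bs <- bootstrap_support(members, reps = 1000, seed = 20191017)
write_newick(bs$tree, "results/tree.nwk")
write.table(bs$support, "results/tree_support.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Tree over", length(members), "members written to results/tree.nwk\n")
cat("Newick:", write_newick(bs$tree), "\n")
if (nrow(bs$support) > 0) {
  cat("Bootstrap support (1000 replicates):\n")
  print(bs$support, row.names = FALSE)
}
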