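#!/usr/bin/env Rscript
# Stage 3: physicochemical characterization of the accepted family members
# (length, MW, pI, instability, aliphatic index, GRAVY), the table-style
# block a family survey reports per gene.

library(cbfsurvey)

proteins <- read_fasta("results/fixtures/proteins.faa", alphabet = "protein")
fam <- read.delim("results/family.tsv")
members <- proteins[fam$protein_id[fam$accepted]]

props <- protein_properties(members)
write.table(props, "results/protein_properties.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

print(props, row.names = FALSE)
cat(sprintf("\n%d of %d members predicted unstable (instability > 40); %d hydrophilic (GRAVY < 0)\n",
            sum(!props$stable), nrow(props), sum(props$gravy < 0)))
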