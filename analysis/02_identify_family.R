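#!/usr/bin/env Rscript
# Stage 2: identify the CBF-like family in the synthetic proteome by local
# alignment homology plus verification of the two signature sequences
# (PKK/RPAGRxKFxETRHP and DSAWR) flanking the AP2 domain.

library(cbfsurvey)

proteins <- read_fasta("results/fixtures/proteins.faa", alphabet = "protein")
truth <- read.delim("results/fixtures/family_truth.tsv")

fam <- identify_family(proteins["member01"], proteins,
                       min_score_frac = 0.4, sep_window = c(40, 120))
write.table(fam, "results/family.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

acc <- fam$protein_id[fam$accepted]
cat("Screened", length(proteins), "proteins;", length(acc), "accepted:",
    paste(acc, collapse = ", "), "\n")
cat("Planted members recovered:",
    length(intersect(acc, truth$protein_id)), "of", nrow(truth), "\n")
cat("False positives:", length(setdiff(acc, truth$protein_id)), "\n")
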