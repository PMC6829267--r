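#!/usr/bin/env Rscript
# Stage 5: extract the 1000-bp upstream promoter of every gene and scan for
# the CRT/DRE motif (RCCGAC, both strands) and the cis-element catalogue.

library(cbfsurvey)

genome <- read_fasta("results/fixtures/genome.fa")
genes <- read_gff3("results/fixtures/genes.gff3")
truth <- read.delim("results/fixtures/motif_truth.tsv")

proms <- extract_promoters(genes, genome, length = 1000)
write_fasta(setNames(proms$sequence, proms$gene_id),
            "results/promoters.fa")

hits <- scan_promoters(proms, crt_dre_motif(), name = "CRT/DRE")
write.table(hits, "results/crtdre_hits.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
counts <- count_motif_hits(proms, crt_dre_motif())
write.table(data.frame(gene_id = names(counts), n_crtdre = counts),
            "results/crtdre_counts.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

grid <- scan_catalogue(proms)
write.table(cbind(gene_id = rownames(grid), as.data.frame(grid)),
            "results/element_grid.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

truth <- truth[match(names(counts), truth$gene_id), ]
plus <- hits[hits$strand == "+", ]
plus_counts <- table(factor(plus$gene_id, levels = names(counts)))
cat("Promoters extracted:", nrow(proms),
    sprintf("(%d truncated)\n", sum(proms$truncated)))
cat("Genes with >= 1 CRT/DRE:", sum(counts >= 1), "of", length(counts), "\n")
cat("Planted copies recovered exactly (plus strand):",
    sum(as.integer(plus_counts) == truth$n_planted), "of", nrow(truth), "\n")
cat("Cis-element grid:", nrow(grid), "genes x", ncol(grid), "elements;",
    sum(grid > 0), "non-zero cells\n")
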