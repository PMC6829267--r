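#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs with planted ground truth.
#
# The fixture emulates the real study's substrate at desk scale: a small
# multi-contig genome whose genes carry 1000-bp promoters (110 of 200 with
# one planted CRT/DRE copy), a winter/summer count table with 30 up- and
# 80 down-planted target genes plus 90 near-boundary decoys, a five-member
# CBF-like protein family among 50 background proteins, and a qPCR cold
# time course with three biological replicates.

library(cbfsurvey)

seed <- 20191017
fix_dir <- "results/fixtures"
dir.create(fix_dir, recursive = TRUE, showWarnings = FALSE)

fam <- make_family(n_members = 5, n_background = 50, seed = seed)
write_fasta(fam$proteins, file.path(fix_dir, "proteins.faa"))
write.table(fam$truth, file.path(fix_dir, "family_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

g <- make_genome(200, seed = seed + 1, n_contigs = 4,
                 motif_copies = c(rep(1L, 110), rep(0L, 90)))
write_fasta(g$genome, file.path(fix_dir, "genome.fa"))
write_gff3(g$genes, file.path(fix_dir, "genes.gff3"))
motif_truth <- data.frame(gene_id = g$truth$gene_id,
                          n_planted = g$truth$n_planted,
                          offsets = vapply(g$truth$offsets, paste,
                                           character(1), collapse = ","))
write.table(motif_truth, file.path(fix_dir, "motif_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

mc <- make_counts(g$genes$gene_id, n_up = 30, n_down = 80, n_decoy = 90,
                  effect_log2fc = 3, noise_sd = 0.1, seed = seed + 2)
write.table(mc$counts, file.path(fix_dir, "counts.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(sample = names(mc$totals), total = mc$totals),
            file.path(fix_dir, "totals.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(mc$truth, file.path(fix_dir, "counts_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# plausible free-text annotations spanning the functional categories
set.seed(seed + 3)
vocab <- c("galactinol synthase", "raffinose synthase", "beta-glucosidase",
           "phospholipase D", "wax-ester synthase", "chitinase class I",
           "pectate lyase", "xyloglucan endotransglucosylase",
           "circadian clock protein CCA1-like", "calmodulin-binding protein",
           "calcium-transporting ATPase", "WRKY transcription factor",
           "MYB transcription factor", "bHLH transcription factor",
           "auxin-responsive protein IAA", "DELLA protein",
           "JAZ protein TIFY", "receptor-like protein kinase",
           "chloroplast photosystem II protein", "sugar transporter",
           "ABC transporter family protein", "hypothetical protein",
           "uncharacterized protein", "ribosomal protein L12")
ann <- data.frame(gene_id = g$genes$gene_id,
                  annotation = sample(vocab, 200, replace = TRUE))
write.table(ann, file.path(fix_dir, "annotations.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# qPCR cold time course: calibrator 0h, strong induction peaking 1-12 h,
# one member (the CsCBF3-like gene) flat
set.seed(seed + 4)
times <- c("0h", "1h", "3h", "6h", "12h", "24h", "48h")
induction <- c(0, 3.2, 2.5, 2.0, 1.4, 0.8, 0.4)  # -ddCt of an induced gene
qpcr <- do.call(rbind, lapply(seq_along(times), function(i) {
  data.frame(sample = times[i], replicate = 1:3,
             ct_target = 26 - induction[i] + rnorm(3, 0, 0.15),
             ct_reference = 20 + rnorm(3, 0, 0.1))
}))
write.table(qpcr, file.path(fix_dir, "qpcr.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Fixtures written to", fix_dir, "\n")
cat("  family: 5 planted members + 50 background proteins\n")
cat("  genome: 200 genes on 4 contigs; 110 promoters carry one CRT/DRE\n")
cat("  counts: 30 up / 80 down planted (2^3-fold), 90 decoys\n")
cat("  qPCR : 7 time points x 3 replicates, calibrator 0h\n")
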