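#!/usr/bin/env Rscript
# Stage 6: FPKM from counts, the winter/summer fold changes, and the qPCR
# cold time course analyzed by 2^-ddCt with Welch significance on dCt.

library(cbfsurvey)

counts <- read.delim("results/fixtures/counts.tsv", check.names = FALSE)
totals_df <- read.delim("results/fixtures/totals.tsv")
totals <- setNames(totals_df$total, totals_df$sample)

expr <- expression_matrix(counts, totals)
write.table(cbind(gene_id = rownames(expr), as.data.frame(round(expr, 3))),
            "results/fpkm.tsv", sep = "\t", quote = FALSE, row.names = FALSE)

fc <- fold_change(expr[, "winter_mature_leaf"], expr[, "summer_mature_leaf"])
fc <- cbind(gene_id = rownames(expr), round(fc[1:2], 4),
            direction = fc$direction)
write.table(fc, "results/fold_changes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Fold-change calls:", sum(fc$direction == "up"), "up,",
    sum(fc$direction == "down"), "down,",
    sum(fc$direction == "unchanged"), "unchanged\n")

qpcr <- read.delim("results/fixtures/qpcr.tsv")
rq <- ddct(qpcr, calibrator = "0h")
write.table(rq$summary, "results/qpcr_rq.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("\nqPCR relative expression (calibrator 0h):\n")
print(transform(rq$summary, rq = round(rq, 2), se = round(se, 3),
                p_value = signif(p_value, 3)), row.names = FALSE)
peak <- rq$summary$sample[which.max(rq$summary$rq)]
cat("Peak induction at", peak, "- significant time points:",
    paste(rq$summary$sample[which(rq$summary$significant)], collapse = ", "),
    "\n")
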