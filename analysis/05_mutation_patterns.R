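#!/usr/bin/env Rscript
# Stage 5 — mutation co-occurrence and mutual exclusivity per subtype.
#
# Pairwise odds ratios (Haldane-Anscombe corrected for display when a cell
# is zero) with two-sided Fisher exact p-values over all 25 genes, within
# each subtype, plus per-subtype mutation proportions. Writes
# cooccurrence_<subtype>.csv, mutation_proportions.csv and a signed-log-OR
# heatmap per subtype.

library(radjoint)

SEED <- 20260401 %% 2147483647
cohort <- generate_cohort(synthetic_config(n_subjects = 500, seed = SEED))
sub <- utils::read.csv("results/subtypes.csv")
labels <- sub$subtype

gen_present <- cohort$dataset$has_genomic
gen <- cohort$dataset$genomic[gen_present, , drop = FALSE]
labs <- labels[gen_present]

rep_ <- pairwise_mutation_or(gen, labs)
print(rep_)
sig <- rep_$pairs[rep_$pairs$p_value < 0.05, ]
sig <- sig[order(sig$subtype, sig$p_value), ]
cat("significant pairs (raw p < 0.05):\n")
print(sig, digits = 3, row.names = FALSE)

dir.create("results", showWarnings = FALSE)
for (st in sort(unique(labs))) {
  utils::write.csv(rep_$pairs[rep_$pairs$subtype == st, ],
                   sprintf("results/cooccurrence_%d.csv", st),
                   row.names = FALSE)
}
props <- mutation_proportions(gen, labs)
utils::write.csv(props, "results/mutation_proportions.csv",
                 row.names = FALSE)
cat("most mutated genes overall:\n")
print(head(props, 8), digits = 2, row.names = FALSE)

# green = co-mutation (log OR > 0), pink = exclusivity (log OR < 0)
pdf("results/cooccurrence_heatmaps.pdf", width = 7, height = 7)
pal <- colorRampPalette(c("hotpink3", "white", "darkgreen"))(61)
for (st in sort(unique(labs))) {
  lor <- log(rep_[[as.character(st)]]$odds_ratio)
  lor[is.na(lor)] <- 0
  lim <- max(abs(lor), 1e-6)
  image(seq_len(ncol(lor)), seq_len(nrow(lor)), t(lor[rev(seq_len(nrow(lor))), ]),
        zlim = c(-lim, lim), col = pal, axes = FALSE,
        xlab = "", ylab = "", main = paste("Subtype", st, "log odds ratio"))
  axis(1, seq_len(ncol(lor)), colnames(lor), las = 2, cex.axis = 0.5)
  axis(2, seq_len(nrow(lor)), rev(rownames(lor)), las = 2, cex.axis = 0.5)
}
dev.off()
cat("heatmaps written to results/cooccurrence_heatmaps.pdf\n")
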