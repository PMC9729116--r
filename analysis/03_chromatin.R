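#!/usr/bin/env Rscript
# snATAC side: QC (>= 200 detected peaks, peaks in >= 10 nuclei, fragments
# 1,500-15,000, >15% reads in peaks, blacklist < 0.02, nucleosome signal
# < 2, TSS enrichment > 4), TF-IDF/LSI on the top 25% of peaks with
# depth-correlated components dropped, and gene activity scores
# (body + 2 kb promoter, median-normalized, log1p).

suppressMessages(library(dmgatlas))

cfg <- sim_config(seed = 1)
sim <- gen_expression(cfg)
atac <- gen_atac(cfg, sim$truth)
am <- qc_filter_atac(atac$mat, atac$qc)
cat("nuclei kept:", ncol(am$counts), "of", ncol(atac$mat$counts),
    "; per-rule removals:\n")
print(attr(am, "qc_log"))

lsi <- tfidf_lsi(am)
cat("LSI components dropped for depth correlation:",
    paste(lsi$dropped, collapse = ", "),
    sprintf("(|r| = %.2f)", abs(lsi$depth_cor[lsi$dropped[1]])), "\n")

# how well the embedding organizes nuclei by planted state
corrected <- center_by_sample(lsi$coords,
                              atac$truth$nucleus_samples[rownames(lsi$coords)])
D <- as.matrix(dist(corrected)); diag(D) <- Inf
ns <- atac$truth$nucleus_states[rownames(corrected)]
purity <- mean(ns[apply(D, 1, which.min)] == ns)
cat("1-NN state purity of the corrected LSI embedding:",
    round(purity, 3), "\n")

act <- gene_activity(am, atac$annotation)
cat("gene activity matrix:", nrow(act$activity), "genes x",
    ncol(act$activity), "nuclei\n")
dir.create("results", showWarnings = FALSE)
write_tsv(data.frame(component = seq_along(lsi$depth_cor),
                     depth_correlation = lsi$depth_cor,
                     kept = seq_along(lsi$depth_cor) %in% lsi$kept),
          "results/lsi_depth_correlations.tsv")
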