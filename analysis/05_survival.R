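#!/usr/bin/env Rscript
# Stage 5: median-split univariate survival screen of network genes.
#
# Every lncRNA and mRNA in the ceRNA network is screened: patients are
# split at the gene's median logCPM, and the high/low arms compared by
# Kaplan-Meier / log-rank, with the Mantel-Haenszel hazard ratio
# (high vs low) reported.

library(cernet)

dat <- "results/data"
clinical <- read_clinical_table(file.path(dat, "clinical.tsv"))

lc <- utils::read.delim(file.path(dat, "logcpm_rna.tsv"), check.names = FALSE)
m <- as.matrix(lc[, -1]); rownames(m) <- lc$gene_id
g <- utils::read.delim(file.path(dat, "rna_counts.tsv.groups.tsv"))
expr <- expr_matrix(m, log = TRUE, prior_count = 0.5,
                    groups = stats::setNames(
                      factor(g$group, levels = c("normal", "tumour")),
                      g$sample_id))

net <- read_network_graphml(file.path(dat, "network.graphml"))
genes <- intersect(net$nodes$id[net$nodes$biotype %in% c("lncRNA", "mRNA")],
                   rownames(m))

scr <- gene_survival_screen(expr, clinical, genes = genes)
utils::write.table(as.data.frame(scr), file.path(dat, "survival_screen.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("screened %d network genes over %d patients\n",
            nrow(scr), sum(scr$n_high[1], scr$n_low[1])))
sig <- scr[scr$logrank_p < 0.05, ]
if (nrow(sig) > 0) {
  cat("genes with log-rank p < 0.05:\n")
  print(sig[order(sig$logrank_p), c("gene", "HR", "logrank_chi2", "logrank_p")],
        row.names = FALSE)
} else {
  cat("no network gene reached log-rank p < 0.05\n")
}
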