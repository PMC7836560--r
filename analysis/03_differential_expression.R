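#!/usr/bin/env Rscript
# Stage 3: moderated-t differential expression, tumour vs normal.
#
# Empirical-Bayes moderated t on filtered logCPM; genes are called
# up/down at FDR < 0.01 and fold change > 2, and a volcano table
# (-log10 FDR vs log2 FC) is written for plotting.

library(cernet)

dat <- "results/data"

read_logcpm <- function(nm) {
  lc <- utils::read.delim(file.path(dat, sprintf("logcpm_%s.tsv", nm)),
                          check.names = FALSE)
  m <- as.matrix(lc[, -1]); rownames(m) <- lc$gene_id
  g <- utils::read.delim(file.path(dat, sprintf("%s_counts.tsv.groups.tsv",
                                                if (nm == "rna") "rna" else "mirna")))
  expr_matrix(m, log = TRUE, prior_count = 0.5,
              groups = stats::setNames(
                factor(g$group, levels = c("normal", "tumour")), g$sample_id))
}

for (nm in c("rna", "mirna")) {
  e <- read_logcpm(nm)
  de <- moderated_t(e, fc_threshold = 2, p_threshold = 0.01,
                    use_adjusted = TRUE)
  utils::write.table(as.data.frame(de), file.path(dat, sprintf("de_%s.tsv", nm)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(volcano_table(de),
                     file.path(dat, sprintf("volcano_%s.tsv", nm)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s: %d up, %d down of %d tested (prior df %.2f, prior var %.3f)\n",
              nm, sum(de$class == "up"), sum(de$class == "down"), nrow(de),
              attr(de, "d0"), attr(de, "s0sq")))
}
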