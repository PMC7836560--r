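#!/usr/bin/env Rscript
# Stage 2: TMM normalisation, logCPM, and the low-expression filter.
#
# Genes below 1 logCPM in more than half of the samples are removed,
# separately for the RNA and miRNA matrices.

library(cernet)

dat <- "results/data"
rna <- read_count_matrix(file.path(dat, "rna_counts.tsv"))
mir <- read_count_matrix(file.path(dat, "mirna_counts.tsv"))

for (nm in c("rna", "mirna")) {
  cm <- if (nm == "rna") rna else mir
  f <- tmm_factors(cm)
  lc <- cpm_matrix(cm, f, log = TRUE, prior_count = 0.5)
  keep <- filter_low_expression(lc, threshold = 1.0, max_low_fraction = 0.5)
  lc <- subset_genes(lc, keep)
  utils::write.table(f, file.path(dat, sprintf("tmm_factors_%s.tsv", nm)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene_id = rownames(lc$values), lc$values, check.names = FALSE),
    file.path(dat, sprintf("logcpm_%s.tsv", nm)),
    sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s: TMM factors in [%.3f, %.3f]; kept %d / %d genes after the logCPM filter\n",
              nm, min(f$norm_factor), max(f$norm_factor),
              length(keep), nrow(cm$counts)))
}
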