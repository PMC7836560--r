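#!/usr/bin/env Rscript
# Stage 1: generate the synthetic tumour/normal multi-omic cohort.
#
# Emulates the shape of a paired bulk RNA-seq + miRNA-seq + clinical
# study: NB counts for 1000 mRNAs / 200 lncRNAs / 150 miRNAs over 50
# tumour and 50 normal samples, 10% planted DE, five planted ceRNA
# triples (latent loading 0.8), a StarBase-like interaction table, and
# censored survival for the tumour arm with two hazard-linked genes.
# Everything downstream is driven by these files.

library(cernet)

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 101)
d <- simulate_dataset(cfg)

write_count_matrix(d$rna, file.path(out, "rna_counts.tsv"))
write_count_matrix(d$mirna, file.path(out, "mirna_counts.tsv"))
write_gene_annotation(d$annotation, file.path(out, "annotation.tsv"))
write_interaction_table(d$interactions, file.path(out, "interactions.tsv"))
write_clinical_table(d$clinical, file.path(out, "clinical.tsv"))
utils::write.table(d$truth$de_genes, file.path(out, "truth_de_genes.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
truth_triples <- do.call(rbind, lapply(d$truth$triples, function(t)
  data.frame(lncrna = t$lncrna, mrna = t$mrna,
             mirnas = paste(t$mirnas, collapse = ","))))
utils::write.table(truth_triples, file.path(out, "truth_triples.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("simulated %d RNA genes x %d samples, %d miRNAs; %d planted DE genes, %d triples, %d interaction edges, %d clinical records\n",
            nrow(d$rna$counts), ncol(d$rna$counts), nrow(d$mirna$counts),
            nrow(d$truth$de_genes), length(d$truth$triples),
            nrow(d$interactions), nrow(d$clinical)))
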