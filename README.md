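# cernet

Competing-endogenous-RNA (ceRNA) network inference and survival
screening for paired tumour/normal bulk transcriptomes.

## What it does

Long noncoding RNAs can act as miRNA sponges: a lncRNA and an mRNA that
share miRNA response elements compete for the same miRNA pool, so the
lncRNA's rise de-represses the mRNA. `cernet` turns that hypothesis into
a tested pipeline over raw RNA-seq + miRNA-seq counts and clinical
follow-up:

1. **Normalisation** — TMM scaling factors and log2 CPM (edgeR), with
   the low-expression filter *drop genes below 1 logCPM in more than
   half of the samples*.
2. **Differential expression** — empirical-Bayes moderated t on logCPM:
   posterior variance (d0·s0² + df·s²)/(d0 + df), t on d0 + df degrees
   of freedom, BH-FDR, and up/down calls at FC > 2 and p < 0.01.
3. **ceRNA inference** — for each DE lncRNA × DE mRNA pair, three lines
   of evidence: the shared-miRNA upper-tail hypergeometric test
   P(X ≥ k) with X ~ Hypergeom(N, K, n); positive, significant Pearson
   correlation of the pair (computed within tumour samples); and the
   regulation-similarity score
   mean_i [1 − |c_i^lnc − c_i^m|/(|c_i^lnc| + |c_i^m|)]^M over the M
   shared miRNAs.
4. **Network assembly** — tripartite lncRNA–miRNA–mRNA graph from the
   passed pairs, exported as SIF / GraphML for Cytoscape.
5. **Survival screen** — per network gene: median split of expression,
   Kaplan–Meier curves, log-rank test, Mantel–Haenszel hazard ratio
   (O_high/E_high)/(O_low/E_low).

A seeded synthetic-data generator (`sim_config()` /
`simulate_dataset()`) plants known DE genes, ceRNA triples (via a
per-sample latent factor loading +s on lncRNA/mRNA and −s on the shared
miRNAs) and expression-linked exponential survival, so the whole
pipeline is validated against ground truth. See the methods vignette
(`vignettes/cerna-pipeline.Rmd`) for models, assumptions and design
choices.

## Worked example

The `analysis/` drivers run the whole workflow on the default synthetic
cohort (50 tumour + 50 normal samples; 1000 mRNA / 200 lncRNA / 150
miRNA genes; 5 planted triples), writing every table under
`results/data/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_normalize_filter.R
Rscript analysis/03_differential_expression.R
Rscript analysis/04_cerna_network.R
Rscript analysis/05_survival.R
Rscript analysis/06_single_cell_summary.R
```

which prints, stage by stage:

```
simulated 1200 RNA genes x 100 samples, 150 miRNAs; 135 planted DE genes,
  5 triples, 921 interaction edges, 50 clinical records
rna: TMM factors in [0.900, 1.086]; kept 1200 / 1200 genes after the logCPM filter
rna: 60 up, 60 down of 1200 tested (prior df 39.44, prior var 0.250)
mirna: 0 up, 15 down of 150 tested (prior df 6.17, prior var 0.351)
tested 11 candidate pairs (20 DE lncRNAs x 100 DE mRNAs); 5 passed all three evidence lines
network: 25 nodes, 30 edges; top hubs: LNC0001, LNC0002, LNC0003
planted triples recovered: 5 / 5
screened 10 network genes over 50 patients
no network gene reached log-rank p < 0.05
```

Reading the numbers: all five planted lncRNA–mRNA competing pairs pass
the three evidence lines and nothing else joins the network beyond
their shared miRNAs; the survival screen at 50 patients is underpowered
for a hazard ratio of 2 (about 50% per-gene power), which is why the
calibration studies below use 200 patients. The same end-to-end run is
available programmatically as `run_pipeline(sim_config(seed = 101),
out_dir = "...")`, which also writes a manifest with md5 hashes of
every stage output (two runs with the same config and seed are
byte-identical).

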