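# End-to-end orchestration: simulate (or ingest) -> normalize/filter ->
# differential expression -> ceRNA inference -> survival screen ->
# export, under one seeded configuration with a content-hashed manifest.

#' Thresholds and options for the full pipeline
#'
#' @param filter_threshold,filter_max_low_fraction logCPM filter: drop a
#'   gene below \code{filter_threshold} in more than
#'   \code{filter_max_low_fraction} of samples.
#' @param fc_threshold,p_threshold,use_adjusted DE classification (fold
#'   change > 2, p < 0.01 on the FDR scale by default).
#' @param hyper_cut,cor_cut,regsim_cut,min_shared ceRNA evidence
#'   thresholds.
#' @param prior_count logCPM prior count.
#' @return List of class \code{pipeline_opts}.
#' @export
pipeline_opts <- function(filter_threshold = 1.0,
                          filter_max_low_fraction = 0.5,
                          fc_threshold = 2, p_threshold = 0.01,
                          use_adjusted = TRUE,
                          hyper_cut = 0.05, cor_cut = 0.05,
                          regsim_cut = 0.5, min_shared = 1L,
                          prior_count = 0.5) {
  structure(as.list(environment()), class = "pipeline_opts")
}

.de_ids_by_biotype <- function(de, annotation, biotype) {
  sig <- de$gene[de$class != "ns"]
  intersect(sig, annotation$gene_id[annotation$biotype == biotype])
}

#' Run the full ceRNA analysis pipeline on a synthetic dataset
#'
#' Stages: simulate -> TMM normalise + logCPM + low-expression filter
#' (RNA and miRNA separately) -> moderated-t DE for genes and miRNAs ->
#' triple-evidence ceRNA inference and network assembly -> median-split
#' survival screen of the network's lncRNA/mRNA nodes -> export. Every
#' stage output is written under \code{out_dir} and content-hashed into
#' \code{manifest.json}; identical (config, opts, seed) give identical
#' hashes.
#'
#' @param config A \code{\link{sim_config}} (its \code{seed} drives all
#'   randomness).
#' @param opts A \code{\link{pipeline_opts}}.
#' @param out_dir Output directory (created if needed); \code{NULL}
#'   skips writing and returns results only.
#' @return List: \code{data} (the simulated dataset), \code{factors_rna},
#'   \code{factors_mir}, \code{logcpm_rna}, \code{logcpm_mir},
#'   \code{de_rna}, \code{de_mir}, \code{pairs}, \code{network},
#'   \code{network_stats}, \code{survival}, \code{manifest}.
#' @export
run_pipeline <- function(config, opts = pipeline_opts(), out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  stage <- function(name, f) {
    tryCatch(f(), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  data <- stage("simulate", function() simulate_dataset(config))

  norm <- stage("normalize", function() {
    f_rna <- tmm_factors(data$rna)
    f_mir <- tmm_factors(data$mirna)
    lc_rna <- cpm_matrix(data$rna, f_rna, log = TRUE,
                         prior_count = opts$prior_count)
    lc_mir <- cpm_matrix(data$mirna, f_mir, log = TRUE,
                         prior_count = opts$prior_count)
    keep_rna <- filter_low_expression(lc_rna, opts$filter_threshold,
                                      opts$filter_max_low_fraction)
    keep_mir <- filter_low_expression(lc_mir, opts$filter_threshold,
                                      opts$filter_max_low_fraction)
    list(f_rna = f_rna, f_mir = f_mir,
         lc_rna = subset_genes(lc_rna, keep_rna),
         lc_mir = subset_genes(lc_mir, keep_mir))
  })

  de <- stage("differential_expression", function() {
    list(rna = moderated_t(norm$lc_rna, fc_threshold = opts$fc_threshold,
                           p_threshold = opts$p_threshold,
                           use_adjusted = opts$use_adjusted),
         mir = moderated_t(norm$lc_mir, fc_threshold = opts$fc_threshold,
                           p_threshold = opts$p_threshold,
                           use_adjusted = opts$use_adjusted))
  })

  cerna <- stage("cerna", function() {
    ann <- data$annotation
    de_lnc <- .de_ids_by_biotype(de$rna, ann, "lncRNA")
    de_mrna <- .de_ids_by_biotype(de$rna, ann, "protein_coding")
    de_mir <- de$mir$gene[de$mir$class != "ns"]
    pairs <- infer_cerna_pairs(de_lnc, de_mrna, de_mir,
                               norm$lc_rna, norm$lc_mir,
                               data$interactions,
                               hyper_cut = opts$hyper_cut,
                               cor_cut = opts$cor_cut,
                               regsim_cut = opts$regsim_cut,
                               min_shared = opts$min_shared)
    net <- build_network(pairs)
    list(pairs = pairs, network = net, stats = network_stats(net))
  })

  surv <- stage("survival", function() {
    nodes <- cerna$network$nodes
    genes <- nodes$id[nodes$biotype %in% c("lncRNA", "mRNA")]
    genes <- intersect(genes, rownames(norm$lc_rna$values))
    if (length(genes) == 0)
      return(suppressMessages(
        gene_survival_screen(norm$lc_rna, data$clinical,
                             genes = character(0))))
    suppressMessages(
      gene_survival_screen(norm$lc_rna, data$clinical, genes = genes))
  })

  manifest <- NULL
  if (!is.null(out_dir)) {
    manifest <- stage("export", function() {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      p <- function(f) file.path(out_dir, f)
      write_count_matrix(data$rna, p("rna_counts.tsv"))
      write_count_matrix(data$mirna, p("mirna_counts.tsv"))
      write_gene_annotation(data$annotation, p("annotation.tsv"))
      write_interaction_table(data$interactions, p("interactions.tsv"))
      write_clinical_table(data$clinical, p("clinical.tsv"))
      .write_tsv(data$truth$de_genes, p("truth_de_genes.tsv"))
      .write_tsv(norm$f_rna, p("tmm_factors_rna.tsv"))
      .write_tsv(norm$f_mir, p("tmm_factors_mirna.tsv"))
      .write_tsv(data.frame(gene_id = rownames(norm$lc_rna$values),
                            norm$lc_rna$values, check.names = FALSE),
                 p("logcpm_rna.tsv"))
      .write_tsv(data.frame(gene_id = rownames(norm$lc_mir$values),
                            norm$lc_mir$values, check.names = FALSE),
                 p("logcpm_mirna.tsv"))
      .write_tsv(as.data.frame(de$rna), p("de_rna.tsv"))
      .write_tsv(as.data.frame(de$mir), p("de_mirna.tsv"))
      .write_tsv(volcano_table(de$rna), p("volcano_rna.tsv"))
      .write_tsv(as.data.frame(cerna$pairs), p("cerna_pairs.tsv"))
      write_network(cerna$network, p("network.sif"), format = "SIF")
      write_network(cerna$network, p("network.graphml"), format = "GraphML")
      .write_tsv(as.data.frame(surv), p("survival_screen.tsv"))

      outputs <- c("rna_counts.tsv", "mirna_counts.tsv", "annotation.tsv",
                   "interactions.tsv", "clinical.tsv", "truth_de_genes.tsv",
                   "tmm_factors_rna.tsv", "tmm_factors_mirna.tsv",
                   "logcpm_rna.tsv", "logcpm_mirna.tsv", "de_rna.tsv",
                   "de_mirna.tsv", "volcano_rna.tsv", "cerna_pairs.tsv",
                   "network.sif", "network.graphml", "survival_screen.tsv")
      man <- list(
        package_version = as.character(utils::packageVersion("cernet")),
        seed = config$seed,
        config = unclass(config),
        thresholds = unclass(opts),
        stage_rows = list(
          genes_simulated = nrow(data$rna$counts),
          mirnas_simulated = nrow(data$mirna$counts),
          genes_kept = nrow(norm$lc_rna$values),
          mirnas_kept = nrow(norm$lc_mir$values),
          de_genes = sum(de$rna$class != "ns"),
          de_mirnas = sum(de$mir$class != "ns"),
          cerna_pairs_tested = nrow(cerna$pairs),
          cerna_pairs_passed = sum(cerna$pairs$passed),
          network_nodes = cerna$stats$n_nodes,
          network_edges = cerna$stats$n_edges,
          genes_screened = nrow(surv)),
        hashes = as.list(tools::md5sum(file.path(out_dir, outputs))))
      names(man$hashes) <- outputs
      jsonlite::write_json(man, p("manifest.json"), auto_unbox = TRUE,
                           pretty = TRUE, digits = NA)
      man
    })
  }

  list(data = data, factors_rna = norm$f_rna, factors_mir = norm$f_mir,
       logcpm_rna = norm$lc_rna, logcpm_mir = norm$lc_mir,
       de_rna = de$rna, de_mir = de$mir,
       pairs = cerna$pairs, network = cerna$network,
       network_stats = cerna$stats, survival = surv,
       manifest = manifest)
}

#' Per-cluster expression summaries for single-cell data
#'
#' Transforms raw values by log2(x + 1) and summarises each requested
#' gene within each cell cluster (count, mean, median, quartiles) —
#' the tabular backbone of per-cluster violin plots. Cluster labels are
#' consumed as input; clustering itself is never computed here.
#'
#' @param expr Numeric cells x genes matrix (raw filtered expression).
#' @param clusters Vector of cluster labels, one per cell (row).
#' @param genes Genes to summarise (default all columns).
#' @return data.frame: gene, cluster, n_cells, mean, median, q25, q75.
#' @export
summarize_by_cluster <- function(expr, clusters, genes = NULL) {
  if (!is.matrix(expr)) expr <- as.matrix(expr)
  if (length(clusters) != nrow(expr))
    stop("usage error: cluster labels must cover all cells")
  if (is.null(genes)) genes <- colnames(expr)
  known <- genes %in% colnames(expr)
  if (any(!known)) {
    warning("gene(s) absent from matrix, skipped: ",
            paste(genes[!known], collapse = ", "))
    genes <- genes[known]
  }
  rows <- list()
  for (g in genes) {
    v <- log2(expr[, g] + 1)
    for (cl in sort(unique(as.character(clusters)))) {
      x <- v[as.character(clusters) == cl]
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, cluster = cl, n_cells = length(x),
        mean = mean(x), median = stats::median(x),
        q25 = unname(stats::quantile(x, 0.25)),
        q75 = unname(stats::quantile(x, 0.75)),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
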