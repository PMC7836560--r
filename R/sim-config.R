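#' Configuration for the synthetic multi-omic dataset generator
#'
#' Defines the statistical structure the simulator plants: negative-binomial
#' counts with tumour/normal group effects, lncRNA-miRNA-mRNA ceRNA triples
#' coupled through a per-sample latent factor, StarBase-like interaction
#' edges, and censored survival times whose hazard depends on the high/low
#' expression group of chosen genes.
#'
#' Defaults describe the study conditions the pipeline is exercised under:
#' a balanced 50/50 tumour/normal cohort, moderate gene panels, 10% planted
#' differential expression with |log2FC| centred on 2 (mean fold change 4,
#' comfortably above the FC > 2 calling threshold so planted truth is
#' detectable), NB dispersion 0.1 (typical
#' of bulk tissue), library sizes log-uniform over one decade so TMM is
#' exercised non-trivially, five planted ceRNA triples at latent loading
#' 0.8, sparse background interaction edges, and a planted hazard of log 2
#' with 30% independent censoring.
#'
#' @param n_tumour,n_normal Number of tumour / normal samples.
#' @param n_mrna,n_lncrna,n_mirna Genes per biotype.
#' @param frac_de Fraction of genes (per biotype) with a planted group
#'   effect. \code{0} plants no effect anywhere, including triple members.
#' @param lfc_mean,lfc_sd Mean and sd of the magnitude of planted log2 fold
#'   changes (signs random for ordinary DE genes; triple members follow the
#'   ceRNA pattern, lncRNA/mRNA up and miRNA down in tumour).
#' @param nb_dispersion Gene-wise negative-binomial dispersion phi
#'   (variance = mu + phi mu^2).
#' @param lib_size_range Length-2 interval; library sizes are drawn
#'   log-uniformly over it.
#' @param n_triples Number of planted ceRNA triples.
#' @param mirnas_per_triple Shared miRNAs per planted triple.
#' @param triple_strength Latent-factor loading in (0,1) applied with sign
#'   + to the triple's lncRNA and mRNA log-means and - to its miRNAs.
#' @param bg_edge_prob Probability of a background miRNA->target edge.
#' @param surv_genes Gene ids whose high/low expression group drives the
#'   hazard; \code{NULL} defaults to the first planted triple's lncRNA and
#'   mRNA (or none when no triples are planted).
#' @param surv_beta Log hazard ratio added per gene when a sample falls in
#'   its high-expression group.
#' @param censor_rate Target fraction of independently censored records.
#' @param baseline_hazard Baseline event rate per day for samples in all
#'   low groups.
#' @param seed RNG seed used by the simulator.
#' @return A validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_tumour = 50, n_normal = 50,
                       n_mrna = 1000, n_lncrna = 200, n_mirna = 150,
                       frac_de = 0.1, lfc_mean = 2.0, lfc_sd = 0.4,
                       nb_dispersion = 0.1,
                       lib_size_range = c(1e6, 1e7),
                       n_triples = 5, mirnas_per_triple = 3,
                       triple_strength = 0.8,
                       bg_edge_prob = 0.005,
                       surv_genes = NULL, surv_beta = log(2),
                       censor_rate = 0.3, baseline_hazard = log(2) / 500,
                       seed = 1L) {
  cfg <- list(n_tumour = as.integer(n_tumour), n_normal = as.integer(n_normal),
              n_mrna = as.integer(n_mrna), n_lncrna = as.integer(n_lncrna),
              n_mirna = as.integer(n_mirna),
              frac_de = frac_de, lfc_mean = lfc_mean, lfc_sd = lfc_sd,
              nb_dispersion = nb_dispersion,
              lib_size_range = as.numeric(lib_size_range),
              n_triples = as.integer(n_triples),
              mirnas_per_triple = as.integer(mirnas_per_triple),
              triple_strength = triple_strength,
              bg_edge_prob = bg_edge_prob,
              surv_genes = surv_genes, surv_beta = surv_beta,
              censor_rate = censor_rate, baseline_hazard = baseline_hazard,
              seed = as.integer(seed))
  with(cfg, {
    if (n_tumour <= 0 || n_normal <= 0 || n_mrna <= 0 || n_lncrna <= 0 ||
        n_mirna <= 0)
      stop("configuration error: all sample and gene counts must be positive")
    if (frac_de < 0 || frac_de > 1)
      stop("configuration error: frac_de must lie in [0,1]")
    if (triple_strength < 0 || triple_strength >= 1)
      stop("configuration error: triple_strength must lie in [0,1)")
    if (censor_rate < 0 || censor_rate >= 1)
      stop("configuration error: censor_rate must lie in [0,1)")
    if (length(lib_size_range) != 2 || any(lib_size_range <= 0) ||
        lib_size_range[1] > lib_size_range[2])
      stop("configuration error: lib_size_range must be a positive interval")
    if (bg_edge_prob < 0 || bg_edge_prob > 1)
      stop("configuration error: bg_edge_prob must lie in [0,1]")
    if (n_triples > 0 &&
        (n_triples > n_lncrna || n_triples > n_mrna ||
         n_triples * mirnas_per_triple > n_mirna))
      stop("configuration error: not enough genes to host the planted triples")
    if (nb_dispersion <= 0)
      stop("configuration error: nb_dispersion must be positive")
  })
  structure(cfg, class = "sim_config")
}
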