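# Synthetic multi-omic dataset generator with planted ground truth.
#
# The generator is seeded once per operation from config$seed (offset per
# operation so that expression, interaction and clinical draws are
# independent streams but jointly reproducible).

.sim_ids <- function(cfg) {
  list(mrna   = sprintf("MRNA%04d", seq_len(cfg$n_mrna)),
       lncrna = sprintf("LNC%04d",  seq_len(cfg$n_lncrna)),
       mirna  = sprintf("MIR%04d",  seq_len(cfg$n_mirna)))
}

#' Simulate tumour/normal RNA and miRNA count matrices with planted truth
#'
#' Counts are negative-binomial with gene baseline log2 means drawn
#' uniformly, per-sample library sizes log-uniform over
#' \code{lib_size_range}, and dispersion \code{nb_dispersion}. A fraction
#' \code{frac_de} of genes per biotype receives a group effect of magnitude
#' \code{|N(lfc_mean, lfc_sd)|} log2 units with random sign. Each planted
#' ceRNA triple couples one lncRNA, one mRNA and \code{mirnas_per_triple}
#' miRNAs through a standard-normal per-sample latent factor that enters
#' the log2 mean with loading \code{+triple_strength} for the lncRNA and
#' mRNA and \code{-triple_strength} for the miRNAs, producing the signed
#' correlation pattern ceRNA inference assumes. When \code{frac_de > 0},
#' triple members are always in the DE set with the ceRNA sign pattern
#' (lncRNA/mRNA up, miRNA down in tumour) so that DE-restricted candidate
#' gating can recover them.
#'
#' @param config A \code{\link{sim_config}}.
#' @return A list with elements \code{rna} (count_matrix of mRNA + lncRNA),
#'   \code{mirna} (count_matrix), \code{annotation} (data.frame gene_id,
#'   biotype), and \code{truth} (list with \code{de_genes} data.frame
#'   (gene_id, lfc), \code{triples} list of (lncrna, mirnas, mrna), and
#'   \code{surv_effects} named numeric of true log hazard ratios).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)

  ids <- .sim_ids(cfg)
  samples <- c(sprintf("T%03d", seq_len(cfg$n_tumour)),
               sprintf("N%03d", seq_len(cfg$n_normal)))
  groups <- c(rep("tumour", cfg$n_tumour), rep("normal", cfg$n_normal))
  n_s <- length(samples)

  all_ids <- c(ids$mrna, ids$lncrna, ids$mirna)
  n_g <- length(all_ids)
  # baseline abundance on the log2-CPM scale; lncRNA/miRNA a little lower
  base <- c(stats::runif(cfg$n_mrna, 3, 9),
            stats::runif(cfg$n_lncrna, 2, 7),
            stats::runif(cfg$n_mirna, 3, 9))
  names(base) <- all_ids

  # planted triples: disjoint lncRNAs, mRNAs and miRNA blocks
  triples <- list()
  if (cfg$n_triples > 0) {
    for (i in seq_len(cfg$n_triples)) {
      mir_idx <- ((i - 1L) * cfg$mirnas_per_triple + 1L):(i * cfg$mirnas_per_triple)
      triples[[i]] <- list(lncrna = ids$lncrna[i],
                           mirnas = ids$mirna[mir_idx],
                           mrna = ids$mrna[i])
    }
  }
  triple_members <- unlist(lapply(triples, function(t) c(t$lncrna, t$mirnas, t$mrna)))

  # planted DE: triple members (ceRNA sign pattern) plus random extra genes
  lfc <- stats::setNames(numeric(n_g), all_ids)
  de_ids <- character(0)
  if (cfg$frac_de > 0) {
    draw_mag <- function(n) abs(stats::rnorm(n, cfg$lfc_mean, cfg$lfc_sd))
    for (t in triples) {
      lfc[t$lncrna] <- draw_mag(1L)
      lfc[t$mrna]   <- draw_mag(1L)
      lfc[t$mirnas] <- -draw_mag(length(t$mirnas))
    }
    for (bt in c("mrna", "lncrna", "mirna")) {
      pool <- setdiff(ids[[bt]], triple_members)
      n_extra <- max(0L, round(cfg$frac_de * length(ids[[bt]])) -
                       sum(ids[[bt]] %in% triple_members))
      extra <- sample(pool, min(n_extra, length(pool)))
      lfc[extra] <- draw_mag(length(extra)) *
        sample(c(-1, 1), length(extra), replace = TRUE)
    }
    de_ids <- names(lfc)[lfc != 0]
  }

  # per-gene per-sample log2 mean: baseline + group effect + latent factors
  logmu <- matrix(rep(base, n_s), nrow = n_g, ncol = n_s,
                  dimnames = list(all_ids, samples))
  tum <- groups == "tumour"
  logmu[, tum] <- logmu[, tum] + lfc
  if (cfg$n_triples > 0 && cfg$triple_strength > 0) {
    for (t in triples) {
      z <- stats::rnorm(n_s)
      logmu[t$lncrna, ] <- logmu[t$lncrna, ] + cfg$triple_strength * z
      logmu[t$mrna, ]   <- logmu[t$mrna, ]   + cfg$triple_strength * z
      logmu[t$mirnas, ] <- sweep(logmu[t$mirnas, , drop = FALSE], 2,
                                 cfg$triple_strength * z, "-")
    }
  }

  # library sizes log-uniform; means scaled so base is per-million-ish
  lib_rna <- exp(stats::runif(n_s, log(cfg$lib_size_range[1]),
                              log(cfg$lib_size_range[2])))
  lib_mir <- exp(stats::runif(n_s, log(cfg$lib_size_range[1] / 5),
                              log(cfg$lib_size_range[2] / 5)))

  rna_ids <- c(ids$mrna, ids$lncrna)
  draw_counts <- function(gids, lib) {
    lm <- logmu[gids, , drop = FALSE]
    mu <- sweep(2^lm, 2, lib / 1e6, "*")
    cnt <- matrix(stats::rnbinom(length(mu), mu = mu,
                                 size = 1 / cfg$nb_dispersion),
                  nrow = nrow(mu), dimnames = dimnames(mu))
    cnt
  }
  rna_counts <- draw_counts(rna_ids, lib_rna)
  mir_counts <- draw_counts(ids$mirna, lib_mir)

  annotation <- data.frame(
    gene_id = all_ids,
    biotype = c(rep("protein_coding", cfg$n_mrna),
                rep("lncRNA", cfg$n_lncrna),
                rep("miRNA", cfg$n_mirna)),
    stringsAsFactors = FALSE)

  surv_genes <- cfg$surv_genes
  if (is.null(surv_genes))
    surv_genes <- if (cfg$n_triples > 0)
      c(triples[[1]]$lncrna, triples[[1]]$mrna) else character(0)
  surv_effects <- stats::setNames(rep(cfg$surv_beta, length(surv_genes)),
                                  surv_genes)

  truth <- list(
    de_genes = data.frame(gene_id = de_ids, lfc = unname(lfc[de_ids]),
                          stringsAsFactors = FALSE),
    triples = triples,
    surv_effects = surv_effects)

  list(rna = count_matrix(rna_counts, stats::setNames(groups, samples)),
       mirna = count_matrix(mir_counts, stats::setNames(groups, samples)),
       annotation = annotation,
       truth = truth)
}

#' Simulate a miRNA-target interaction table with planted edges
#'
#' Every planted triple contributes its miRNA->lncRNA and miRNA->mRNA
#' edges; in addition each possible (miRNA, target) pair receives an
#' independent background edge with probability \code{bg_edge_prob}.
#'
#' @param config A \code{\link{sim_config}}.
#' @param truth Ground truth from \code{\link{simulate_expression}} run
#'   under the same config.
#' @return data.frame with columns \code{mirna_id}, \code{target_id}
#'   (deduplicated, no self edges).
#' @export
simulate_interactions <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed + 1L)
  ids <- .sim_ids(cfg)
  targets <- c(ids$mrna, ids$lncrna)

  for (t in truth$triples) {
    if (!(t$lncrna %in% ids$lncrna) || !(t$mrna %in% ids$mrna) ||
        !all(t$mirnas %in% ids$mirna))
      stop("consistency error: ground truth references unknown gene ids")
  }

  planted <- do.call(rbind, lapply(truth$triples, function(t)
    data.frame(mirna_id = rep(t$mirnas, 2L),
               target_id = rep(c(t$lncrna, t$mrna), each = length(t$mirnas)),
               stringsAsFactors = FALSE)))

  bg <- NULL
  if (cfg$bg_edge_prob > 0) {
    n_pairs <- length(ids$mirna) * length(targets)
    hit <- which(stats::runif(n_pairs) < cfg$bg_edge_prob)
    if (length(hit) > 0) {
      mi <- ((hit - 1L) %% length(ids$mirna)) + 1L
      ti <- ((hit - 1L) %/% length(ids$mirna)) + 1L
      bg <- data.frame(mirna_id = ids$mirna[mi], target_id = targets[ti],
                       stringsAsFactors = FALSE)
    }
  }
  edges <- rbind(planted, bg)
  if (is.null(edges))
    edges <- data.frame(mirna_id = character(0), target_id = character(0),
                        stringsAsFactors = FALSE)
  edges <- unique(edges)
  edges <- edges[order(edges$mirna_id, edges$target_id), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Simulate censored survival records for the tumour samples
#'
#' Event times are exponential with log hazard
#' \code{log(baseline_hazard) + sum_g surv_beta * 1[sample in the high
#' group of gene g]}, where high/low is the median split of the gene's
#' library-size-normalised expression (log2 CPM + 1) across tumour
#' samples. Censoring is an independent exponential whose rate is chosen
#' so that a baseline-hazard sample is censored with probability
#' \code{censor_rate}.
#'
#' @param config A \code{\link{sim_config}}.
#' @param expr The RNA \code{count_matrix} from
#'   \code{\link{simulate_expression}}.
#' @param truth Matching ground truth (supplies \code{surv_effects}).
#' @return data.frame with columns \code{sample_id}, \code{time} (days,
#'   > 0), \code{event} (1 death, 0 censored); tumour samples only.
#' @export
simulate_clinical <- function(config, expr, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(expr, "count_matrix"))
  cfg <- config
  set.seed(cfg$seed + 2L)

  tum <- names(expr$groups)[expr$groups == "tumour"]
  surv_genes <- names(truth$surv_effects)
  missing <- setdiff(surv_genes, rownames(expr$counts))
  if (length(missing) > 0)
    stop("consistency error: surv_gene absent from expression matrix: ",
         missing[1L])

  loghaz <- rep(log(cfg$baseline_hazard), length(tum))
  names(loghaz) <- tum
  if (length(surv_genes) > 0) {
    lib <- colSums(expr$counts[, tum, drop = FALSE])
    for (g in surv_genes) {
      v <- log2(expr$counts[g, tum] / lib * 1e6 + 1)
      high <- v > stats::median(v)
      loghaz <- loghaz + truth$surv_effects[[g]] * high
    }
  }
  t_event <- stats::rexp(length(tum), rate = exp(loghaz))
  if (cfg$censor_rate > 0) {
    c_rate <- cfg$baseline_hazard * cfg$censor_rate / (1 - cfg$censor_rate)
    t_cens <- stats::rexp(length(tum), rate = c_rate)
  } else {
    t_cens <- rep(Inf, length(tum))
  }
  time <- pmin(t_event, t_cens)
  time <- pmax(time, .Machine$double.eps)
  data.frame(sample_id = tum,
             time = unname(time),
             event = as.integer(t_event <= t_cens),
             stringsAsFactors = FALSE)
}

#' Generate the complete synthetic dataset
#'
#' Convenience wrapper running \code{\link{simulate_expression}},
#' \code{\link{simulate_interactions}} and \code{\link{simulate_clinical}}
#' under one config.
#'
#' @param config A \code{\link{sim_config}}.
#' @return List with \code{rna}, \code{mirna}, \code{annotation},
#'   \code{interactions}, \code{clinical}, \code{truth}.
#' @export
simulate_dataset <- function(config) {
  ex <- simulate_expression(config)
  interactions <- simulate_interactions(config, ex$truth)
  clinical <- simulate_clinical(config, ex$rna, ex$truth)
  c(ex, list(interactions = interactions, clinical = clinical))
}
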