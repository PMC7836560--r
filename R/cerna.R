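# Triple-evidence ceRNA inference. A lncRNA-mRNA pair is called a
# competing pair when (i) it shares more miRNA regulators than expected
# by chance (one-sided hypergeometric test over the measured miRNA
# universe), (ii) the two transcripts are positively correlated in
# expression, and (iii) the shared miRNAs regulate both partners
# similarly (regulation-similarity score).

#' Shared miRNA regulators of a lncRNA-mRNA pair
#'
#' Intersects the miRNA sets targeting each partner with the miRNA
#' universe and returns the overlap and the hypergeometric counts.
#'
#' @param lncrna_id,mrna_id Gene ids.
#' @param interactions Interaction data.frame (mirna_id, target_id).
#' @param universe Character vector of miRNA ids forming the population.
#' @return List: \code{shared} (id set), \code{k}, \code{K} (miRNAs
#'   targeting the lncRNA), \code{n} (miRNAs targeting the mRNA),
#'   \code{N} (universe size).
#' @export
shared_mirnas <- function(lncrna_id, mrna_id, interactions, universe) {
  if (length(universe) == 0) stop("usage error: empty miRNA universe")
  mir_lnc <- intersect(interactions$mirna_id[interactions$target_id == lncrna_id],
                       universe)
  mir_m <- intersect(interactions$mirna_id[interactions$target_id == mrna_id],
                     universe)
  shared <- intersect(mir_lnc, mir_m)
  list(shared = sort(shared), k = length(shared), K = length(mir_lnc),
       n = length(mir_m), N = length(universe))
}

#' Upper-tail hypergeometric p-value for shared-miRNA overlap
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability that a
#' random draw of n miRNAs from a universe of N containing K
#' lncRNA-regulators overlaps the mRNA's regulators in at least k.
#'
#' @param k Observed shared count.
#' @param K miRNAs targeting the lncRNA.
#' @param n miRNAs targeting the mRNA.
#' @param N Universe size.
#' @return The upper-tail probability in (0, 1].
#' @export
hypergeom_pvalue <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || k > min(K, n) || K > N || n > N)
    stop("usage error: inconsistent hypergeometric counts")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Pearson correlation of a candidate pair
#'
#' @param x,y Equal-length expression vectors (>= 3 finite values).
#' @return List with \code{r} and two-sided \code{p} (t transform,
#'   n - 2 df); both \code{NA} with a warning when either vector has zero
#'   variance.
#' @export
pair_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("usage error: need equal-length vectors of length >= 3")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("usage error: non-finite expression values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: correlation undefined, pair flagged")
    return(list(r = NA_real_, p = NA_real_))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Regulation-similarity score over shared miRNAs
#'
#' For M shared miRNAs with correlations c_i^lnc (miRNA vs lncRNA) and
#' c_i^m (miRNA vs mRNA), the score is
#' \deqn{\frac{1}{M}\sum_{i=1}^{M}\left[1 -
#'   \frac{|c_i^{lnc} - c_i^{m}|}{|c_i^{lnc}| + |c_i^{m}|}\right]^{M}}
#' A position where both correlations are exactly 0 contributes 0
#' (uninformative, treated as maximally dissimilar). The score lies in
#' [0,1]; 1 means every shared miRNA regulates both partners identically.
#'
#' @param cors_lnc,cors_mrna Equal-length vectors of correlations in
#'   [-1,1].
#' @return Score in [0, 1].
#' @export
regulation_similarity <- function(cors_lnc, cors_mrna) {
  M <- length(cors_lnc)
  if (M == 0 || length(cors_mrna) != M)
    stop("usage error: need equal-length non-empty correlation vectors")
  if (any(abs(c(cors_lnc, cors_mrna)) > 1))
    stop("usage error: correlations must lie in [-1,1]")
  denom <- abs(cors_lnc) + abs(cors_mrna)
  term <- ifelse(denom == 0, 0,
                 (1 - abs(cors_lnc - cors_mrna) / denom)^M)
  mean(term)
}

#' Infer competing lncRNA-mRNA pairs (triple evidence)
#'
#' For every candidate lncRNA x mRNA pair whose shared measured miRNAs
#' include at least \code{min_shared} differentially expressed miRNAs,
#' computes the shared-miRNA hypergeometric p (over the measured-miRNA
#' universe), the lncRNA-mRNA Pearson correlation, and the
#' regulation-similarity score of the shared miRNAs. A pair passes iff
#' hyper_p < hyper_cut, cor_r > 0 with cor_p < cor_cut, and
#' reg_sim >= regsim_cut.
#'
#' @param de_lnc,de_mrna,de_mir DE lncRNA / mRNA / miRNA id vectors
#'   (candidates; \code{de_mir = NULL} disables the DE-miRNA gate and
#'   gates on all shared miRNAs instead).
#' @param expr logCPM \code{\link{expr_matrix}} containing the lncRNAs
#'   and mRNAs.
#' @param mir_expr logCPM \code{\link{expr_matrix}} of miRNAs (same
#'   samples as \code{expr}).
#' @param interactions Interaction data.frame (mirna_id, target_id).
#' @param hyper_cut,cor_cut,regsim_cut,min_shared Evidence thresholds.
#' @param correlation_samples \code{"tumour"} (default) computes all
#'   correlation evidence within the tumour samples, so a shared
#'   tumour/normal mean shift cannot masquerade as co-expression;
#'   \code{"all"} uses every sample (also the fallback when no group
#'   labels are attached).
#' @return data.frame of class \code{cerna_pairs}: lncRNA, mRNA,
#'   n_shared, n_shared_de, shared_mirnas (comma-joined), k, K, n, N,
#'   hyper_p, cor_r, cor_p, reg_sim, passed; sorted by hyper_p then ids.
#' @export
infer_cerna_pairs <- function(de_lnc, de_mrna, de_mir, expr, mir_expr,
                              interactions, hyper_cut = 0.05,
                              cor_cut = 0.05, regsim_cut = 0.5,
                              min_shared = 1L,
                              correlation_samples = c("tumour", "all")) {
  stopifnot(inherits(expr, "expr_matrix"), inherits(mir_expr, "expr_matrix"))
  if (!identical(colnames(expr$values), colnames(mir_expr$values)))
    stop("usage error: expression matrices must share sample columns")
  correlation_samples <- match.arg(correlation_samples)
  cor_cols <- colnames(expr$values)
  if (correlation_samples == "tumour" && !is.null(expr$groups)) {
    tum <- names(expr$groups)[expr$groups == "tumour"]
    if (length(tum) >= 3) cor_cols <- intersect(cor_cols, tum)
  }

  measured_mir <- rownames(mir_expr$values)
  universe <- intersect(unique(interactions$mirna_id), measured_mir)
  de_lnc <- intersect(de_lnc, rownames(expr$values))
  de_mrna <- intersect(de_mrna, rownames(expr$values))

  # index interactions by target for speed
  ints <- interactions[interactions$mirna_id %in% universe, , drop = FALSE]
  by_target <- split(ints$mirna_id, ints$target_id)

  rows <- list()
  for (lnc in de_lnc) {
    mir_lnc <- by_target[[lnc]]
    if (is.null(mir_lnc)) next
    for (mrna in de_mrna) {
      mir_m <- by_target[[mrna]]
      if (is.null(mir_m)) next
      shared <- sort(intersect(mir_lnc, mir_m))
      if (length(shared) == 0) next
      shared_de <- if (is.null(de_mir)) shared else intersect(shared, de_mir)
      if (length(shared_de) < min_shared) next

      hp <- hypergeom_pvalue(length(shared), length(mir_lnc),
                             length(mir_m), length(universe))
      x <- expr$values[lnc, cor_cols]; y <- expr$values[mrna, cor_cols]
      pc <- if (stats::sd(x) == 0 || stats::sd(y) == 0)
        list(r = NA_real_, p = NA_real_) else pair_correlation(x, y)
      cl <- vapply(shared, function(mi)
        stats::cor(mir_expr$values[mi, cor_cols], x), numeric(1))
      cm <- vapply(shared, function(mi)
        stats::cor(mir_expr$values[mi, cor_cols], y), numeric(1))
      ok <- is.finite(cl) & is.finite(cm)
      rs <- if (any(ok)) regulation_similarity(cl[ok], cm[ok]) else NA_real_

      passed <- !is.na(pc$r) && !is.na(rs) &&
        hp < hyper_cut && pc$r > 0 && pc$p < cor_cut && rs >= regsim_cut
      rows[[length(rows) + 1L]] <- data.frame(
        lncRNA = lnc, mRNA = mrna,
        n_shared = length(shared), n_shared_de = length(shared_de),
        shared_mirnas = paste(shared, collapse = ","),
        k = length(shared), K = length(mir_lnc), n = length(mir_m),
        N = length(universe), hyper_p = hp,
        cor_r = pc$r, cor_p = pc$p, reg_sim = rs, passed = passed,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(lncRNA = character(0), mRNA = character(0),
               n_shared = integer(0), n_shared_de = integer(0),
               shared_mirnas = character(0), k = integer(0), K = integer(0),
               n = integer(0), N = integer(0), hyper_p = numeric(0),
               cor_r = numeric(0), cor_p = numeric(0), reg_sim = numeric(0),
               passed = logical(0), stringsAsFactors = FALSE)
  out <- out[order(out$hyper_p, out$lncRNA, out$mRNA), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cerna_pairs", "data.frame")
  out
}

#' Assemble the tripartite ceRNA network from passed pairs
#'
#' Nodes are the lncRNAs, shared miRNAs and mRNAs of the passed pairs;
#' each pair contributes one lncRNA--miRNA and one miRNA--mRNA edge per
#' shared miRNA, deduplicated across pairs.
#'
#' @param pairs A \code{cerna_pairs} data.frame (only rows with
#'   \code{passed} are used).
#' @return Object of class \code{cerna_network}: \code{nodes} data.frame
#'   (id, biotype, degree) and \code{edges} data.frame (source, relation,
#'   target, evidence = contributing pair ids).
#' @export
build_network <- function(pairs) {
  pp <- pairs[pairs$passed, , drop = FALSE]
  edges <- list()
  for (i in seq_len(nrow(pp))) {
    mirs <- strsplit(pp$shared_mirnas[i], ",", fixed = TRUE)[[1]]
    if (length(mirs) == 0) next
    pid <- paste(pp$lncRNA[i], pp$mRNA[i], sep = "|")
    edges[[length(edges) + 1L]] <- rbind(
      data.frame(source = pp$lncRNA[i], relation = "lnc_mir", target = mirs,
                 evidence = pid, stringsAsFactors = FALSE),
      data.frame(source = mirs, relation = "mir_mrna", target = pp$mRNA[i],
                 evidence = pid, stringsAsFactors = FALSE))
  }
  if (length(edges) > 0) {
    edges <- do.call(rbind, edges)
    ev <- stats::aggregate(evidence ~ source + relation + target, data = edges,
                           FUN = function(x) paste(sort(unique(x)),
                                                   collapse = ";"))
    edges <- ev[order(ev$relation, ev$source, ev$target), , drop = FALSE]
    edges <- edges[, c("source", "relation", "target", "evidence")]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(source = character(0), relation = character(0),
                        target = character(0), evidence = character(0),
                        stringsAsFactors = FALSE)
  }

  lncs <- sort(unique(pp$lncRNA))
  mirs_all <- sort(unique(unlist(strsplit(pp$shared_mirnas, ",", fixed = TRUE))))
  mrnas <- sort(unique(pp$mRNA))
  nodes <- data.frame(
    id = c(lncs, mirs_all, mrnas),
    biotype = c(rep("lncRNA", length(lncs)), rep("miRNA", length(mirs_all)),
                rep("mRNA", length(mrnas))),
    stringsAsFactors = FALSE)
  deg <- table(c(edges$source, edges$target))
  nodes$degree <- as.integer(deg[nodes$id])
  nodes$degree[is.na(nodes$degree)] <- 0L
  structure(list(nodes = nodes, edges = edges), class = "cerna_network")
}

#' Node, edge and degree summary of a ceRNA network
#'
#' @param net A \code{cerna_network}.
#' @return List: \code{n_nodes}, \code{n_edges}, \code{degree} data.frame
#'   (id, biotype, degree, descending degree).
#' @export
network_stats <- function(net) {
  stopifnot(inherits(net, "cerna_network"))
  deg <- net$nodes[order(-net$nodes$degree, net$nodes$id), , drop = FALSE]
  rownames(deg) <- NULL
  list(n_nodes = nrow(net$nodes), n_edges = nrow(net$edges), degree = deg)
}

#' @export
print.cerna_network <- function(x, ...) {
  cat(sprintf("cerna_network: %d nodes (%d lncRNA, %d miRNA, %d mRNA), %d edges\n",
              nrow(x$nodes), sum(x$nodes$biotype == "lncRNA"),
              sum(x$nodes$biotype == "miRNA"), sum(x$nodes$biotype == "mRNA"),
              nrow(x$edges)))
  invisible(x)
}
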