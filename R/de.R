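# Two-group differential expression with empirical-Bayes moderated
# t-statistics on logCPM (limma-trend style, no precision weights), BH
# adjustment, and up/down/ns classification at |log2FC| > 1 and p < 0.01.

#' Estimate the empirical-Bayes variance prior
#'
#' Fits the scaled inverse-chi-square prior (d0, s0^2) to the per-gene
#' residual variances by moment matching on the log variances (limma's
#' fitFDist). Returns \code{d0 = Inf} when the spread of log variances is
#' no larger than pure chi-square sampling noise.
#'
#' @param s2 Per-gene residual variances (positive, finite).
#' @param df Residual degrees of freedom (scalar or per gene).
#' @return List with \code{d0} (prior df, possibly \code{Inf}) and
#'   \code{s0sq} (prior variance).
#' @export
estimate_prior <- function(s2, df) {
  s2 <- s2[is.finite(s2) & s2 > 0]
  if (length(s2) < 2)
    stop("estimation error: need at least 2 genes with positive variance")
  fit <- limma::fitFDist(s2, df1 = df)
  if (is.null(fit$scale) || !is.finite(fit$scale) || fit$scale <= 0)
    stop("estimation error: prior variance could not be estimated")
  list(d0 = fit$df2, s0sq = fit$scale)
}

#' Moderated two-group t-test on logCPM
#'
#' Per gene: logFC = mean(tumour) - mean(normal); pooled residual variance
#' s^2 with df = n - 2; posterior variance
#' (d0 s0^2 + df s^2) / (d0 + df); moderated t = logFC /
#' sqrt(posterior variance (1/n1 + 1/n2)); two-sided p on d0 + df degrees
#' of freedom; BH-adjusted p; classification per
#' \code{\link{classify_de}}. With \code{prior = list(d0 = 0)} the
#' ordinary pooled two-sample t-statistic is recovered.
#'
#' @param logcpm An \code{\link{expr_matrix}} on the log scale with sample
#'   groups (or supply \code{groups}).
#' @param groups Optional named factor/character of tumour/normal labels.
#' @param prior Optional list \code{(d0, s0sq)}; default estimated from
#'   the data via \code{\link{estimate_prior}}.
#' @param fc_threshold,p_threshold,use_adjusted Classification thresholds,
#'   see \code{\link{classify_de}}.
#' @return data.frame of class \code{de_result}: gene, logFC, AveExpr,
#'   s2, df_residual, s2_post, t, P.Value, adj.P.Val, class; attributes
#'   \code{d0}, \code{s0sq}.
#' @export
moderated_t <- function(logcpm, groups = NULL, prior = NULL,
                        fc_threshold = 2, p_threshold = 0.01,
                        use_adjusted = TRUE) {
  stopifnot(inherits(logcpm, "expr_matrix"))
  if (!logcpm$log) stop("usage error: moderated_t expects logCPM input")
  E <- logcpm$values
  if (is.null(groups)) groups <- logcpm$groups
  if (is.null(groups)) stop("usage error: sample groups are required")
  groups <- factor(as.character(groups[colnames(E)]),
                   levels = c("normal", "tumour"))
  if (anyNA(groups)) stop("usage error: missing group label")
  n1 <- sum(groups == "tumour"); n2 <- sum(groups == "normal")
  if (n1 < 2 || n2 < 2)
    stop("usage error: each group needs at least 2 samples")

  mt <- rowMeans(E[, groups == "tumour", drop = FALSE])
  mn <- rowMeans(E[, groups == "normal", drop = FALSE])
  logFC <- mt - mn
  ave <- rowMeans(E)
  df <- n1 + n2 - 2
  rss <- rowSums((E[, groups == "tumour", drop = FALSE] - mt)^2) +
    rowSums((E[, groups == "normal", drop = FALSE] - mn)^2)
  s2 <- rss / df

  if (is.null(prior)) prior <- estimate_prior(s2, df)
  d0 <- prior$d0
  s0sq <- if (is.null(prior$s0sq)) 0 else prior$s0sq
  s2_post <- if (is.infinite(d0)) rep(s0sq, length(s2))
             else (d0 * s0sq + df * s2) / (d0 + df)
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  tstat <- ifelse(se > 0, logFC / se, sign(logFC) * Inf)
  tstat[se == 0 & logFC == 0] <- 0
  df_total <- d0 + df
  p <- 2 * stats::pt(abs(tstat), df = df_total, lower.tail = FALSE)
  p[se == 0 & logFC == 0] <- 1
  padj <- bh_adjust(p)

  res <- data.frame(gene = rownames(E), logFC = unname(logFC),
                    AveExpr = unname(ave), s2 = unname(s2),
                    df_residual = df, s2_post = unname(s2_post),
                    t = unname(tstat), P.Value = unname(p),
                    adj.P.Val = unname(padj), stringsAsFactors = FALSE)
  res$class <- classify_de(res, fc_threshold = fc_threshold,
                           p_threshold = p_threshold,
                           use_adjusted = use_adjusted)
  attr(res, "d0") <- d0
  attr(res, "s0sq") <- s0sq
  class(res) <- c("de_result", "data.frame")
  res
}

#' Benjamini-Hochberg FDR adjustment
#'
#' @param p Vector of p-values in [0,1].
#' @return Step-up BH adjusted p-values, capped at 1.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("usage error: p-values must lie in [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' Classify genes as up / down / ns
#'
#' Up iff logFC > log2(fc_threshold) and p* < p_threshold; down iff
#' logFC < -log2(fc_threshold) and p* < p_threshold; otherwise ns. p* is
#' the BH-adjusted p when \code{use_adjusted} (the default, matching a
#' volcano drawn on FDR), else the raw p.
#'
#' @param result A \code{de_result} data.frame (needs logFC, P.Value,
#'   adj.P.Val).
#' @param fc_threshold Fold-change cutoff (> applied to both directions).
#' @param p_threshold Significance cutoff.
#' @param use_adjusted Threshold the adjusted p rather than the raw p.
#' @return Character vector of labels in \code{{"up","down","ns"}}.
#' @export
classify_de <- function(result, fc_threshold = 2, p_threshold = 0.01,
                        use_adjusted = TRUE) {
  if (fc_threshold <= 0 || p_threshold <= 0)
    stop("usage error: thresholds must be positive")
  pstar <- if (use_adjusted) result$adj.P.Val else result$P.Value
  lfc_cut <- log2(fc_threshold)
  ifelse(pstar < p_threshold & result$logFC > lfc_cut, "up",
         ifelse(pstar < p_threshold & result$logFC < -lfc_cut, "down", "ns"))
}

#' Volcano-plot table
#'
#' Reshapes a DE result into (gene, logFC, -log10 adjusted p, class);
#' -log10 p is capped at \code{cap} for p = 0 and the affected rows
#' flagged.
#'
#' @param result A \code{de_result}.
#' @param cap Maximum -log10 p for p = 0.
#' @return data.frame with columns gene, logFC, neg_log10_fdr, capped,
#'   class.
#' @export
volcano_table <- function(result, cap = 300) {
  y <- -log10(result$adj.P.Val)
  capped <- !is.finite(y) | y > cap
  y[capped] <- cap
  data.frame(gene = result$gene, logFC = result$logFC,
             neg_log10_fdr = y, capped = capped, class = result$class,
             stringsAsFactors = FALSE)
}
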