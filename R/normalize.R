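# Between-sample normalisation and the low-expression filter.
#
# TMM (trimmed mean of M-values) scaling factors and (log)CPM are computed
# through edgeR, the method's reference implementation; this module wraps
# them with the validation and container types the pipeline uses.

#' TMM scaling factors
#'
#' Computes per-sample trimmed-mean-of-M-values scaling factors: the
#' reference sample is the one whose upper-quartile count fraction is
#' closest to the mean upper-quartile fraction; each sample's factor is
#' 2^(weighted trimmed mean of per-gene log ratios against the reference),
#' trimming \code{logratio_trim} on M and \code{sum_trim} on A, with
#' inverse asymptotic binomial variance weights; factors are rescaled to
#' geometric mean 1.
#'
#' @param counts A \code{\link{count_matrix}}.
#' @param logratio_trim Fraction trimmed at each end of the M values.
#' @param sum_trim Fraction trimmed at each end of the A values.
#' @param a_cutoff Genes with A below this are dropped before trimming.
#' @return data.frame with columns \code{sample_id}, \code{lib_size},
#'   \code{norm_factor}; the chosen reference sample id is attached as
#'   attribute \code{ref_sample}.
#' @export
tmm_factors <- function(counts, logratio_trim = 0.3, sum_trim = 0.05,
                        a_cutoff = -1e10) {
  stopifnot(inherits(counts, "count_matrix"))
  m <- counts$counts
  if (ncol(m) < 2) stop("TMM needs at least 2 samples")
  lib <- colSums(m)
  if (any(lib <= 0))
    stop("normalization error: sample with zero library size: ",
         colnames(m)[lib <= 0][1L])
  f75 <- apply(m, 2, function(x) stats::quantile(x, 0.75)) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  shared <- vapply(seq_len(ncol(m)),
                   function(j) any(m[, j] > 0 & m[, ref] > 0), logical(1))
  if (!all(shared))
    stop("normalization error: sample shares no nonzero genes with the ",
         "reference: ", colnames(m)[!shared][1L])
  nf <- edgeR::calcNormFactors(m, lib.size = lib, method = "TMM",
                               refColumn = ref,
                               logratioTrim = logratio_trim,
                               sumTrim = sum_trim, Acutoff = a_cutoff)
  out <- data.frame(sample_id = colnames(m), lib_size = unname(lib),
                    norm_factor = unname(nf), stringsAsFactors = FALSE)
  attr(out, "ref_sample") <- colnames(m)[ref]
  out
}

#' Counts per million, optionally log2 with a prior count
#'
#' CPM uses the TMM-effective library size \code{lib_size * norm_factor};
#' on the log scale a library-size-scaled prior count keeps zeros finite
#' (the standard edgeR offset).
#'
#' @param counts A \code{\link{count_matrix}}.
#' @param factors Output of \code{\link{tmm_factors}} (or \code{NULL} for
#'   unit factors).
#' @param log Return log2 CPM?
#' @param prior_count Prior count used when \code{log = TRUE}.
#' @return An \code{\link{expr_matrix}}.
#' @export
cpm_matrix <- function(counts, factors = NULL, log = FALSE,
                       prior_count = 0.5) {
  stopifnot(inherits(counts, "count_matrix"))
  m <- counts$counts
  if (is.null(factors)) {
    eff <- colSums(m)
  } else {
    if (!all(colnames(m) %in% factors$sample_id))
      stop("factors do not cover all samples")
    factors <- factors[match(colnames(m), factors$sample_id), ]
    eff <- factors$lib_size * factors$norm_factor
  }
  if (any(eff <= 0)) stop("zero effective library size")
  v <- edgeR::cpm(m, lib.size = eff, log = log, prior.count = prior_count)
  dimnames(v) <- dimnames(m)
  expr_matrix(v, log = log, prior_count = if (log) prior_count else NA_real_,
              groups = counts$groups)
}

#' Low-expression filter on the logCPM scale
#'
#' Keeps a gene iff it falls below \code{threshold} logCPM in no more than
#' \code{max_low_fraction} of the samples, i.e. genes below threshold in
#' strictly more than that fraction are removed. Gene order is preserved.
#'
#' @param logcpm An \code{\link{expr_matrix}} on the log scale.
#' @param threshold logCPM cutoff.
#' @param max_low_fraction Maximum tolerated fraction of low samples.
#' @return Character vector of kept gene ids.
#' @export
filter_low_expression <- function(logcpm, threshold = 1.0,
                                  max_low_fraction = 0.5) {
  stopifnot(inherits(logcpm, "expr_matrix"))
  if (!logcpm$log)
    stop("usage error: filter_low_expression expects log-scale input")
  n_low <- rowSums(logcpm$values < threshold)
  keep <- n_low <= max_low_fraction * ncol(logcpm$values)
  rownames(logcpm$values)[keep]
}

#' Subset an expression matrix to a gene set, preserving order
#'
#' @param x An \code{\link{expr_matrix}}.
#' @param genes Gene ids to keep (must exist).
#' @return The subsetted \code{expr_matrix}.
#' @export
subset_genes <- function(x, genes) {
  stopifnot(inherits(x, "expr_matrix"))
  missing <- setdiff(genes, rownames(x$values))
  if (length(missing) > 0) stop("unknown gene id: ", missing[1L])
  expr_matrix(x$values[genes, , drop = FALSE], log = x$log,
              prior_count = x$prior_count, groups = x$groups)
}
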