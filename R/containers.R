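#' Construct a validated count matrix
#'
#' A \code{count_matrix} bundles a genes x samples matrix of raw,
#' non-negative integer counts with the tumour/normal group label of every
#' sample. It is the common currency of the normalisation and differential
#' expression steps.
#'
#' @param counts Integer matrix, genes in rows, samples in columns. Row and
#'   column names are required and must be unique.
#' @param groups Character or factor vector, one entry per sample, each
#'   \code{"tumour"} or \code{"normal"}. May be named by sample id; if
#'   unnamed it is matched positionally to \code{colnames(counts)}.
#' @return An object of class \code{count_matrix}: a list with elements
#'   \code{counts} (the validated matrix) and \code{groups} (a named factor
#'   with levels \code{normal}, \code{tumour}).
#' @export
count_matrix <- function(counts, groups) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count matrix must have gene row names and sample column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene id in count matrix: ",
         rownames(counts)[duplicated(rownames(counts))][1L])
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample id in count matrix: ",
         colnames(counts)[duplicated(colnames(counts))][1L])
  if (!is.numeric(counts)) stop("counts must be numeric")
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("invalid count (negative or non-integral) for gene %s, sample %s",
                 rownames(counts)[bad[1L, 1L]], colnames(counts)[bad[1L, 2L]]))
  storage.mode(counts) <- "double"
  if (is.null(names(groups))) {
    if (length(groups) != ncol(counts))
      stop("groups length does not match number of samples")
    names(groups) <- colnames(counts)
  }
  missing <- setdiff(colnames(counts), names(groups))
  if (length(missing) > 0)
    stop("missing group label for sample ", missing[1L])
  groups <- groups[colnames(counts)]
  if (!all(as.character(groups) %in% c("tumour", "normal")))
    stop("sample groups must be 'tumour' or 'normal'")
  groups <- factor(as.character(groups), levels = c("normal", "tumour"))
  names(groups) <- colnames(counts)
  structure(list(counts = counts, groups = groups), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (%d tumour, %d normal)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$groups == "tumour"), sum(x$groups == "normal")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Construct an expression matrix (CPM or logCPM)
#'
#' @param values Numeric genes x samples matrix.
#' @param log Logical; \code{TRUE} if values are log2 CPM.
#' @param prior_count Prior count used when computing log values.
#' @param groups Optional named factor of sample groups (as in
#'   \code{\link{count_matrix}}).
#' @return An object of class \code{expr_matrix}.
#' @export
expr_matrix <- function(values, log, prior_count = NA_real_, groups = NULL) {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix must have gene and sample names")
  if (log) {
    if (any(!is.finite(values))) stop("log expression values must be finite")
  } else if (any(values < 0)) {
    stop("CPM values must be non-negative")
  }
  if (!is.null(groups)) groups <- groups[colnames(values)]
  structure(list(values = values, log = isTRUE(log),
                 prior_count = prior_count, groups = groups),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$log) sprintf("log2 CPM, prior %.3g", x$prior_count) else "CPM"))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)
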