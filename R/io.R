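# TSV readers/writers for every table the pipeline touches, plus
# Cytoscape-compatible network export. TSV (tab separated, UTF-8, header
# row) is the canonical dialect throughout; gene identifiers are opaque
# strings.

.read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("format error: empty file ", path)
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    check.names = FALSE, stringsAsFactors = FALSE)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write / read a count matrix with its sample groups
#'
#' The matrix file is a TSV with a \code{gene_id} first column and one
#' column per sample; the companion group file has columns
#' \code{sample_id}, \code{group}.
#'
#' @param x A \code{\link{count_matrix}}.
#' @param path Matrix TSV path.
#' @param groups_path Sample-group TSV path (defaults to
#'   \code{<path>.groups.tsv}).
#' @return \code{write_count_matrix}: the path, invisibly.
#'   \code{read_count_matrix}: a validated \code{count_matrix}.
#' @export
write_count_matrix <- function(x, path,
                               groups_path = paste0(path, ".groups.tsv")) {
  stopifnot(inherits(x, "count_matrix"))
  df <- data.frame(gene_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(df, path)
  .write_tsv(data.frame(sample_id = names(x$groups),
                        group = as.character(x$groups)), groups_path)
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path,
                              groups_path = paste0(path, ".groups.tsv")) {
  df <- .read_tsv(path)
  if (colnames(df)[1L] != "gene_id")
    stop("format error: first column must be gene_id")
  samples <- colnames(df)[-1L]
  if (anyDuplicated(samples))
    stop("format error: duplicate sample column ",
         samples[duplicated(samples)][1L])
  if (anyDuplicated(df$gene_id))
    stop("format error: duplicate gene id ",
         df$gene_id[duplicated(df$gene_id)][1L])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("format error: non-numeric counts in ", path)
  rownames(m) <- df$gene_id
  g <- .read_tsv(groups_path)
  if (!all(c("sample_id", "group") %in% colnames(g)))
    stop("format error: group file needs sample_id and group columns")
  count_matrix(m, stats::setNames(g$group, g$sample_id))
}

#' Read / write a gene annotation table (gene_id, biotype)
#'
#' Biotypes must be one of \code{protein_coding}, \code{lncRNA},
#' \code{miRNA}; duplicate gene ids are rejected.
#'
#' @param path TSV path.
#' @return data.frame with columns \code{gene_id}, \code{biotype}.
#' @export
read_gene_annotation <- function(path) {
  df <- .read_tsv(path)
  if (!all(c("gene_id", "biotype") %in% colnames(df)))
    stop("format error: annotation needs gene_id and biotype columns")
  if (anyDuplicated(df$gene_id))
    stop("format error: duplicate gene id in annotation: ",
         df$gene_id[duplicated(df$gene_id)][1L])
  ok <- df$biotype %in% c("protein_coding", "lncRNA", "miRNA")
  if (!all(ok))
    stop("format error: unknown biotype ", df$biotype[!ok][1L])
  df[, c("gene_id", "biotype")]
}

#' @rdname read_gene_annotation
#' @param annotation data.frame to write.
#' @export
write_gene_annotation <- function(annotation, path)
  .write_tsv(annotation[, c("gene_id", "biotype")], path)

#' Read / write a miRNA-target interaction table
#'
#' Columns \code{mirna_id}, \code{target_id}. Duplicate rows are collapsed
#' to a single edge with a warning; self edges are rejected.
#'
#' @param path TSV path.
#' @return data.frame of unique directed edges.
#' @export
read_interaction_table <- function(path) {
  df <- .read_tsv(path)
  if (!all(c("mirna_id", "target_id") %in% colnames(df)))
    stop("format error: interactions need mirna_id and target_id columns")
  df <- df[, c("mirna_id", "target_id")]
  if (any(df$mirna_id == df$target_id))
    stop("format error: self edge in interaction table")
  n0 <- nrow(df)
  df <- unique(df)
  if (nrow(df) < n0)
    warning(sprintf("collapsed %d duplicate interaction row(s)", n0 - nrow(df)))
  rownames(df) <- NULL
  df
}

#' @rdname read_interaction_table
#' @param interactions data.frame to write.
#' @export
write_interaction_table <- function(interactions, path)
  .write_tsv(interactions[, c("mirna_id", "target_id")], path)

#' Read / write a clinical survival table
#'
#' Columns \code{sample_id}, \code{time} (days, > 0), \code{event}
#' (1 = death, 0 = censored); one record per sample.
#'
#' @param path TSV path.
#' @return Validated data.frame.
#' @export
read_clinical_table <- function(path) {
  df <- .read_tsv(path)
  if (!all(c("sample_id", "time", "event") %in% colnames(df)))
    stop("format error: clinical table needs sample_id, time, event columns")
  if (anyDuplicated(df$sample_id))
    stop("format error: duplicate sample in clinical table: ",
         df$sample_id[duplicated(df$sample_id)][1L])
  if (any(!is.finite(df$time)) || any(df$time <= 0))
    stop("format error: clinical time must be > 0")
  if (!all(df$event %in% c(0, 1)))
    stop("format error: clinical event must be 0 or 1")
  df[, c("sample_id", "time", "event")]
}

#' @rdname read_clinical_table
#' @param clinical data.frame to write.
#' @export
write_clinical_table <- function(clinical, path)
  .write_tsv(clinical[, c("sample_id", "time", "event")], path)

#' Export a ceRNA network for Cytoscape
#'
#' SIF lines are \code{source<TAB>relation<TAB>target} with relations
#' \code{lnc_mir} (lncRNA--miRNA) and \code{mir_mrna} (miRNA--mRNA).
#' GraphML carries a \code{biotype} node attribute and \code{relation} /
#' \code{evidence} edge attributes, and round-trips through
#' \code{\link{read_network_graphml}}.
#'
#' @param network A \code{cerna_network} from \code{\link{build_network}}.
#' @param path Output file.
#' @param format \code{"SIF"} or \code{"GraphML"}.
#' @return The path, invisibly.
#' @export
write_network <- function(network, path, format = c("SIF", "GraphML")) {
  stopifnot(inherits(network, "cerna_network"))
  format <- match.arg(format)
  if (format == "SIF") {
    lines <- character(0)
    if (nrow(network$edges) > 0)
      lines <- with(network$edges, paste(source, relation, target,
                                         sep = "\t"))
    writeLines(lines, path)
  } else {
    g <- .network_to_igraph(network)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

.network_to_igraph <- function(network) {
  if (nrow(network$nodes) == 0)
    return(igraph::make_empty_graph(directed = FALSE))
  g <- igraph::graph_from_data_frame(
    d = if (nrow(network$edges) > 0)
      network$edges[, c("source", "target", "relation", "evidence")]
    else data.frame(source = character(0), target = character(0),
                    relation = character(0), evidence = character(0)),
    directed = FALSE,
    vertices = network$nodes[, c("id", "biotype")])
  g
}

#' Re-import a GraphML network written by \code{\link{write_network}}
#'
#' @param path GraphML file.
#' @return List with \code{nodes} (id, biotype) and \code{edges}
#'   (source, target, relation, evidence) data.frames.
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- data.frame(id = igraph::vertex_attr(g, "name"),
                      biotype = igraph::vertex_attr(g, "biotype"),
                      stringsAsFactors = FALSE)
  el <- igraph::as_edgelist(g)
  edges <- data.frame(source = el[, 1], target = el[, 2],
                      relation = igraph::edge_attr(g, "relation"),
                      evidence = igraph::edge_attr(g, "evidence"),
                      stringsAsFactors = FALSE)
  list(nodes = nodes, edges = edges)
}
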