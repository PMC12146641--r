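# Joint clustering of the RNA and ATAC reductions and correlation-based
# cell-type annotation against reference pseudobulks.
#
# The joint graph deliberately substitutes a standardized-concatenation
# shared-nearest-neighbor (SNN) graph for the weighted-nearest-neighbor
# algorithm: each embedding is standardized per component, the two are
# concatenated, and an SNN graph with Jaccard edge weights is built over
# Euclidean k nearest neighbors.

#' Shared-nearest-neighbor graph over joint RNA + ATAC embeddings
#'
#' @param rna \code{reduced_matrix} from \code{pca_reduce}; components
#'   1..50 (or fewer) are used.
#' @param atac \code{reduced_matrix} from \code{lsi_reduce}; components
#'   2..40 (or fewer) are used, dropping the depth-tracking first component.
#' @param k number of nearest neighbors (default 20); must be < n_cells.
#' @param dims_rna,dims_atac integer vectors of component indices; defaults
#'   1:50 and 2:40, capped at what is available.
#' @return a weighted undirected \code{igraph} graph; vertex names are cell
#'   barcodes, edge weight is the Jaccard overlap of k-NN sets (self
#'   included). Zero-weight pairs carry no edge.
#' @export
joint_neighbor_graph <- function(rna, atac, k = 20,
                                 dims_rna = 1:50, dims_atac = 2:40) {
  stopifnot(inherits(rna, "reduced_matrix"), inherits(atac, "reduced_matrix"))
  if (!identical(rownames(rna$embedding), rownames(atac$embedding)))
    stop("joint_neighbor_graph: embeddings must share the same cell order")
  n <- nrow(rna$embedding)
  if (k >= n) stop("joint_neighbor_graph: k must be smaller than the cell count")
  dims_rna <- dims_rna[dims_rna <= ncol(rna$embedding)]
  dims_atac <- dims_atac[dims_atac <= ncol(atac$embedding)]
  std <- function(e) {
    s <- apply(e, 2, stats::sd)
    scale(e, center = TRUE, scale = ifelse(s > 0, s, 1))
  }
  x <- cbind(std(rna$embedding[, dims_rna, drop = FALSE]),
             std(atac$embedding[, dims_atac, drop = FALSE]))
  d <- as.matrix(stats::dist(x))
  # k-NN sets including the point itself (ties broken by cell order)
  nn <- apply(d, 1, function(row) order(row)[seq_len(k + 1L)])  # (k+1) x n
  memb <- matrix(FALSE, n, n)
  for (i in seq_len(n)) memb[i, nn[, i]] <- TRUE
  shared <- tcrossprod(memb * 1)
  jac <- shared / (2 * (k + 1L) - shared)
  diag(jac) <- 0
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::V(g)$name <- rownames(rna$embedding)
  g
}

#' Louvain community detection on a neighbor graph
#'
#' @param graph weighted \code{igraph} graph.
#' @param resolution modularity resolution (default 1.0).
#' @param seed integer seed; the Louvain heuristic is seeded for
#'   reproducibility.
#' @return named integer vector barcode -> cluster id (1-based).
#' @export
louvain_cluster <- function(graph, resolution = 1.0, seed = 1L) {
  set.seed(seed)
  cl <- igraph::cluster_louvain(graph, resolution = resolution)
  stats::setNames(igraph::membership(cl), igraph::V(graph)$name)
}

#' Annotate clusters by Spearman correlation to reference pseudobulks
#'
#' Query and reference are restricted to their shared feature ids; the top
#' \code{n_var} variable genes are selected on the reference side; each
#' query pseudobulk is assigned the reference label with the highest
#' Spearman correlation (average ranks for ties; label ties broken by
#' reference label order).
#'
#' @param query \code{pseudobulk_set} of cluster pseudobulks.
#' @param reference \code{pseudobulk_set} (or features x labels matrix) of
#'   reference profiles.
#' @param n_var number of variable genes used (default 3000, capped at the
#'   shared feature count).
#' @return data.frame: cluster, label, rho.
#' @export
annotate_clusters <- function(query, reference, n_var = 3000) {
  qm <- if (inherits(query, "pseudobulk_set")) query$values else query
  rm_ <- if (inherits(reference, "pseudobulk_set")) reference$values else reference
  shared <- intersect(rownames(qm), rownames(rm_))
  if (length(shared) < 3)
    stop("annotate_clusters: fewer than 3 shared features")
  qm <- qm[shared, , drop = FALSE]
  rm_ <- rm_[shared, , drop = FALSE]
  v <- apply(rm_, 1, stats::var)
  top <- order(-v)[seq_len(min(n_var, length(shared)))]
  rho <- stats::cor(qm[top, , drop = FALSE], rm_[top, , drop = FALSE],
                    method = "spearman")
  best <- apply(rho, 1, which.max)  # which.max takes the first on ties
  data.frame(cluster = colnames(qm),
             label = colnames(rm_)[best],
             rho = rho[cbind(seq_len(nrow(rho)), best)],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Constant-label annotation when no reference is available
#'
#' Samples from cell lines, sorted cell types or tissues without a
#' reference counterpart are annotated with the original source name.
#'
#' @param clusters vector of cluster ids.
#' @param source_name the cell line / cell type / tissue name.
#' @return data.frame: cluster, label.
#' @export
fallback_annotation <- function(clusters, source_name) {
  if (!is.character(source_name) || length(source_name) != 1 ||
      !nzchar(source_name))
    stop("fallback_annotation: source name must be a non-empty string")
  data.frame(cluster = as.character(unique(clusters)), label = source_name,
             stringsAsFactors = FALSE)
}
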