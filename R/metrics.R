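# Evaluation metrics -----------------------------------------------------

#' Pseudotime R-squared
#'
#' The square of the Pearson correlation between true and inferred
#' pseudotime (affine-invariant).
#'
#' @param pseudotime_true,pseudotime_inferred equal-length vectors
#'   (length >= 2, nonconstant).
#' @return scalar in `[0, 1]`.
#' @export
r_squared <- function(pseudotime_true, pseudotime_inferred) {
  stopifnot(length(pseudotime_true) == length(pseudotime_inferred),
            length(pseudotime_true) >= 2)
  if (sd(pseudotime_true) == 0 || sd(pseudotime_inferred) == 0)
    stop("undefined metric: constant pseudotime vector")
  cor(pseudotime_true, pseudotime_inferred)^2
}

#' Per-cell kNN purity of an inferred pseudotime
#'
#' For each cell, the Jaccard index between its k-nearest-neighbor sets
#' (by absolute pseudotime difference) under the true and inferred
#' orderings.
#'
#' @param pseudotime_true,pseudotime_inferred equal-length vectors.
#' @param k neighborhood size (default 50, truncated below n).
#' @return numeric vector (one value per cell).
#' @export
knn_purity <- function(pseudotime_true, pseudotime_inferred, k = 50) {
  n <- length(pseudotime_true)
  stopifnot(length(pseudotime_inferred) == n, k >= 1)
  k <- min(k, n - 1L)
  nbset <- function(pt, i) {
    d <- abs(pt - pt[i])
    d[i] <- Inf
    order(d)[seq_len(k)]
  }
  vapply(seq_len(n), function(i) {
    a <- nbset(pseudotime_true, i)
    b <- nbset(pseudotime_inferred, i)
    length(intersect(a, b)) / length(union(a, b))
  }, 0)
}

#' Graph connectivity of cell types in a kNN graph
#'
#' Mean over cell types of the fraction of the type's cells lying in the
#' largest connected component of the subgraph induced by that type.
#'
#' @param embedding_graph either an igraph object over cells or an
#'   embedding matrix (a kNN graph with `k` neighbors is built from it).
#' @param cell_types type labels (length = number of cells).
#' @param k neighbors for graph construction when an embedding is given
#'   (default 15).
#' @return scalar in `(0, 1]`.
#' @export
graph_connectivity <- function(embedding_graph, cell_types, k = 15) {
  if (!igraph::is_igraph(embedding_graph))
    embedding_graph <- knn_graph(embedding_graph, k)
  types <- unique(cell_types)
  scores <- vapply(types, function(ty) {
    idx <- which(cell_types == ty)
    if (!length(idx)) {
      warning("empty cell type '", ty, "' excluded")
      return(NA_real_)
    }
    sub <- igraph::induced_subgraph(embedding_graph, idx)
    max(igraph::components(sub)$csize) / length(idx)
  }, 0)
  mean(scores, na.rm = TRUE)
}

# Undirected symmetric kNN graph from an embedding.
knn_graph <- function(embedding, k = 15) {
  n <- nrow(embedding)
  k <- min(k, n - 1L)
  D <- as.matrix(dist(embedding))
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    nb <- setdiff(order(D[i, ]), i)[seq_len(k)]
    cbind(i, nb)
  }))
  igraph::graph_from_edgelist(edges, directed = FALSE)
}

#' Batch average silhouette width (batch mixing score)
#'
#' Per cell type, the mean of `1 - |silhouette|` computed on batch labels
#' in the embedding, averaged over types; 1 means batches are perfectly
#' mixed within each type, 0 perfectly separated.
#'
#' @param embedding numeric matrix (cells x dims).
#' @param batch_labels,cell_types per-cell labels.
#' @return scalar in `[0, 1]`.
#' @export
batch_asw <- function(embedding, batch_labels, cell_types) {
  if (length(unique(batch_labels)) < 2)
    stop("undefined metric: a single batch has no silhouette")
  types <- unique(cell_types)
  scores <- vapply(types, function(ty) {
    idx <- which(cell_types == ty)
    b <- batch_labels[idx]
    if (length(unique(b)) < 2 || length(idx) < 3) return(NA_real_)
    sil <- cluster::silhouette(as.integer(factor(b)),
                               dist(embedding[idx, , drop = FALSE]))
    mean(1 - abs(sil[, "sil_width"]))
  }, 0)
  mean(scores, na.rm = TRUE)
}

#' Mean cosine similarity between velocity fields
#'
#' Mean over cells of the cosine of the angle between the true and
#' inferred velocity vectors; scale invariant. Zero rows are skipped and
#' their count reported as an attribute.
#'
#' @param v_true,v_inferred equal-shape matrices (cells x genes).
#' @return scalar in `[-1, 1]` with attribute `n_skipped`.
#' @export
velocity_cosine <- function(v_true, v_inferred) {
  stopifnot(identical(dim(v_true), dim(v_inferred)))
  nt <- sqrt(rowSums(v_true^2))
  ni <- sqrt(rowSums(v_inferred^2))
  ok <- nt > 0 & ni > 0
  val <- mean(rowSums(v_true[ok, , drop = FALSE] *
                        v_inferred[ok, , drop = FALSE]) / (nt[ok] * ni[ok]))
  attr(val, "n_skipped") <- sum(!ok)
  val
}

#' AUPRC, AUROC and the AUPRC ratio
#'
#' Standard areas under the precision-recall and ROC curves for a binary
#' truth against continuous scores; the AUPRC ratio divides by the
#' positive prevalence (the random-classifier baseline).
#'
#' @param truth_binary logical/0-1 vector with both classes present.
#' @param scores numeric scores (higher = more positive).
#' @return list with `auprc`, `auroc`, `auprc_ratio`.
#' @export
auprc_auroc <- function(truth_binary, scores) {
  y <- as.integer(truth_binary != 0)
  stopifnot(length(y) == length(scores))
  if (length(unique(y)) < 2)
    stop("undefined metric: truth contains a single class")
  np <- sum(y); nn <- sum(1 - y)
  # AUROC via the rank statistic (ties handled by midranks)
  r <- rank(scores)
  auroc <- (sum(r[y == 1]) - np * (np + 1) / 2) / (np * nn)
  # AUPRC by stepping thresholds from the highest score down
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(y[ord])
  prec <- tp / seq_along(tp)
  rec <- tp / np
  auprc <- sum(diff(c(0, rec)) * prec)
  list(auprc = auprc, auroc = auroc, auprc_ratio = auprc / (np / length(y)))
}

#' Bonferroni correction
#'
#' `min(p * n, 1)` per p-value.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @return adjusted p-values.
#' @export
bonferroni <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "bonferroni")
}

#' Summary statistics of a count matrix
#'
#' The per-cell and per-gene distribution descriptors used to compare
#' simulated with experimental data: library size and zero proportion per
#' cell; zero proportion, mean and variance per gene (with the
#' zero-vs-mean pairing). The ATAC variant reports library size, cell
#' sparsity and peak mean.
#'
#' @param counts nonnegative cell x gene (or cell x region) matrix.
#' @param modality `"rna"` or `"atac"`.
#' @return list of named numeric vectors.
#' @export
summary_stats <- function(counts, modality = c("rna", "atac")) {
  modality <- match.arg(modality)
  stopifnot(all(counts >= 0))
  if (modality == "atac")
    return(list(lib_size_per_cell = rowSums(counts),
                cell_sparsity = rowMeans(counts == 0),
                peak_mean = colMeans(counts)))
  list(lib_size_per_cell = rowSums(counts),
       zero_prop_per_cell = rowMeans(counts == 0),
       zero_prop_per_gene = colMeans(counts == 0),
       mean_per_gene = colMeans(counts),
       var_per_gene = apply(counts, 2, stats::var),
       zero_vs_mean = data.frame(mean = colMeans(counts),
                                 zero_prop = colMeans(counts == 0)))
}

#' @importFrom stats p.adjust var
NULL
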