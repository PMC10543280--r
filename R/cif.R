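# Cell identity factors --------------------------------------------------
#
# Each cell carries one latent identity vector per kinetic parameter
# (kon, koff, s), laid out in four contiguous segments:
#   non-diff | diff | tf | lig
# The non-diff segment is shared environmental heterogeneity; the diff
# segment encodes tree position (trajectory or cluster); the tf segment
# carries the previous cell's TF expression (GRN feedback); the lig segment
# carries neighboring cells' ligand expression (CCI).

#' Sample the non-differential CIF segment
#'
#' Entries are i.i.d. Gaussian with mean 1 and standard deviation
#' `sigma_cif`. The unit mean keeps the kinetic-parameter products centred
#' on positive values; rank-based scaling later erases location anyway.
#'
#' @param ncell,n_nd matrix dimensions (`n_nd` may be 0).
#' @param sigma_cif standard deviation (>= 0).
#' @param stream optional integer seed.
#' @return `ncell` x `n_nd` matrix.
#' @export
sample_nondiff_cif <- function(ncell, n_nd, sigma_cif, stream = NULL) {
  stopifnot(ncell >= 1, n_nd >= 0)
  if (sigma_cif < 0) stop("sigma_cif must be nonnegative")
  with_stream(stream,
    matrix(rnorm(ncell * n_nd, mean = 1, sd = sigma_cif),
           nrow = ncell, ncol = n_nd))
}

#' Place cells on the differentiation tree
#'
#' Continuous mode distributes cells over root-to-leaf lineages
#' proportionally to lineage length, at stratified-uniform positions along
#' each lineage; pseudotime is the path distance from the root. Discrete
#' mode assigns cells to leaves round-robin (balanced).
#'
#' @param tree a `diff_tree`.
#' @param ncell number of cells.
#' @param mode `"continuous"` or `"discrete"`.
#' @param stream optional integer seed.
#' @return a data frame (cell meta) with columns `cell`, `lineage`,
#'   `type` (nearest node below the position), `pseudotime`, and for
#'   continuous mode `edge_child` and `offset` locating the position on its
#'   tree edge.
#' @export
place_cells <- function(tree, ncell, mode = c("continuous", "discrete"),
                        stream = NULL) {
  mode <- match.arg(mode)
  lineages <- tree_lineages(tree)
  nl <- length(lineages)
  if (mode == "discrete") {
    leaf <- tree$leaves[(seq_len(ncell) - 1L) %% length(tree$leaves) + 1L]
    off <- unname(tree$blen[leaf])
    off[is.na(off)] <- 0
    return(data.frame(cell = seq_len(ncell), lineage = match(leaf, tree$leaves),
                      type = leaf, pseudotime = unname(tree$depth[leaf]),
                      edge_child = leaf, offset = off,
                      stringsAsFactors = FALSE))
  }
  with_stream(stream, {
    lens <- vapply(lineages, function(p) unname(tree$depth[tail(p, 1)]), 0)
    if (all(lens == 0)) lens <- rep(1, nl)
    alloc <- floor(ncell * lens / sum(lens))
    rem <- ncell - sum(alloc)
    if (rem > 0) {
      extra <- order(lens, decreasing = TRUE)[(seq_len(rem) - 1L) %% nl + 1L]
      for (i in extra) alloc[i] <- alloc[i] + 1L
    }
    meta <- do.call(rbind, lapply(seq_len(nl), function(li) {
      n <- alloc[li]
      if (n == 0) return(NULL)
      path <- lineages[[li]]
      # stratified-uniform depths along [0, lineage length]
      d <- (seq_len(n) - runif(n)) / n * lens[li]
      node_d <- tree$depth[path]
      child_idx <- vapply(d, function(x) max(which(node_d <= x + 1e-12)), 0L)
      child_idx <- pmin(child_idx + (d > node_d[child_idx] + 1e-12),
                        length(path))
      child_idx[child_idx < 2L] <- 2L
      ec <- path[child_idx]
      data.frame(cell = NA_integer_, lineage = li, type = ec,
                 pseudotime = d, edge_child = ec,
                 offset = d - unname(tree$depth[path[child_idx - 1L]]),
                 stringsAsFactors = FALSE)
    }))
    meta <- meta[order(meta$lineage, meta$pseudotime), ]
    meta$cell <- seq_len(nrow(meta))
    rownames(meta) <- NULL
    meta
  })
}

# Brownian values over the tree nodes: each node's value = parent's value
# plus N(0, rate^2 * branch length). Returns named vector over nodes.
node_brownian <- function(tree, rate) {
  val <- setNames(numeric(length(tree$nodes)), tree$nodes)
  todo <- tree$root
  while (length(todo)) {
    n <- todo[1]; todo <- todo[-1]
    for (k in tree_children(tree, n)) {
      val[k] <- val[n] + rnorm(1, 0, rate * sqrt(max(tree$blen[k], 0)))
      todo <- c(todo, k)
    }
  }
  val
}

#' Sample the differential CIF segment
#'
#' Continuous mode: each diff-CIF coordinate is a Brownian walk along the
#' tree whose scale is set by tree distance alone — a cell at path
#' distance D from the root has value `sum of increments
#' q_t ~ N(0, delta_d)`, so `Var = D`. Cells on a shared branch share the
#' walk up to their divergence, which is what imprints the trajectory;
#' `sigma_cif` does not enter the walk (it scales the non-diff
#' heterogeneity against this fixed-scale signal, so a larger `sigma_cif`
#' yields noisier trajectories). Discrete mode: each leaf type gets a
#' mean vector from the same unit-rate walk evaluated at the leaves, and
#' cells are shifted around their type mean by `N(0, sigma_cif)`.
#'
#' @param tree a `diff_tree`.
#' @param ncell number of cells.
#' @param n_diff segment width.
#' @param sigma_cif within-type spread (discrete mode); the continuous
#'   walk is scaled by tree distance alone.
#' @param mode `"continuous"` or `"discrete"`.
#' @param stream optional integer seed.
#' @param meta optional precomputed [place_cells()] output (so that the
#'   same positions can be reused across the three kinetic parameters or
#'   across time steps).
#' @return list with `cif` (`ncell` x `n_diff` matrix) and `meta`.
#' @export
sample_diff_cif <- function(tree, ncell, n_diff, sigma_cif,
                            mode = c("continuous", "discrete"),
                            stream = NULL, meta = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_diff >= 0, sigma_cif >= 0)
  with_stream(stream, {
    if (is.null(meta)) meta <- place_cells(tree, ncell, mode)
    stopifnot(nrow(meta) == ncell)
    if (n_diff == 0)
      return(list(cif = matrix(0, ncell, 0), meta = meta))
    if (mode == "discrete") {
      centers <- vapply(seq_len(n_diff), function(i)
        node_brownian(tree, rate = 1), numeric(length(tree$nodes)))
      cif <- centers[meta$type, , drop = FALSE] +
        matrix(rnorm(ncell * n_diff, 0, sigma_cif), ncell, n_diff)
      rownames(cif) <- NULL
      return(list(cif = cif, meta = meta))
    }
    cif <- matrix(0, ncell, n_diff)
    for (j in seq_len(n_diff)) {
      # walk along each edge through the cells sitting on it, sharing
      # node values across lineages
      nodeval <- setNames(numeric(length(tree$nodes)), tree$nodes)
      todo <- tree$root
      while (length(todo)) {
        n <- todo[1]; todo <- todo[-1]
        for (k in tree_children(tree, n)) {
          on_edge <- which(meta$edge_child == k)
          ord <- on_edge[order(meta$offset[on_edge])]
          prev_off <- 0
          prev_val <- nodeval[n]
          for (ci in ord) {
            step <- max(meta$offset[ci] - prev_off, 0)
            prev_val <- prev_val + rnorm(1, 0, sqrt(step))
            cif[ci, j] <- prev_val
            prev_off <- meta$offset[ci]
          }
          nodeval[k] <- prev_val +
            rnorm(1, 0, sqrt(max(tree$blen[k] - prev_off, 0)))
          todo <- c(todo, k)
        }
      }
    }
    list(cif = cif, meta = meta)
  })
}

#' Update the TF segment of a cell's CIF from the previous cell's expression
#'
#' Entry i is `x_i / (x_i + mean(x over TFs))`, where `x_i` is the previous
#' cell's expression of TF i — a saturating normalization in `[0, 1)`. An
#' all-zero TF expression returns zeros (no regulation exerted).
#'
#' @param prev_expression nonnegative gene-length vector (previous cell).
#' @param tf_ids 1-based gene ids of the TFs.
#' @return numeric vector of length `length(tf_ids)`.
#' @export
update_tf_cif <- function(prev_expression, tf_ids) {
  stopifnot(all(prev_expression >= 0))
  x <- prev_expression[tf_ids]
  m <- mean(x)
  if (m == 0) return(rep(0, length(tf_ids)))
  x / (x + m)
}

#' Assemble a CIF (or RIV-compatible) matrix from its four segments
#'
#' @param nd,diff,tf,lig matrices with equal row counts (zero-column
#'   matrices for disabled segments).
#' @return matrix with a `segments` attribute giving the four widths.
#' @export
assemble_cif <- function(nd, diff, tf = NULL, lig = NULL) {
  ncell <- nrow(nd)
  tf <- tf %||% matrix(0, ncell, 0)
  lig <- lig %||% matrix(0, ncell, 0)
  if (!all(vapply(list(diff, tf, lig), nrow, 0L) == ncell))
    stop("segment row counts disagree")
  m <- cbind(nd, diff, tf, lig)
  attr(m, "segments") <- c(nd = ncol(nd), diff = ncol(diff),
                           tf = ncol(tf), lig = ncol(lig))
  m
}
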