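# Gene regulatory network inputs -----------------------------------------

#' Build a GRN specification from an edge table
#'
#' The GRN is a 3-column table (regulator, target, effect > 0) over 1-based
#' gene ids. The derived effect matrix has one row per TF (unique
#' regulator) and one column per gene; entry (i, j) is the regulation
#' strength of TF i on gene j. It is embedded in the synthesis-rate GIV so
#' that stronger regulation raises the target's s and hence its expression.
#'
#' @param edges data frame (or file path of a headered TSV) with columns
#'   `regulator`, `target`, `effect`.
#' @param ngene total number of simulated genes.
#' @return a `grn_spec`: list with `edges`, `tfs`, `ngene`, `effect_matrix`
#'   (nTF x ngene).
#' @export
load_grn <- function(edges, ngene) {
  if (is.character(edges))
    edges <- read.table(edges, header = TRUE, sep = "\t")
  stopifnot(is.data.frame(edges), ncol(edges) >= 3L, ngene >= 1L)
  edges <- edges[, 1:3]
  names(edges) <- c("regulator", "target", "effect")
  edges$regulator <- as.integer(edges$regulator)
  edges$target <- as.integer(edges$target)
  for (i in seq_len(nrow(edges))) {
    e <- edges[i, ]
    if (is.na(e$regulator) || is.na(e$target) ||
        e$regulator < 1 || e$regulator > ngene ||
        e$target < 1 || e$target > ngene)
      stop("GRN row ", i, ": gene id outside 1..", ngene)
    if (e$regulator == e$target)
      stop("GRN row ", i, ": self-loop on gene ", e$regulator)
    if (!is.finite(e$effect) || e$effect <= 0)
      stop("GRN row ", i, ": effect must be a positive real")
  }
  tfs <- sort(unique(edges$regulator))
  eff <- matrix(0, nrow = length(tfs), ncol = ngene,
                dimnames = list(paste0("TF", tfs), paste0("gene", 1:ngene)))
  for (i in seq_len(nrow(edges)))
    eff[match(edges$regulator[i], tfs), edges$target[i]] <-
      eff[match(edges$regulator[i], tfs), edges$target[i]] + edges$effect[i]
  structure(list(edges = edges, tfs = tfs, ngene = ngene,
                 effect_matrix = eff),
            class = "grn_spec")
}

#' @export
print.grn_spec <- function(x, ...) {
  cat("<grn_spec> ", nrow(x$edges), " edges, ", length(x$tfs), " TFs over ",
      x$ngene, " genes\n", sep = "")
  invisible(x)
}

#' Bundled 100-gene GRN (synthetic)
#'
#' A seeded synthetic stand-in for the classic 100-gene benchmark GRN:
#' 9 master TFs, each regulating a module of targets, plus the TF-TF edge
#' gene 19 -> gene 20 used in worked examples. Effects are drawn uniformly
#' from \[1, 5\]. The topology is generated, not copied from any published
#' network; it reproduces the shape (gene count, TF-module structure) only.
#'
#' @param seed fixture seed (default 7, fixed so that all dataset grids
#'   share one network).
#' @return a `grn_spec` over 100 genes.
#' @export
grn_100 <- function(seed = 7) {
  with_stream(seed, {
    tfs <- c(2, 6, 10, 19, 33, 47, 62, 74, 91)
    pool <- setdiff(1:100, tfs)
    targets <- split(sample(pool), rep(seq_along(tfs), length.out = length(pool)))
    edges <- do.call(rbind, lapply(seq_along(tfs), function(i) {
      tg <- sort(targets[[i]])
      data.frame(regulator = tfs[i], target = tg,
                 effect = round(runif(length(tg), 1, 5), 2))
    }))
    # a TF regulating another TF, used in worked examples (gene 19 -> 20)
    edges <- rbind(edges,
                   data.frame(regulator = 19, target = 20, effect = 4))
    edges <- edges[!duplicated(edges[, 1:2]), ]
    load_grn(edges, ngene = 100)
  })
}

#' Ligand-receptor database
#'
#' @param pairs data frame (or headered TSV path) with columns `ligand`,
#'   `receptor`, `effect` (> 0).
#' @param ngene total number of simulated genes (ligand/receptor ids must
#'   resolve against it).
#' @return an `lr_db`: the validated table with `ngene` attached.
#' @export
load_lr_db <- function(pairs, ngene) {
  if (is.character(pairs))
    pairs <- read.table(pairs, header = TRUE, sep = "\t")
  stopifnot(is.data.frame(pairs), ncol(pairs) >= 3L, nrow(pairs) >= 1L)
  pairs <- pairs[, 1:3]
  names(pairs) <- c("ligand", "receptor", "effect")
  pairs$ligand <- as.integer(pairs$ligand)
  pairs$receptor <- as.integer(pairs$receptor)
  ok <- function(v) all(!is.na(v) & v >= 1 & v <= ngene)
  if (!ok(pairs$ligand) || !ok(pairs$receptor))
    stop("ligand/receptor ids must be in 1..", ngene)
  if (any(pairs$effect <= 0)) stop("LR effects must be positive")
  structure(list(pairs = pairs, ngene = ngene), class = "lr_db")
}

#' Evolve a GRN along pseudotime (cell-specific GRN mode)
#'
#' Starting from the input network, random edges are added or deleted
#' gradually from one cell to the next (cells ordered by pseudotime), each
#' edge event occurring independently with probability `change_rate` per
#' cell transition. The full per-cell series is retained as ground truth.
#'
#' @param grn a `grn_spec`.
#' @param ncell number of cells (series length).
#' @param change_rate per-transition probability of an edge addition and of
#'   an edge deletion event.
#' @param add,delete logical switches for the two event types.
#' @param stream optional integer seed.
#' @return list of `ncell` `grn_spec` objects; element 1 is the input.
#' @export
evolve_grn <- function(grn, ncell, change_rate, add = TRUE, delete = TRUE,
                       stream = NULL) {
  stopifnot(inherits(grn, "grn_spec"), ncell >= 1L, change_rate >= 0)
  with_stream(stream, {
    series <- vector("list", ncell)
    series[[1]] <- grn
    cur <- grn$edges
    for (t in seq_len(ncell - 1L)) {
      if (delete && nrow(cur) > 1L) {
        drop <- runif(nrow(cur)) < change_rate
        if (any(drop) && sum(!drop) >= 1L) cur <- cur[!drop, ]
      }
      if (add && runif(1) < change_rate) {
        reg <- sample(grn$tfs, 1L)
        tgt <- sample(setdiff(seq_len(grn$ngene), reg), 1L)
        if (!any(cur$regulator == reg & cur$target == tgt))
          cur <- rbind(cur, data.frame(regulator = reg, target = tgt,
                                       effect = round(runif(1, 1, 5), 2)))
      }
      series[[t + 1L]] <- load_grn(cur, grn$ngene)
    }
    series
  })
}
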