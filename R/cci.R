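# Cell-cell interaction ground truth and the spatial simulation ----------

#' Sample the cell-type-level CCI ground truth
#'
#' For each unordered cell-type pair (same-type pairs excluded by
#' default), a uniform number of ligand-receptor rows in
#' `pairs_range` is sampled without replacement from the database.
#'
#' @param lr_db an `lr_db`.
#' @param cell_types character vector of type labels.
#' @param pairs_range integer range (lo, hi) of LR rows per type pair;
#'   defaults to `(min(3, m), m)` where m is the database size.
#' @param include_same_type also populate same-type pairs.
#' @param stream optional integer seed.
#' @return data frame with columns `type_a`, `type_b`, `lr_row`.
#' @export
sample_cci_truth <- function(lr_db, cell_types, pairs_range = NULL,
                             include_same_type = FALSE, stream = NULL) {
  stopifnot(inherits(lr_db, "lr_db"))
  m <- nrow(lr_db$pairs)
  pairs_range <- pairs_range %||% c(min(3L, m), m)
  if (pairs_range[1] < 1 || pairs_range[2] > m || pairs_range[1] > pairs_range[2])
    stop("pairs_range must lie within [1, ", m, "]")
  types <- unique(cell_types)
  with_stream(stream, {
    out <- list()
    for (i in seq_along(types)) {
      jmax <- if (include_same_type) i else i - 1L
      for (j in seq_len(max(jmax, 0L))) {
        choices <- seq.int(pairs_range[1], pairs_range[2])
        nsel <- choices[sample.int(length(choices), 1L)]
        rows <- sort(sample.int(m, nsel))
        out[[length(out) + 1L]] <- data.frame(
          type_a = types[j], type_b = types[i], lr_row = rows,
          stringsAsFactors = FALSE)
      }
    }
    if (!length(out))
      return(data.frame(type_a = character(), type_b = character(),
                        lr_row = integer(), stringsAsFactors = FALSE))
    do.call(rbind, out)
  })
}

# Directed neighbor pairs implied by the type-level truth: for neighboring
# cells (i, j) of types (ti, tj) with (ti, tj) in the truth, both
# directions carry the pair's LR rows (ligand in the sender).
implied_cci_edges <- function(type_truth, nb_pairs, types) {
  if (is.null(nb_pairs) || !nrow(nb_pairs)) return(data.frame(from = integer(), to = integer(),
                                         lr_row = integer()))
  key <- paste(type_truth$type_a, type_truth$type_b)
  out <- list()
  for (r in seq_len(nrow(nb_pairs))) {
    i <- nb_pairs$from[r]; j <- nb_pairs$to[r]
    ti <- types[i]; tj <- types[j]
    hit <- key == paste(ti, tj) | key == paste(tj, ti)
    if (any(hit))
      out[[length(out) + 1L]] <- data.frame(from = i, to = j,
                                            lr_row = type_truth$lr_row[hit])
  }
  if (!length(out)) return(data.frame(from = integer(), to = integer(),
                                      lr_row = integer()))
  do.call(rbind, out)
}

#' Sample the single-cell-level CCI ground truth
#'
#' A uniform sample of `round(fraction * total)` of the directed
#' (neighboring cell pair, LR row) edges implied by the type-level truth.
#'
#' @param implied data frame of implied edges (`from`, `to`, `lr_row`).
#' @param fraction retained fraction in `[0, 1]` (default 0.8).
#' @param stream optional integer seed.
#' @return subset of `implied`.
#' @export
sample_cell_level_truth <- function(implied, fraction = 0.8, stream = NULL) {
  stopifnot(fraction >= 0, fraction <= 1)
  n <- nrow(implied)
  keep_n <- round(fraction * n)
  if (keep_n == 0) return(implied[0, ])
  with_stream(stream, {
    keep <- sort(sample.int(n, keep_n))
    implied[keep, ]
  })
}

#' Build a cell's ligand CIF segment
#'
#' Length `nlig * nnbs`: slot j holds the (saturating-normalized) ligand
#' expression of the cell occupying neighbor slot j at the previous step,
#' masked to the LR rows active in the single-cell truth for that sender;
#' empty slots and inactive rows are 0. Normalization is
#' `x / (x + mean(x over ligand genes))`, matching the TF feedback.
#'
#' @param cell receiving cell id.
#' @param nb integer vector of neighbor ids (slot order).
#' @param prev_expr previous-step expression matrix (cells x genes).
#' @param lr_db an `lr_db`.
#' @param cell_truth single-cell truth (`from`, `to`, `lr_row`).
#' @param nnbs slot count.
#' @return numeric vector of length `nrow(lr_db$pairs) * nnbs`.
#' @export
build_lig_cif <- function(cell, nb, prev_expr, lr_db, cell_truth, nnbs = 4) {
  nlig <- nrow(lr_db$pairs)
  seg <- numeric(nlig * nnbs)
  if (!length(nb)) return(seg)
  lig_genes <- lr_db$pairs$ligand
  for (j in seq_len(min(length(nb), nnbs))) {
    sender <- nb[j]
    x <- prev_expr[sender, lig_genes]
    mlig <- mean(x)
    vals <- if (mlig == 0) numeric(nlig) else x / (x + mlig)
    active <- cell_truth$lr_row[cell_truth$from == sender &
                                  cell_truth$to == cell]
    mask <- seq_len(nlig) %in% active
    seg[(j - 1L) * nlig + seq_len(nlig)] <- vals * mask
  }
  seg
}

# (nlig*nnbs) x ngene CCI effect matrix for the s GIV: the entry for
# (slot j, LR row l) at the receptor gene of row l is the row's effect.
lig_effect_matrix <- function(lr_db, ngene, nnbs = 4) {
  nlig <- nrow(lr_db$pairs)
  m <- matrix(0, nlig * nnbs, ngene)
  for (j in seq_len(nnbs)) for (l in seq_len(nlig))
    m[(j - 1L) * nlig + l, lr_db$pairs$receptor[l]] <- lr_db$pairs$effect[l]
  m
}

# Position of a depth along a root-to-leaf path: (edge child, offset, type).
position_on_path <- function(tree, path, depth) {
  node_d <- tree$depth[path]
  depth <- min(max(depth, 0), node_d[length(path)])
  ci <- max(which(node_d <= depth + 1e-12))
  if (ci < length(path) && depth > node_d[ci] + 1e-12) ci <- ci + 1L
  ci <- max(ci, 2L)
  list(edge_child = path[ci], offset = depth - unname(node_d[ci - 1L]),
       type = path[ci], pseudotime = depth)
}

#' Run the stepwise spatial simulation with cell-cell interactions
#'
#' At step t a new cell is born at the tree root and placed on the grid;
#' every live cell advances along its (randomly chosen) root-to-leaf path
#' by (tree depth)/ncell per step, so cells born at different steps occupy
#' different stages and every type is present in the final snapshot. After
#' all cells are placed, `tc` extra settling steps run with the population
#' in place. Each step re-derives the synthesis rate from the current TF
#' and ligand identity factors (inherited from the previous step) and
#' resamples expression; accessibility and the switching rates kon/koff
#' are fixed across steps (their TF/ligand weights are zero). A cell keeps
#' one diff-CIF throughout, drawn at its final tree position, so the
#' trajectory is preserved in the output snapshot. Only the final step is
#' emitted.
#'
#' @param config a [sim_config()] with `spatial = TRUE` and an `lr_db`.
#' @return an `msim_result` with the additional `spatial` element: grid
#'   state, neighbor lists, and the type- and cell-level CCI truths.
#' @export
run_spatial_simulation <- function(config) {
  cfg <- config
  stopifnot(inherits(cfg, "sim_config"), !is.null(cfg$lr_db))
  sd_ <- function(key) derive_seed(cfg$seed, key)
  tree <- cfg$tree
  ncell <- cfg$ncell
  lineages <- tree_lineages(tree)
  total_steps <- ncell + cfg$tc
  step_len <- max(tree$depth) / ncell

  with_stream(sd_("spatial.paths"), {
    path_of <- sample.int(length(lineages), ncell, replace = TRUE)
  })
  # final tree position of each cell (born at step i, advanced since)
  meta <- do.call(rbind, lapply(seq_len(ncell), function(i) {
    p <- position_on_path(tree, lineages[[path_of[i]]],
                          (total_steps - i) * step_len)
    data.frame(cell = i, lineage = path_of[i], type = p$type,
               pseudotime = p$pseudotime, edge_child = p$edge_child,
               offset = p$offset, stringsAsFactors = FALSE)
  }))

  # grid placement (affinity uses the snapshot types)
  state <- with_stream(sd_("spatial.place"), {
    if (cfg$layout %in% c("layers", "islands")) {
      prelayout(cfg$layout, meta$type, ncell, pn = cfg$pn,
                capacity_pct = cfg$grid_capacity)
    } else {
      st <- init_grid(ncell, cfg$grid_capacity)
      for (i in seq_len(ncell)) st <- place_cell(st, i, meta$type[i], cfg$pn)
      st
    }
  })
  nb_list <- lapply(seq_len(ncell), function(i)
    neighbors(state, i, radius = 1, nnbs = cfg$nnbs))
  nb_pairs <- do.call(rbind, lapply(seq_len(ncell), function(i)
    if (length(nb_list[[i]]))
      data.frame(from = nb_list[[i]], to = i) else NULL))

  type_truth <- sample_cci_truth(cfg$lr_db, meta$type,
                                 stream = sd_("cci.type"))
  implied <- implied_cci_edges(type_truth, nb_pairs, meta$type)
  cell_truth <- sample_cell_level_truth(implied, cfg$cci_fraction,
                                        stream = sd_("cci.cell"))

  # identity factors and weights
  ntf <- if (is.null(cfg$grn)) 0L else length(cfg$grn$tfs)
  nlig <- nrow(cfg$lr_db$pairs)
  nligseg <- nlig * cfg$nnbs
  mk_cif <- function(p) {
    nd <- sample_nondiff_cif(ncell, cfg$n_nd, cfg$sigma_cif,
                             stream = sd_(paste0("cif.nd.", p)))
    df <- sample_diff_cif(tree, ncell, cfg$n_diff, cfg$sigma_cif,
                          "continuous", stream = sd_(paste0("cif.diff.", p)),
                          meta = meta)$cif
    tf <- with_stream(sd_(paste0("cif.tf.", p)),
                      matrix(rnorm(ncell * ntf, 1, cfg$sigma_cif), ncell, ntf))
    lig <- with_stream(sd_(paste0("cif.lig.", p)),
                       matrix(rnorm(ncell * nligseg, 1, cfg$sigma_cif),
                              ncell, nligseg))
    assemble_cif(nd, df, tf, lig)
  }
  cif <- list(kon = mk_cif("kon"), koff = mk_cif("koff"), s = mk_cif("s"))
  lig_eff <- lig_effect_matrix(cfg$lr_db, cfg$ngene, cfg$nnbs)
  giv <- build_giv_set(cfg, lig_effect = lig_eff, stream = sd_("giv"))

  r2g <- generate_region_to_gene(cfg$ngene, cfg$region_dist,
                                 stream = sd_("region"))
  riv <- sample_riv(ncol(cif$kon), r2g$nregion, cfg$riv_p0, cfg$riv_mean,
                    cfg$riv_sd, stream = sd_("riv"))
  atac_ref <- default_atac_reference(p_zero = cfg$atac_p_zero,
                                     density = cfg$atac_density,
                                     stream = sd_("atacref"))
  atac <- simulate_atac(cif$kon, riv, atac_ref, stream = sd_("atac"))
  kref <- cfg$kinetic_ref %||% default_kinetic_reference()

  kon <- assemble_kon(cif$kon %*% giv$kon, atac, r2g$Z, cfg$ea, kref$kon,
                      stream = sd_("kin.kon")) / 10^cfg$bimod
  koff <- assemble_koff(cif$koff %*% giv$koff, cfg$bimod, kref$koff,
                        stream = sd_("kin.koff"))

  tf_idx <- cfg$n_nd + cfg$n_diff + seq_len(ntf)
  lig_idx <- cfg$n_nd + cfg$n_diff + ntf + seq_len(nligseg)
  expr <- matrix(0, ncell, cfg$ngene)
  s_now <- NULL
  # static per-(sender, receiver) active LR rows, for the step loop
  act_map <- split(cell_truth$lr_row, paste(cell_truth$from, cell_truth$to))
  lig_genes <- cfg$lr_db$pairs$ligand
  with_stream(sd_("spatial.loop"), {
    for (t in seq_len(total_steps)) {
      present <- seq_len(min(t, ncell))
      if (t > 1L) {
        n_prev <- min(t - 1L, ncell)
        for (i in present) {
          if (i > n_prev) next  # newborn keeps its Gaussian init
          if (ntf)
            cif$s[i, tf_idx] <- update_tf_cif(expr[i, ], cfg$grn$tfs)
          nb <- nb_list[[i]][nb_list[[i]] <= n_prev]
          seg <- numeric(nligseg)
          for (j in seq_along(nb)) {
            active <- act_map[[paste(nb[j], i)]]
            if (is.null(active)) next
            xl <- expr[nb[j], lig_genes]
            ml <- mean(xl)
            if (ml == 0) next
            vals <- xl / (xl + ml)
            vals[-active] <- 0
            seg[(j - 1L) * nlig + seq_len(nlig)] <- vals
          }
          cif$s[i, lig_idx] <- seg
        }
      }
      M3 <- cif$s[present, , drop = FALSE] %*% giv$s
      s_now <- assemble_s(M3, cfg$scale_s, kref$s)
      expr[present, ] <- beta_poisson_counts(kon[present, , drop = FALSE],
                                             koff[present, , drop = FALSE],
                                             s_now, cfg$sigma_i)
    }
  })

  params <- list(kon = kon, koff = koff, s = {
    s_full <- matrix(NA_real_, ncell, cfg$ngene); s_full[] <- s_now; s_full
  }, d = 1)
  res <- list(counts = expr, atac = atac, region_map = r2g$Z,
              motif_map = if (!is.null(cfg$grn))
                derive_motif_matrix(cfg$grn$effect_matrix, r2g$Z) else NULL,
              kinetics = params, meta = cbind(meta,
                state$cells[match(meta$cell, state$cells$cell),
                            c("row", "col")]),
              cif = cif, giv = giv, grn = cfg$grn, config = cfg,
              spatial = list(state = state, neighbors = nb_list,
                             type_truth = type_truth,
                             cell_truth = cell_truth, implied = implied))
  if (cfg$velocity)
    res <- c(res, simulate_velocity_chain(cfg, params, meta, sd_))
  class(res) <- "msim_result"
  res
}

#' Ligand-receptor correlation validation
#'
#' For a chosen ligand-receptor pair, every cell contributes its (up to 4)
#' neighbors and 4 randomly sampled non-adjacent control cells; the
#' (sender ligand, receiver receptor) expression pairs are grouped into
#' (i) neighbors with an active interaction, (ii) neighbors without one,
#' (iii) non-neighbors, and the Pearson correlation is computed per group.
#' Same-type cell pairs are ignored (they are similar regardless of
#' signaling). Correlations are computed separately per ligand-receptor
#' row — pooling rows would confound the estimate with between-gene mean
#' differences — and averaged over the requested rows.
#'
#' @param result an `msim_result` from [run_spatial_simulation()].
#' @param lr_rows LR database row ids to evaluate (default: all; the
#'   reported values average over them).
#' @param min_pairs rows contribute to a group's average only where they
#'   have at least this many expression pairs (default 10).
#' @param stream optional integer seed (controls the non-adjacent draw).
#' @return named numeric vector
#'   `(corr_cci_neighbors, corr_noncci_neighbors, corr_nonneighbors)` with
#'   attributes `per_row` (3 x rows matrix) and `n_pairs` (total pairs per
#'   group).
#' @export
cci_correlation_check <- function(result, lr_rows = NULL, min_pairs = 10,
                                  stream = NULL) {
  sp <- result$spatial
  if (is.null(sp)) stop("result contains no spatial data")
  lr <- result$config$lr_db$pairs
  lr_rows <- lr_rows %||% seq_len(nrow(lr))
  if (any(lr_rows < 1 | lr_rows > nrow(lr)))
    stop("lr_rows outside the ligand-receptor database")
  x <- result$counts
  types <- result$meta$type
  ncell <- nrow(x)
  truth_key <- paste(sp$cell_truth$from, sp$cell_truth$to,
                     sp$cell_truth$lr_row)
  with_stream(stream, {
    # 4 non-adjacent controls per cell, shared across rows
    mi_list <- lapply(seq_len(ncell), function(i) {
      non_adj <- setdiff(seq_len(ncell), c(i, sp$neighbors[[i]]))
      sample(non_adj, min(4L, length(non_adj)))
    })
    per_row <- vapply(lr_rows, function(l) {
      g <- list(cci = list(a = c(), b = c()),
                noncci = list(a = c(), b = c()),
                nonnb = list(a = c(), b = c()))
      for (i in seq_len(ncell)) {
        for (j in sp$neighbors[[i]]) {
          if (types[i] == types[j]) next
          grp <- if (paste(i, j, l) %in% truth_key) "cci" else "noncci"
          g[[grp]]$a <- c(g[[grp]]$a, x[i, lr$ligand[l]])
          g[[grp]]$b <- c(g[[grp]]$b, x[j, lr$receptor[l]])
        }
        for (j in mi_list[[i]]) {
          if (types[i] == types[j]) next
          g$nonnb$a <- c(g$nonnb$a, x[i, lr$ligand[l]])
          g$nonnb$b <- c(g$nonnb$b, x[j, lr$receptor[l]])
        }
      }
      corr <- function(p) if (length(p$a) >= min_pairs)
        suppressWarnings(cor(p$a, p$b)) else NA_real_
      c(corr(g$cci), corr(g$noncci), corr(g$nonnb),
        length(g$cci$a), length(g$noncci$a), length(g$nonnb$a))
    }, numeric(6))
    out <- c(corr_cci_neighbors = mean(per_row[1, ], na.rm = TRUE),
             corr_noncci_neighbors = mean(per_row[2, ], na.rm = TRUE),
             corr_nonneighbors = mean(per_row[3, ], na.rm = TRUE))
    attr(out, "per_row") <- per_row[1:3, , drop = FALSE]
    attr(out, "n_pairs") <- rowSums(per_row[4:6, , drop = FALSE])
    out
  })
}
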