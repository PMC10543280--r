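# Spatial grid, layouts and cell placement -------------------------------
#
# Cells live on a k x k grid, one per position. A newborn cell is placed
# with probability pn (cell-type affinity) next to a same-type cell;
# alternative "layers" and "islands" layouts pre-assign all positions.
# Neighborhoods are 4-adjacent at radius 1 (diagonals excluded).

#' Initialize an empty spatial grid
#'
#' @param ncell number of cells the grid must accommodate.
#' @param capacity_pct grid capacity as a percentage of `ncell`
#'   (default 250).
#' @return a `spatial_state`: list with side length `k`, occupancy matrix
#'   `occ` (0 = free) and a `cells` table (cell, row, col, type).
#' @export
init_grid <- function(ncell, capacity_pct = 250) {
  stopifnot(ncell >= 1)
  if (capacity_pct < 100) stop("grid capacity must be at least 100% of ncell")
  k <- ceiling(sqrt(capacity_pct / 100 * ncell))
  structure(list(k = k, occ = matrix(0L, k, k),
                 cells = data.frame(cell = integer(), row = integer(),
                                    col = integer(), type = character(),
                                    stringsAsFactors = FALSE)),
            class = "spatial_state")
}

grid_free <- function(state) which(state$occ == 0L, arr.ind = TRUE)

adjacent4 <- function(k, row, col) {
  cand <- rbind(c(row - 1L, col), c(row + 1L, col),
                c(row, col - 1L), c(row, col + 1L))
  cand[cand[, 1] >= 1 & cand[, 1] <= k & cand[, 2] >= 1 & cand[, 2] <= k, ,
       drop = FALSE]
}

#' Place one cell on the grid
#'
#' With probability `pn` the cell takes a uniformly chosen free position
#' 4-adjacent to an existing same-type cell (falling back to a uniform free
#' position if none exists); otherwise a uniform free position.
#'
#' @param state a `spatial_state`.
#' @param cell integer cell id.
#' @param cell_type type label of the new cell.
#' @param pn cell-type affinity in `[0, 1]`.
#' @param stream optional integer seed.
#' @return the updated `spatial_state`.
#' @export
place_cell <- function(state, cell, cell_type, pn, stream = NULL) {
  free <- grid_free(state)
  if (!nrow(free)) stop("grid is full")
  with_stream(stream, {
    pos <- NULL
    if (runif(1) < pn) {
      same <- state$cells[state$cells$type == cell_type, ]
      if (nrow(same)) {
        cand <- unique(do.call(rbind, lapply(seq_len(nrow(same)), function(i)
          adjacent4(state$k, same$row[i], same$col[i]))))
        cand <- cand[state$occ[cand] == 0L, , drop = FALSE]
        if (nrow(cand)) pos <- cand[sample.int(nrow(cand), 1L), ]
      }
    }
    if (is.null(pos)) pos <- free[sample.int(nrow(free), 1L), ]
    state$occ[pos[1], pos[2]] <- as.integer(cell)
    state$cells <- rbind(state$cells,
                         data.frame(cell = as.integer(cell), row = pos[1],
                                    col = pos[2], type = cell_type,
                                    stringsAsFactors = FALSE))
    state
  })
}

#' Pre-assign all cell locations for the layers/islands layouts
#'
#' `layers`: cells are sorted by type and laid down in row-major order, so
#' each type forms a contiguous band. `islands`: the designated island
#' types are grown as contiguous 4-connected blobs (new cells placed next
#' to an existing blob cell), non-overlapping; remaining types are placed
#' with affinity `pn`. Finally `randomize_frac` of all cells are moved to
#' random free positions to add noise.
#'
#' @param layout `"layers"` or `"islands"`.
#' @param cell_types character vector of per-cell types (cell order = id).
#' @param ncell number of cells.
#' @param island_types types forming islands (default: first unique type).
#' @param pn affinity for the non-island cells.
#' @param randomize_frac fraction of cells relocated at the end
#'   (default 0.05).
#' @param capacity_pct grid capacity percentage.
#' @param stream optional integer seed.
#' @return a filled `spatial_state`.
#' @export
prelayout <- function(layout = c("layers", "islands"), cell_types,
                      ncell = length(cell_types), island_types = NULL,
                      pn = 0.8, randomize_frac = 0.05,
                      capacity_pct = 250, stream = NULL) {
  layout <- match.arg(layout)
  state <- init_grid(ncell, capacity_pct)
  with_stream(stream, {
    if (layout == "layers") {
      ord <- order(cell_types)
      free_seq <- which(matrix(TRUE, state$k, state$k), arr.ind = TRUE)
      free_seq <- free_seq[order(free_seq[, 1], free_seq[, 2]), ]
      for (i in seq_along(ord)) {
        cell <- ord[i]
        state$occ[free_seq[i, 1], free_seq[i, 2]] <- as.integer(cell)
        state$cells <- rbind(state$cells,
                             data.frame(cell = cell, row = free_seq[i, 1],
                                        col = free_seq[i, 2],
                                        type = cell_types[cell],
                                        stringsAsFactors = FALSE))
      }
    } else {
      island_types <- island_types %||% unique(cell_types)[1]
      if (sum(cell_types %in% island_types) > state$k^2)
        stop("island types exceed grid capacity")
      for (ty in island_types) {
        members <- which(cell_types == ty)
        if (!length(members)) next
        blob <- NULL
        free <- grid_free(state)
        start <- free[sample.int(nrow(free), 1L), ]
        for (cell in members) {
          if (is.null(blob)) {
            pos <- start
          } else {
            cand <- unique(do.call(rbind, lapply(seq_len(nrow(blob)),
              function(i) adjacent4(state$k, blob[i, 1], blob[i, 2]))))
            cand <- cand[state$occ[cand] == 0L, , drop = FALSE]
            if (!nrow(cand)) stop("island growth blocked: grid too tight")
            pos <- cand[sample.int(nrow(cand), 1L), ]
          }
          state$occ[pos[1], pos[2]] <- as.integer(cell)
          state$cells <- rbind(state$cells,
                               data.frame(cell = cell, row = pos[1],
                                          col = pos[2], type = ty,
                                          stringsAsFactors = FALSE))
          blob <- rbind(blob, pos)
        }
      }
      for (cell in which(!(cell_types %in% island_types)))
        state <- place_cell(state, cell, cell_types[cell], pn)
    }
    if (randomize_frac > 0) {
      nmove <- round(randomize_frac * ncell)
      if (nmove > 0) {
        movers <- sample.int(ncell, nmove)
        for (cell in movers) {
          idx <- which(state$cells$cell == cell)
          state$occ[state$cells$row[idx], state$cells$col[idx]] <- 0L
          free <- grid_free(state)
          pos <- free[sample.int(nrow(free), 1L), ]
          state$occ[pos[1], pos[2]] <- as.integer(cell)
          state$cells$row[idx] <- pos[1]
          state$cells$col[idx] <- pos[2]
        }
      }
    }
    state$cells <- state$cells[order(state$cells$cell), ]
    rownames(state$cells) <- NULL
    state
  })
}

#' Interacting neighbors of a placed cell
#'
#' The up-to-`nnbs` nearest occupied positions within `radius` (Euclidean),
#' 4-adjacency at radius 1 (a diagonal cell at distance sqrt(2) is not a
#' neighbor). Ordering is deterministic: the four cardinal slots
#' (up, down, left, right) first, then remaining positions by distance.
#'
#' @param state a `spatial_state`.
#' @param cell cell id (must be placed).
#' @param radius neighborhood radius (default 1).
#' @param nnbs maximum number of neighbors (default 4).
#' @return integer vector of neighbor cell ids (possibly empty).
#' @export
neighbors <- function(state, cell, radius = 1, nnbs = 4) {
  idx <- which(state$cells$cell == cell)
  if (!length(idx)) stop("cell ", cell, " is not placed")
  r0 <- state$cells$row[idx]; c0 <- state$cells$col[idx]
  rr <- max(1L, ceiling(radius))
  rows <- max(1L, r0 - rr):min(state$k, r0 + rr)
  cols <- max(1L, c0 - rr):min(state$k, c0 + rr)
  cand <- expand.grid(row = rows, col = cols)
  cand$d <- sqrt((cand$row - r0)^2 + (cand$col - c0)^2)
  cand <- cand[cand$d > 0 & cand$d <= radius + 1e-9, ]
  occ <- state$occ[cbind(cand$row, cand$col)]
  cand <- cand[occ != 0L, ]
  if (!nrow(cand)) return(integer(0))
  dr <- cand$row - r0; dc <- cand$col - c0
  prio <- rep(5L, nrow(cand))
  prio[dr == -1 & dc == 0] <- 1L  # up
  prio[dr == 1 & dc == 0] <- 2L   # down
  prio[dr == 0 & dc == -1] <- 3L  # left
  prio[dr == 0 & dc == 1] <- 4L   # right
  ord <- order(prio, cand$d, dr, dc)
  ids <- state$occ[cbind(cand$row, cand$col)][ord]
  head(ids, nnbs)
}
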