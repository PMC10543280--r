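test_that("grid sizing follows the capacity rule", {
  expect_equal(init_grid(1000)$k, 50L)   # 250% of 1000 -> 2500 -> 50x50
  expect_equal(init_grid(1)$k, 2L)
  expect_error(init_grid(10, 50), "at least 100")
})

test_that("placement respects affinity and fills the grid", {
  st <- init_grid(4, 100)  # 2x2, exactly 4 slots
  st <- place_cell(st, 1, "A", pn = 1, stream = 1)
  # pn = 1 with one same-type cell present: always adjacent
  for (rep in 1:10) {
    st2 <- place_cell(st, 2, "A", pn = 1, stream = rep)
    p1 <- st2$cells[1, c("row", "col")]
    p2 <- st2$cells[2, c("row", "col")]
    expect_equal(abs(p1$row - p2$row) + abs(p1$col - p2$col), 1)
  }
  # empty grid: uniform placement, no error
  expect_s3_class(place_cell(init_grid(5), 1, "B", pn = 1, stream = 2),
                  "spatial_state")
  # full grid errors
  for (i in 2:4) st <- place_cell(st, i, "A", pn = 0.5, stream = i)
  expect_error(place_cell(st, 5, "A", 0.5), "full")
})

test_that("higher affinity yields more same-type adjacency", {
  frac_same <- function(pn, seed) {
    types <- rep(c("A", "B", "C"), length.out = 240)
    st <- with_stream(seed, {
      s <- init_grid(240)
      for (i in 1:240) s <- place_cell(s, i, types[i], pn)
      s
    })
    hits <- 0; tot <- 0
    for (i in 1:240) {
      nb <- neighbors(st, i)
      tot <- tot + length(nb)
      hits <- hits + sum(types[nb] == types[i])
    }
    hits / tot
  }
  f1 <- mean(vapply(1:5, function(s) frac_same(1, s), 0))
  f8 <- mean(vapply(1:5, function(s) frac_same(0.8, s), 0))
  expect_gt(f1, f8)
})

test_that("neighborhoods are 4-adjacent, bounded and symmetric", {
  st <- init_grid(9, 100)  # 3x3
  # fill all 9 positions deterministically
  k <- st$k
  cellid <- 0
  for (r in 1:3) for (c in 1:3) {
    cellid <- cellid + 1
    st$occ[r, c] <- cellid
    st$cells <- rbind(st$cells, data.frame(cell = cellid, row = r, col = c,
                                           type = "A"))
  }
  center <- st$occ[2, 2]
  nb <- neighbors(st, center)
  expect_length(nb, 4L)
  expect_setequal(nb, c(st$occ[1, 2], st$occ[3, 2], st$occ[2, 1], st$occ[2, 3]))

  # diagonal-only neighbor at radius 1 is excluded
  st2 <- init_grid(4, 100)
  st2$occ[1, 1] <- 1L; st2$occ[2, 2] <- 2L
  st2$cells <- data.frame(cell = 1:2, row = c(1, 2), col = c(1, 2),
                          type = c("A", "B"))
  expect_length(neighbors(st2, 1), 0L)

  # isolated cell
  st3 <- place_cell(init_grid(10), 1, "A", 0.5, stream = 3)
  expect_length(neighbors(st3, 1), 0L)

  # symmetry over a random occupancy
  st4 <- with_stream(4, {
    s <- init_grid(40)
    for (i in 1:40) s <- place_cell(s, i, sample(c("A", "B"), 1), 0.7)
    s
  })
  for (i in 1:40) for (j in neighbors(st4, i))
    expect_true(i %in% neighbors(st4, j))
})

test_that("pre-assigned layouts produce bands and connected islands", {
  types <- rep(c("A", "B", "C"), each = 30)
  st <- prelayout("layers", types, randomize_frac = 0, stream = 5)
  # row-major order of sorted types: the first rows hold only A, last only C
  first_rows <- st$cells$row[st$cells$type == "A"]
  last_rows <- st$cells$row[st$cells$type == "C"]
  expect_lte(max(first_rows), min(last_rows) + 1)

  sti <- prelayout("islands", types, island_types = "B",
                   randomize_frac = 0, stream = 6)
  isl <- sti$cells[sti$cells$type == "B", ]
  # island forms one 4-connected component
  g <- igraph::graph_from_edgelist(do.call(rbind, lapply(
    seq_len(nrow(isl)), function(i) {
      adj <- which(abs(isl$row - isl$row[i]) + abs(isl$col - isl$col[i]) == 1)
      if (length(adj)) cbind(i, adj) else NULL
    })), directed = FALSE)
  expect_equal(igraph::components(g)$no, 1L)

  # zero randomization is deterministic given the stream
  st2 <- prelayout("layers", types, randomize_frac = 0, stream = 5)
  expect_identical(st$cells, st2$cells)

  # occupancy stays injective
  expect_false(anyDuplicated(st$cells[, c("row", "col")]) > 0)
})
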