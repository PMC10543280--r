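test_that("type-level interaction truth samples the database per type pair", {
  lr <- tiny_lr()
  tt <- sample_cci_truth(lr, c("A", "B", "C"), pairs_range = c(2, 2),
                         stream = 1)
  # every distinct type pair uses all rows when the range forces m
  expect_equal(nrow(tt), 3L * 2L)  # C(3,2) pairs x 2 rows
  expect_true(all(tt$type_a != tt$type_b))

  tt5 <- sample_cci_truth(lr, paste0("t", 1:5), pairs_range = c(1, 2),
                          stream = 2)
  expect_equal(length(unique(paste(tt5$type_a, tt5$type_b))), 10L)  # C(5,2)
  expect_error(sample_cci_truth(lr, c("A", "B"), pairs_range = c(1, 9)),
               "within")
})

test_that("per-pair row counts are uniform on the requested range", {
  lr <- load_lr_db(data.frame(ligand = 1:6, receptor = 7:12,
                              effect = 1), 12)
  counts <- with_stream(3, {
    vapply(1:2000, function(i) {
      tt <- sample_cci_truth(lr, c("A", "B"), pairs_range = c(3, 6))
      nrow(tt)
    }, 0)
  })
  expect_lt(abs(mean(counts) - 4.5), 0.1)
})

test_that("single-cell truth is an exact-fraction subsample", {
  implied <- data.frame(from = rep(1:10, each = 10), to = rep(1:10, 10),
                        lr_row = 1L)
  expect_equal(nrow(sample_cell_level_truth(implied, 1)), 100L)
  expect_equal(nrow(sample_cell_level_truth(implied, 0)), 0L)
  s8 <- sample_cell_level_truth(implied, 0.8, stream = 4)
  expect_equal(nrow(s8), 80L)
  # subset property
  expect_true(all(paste(s8$from, s8$to, s8$lr_row) %in%
                    paste(implied$from, implied$to, implied$lr_row)))
})

test_that("ligand factors normalize, mask and vanish without neighbors", {
  lr <- tiny_lr()
  expr <- matrix(0, 3, 12)
  expect_equal(build_lig_cif(1, integer(0), expr, lr,
                             data.frame(from = integer(), to = integer(),
                                        lr_row = integer())),
               rep(0, 8))
  # one neighbor whose ligand expression equals the ligand mean -> 0.5
  expr[2, 11] <- 4; expr[2, 12] <- 4
  truth <- data.frame(from = 2L, to = 1L, lr_row = 1L)
  seg <- build_lig_cif(1, 2L, expr, lr, truth, nnbs = 4)
  expect_equal(seg[1], 0.5)
  expect_equal(seg[2], 0)  # row 2 masked out despite expression
  expect_equal(sum(seg != 0), 1L)
})

test_that("a small spatial run satisfies its structural contracts", {
  lr <- tiny_lr(40)
  cfg <- sim_config(ncell = 70, ngene = 40, tree = "Phyla3",
                    mode = "continuous", grn = tiny_grn(40), lr_db = lr,
                    spatial = TRUE, tc = 5, seed = 5)
  res <- sim_true_counts(cfg)
  expect_s3_class(res, "msim_result")
  st <- res$spatial$state
  # occupancy injective, within bounds
  expect_false(anyDuplicated(st$cells[, c("row", "col")]) > 0)
  expect_true(all(st$cells$row >= 1 & st$cells$row <= st$k))
  # neighbor relation symmetric
  for (i in seq_len(70)) for (j in res$spatial$neighbors[[i]])
    expect_true(i %in% res$spatial$neighbors[[j]])
  # single-cell truth is the exact published fraction of implied edges
  expect_equal(nrow(res$spatial$cell_truth),
               round(0.8 * nrow(res$spatial$implied)))
  # cells born at different steps cover multiple developmental stages
  expect_gt(length(unique(res$meta$type)), 1L)
  expect_true(all(res$counts >= 0))
})

test_that("shuffled expression shows no ligand-receptor correlation", {
  lr <- tiny_lr(40)
  cfg <- sim_config(ncell = 80, ngene = 40, tree = "Phyla3",
                    mode = "continuous", grn = tiny_grn(40), lr_db = lr,
                    spatial = TRUE, tc = 5, seed = 6)
  res <- sim_true_counts(cfg)
  shuf <- res
  set.seed(7)
  shuf$counts <- res$counts[sample(nrow(res$counts)), ]
  cc <- cci_correlation_check(shuf, stream = 8)
  # all three groups are near zero once cells are shuffled (at this toy
  # size the estimates carry sampling noise, hence the loose band)
  expect_true(all(abs(cc) < 0.3, na.rm = TRUE))
  expect_error(cci_correlation_check(res, lr_rows = 99), "database")
})

test_that("degenerate single-cell run emits one cell without interactions", {
  lr <- tiny_lr(30)
  cfg <- sim_config(ncell = 1, ngene = 30, tree = "Phyla1",
                    mode = "continuous", lr_db = lr, spatial = TRUE,
                    tc = 0, seed = 9)
  res <- sim_true_counts(cfg)
  expect_equal(nrow(res$counts), 1L)
  expect_equal(nrow(res$spatial$cell_truth), 0L)
})
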