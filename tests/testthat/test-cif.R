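test_that("non-diff factors are unit-mean Gaussian with the requested sd", {
  m <- sample_nondiff_cif(10, 4, 0, stream = 1)
  expect_true(all(m == 1))
  m2 <- sample_nondiff_cif(1000, 100, 0.5, stream = 2)
  expect_lt(abs(sd(m2) - 0.5) / 0.5, 0.01)
  expect_lt(abs(mean(m2) - 1), 0.01)
  m3 <- sample_nondiff_cif(5, 0, 0.1)
  expect_equal(dim(m3), c(5L, 0L))
  expect_error(sample_nondiff_cif(5, 2, -0.1), "nonnegative")
})

test_that("cell placement is balanced (discrete) and lineage-proportional", {
  tr <- builtin_tree("Phyla5")
  meta <- place_cells(tr, 500, "discrete")
  expect_equal(as.vector(table(meta$type)), rep(100L, 5))
  metac <- place_cells(tr, 300, "continuous", stream = 3)
  expect_true(all(metac$pseudotime >= 0))
  expect_true(all(metac$pseudotime <= max(tr$depth) + 1e-9))
  expect_equal(nrow(metac), 300L)
})

test_that("diff factors follow Brownian variance additivity along the tree", {
  tr <- builtin_tree("Phyla1")
  meta <- place_cells(tr, 8, "continuous", stream = 4)
  # dimensions are i.i.d. walks: variance across many dims at path
  # distance D approximates D (the walk scale is the tree distance)
  res <- sample_diff_cif(tr, 8, 4000, sigma_cif = 0.5, "continuous",
                         stream = 5, meta = meta)
  v <- apply(res$cif, 1, var)
  expected <- meta$pseudotime
  expect_lt(max(abs(v - expected) / pmax(expected, 0.05)), 0.15)
})

test_that("cells at the same tree position share their diff factors", {
  tr <- builtin_tree("Phyla3")
  # two pairs of cells at identical positions on the same edges
  meta <- data.frame(cell = 1:4, lineage = c(1, 1, 2, 2),
                     type = c("A", "A", "C", "C"),
                     pseudotime = c(1.5, 1.5, 0.7, 0.7),
                     edge_child = c("A", "A", "C", "C"),
                     offset = c(0.5, 0.5, 0.7, 0.7),
                     stringsAsFactors = FALSE)
  res <- sample_diff_cif(tr, 4, 5, sigma_cif = 0.1, "continuous",
                         stream = 7, meta = meta)
  expect_equal(res$cif[1, ], res$cif[2, ])
  expect_equal(res$cif[3, ], res$cif[4, ])
  expect_false(all(res$cif[1, ] == res$cif[3, ]))
})

test_that("discrete diff factors separate types at fixed centers", {
  tr <- builtin_tree("Phyla5")
  res <- sample_diff_cif(tr, 250, 8, sigma_cif = 0.1, "discrete", stream = 8)
  cents <- aggregate(res$cif, list(type = res$meta$type), mean)
  spread <- mean(apply(res$cif - as.matrix(
    cents[match(res$meta$type, cents$type), -1]), 2, sd))
  expect_lt(spread, 0.15)   # within-type spread tracks sigma_cif
  d <- dist(as.matrix(cents[, -1]))
  expect_gt(min(d), 0.5)    # between-type separation set by the tree
})

test_that("TF factor normalization matches its closed form", {
  expect_equal(update_tf_cif(rep(3, 6), 1:6), rep(0.5, 6))
  x <- c(2, rep(0, 4))
  expect_equal(update_tf_cif(x, 1:5)[1], 5 / 6)  # n/(n+1) with n TFs
  expect_equal(update_tf_cif(rep(0, 4), 1:4), rep(0, 4))
  # output is always in [0, 1)
  for (s in 1:20) {
    set.seed(s)
    out <- update_tf_cif(rpois(10, 5), 1:10)
    expect_true(all(out >= 0 & out < 1))
  }
})

test_that("segment assembly concatenates consistently and multiplies", {
  cif <- assemble_cif(matrix(1, 3, 2), matrix(2, 3, 2))
  expect_equal(ncol(cif), 4L)
  expect_equal(unname(attr(cif, "segments")), c(2L, 2L, 0L, 0L))
  giv <- assemble_giv(matrix(1, 2, 5), matrix(0.5, 2, 5))
  expect_equal(dim(cif %*% giv), c(3L, 5L))
  expect_error(assemble_cif(matrix(1, 3, 2), matrix(2, 4, 2)), "disagree")

  set.seed(9)
  a <- matrix(rnorm(12), 3, 4); b <- matrix(rnorm(8), 4, 2)
  brute <- matrix(0, 3, 2)
  for (i in 1:3) for (j in 1:2) brute[i, j] <- sum(a[i, ] * b[, j])
  expect_equal(a %*% b, brute)
})
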