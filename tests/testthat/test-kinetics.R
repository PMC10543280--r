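test_that("rank scaling preserves order and matches the reference", {
  ref <- default_kinetic_reference()$kon
  x <- sort(rnorm(50))
  out <- rank_scale(x, ref, stream = 1)
  expect_equal(out, sort(out))               # sorted input -> sorted draw

  set.seed(2)
  x2 <- rnorm(2000)
  out2 <- rank_scale(x2, ref, stream = 3)
  # rank order preserved exactly: output is nondecreasing along the input
  # order (reference draws may tie, so Spearman is only ~1)
  expect_false(is.unsorted(out2[order(x2)]))
  expect_gt(cor(x2, out2, method = "spearman"), 0.99999)

  big <- rank_scale(rnorm(1e5), ref, stream = 4)
  ks <- suppressWarnings(stats::ks.test(big, ref)$statistic)
  expect_lt(unname(ks), 0.02)
  expect_length(rank_scale(numeric(0), ref), 0L)
  expect_error(rank_scale(1:3, numeric(0)), "empty")
})

test_that("rank scaling is idempotent in distribution and monotone-invariant", {
  ref <- default_kinetic_reference()$s
  set.seed(5)
  x <- matrix(rnorm(4000), 80, 50)
  once <- rank_scale(x, ref, stream = 6)
  twice <- rank_scale(once, ref, stream = 7)
  ks <- suppressWarnings(stats::ks.test(as.vector(once),
                                        as.vector(twice))$statistic)
  expect_lt(unname(ks), 0.03)

  # invariance to strictly monotone transforms, against a brute-force
  # sort-and-place oracle
  small <- matrix(rexp(30), 5, 6)
  a <- rank_scale(small, ref, stream = 8)
  b <- rank_scale(log(small), ref, stream = 8)
  expect_equal(a, b)
  draws <- with_stream(8, sort(sample(ref, 30, replace = TRUE)))
  oracle <- small
  oracle[order(small)] <- draws
  expect_equal(a, oracle)
})

test_that("accessibility gates kon and falls back to the raw surface", {
  ref <- default_kinetic_reference()
  set.seed(9)
  M1 <- matrix(rnorm(600), 30, 20)
  r2g <- generate_region_to_gene(20, c(1, 0, 0), stream = 10)
  zero_atac <- matrix(0, 30, r2g$nregion)
  kon <- assemble_kon(M1, zero_atac, r2g$Z, ea = 0.5, ref$kon, stream = 11)
  # with no accessible regions, ordering is fully driven by the raw surface
  expect_false(is.unsorted(as.vector(kon)[order(M1)]))
  expect_true(all(kon > 0))
  expect_equal(dim(kon), dim(M1))
})

test_that("the bimodality divisor raises downstream zero counts", {
  ref <- default_kinetic_reference()
  set.seed(12)
  M <- matrix(rnorm(6000), 100, 60)
  kon <- rank_scale(M, ref$kon, stream = 13)
  koff <- assemble_koff(M + rnorm(6000, 0, 0.3), 0, ref$koff, stream = 14)
  s <- assemble_s(M + rnorm(6000, 0, 0.3), 1, ref$s, stream = 15)
  x0 <- beta_poisson_counts(kon, koff, s, 1, stream = 16)
  x1 <- beta_poisson_counts(kon / 10, koff / 10, s, 1, stream = 16)
  expect_gt(mean(x1 == 0), mean(x0 == 0))
  expect_true(all(assemble_koff(M, 2, ref$koff, stream = 17) > 0))
})

test_that("the synthesis scale acts linearly on expected library size", {
  ref <- default_kinetic_reference()
  set.seed(18)
  M <- matrix(rnorm(5000), 100, 50)
  kon <- rank_scale(M, ref$kon, stream = 19)
  koff <- rank_scale(M + rnorm(5000, 0, 0.3), ref$koff, stream = 20)
  s1 <- assemble_s(M, 1, ref$s, stream = 21)
  s2 <- assemble_s(M, 2, ref$s, stream = 21)
  expect_equal(s2, 2 * s1)
  x1 <- beta_poisson_counts(kon, koff, s1, 1, stream = 22)
  x2 <- beta_poisson_counts(kon, koff, s2, 1, stream = 23)
  expect_lt(abs(sum(x2) / sum(x1) - 2), 0.05)
})

test_that("reference samples load from single-column text files", {
  f <- tempfile()
  writeLines(format(c(0.5, 1.2, 3.4)), f)
  expect_equal(read_reference_file(f), c(0.5, 1.2, 3.4))
  writeLines(c("1.0", "-2"), f)
  expect_error(read_reference_file(f), "positive")
  unlink(f)
})
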