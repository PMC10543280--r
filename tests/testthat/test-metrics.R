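test_that("pseudotime R-squared is the squared correlation", {
  t <- 1:20
  expect_equal(r_squared(t, t), 1)
  expect_equal(r_squared(t, 3 * t - 7), 1)
  set.seed(1)
  expect_lt(r_squared(rnorm(1e4), rnorm(1e4)), 0.01)
  expect_error(r_squared(rep(1, 5), 1:5), "constant")
})

test_that("kNN purity matches identical, reversed and random orderings", {
  t <- seq(0, 1, length.out = 10)
  expect_equal(knn_purity(t, t, k = 3), rep(1, 10))
  # reversed line: neighborhoods coincide; endpoints score 1
  kp <- knn_purity(t, rev(t), k = 3)
  expect_equal(kp[1], 1)
  expect_equal(kp[10], 1)
  expect_true(all(kp > 0))
  # random ordering: mean ~ k/n (hypergeometric overlap)
  set.seed(2)
  n <- 600; k <- 50
  kp2 <- knn_purity(runif(n), runif(n), k = k)
  jexp <- (k / n * k) / (2 * k - k / n * k)  # E|A&B| / E|A|B|
  expect_lt(abs(mean(kp2) - jexp) / jexp, 0.25)
})

test_that("graph connectivity counts largest components per type", {
  g <- igraph::make_full_graph(10)
  expect_equal(graph_connectivity(g, rep("A", 10)), 1)
  # one type split into two equal components contributes 0.5
  g2 <- igraph::make_graph(edges = c(1, 2, 3, 4), n = 4, directed = FALSE)
  expect_equal(graph_connectivity(g2, rep("A", 4)), 0.5)
  # brute-force check on a random small graph
  set.seed(3)
  g3 <- igraph::sample_gnp(12, 0.15)
  ty <- sample(c("A", "B"), 12, replace = TRUE)
  got <- graph_connectivity(g3, ty)
  brute <- mean(vapply(unique(ty), function(t) {
    idx <- which(ty == t)
    sub <- igraph::induced_subgraph(g3, idx)
    max(igraph::components(sub)$csize) / length(idx)
  }, 0))
  expect_equal(got, brute)
})

test_that("batch silhouette score spans its mixing limits", {
  set.seed(4)
  mixed <- matrix(rnorm(200), 100, 2)
  b <- rep(1:2, 50)
  ty <- rep("A", 100)
  expect_gt(batch_asw(mixed, b, ty), 0.7)
  sep <- mixed
  sep[b == 2, ] <- sep[b == 2, ] + 50
  expect_lt(batch_asw(sep, b, ty), 0.1)
  expect_error(batch_asw(mixed, rep(1, 100), ty), "single batch")
  # equality with a hand-rolled silhouette on a tiny instance
  emb <- matrix(c(0, 0, 0, 1, 5, 0, 5, 1), 4, 2, byrow = TRUE)
  bl <- c(1, 2, 1, 2)
  tyl <- rep("A", 4)
  sil_hand <- vapply(1:4, function(i) {
    d <- as.matrix(dist(emb))
    a <- mean(d[i, setdiff(which(bl == bl[i]), i)])
    bb <- mean(d[i, which(bl != bl[i])])
    (bb - a) / max(a, bb)
  }, 0)
  expect_equal(batch_asw(emb, bl, tyl), mean(1 - abs(sil_hand)))
})

test_that("velocity cosine similarity is scale-invariant and signed", {
  set.seed(5)
  v <- matrix(rnorm(50), 10, 5)
  expect_equal(as.numeric(velocity_cosine(v, v)), 1)
  expect_equal(as.numeric(velocity_cosine(v, -v)), -1)
  expect_equal(as.numeric(velocity_cosine(v, 2 * v)), 1)
  vz <- v; vz[1, ] <- 0
  expect_equal(attr(velocity_cosine(vz, v), "n_skipped"), 1L)
})

test_that("classifier areas match a brute-force threshold sweep", {
  y <- c(1, 0, 1, 0)
  s <- c(0.9, 0.8, 0.4, 0.1)
  got <- auprc_auroc(y, s)
  # brute force over all thresholds
  ths <- sort(unique(s), decreasing = TRUE)
  pts <- t(vapply(ths, function(th) {
    pred <- s >= th
    c(rec = sum(pred & y == 1) / sum(y == 1),
      prec = sum(pred & y == 1) / sum(pred),
      fpr = sum(pred & y == 0) / sum(y == 0))
  }, c(0, 0, 0)))
  auprc_bf <- sum(diff(c(0, pts[, "rec"])) * pts[, "prec"])
  expect_equal(got$auprc, auprc_bf)
  # 3 of the 4 positive-negative pairs are ranked correctly
  expect_equal(got$auroc, 0.75)
  expect_equal(got$auprc_ratio, got$auprc / 0.5)

  # random scorer: ratio ~ 1; perfect ranking: auroc = 1
  set.seed(6)
  yy <- rbinom(5000, 1, 0.2)
  ss <- runif(5000)
  expect_lt(abs(auprc_auroc(yy, ss)$auprc_ratio - 1), 0.1)
  expect_equal(auprc_auroc(yy, yy + 0)$auroc, 1)
  expect_error(auprc_auroc(rep(1, 4), 1:4), "single class")
})

test_that("Bonferroni adjustment matches its definition", {
  expect_equal(bonferroni(0.03), 0.03)
  expect_equal(bonferroni(c(0.01, 0.5)), c(0.02, 1))
  expect_equal(bonferroni(rep(1, 3)), rep(1, 3))
  expect_error(bonferroni(c(0.1, 1.2)), "0, 1")
})

test_that("summary statistics match direct recomputation", {
  z <- matrix(0, 3, 3)
  st <- summary_stats(z)
  expect_equal(st$zero_prop_per_gene, rep(1, 3))
  expect_equal(st$mean_per_gene, rep(0, 3))

  m <- matrix(c(1, 0, 0, 1), 2, 2)
  st2 <- summary_stats(m)
  expect_equal(st2$lib_size_per_cell, c(1, 1))
  expect_equal(st2$zero_prop_per_gene, c(0.5, 0.5))

  set.seed(7)
  r <- matrix(rpois(60, 3), 6, 10)
  st3 <- summary_stats(r)
  expect_equal(st3$var_per_gene, apply(r, 2, var))
  expect_equal(st3$lib_size_per_cell, rowSums(r))
  sta <- summary_stats(r, "atac")
  expect_equal(sta$peak_mean, colMeans(r))
})
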