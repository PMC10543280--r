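test_that("Beta-Poisson sampling matches its closed-form mean", {
  # sigma_i = 0 returns the theoretical mean exactly
  expect_equal(beta_poisson_counts(2, 3, 10, 0), 2 / 5 * 10)

  # Monte-Carlo mean over a parameter grid, 1e5 draws each
  grid <- expand.grid(kon = c(0.3, 1, 5), koff = c(0.5, 2), s = c(10, 50))
  for (r in seq_len(nrow(grid))) {
    p <- grid[r, ]
    n <- 1e5
    x <- beta_poisson_counts(rep(p$kon, n), rep(p$koff, n), rep(p$s, n),
                             1, stream = 100 + r)
    mu <- p$s * p$kon / (p$kon + p$koff)
    expect_lt(abs(mean(x) - mu) / mu, 0.01)
  }

  # Beta concentration limit: kon >> koff behaves like Poisson(s)
  x <- beta_poisson_counts(rep(100, 1e5), rep(0.01, 1e5), rep(20, 1e5),
                           1, stream = 200)
  expect_lt(abs(var(x) / mean(x) - 1), 0.05)
  expect_error(beta_poisson_counts(-1, 1, 1, 1), "positive")
})

test_that("intrinsic-noise weight tunes output variance monotonically", {
  n <- 2e4
  vars <- vapply(c(0.2, 0.5, 1), function(si)
    var(beta_poisson_counts(rep(1, n), rep(1, n), rep(10, n), si,
                            stream = 300)), 0)
  expect_true(all(diff(vars) > 0))
})

test_that("the steady-state initial condition has exactly zero velocity", {
  init <- kinetic_init(1, 1, 10, 1, 1)
  expect_equal(init$xs, 5)
  expect_equal(init$xu, 5)
  set.seed(31)
  kon <- matrix(rexp(40) + 0.1, 8, 5)
  koff <- matrix(rexp(40) + 0.1, 8, 5)
  s <- matrix(rexp(40) + 1, 8, 5)
  beta <- runif(5, 0.5, 1.5); d <- runif(5, 0.5, 1.5)
  init2 <- kinetic_init(kon, koff, s, beta, d)
  v <- rna_velocity(init2$xu, init2$xs, beta, d)
  expect_equal(max(abs(v)), 0)
  # koff -> Inf limit empties the promoter
  init3 <- kinetic_init(1, 1e9, 10, 1, 1)
  expect_lt(init3$xs, 1e-6)
})

test_that("kinetic stepping has the documented step structure and limits", {
  # kon = koff = 1: L = 2, two steps of size 1
  res <- simulate_kinetic(5, 5, 1, 1, 10, 1, 1, state0 = TRUE, stream = 32)
  expect_length(res$xs, 1L)

  # promoter pinned on: xu converges to s / beta
  n <- 200
  out <- simulate_kinetic(rep(0, n), rep(0, n), rep(50, n), rep(1e-9, n),
                          rep(20, n), rep(2, n), rep(1, n),
                          state0 = rep(TRUE, n), stream = 33)
  expect_lt(max(abs(out$xu - 20 / 2)), 0.5)

  # null dynamics: beta = d = 0 with promoter pinned off
  out0 <- simulate_kinetic(3, 4, 1, 1e9, 10, 0, 0,
                           state0 = FALSE, stream = 34)
  expect_equal(out0$xs, 3)
  expect_equal(out0$xu, 4)
})

test_that("velocity equals its elementwise definition", {
  expect_equal(rna_velocity(2, 1, 1, 1), 1)
  set.seed(35)
  xu <- matrix(rpois(30, 5), 6, 5); xs <- matrix(rpois(30, 5), 6, 5)
  beta <- runif(5); d <- runif(5)
  brute <- matrix(0, 6, 5)
  for (i in 1:6) for (j in 1:5)
    brute[i, j] <- beta[j] * xu[i, j] - d[j] * xs[i, j]
  expect_equal(rna_velocity(xu, xs, beta, d), brute)
  xs2 <- matrix(runif(30), 6, 5)
  expect_equal(max(abs(rna_velocity(xs2 * 2, xs2, 1, 2))), 0)
})

test_that("kNN smoothing preserves direction and normalizes", {
  v <- matrix(c(3, 4), 1, 2)
  emb <- matrix(0, 1, 2)
  out <- knn_smooth_velocity(rbind(v, v), rbind(emb, emb + 1), k = 1)
  expect_equal(sqrt(rowSums(out^2)), c(1, 1))
  expect_equal(out[1, ], c(3, 4) / 5)

  # identical velocities: smoothing is identity up to normalization
  v2 <- matrix(rep(c(1, 2, 2), each = 20), 20, 3)
  emb2 <- matrix(rnorm(40), 20, 2)
  out2 <- knn_smooth_velocity(v2, emb2, k = 5)
  expect_equal(out2, v2 / 3, tolerance = 1e-12)

  # default k follows the ncell/50 rule
  expect_equal(formals(knn_smooth_velocity)$k,
               quote(max(1L, round(nrow(v) / 50))))
})

test_that("velocity points along the trajectory on a linear tree", {
  cfg <- sim_config(ncell = 250, ngene = 100, tree = "Phyla1",
                    mode = "continuous", velocity = TRUE, seed = 3)
  res <- sim_true_counts(cfg)
  expect_true(all(res$xs >= 0) && all(res$xu >= 0))
  expect_equal(res$velocity,
               rna_velocity(res$xu, res$xs, res$beta, res$d))
  emb <- prcomp(log1p(res$counts), rank. = 10)$x
  vs <- knn_smooth_velocity(res$velocity, emb)
  # project each cell's velocity on the local expression gradient along
  # pseudotime (profiles are non-monotone, so a global slope would not
  # represent the trajectory direction at a given cell)
  pt <- res$meta$pseudotime
  delta <- diff(range(pt)) / 10
  proj <- vapply(seq_along(pt), function(i) {
    ahead <- pt > pt[i] & pt <= pt[i] + delta
    behind <- pt < pt[i] & pt >= pt[i] - delta
    if (!any(ahead) || !any(behind)) return(NA_real_)
    u <- colMeans(res$counts[ahead, , drop = FALSE]) -
      colMeans(res$counts[behind, , drop = FALSE])
    sum(vs[i, ] * u)
  }, 0)
  expect_gt(mean(proj > 0, na.rm = TRUE), 0.5)
})
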