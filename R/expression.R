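# Expression: Beta-Poisson and full kinetic model ------------------------

#' Sample true counts from the Beta-Poisson model
#'
#' Per entry: `y ~ Beta(kon, koff)`, `x ~ Poisson(y * s)`, and the
#' returned value interpolates between the sample and the theoretical mean
#' `s * kon / (kon + koff)` with intrinsic-noise weight `sigma_i`
#' (0 = noiseless mean, 1 = full sample).
#'
#' @param kon,koff,s strictly positive matrices (or vectors) of equal
#'   shape.
#' @param sigma_i intrinsic-noise weight in `[0, 1]`.
#' @param stream optional integer seed.
#' @return nonnegative matrix shaped like `kon`.
#' @export
beta_poisson_counts <- function(kon, koff, s, sigma_i = 1, stream = NULL) {
  if (any(kon <= 0) || any(koff <= 0) || any(s <= 0))
    stop("kinetic parameters must be strictly positive")
  if (sigma_i < 0 || sigma_i > 1) stop("sigma_i must be in [0, 1]")
  with_stream(stream, {
    mu <- s * kon / (kon + koff)
    if (sigma_i == 0) return(mu)
    y <- rbeta(length(kon), kon, koff)
    x <- rpois(length(kon), y * as.vector(s))
    out <- sigma_i * x + (1 - sigma_i) * mu
    if (is.matrix(kon)) out <- matrix(out, nrow(kon), ncol(kon))
    out
  })
}

#' Sample per-gene splicing and degradation rates
#'
#' Gaussian with truncation from below, one pair per gene.
#'
#' @param ngene number of genes.
#' @param mean,sd Gaussian parameters (defaults 1 and 0.1).
#' @param min_rate truncation floor (default 0.1).
#' @param stream optional integer seed.
#' @return list with vectors `beta` and `d`.
#' @export
sample_splice_rates <- function(ngene, mean = 1, sd = 0.1, min_rate = 0.1,
                                stream = NULL) {
  with_stream(stream, list(beta = pmax(rnorm(ngene, mean, sd), min_rate),
                           d = pmax(rnorm(ngene, mean, sd), min_rate)))
}

#' Steady-state initial spliced/unspliced counts
#'
#' `xs = s * kon * beta / (kon + koff)` and
#' `xu = s * kon * d / (kon + koff)`, the initial state whose velocity
#' `beta * xu - d * xs` is identically zero.
#'
#' @param kon,koff,s positive arrays of equal shape.
#' @param beta,d splicing/degradation rates (recycled across cells when
#'   `kon` is a matrix with genes in columns).
#' @return list with `xs` and `xu`.
#' @export
kinetic_init <- function(kon, koff, s, beta, d) {
  base <- s * kon / (kon + koff)
  if (is.matrix(base)) {
    xs <- sweep(base, 2, beta, `*`)
    xu <- sweep(base, 2, d, `*`)
  } else {
    xs <- base * beta
    xu <- base * d
  }
  list(xs = xs, xu = xu)
}

#' Step the two-state promoter kinetic model
#'
#' The cell-cycle length is `L = eta_l * (1/kon + 1/koff)`, divided into
#' `m = L / min(1/kon, 1/koff)` steps of size `L/m`, so the per-step
#' switching probabilities `pon = kon * L/m` and `poff = koff * L/m` are
#' valid probabilities. Each step updates the promoter state and then
#'   `xs <- xs + (L/m) * (beta * xu - d * xs)`
#'   `xu <- xu + (L/m) * (s - beta * xu)`   (promoter on)
#'   `xu <- xu - (L/m) * (beta * xu)`       (promoter off)
#' Counts are real-valued during stepping and clipped at 0; the returned
#' values are the final-step states. `m` is capped at `max_steps` for
#' numerical thrift when kon and koff are very dissimilar.
#'
#' @param xs0,xu0 initial spliced/unspliced counts (arrays of the common
#'   shape).
#' @param kon,koff,s positive arrays of the common shape.
#' @param beta,d rates, recycled like in [kinetic_init()].
#' @param eta_l cycle-length factor (> 0).
#' @param state0 optional initial promoter state (logical array; default
#'   random by `kon/(kon+koff)`).
#' @param max_steps cap on the per-entry step count.
#' @param stream optional integer seed.
#' @return list with `xs`, `xu`, `state` (final promoter state, logical).
#' @export
simulate_kinetic <- function(xs0, xu0, kon, koff, s, beta, d, eta_l = 1,
                             state0 = NULL, max_steps = 100, stream = NULL) {
  stopifnot(all(kon > 0), all(koff > 0), all(s > 0), eta_l > 0)
  with_stream(stream, {
    dims <- dim(kon)
    n <- length(kon)
    bmat <- if (!is.null(dims)) rep(beta, each = dims[1]) else beta
    dmat <- if (!is.null(dims)) rep(d, each = dims[1]) else d
    L <- eta_l * (1 / kon + 1 / koff)
    dt <- eta_l * pmin(1 / kon, 1 / koff)       # = L/m
    m <- pmin(ceiling(L / dt - 1e-9), max_steps)
    pon <- pmin(kon * dt, 1)
    poff <- pmin(koff * dt, 1)
    xs <- as.vector(xs0); xu <- as.vector(xu0)
    state <- if (is.null(state0))
      runif(n) < as.vector(kon / (kon + koff)) else as.vector(state0)
    maxm <- max(m)
    for (t in seq_len(maxm)) {
      act <- t <= m
      u <- runif(n)
      turn_on <- !state & (u < pon)
      turn_off <- state & (u < poff)
      state[act & turn_on] <- TRUE
      state[act & turn_off] <- FALSE
      dxs <- dt * (bmat * xu - dmat * xs)
      dxu <- ifelse(state, dt * (s - bmat * xu), -dt * bmat * xu)
      xs[act] <- pmax(xs[act] + dxs[act], 0)
      xu[act] <- pmax(xu[act] + dxu[act], 0)
    }
    shape <- function(v) if (!is.null(dims)) array(v, dims) else v
    list(xs = shape(xs), xu = shape(xu), state = shape(state))
  })
}

#' Ground-truth RNA velocity
#'
#' `v = beta * xu - d * xs`, elementwise.
#'
#' @param xu,xs unspliced/spliced counts (equal shape).
#' @param beta,d per-gene rates (recycled over cells for matrices with
#'   genes in columns) or arrays of the same shape.
#' @return array shaped like `xs`.
#' @export
rna_velocity <- function(xu, xs, beta, d) {
  stopifnot(identical(dim(xu), dim(xs)))
  if (is.matrix(xs) && length(beta) == ncol(xs)) {
    sweep(xu, 2, beta, `*`) - sweep(xs, 2, d, `*`)
  } else {
    beta * xu - d * xs
  }
}

#' Gaussian-kernel kNN smoothing and normalization of velocity
#'
#' Each cell's velocity is replaced by a Gaussian-kernel-weighted average
#' over its k nearest neighbors in the embedding (k = `ncell/50`, at least
#' 1), then divided by its own norm. Zero-norm rows are left unnormalized.
#'
#' @param v velocity matrix (`ncell` x `ngene`).
#' @param cell_embedding matrix with one row per cell (any dimension).
#' @param k neighborhood size; default `max(1, round(ncell/50))`.
#' @return smoothed, row-normalized velocity matrix.
#' @export
knn_smooth_velocity <- function(v, cell_embedding,
                                k = max(1L, round(nrow(v) / 50))) {
  ncell <- nrow(v)
  stopifnot(nrow(cell_embedding) == ncell, k >= 1, k < max(ncell, 2))
  D <- as.matrix(dist(cell_embedding))
  out <- v
  for (i in seq_len(ncell)) {
    ord <- order(D[i, ])
    nb <- setdiff(ord, i)[seq_len(min(k, ncell - 1L))]
    idx <- c(i, nb)
    dd <- D[i, idx]
    h <- max(dd[length(dd)], 1e-12)
    w <- exp(-(dd / h)^2 / 2)
    out[i, ] <- colSums(v[idx, , drop = FALSE] * (w / sum(w)))
  }
  nrm <- sqrt(rowSums(out^2))
  nz <- nrm > 0
  out[nz, ] <- out[nz, , drop = FALSE] / nrm[nz]
  out
}
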