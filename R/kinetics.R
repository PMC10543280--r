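# Kinetic parameters -----------------------------------------------------
#
# The raw CIF x GIV surfaces are carried to realistic scales by rank-based
# scaling: values are replaced by an ordered sample from a reference
# distribution, preserving ranks exactly. The degradation rate d is fixed
# at 1, so the theoretical mean expression is s * kon / (kon + koff).

#' Rank-based scaling to a reference distribution
#'
#' Draws `length(X)` values from the empirical reference (with
#' replacement), sorts them, and places them into the shape of `X` by the
#' rank order of `X`'s entries. The rank order is preserved exactly (ties
#' broken by position, deterministically); the output value multiset is an
#' i.i.d. sample from the reference.
#'
#' @param X numeric matrix or vector.
#' @param reference nonempty numeric sample defining the target
#'   distribution.
#' @param stream optional integer seed.
#' @return object shaped like `X`.
#' @export
rank_scale <- function(X, reference, stream = NULL) {
  if (!length(reference)) stop("empty reference sample")
  if (!length(X)) return(X)
  with_stream(stream, {
    draws <- sort(sample(reference, length(X), replace = TRUE))
    out <- X
    out[order(X)] <- draws
    out
  })
}

#' Bundled reference kinetic distributions
#'
#' Parametric log-normal samples standing in for kinetic parameters
#' estimated from real data: `log10(kon)` and `log10(koff)` ~
#' Normal(-0.3, 0.6), `log10(s)` ~ Normal(1.2, 0.4); 10^4 draws each at a
#' fixed fixture seed. Users may substitute empirical samples (e.g. from
#' single-column text files via [read_reference_file()]).
#'
#' @param n draws per parameter.
#' @param seed fixture seed (fixed default).
#' @return list with positive samples `kon`, `koff`, `s`.
#' @export
default_kinetic_reference <- function(n = 10000, seed = 42) {
  with_stream(seed, list(kon = 10^rnorm(n, -0.3, 0.6),
                         koff = 10^rnorm(n, -0.3, 0.6),
                         s = 10^rnorm(n, 1.2, 0.4)))
}

#' Read a reference sample from a single-column numeric text file
#'
#' @param path file with one positive number per line.
#' @return numeric vector.
#' @export
read_reference_file <- function(path) {
  x <- scan(path, what = numeric(), quiet = TRUE)
  if (!length(x) || any(!is.finite(x)) || any(x <= 0))
    stop("reference file must contain positive finite numbers")
  x
}

#' Assemble the promoter activation rate kon
#'
#' Accessibility gates activation: the accessibility of a gene's
#' controlling regions (`atac %*% Z`) forms the ATAC-driven surface M1';
#' its zeros are replaced by the corresponding raw CIF x GIV entries
#' rescaled below the smallest nonzero of M1' (so closed chromatin still
#' ranks below open). The ATAC-driven and raw rank sources are blended
#' convexly with weight `ea`, then rank-scaled to the kon reference.
#'
#' @param M1 raw CIF x GIV surface for kon (`ncell` x `ngene`).
#' @param atac accessibility matrix (`ncell` x `nregion`), or `NULL` to
#'   use the raw surface alone.
#' @param Z region-to-gene map (`nregion` x `ngene`).
#' @param ea ATAC-effect weight in `[0, 1]`.
#' @param reference kon reference sample.
#' @param stream optional integer seed.
#' @return strictly positive `ncell` x `ngene` matrix.
#' @export
assemble_kon <- function(M1, atac, Z, ea, reference, stream = NULL) {
  with_stream(stream, {
    if (is.null(atac) || ea == 0)
      return(rank_scale(M1, reference))
    stopifnot(ncol(atac) == nrow(Z), ncol(M1) == ncol(Z))
    M1p <- atac %*% Z
    zeros <- M1p == 0
    if (any(zeros)) {
      nz <- M1p[!zeros]
      nz_min <- if (length(nz)) min(nz) else 1
      z_vals <- M1[zeros]
      rng <- range(z_vals)
      span <- rng[2] - rng[1]
      scaled <- if (span > 0) (z_vals - rng[1]) / span else rep(0.5, length(z_vals))
      M1p[zeros] <- scaled * nz_min * 0.99
    }
    # convex blend of the two rank sources (ranks normalized to [0, 1])
    r_atac <- rank(M1p, ties.method = "first") / length(M1p)
    r_raw <- rank(M1, ties.method = "first") / length(M1)
    blend <- matrix(ea * r_atac + (1 - ea) * r_raw, nrow(M1), ncol(M1))
    rank_scale(blend, reference)
  })
}

#' Assemble the promoter deactivation rate koff
#'
#' Rank-scaled raw surface divided by `10^B`; the same divisor is applied
#' to kon by the orchestrator, so a larger bimodality factor B slows both
#' switching rates and increases expression bimodality.
#'
#' @param M2 raw CIF x GIV surface for koff.
#' @param B bimodality factor (>= 0).
#' @param reference koff reference sample.
#' @param stream optional integer seed.
#' @return strictly positive matrix.
#' @export
assemble_koff <- function(M2, B, reference, stream = NULL) {
  stopifnot(B >= 0)
  rank_scale(M2, reference, stream = stream) / 10^B
}

#' Assemble the synthesis rate s
#'
#' Rank-scaled raw surface linearly scaled by `scale_s` (cell size).
#'
#' @param M3 raw CIF x GIV surface for s.
#' @param scale_s positive linear factor.
#' @param reference s reference sample.
#' @param stream optional integer seed.
#' @return strictly positive matrix.
#' @export
assemble_s <- function(M3, scale_s, reference, stream = NULL) {
  stopifnot(scale_s > 0)
  rank_scale(M3, reference, stream = stream) * scale_s
}
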