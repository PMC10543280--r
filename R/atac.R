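# Chromatin accessibility ------------------------------------------------
#
# Regions are abstract indices. Each gene is controlled by 1-3 consecutive
# regions; region accessibility is generated from the kon CIF and a region
# identity vector (RIV) matrix, rank-scaled to an accessibility reference,
# and coupled back into kon through the region-to-gene map.

#' Sample a region identity vector matrix
#'
#' Entries are 0 with probability `p0` and Gaussian(`riv_mean`, `riv_sd`)
#' otherwise — the region analogue of [sample_giv()].
#'
#' @param ncif_total CIF width (rows).
#' @param nregion number of regions (columns).
#' @param p0 zero probability.
#' @param riv_mean,riv_sd Gaussian component.
#' @param stream optional integer seed.
#' @return `ncif_total` x `nregion` matrix.
#' @export
sample_riv <- function(ncif_total, nregion, p0, riv_mean = 0, riv_sd = 1,
                       stream = NULL) {
  if (!is.numeric(p0) || p0 < 0 || p0 > 1) stop("p0 must be in [0, 1]")
  sample_giv(ncif_total, nregion, p0, riv_mean, riv_sd, stream = stream)
}

#' Generate the region-to-gene map
#'
#' For each gene a region count k in 1..3 is drawn from `r`, and k fresh
#' consecutive region indices are assigned, so regions form a contiguous
#' 1..nregion cover with no orphans.
#'
#' @param ngene number of genes.
#' @param r length-3 probability vector over region counts 1..3.
#' @param stream optional integer seed.
#' @return list with `Z` (binary `nregion` x `ngene` matrix) and `nregion`.
#' @export
generate_region_to_gene <- function(ngene, r = c(0.1, 0.5, 0.4),
                                    stream = NULL) {
  stopifnot(length(r) == 3, all(r >= 0))
  if (abs(sum(r) - 1) > 1e-9) stop("r must sum to 1")
  with_stream(stream, {
    k <- sample.int(3L, ngene, replace = TRUE, prob = r)
    nregion <- sum(k)
    Z <- matrix(0L, nregion, ngene,
                dimnames = list(paste0("region", seq_len(nregion)),
                                paste0("gene", seq_len(ngene))))
    stop_at <- cumsum(k)
    for (g in seq_len(ngene))
      Z[(stop_at[g] - k[g] + 1L):stop_at[g], g] <- 1L
    list(Z = Z, nregion = nregion, region_count = k)
  })
}

#' Derive the TF-motif-to-region matrix
#'
#' `Mtr[i, j] = 1` iff TF j regulates any gene mapped to region i, so that
#' the support of `t(Mtr) %*% Z^T`-style products covers the GRN:
#' `support(Mtr . Mrg) >= support(Mtg)`.
#'
#' @param Mtg GRN effect matrix (nTF x ngene).
#' @param Z region-to-gene map (nregion x ngene).
#' @return binary `nregion` x `nTF` matrix (region-by-motif).
#' @export
derive_motif_matrix <- function(Mtg, Z) {
  stopifnot(ncol(Mtg) == ncol(Z))
  reg <- (Z %*% t(Mtg != 0)) > 0   # nregion x nTF
  storage.mode(reg) <- "integer"
  reg
}

#' Default accessibility reference distribution
#'
#' A zero-inflated exponential: mass `p_zero` at 0, otherwise
#' Exponential(rate = 1/density). A parametric stand-in for an empirical
#' accessibility profile; any positive sample (e.g. read from a
#' single-column text file) can be supplied instead wherever a reference is
#' accepted.
#'
#' @param n sample size.
#' @param p_zero zero mass.
#' @param density mean of the nonzero component.
#' @param stream optional integer seed.
#' @return numeric vector of length `n`.
#' @export
default_atac_reference <- function(n = 10000, p_zero = 0.7, density = 1,
                                   stream = NULL) {
  with_stream(stream, {
    x <- rexp(n, rate = 1 / density)
    x[runif(n) < p_zero] <- 0
    x
  })
}

#' Simulate the accessibility matrix
#'
#' `CIF %*% RIV`, rank-scaled to the reference distribution, plus a small
#' Gaussian intrinsic noise (`intrinsic_sd_frac` of the reference's sd),
#' clipped at 0.
#'
#' @param cif_kon the kon CIF matrix (`ncell` x `ncif_total`).
#' @param riv a RIV matrix (`ncif_total` x `nregion`).
#' @param reference nonempty numeric accessibility sample.
#' @param intrinsic_sd_frac intrinsic noise sd as a fraction of `sd(reference)`.
#' @param stream optional integer seed.
#' @return `ncell` x `nregion` nonnegative matrix.
#' @export
simulate_atac <- function(cif_kon, riv, reference,
                          intrinsic_sd_frac = 0.05, stream = NULL) {
  if (!length(reference)) stop("empty accessibility reference")
  stopifnot(ncol(cif_kon) == nrow(riv))
  with_stream(stream, {
    raw <- cif_kon %*% riv
    scaled <- rank_scale(raw, reference)
    noise_sd <- intrinsic_sd_frac * sd(reference)
    if (noise_sd > 0)
      scaled <- scaled + matrix(rnorm(length(scaled), 0, noise_sd),
                                nrow(scaled), ncol(scaled))
    pmax(scaled, 0)
  })
}
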