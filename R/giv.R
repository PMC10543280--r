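# Gene identity vectors --------------------------------------------------
#
# A gene's identity vector weights the CIF dimensions: CIF %*% GIV is the
# raw cell x gene surface for one kinetic parameter. The tf segment of the
# s-GIV is the GRN effect matrix; the lig segment is the CCI effect matrix;
# both are zero for kon/koff (regulation acts on synthesis only).

#' Sample a zero-inflated Gaussian GIV block
#'
#' Each entry is 0 with probability `p0`, otherwise
#' Gaussian(`giv_mean`, `giv_sd`).
#'
#' @param n_rows,n_cols dimensions.
#' @param p0 zero probability in `[0, 1]`.
#' @param giv_mean,giv_sd Gaussian component parameters.
#' @param stream optional integer seed.
#' @return `n_rows` x `n_cols` matrix.
#' @export
sample_giv <- function(n_rows, n_cols, p0, giv_mean = 0, giv_sd = 1,
                       stream = NULL) {
  if (!is.numeric(p0) || p0 < 0 || p0 > 1) stop("p0 must be in [0, 1]")
  with_stream(stream, {
    m <- matrix(rnorm(n_rows * n_cols, giv_mean, giv_sd), n_rows, n_cols)
    m[matrix(runif(n_rows * n_cols) < p0, n_rows, n_cols)] <- 0
    m
  })
}

#' Build the diff segment of the synthesis-rate GIV under a GRN
#'
#' Ties regulated genes to their regulators in the trajectory/cluster
#' space: (1) each TF gene's column gets exactly 2 randomly chosen nonzero
#' entries at a fixed small magnitude; (2) each pure-target gene's column
#' is the TF-block product with its column of the effect matrix (targets
#' inherit their regulators' identity, combined linearly for multiple
#' regulators); (3) a gene that is both TF and target gets the average of
#' (1) and (2). Genes outside the GRN are sampled from the usual
#' zero-inflated Gaussian.
#'
#' @param grn a `grn_spec`.
#' @param n_diff diff-segment width (>= 2).
#' @param ngene number of genes.
#' @param fixed_value the fixed small magnitude for TF entries
#'   (default 0.2).
#' @param p0,giv_mean,giv_sd mixture parameters for non-GRN genes.
#' @param stream optional integer seed.
#' @return `n_diff` x `ngene` matrix.
#' @export
build_diff_giv <- function(grn, n_diff, ngene = grn$ngene,
                           fixed_value = 0.2, p0 = 0.7,
                           giv_mean = 0, giv_sd = 1, stream = NULL) {
  stopifnot(inherits(grn, "grn_spec"))
  if (n_diff < 2) stop("n_diff must be at least 2 to encode TF identities")
  with_stream(stream, {
    tfs <- grn$tfs
    targets <- sort(unique(grn$edges$target))
    tf_block <- matrix(0, n_diff, length(tfs))   # n_diff x nTF
    for (i in seq_along(tfs))
      tf_block[sample.int(n_diff, 2L), i] <- fixed_value
    target_block <- tf_block %*% grn$effect_matrix  # n_diff x ngene
    out <- sample_giv(n_diff, ngene, p0, giv_mean, giv_sd)
    pure_tf <- setdiff(tfs, targets)
    pure_tg <- setdiff(targets, tfs)
    both <- intersect(tfs, targets)
    out[, pure_tf] <- tf_block[, match(pure_tf, tfs), drop = FALSE]
    out[, pure_tg] <- target_block[, pure_tg, drop = FALSE]
    if (length(both))
      out[, both] <- 0.5 * (tf_block[, match(both, tfs), drop = FALSE] +
                              target_block[, both, drop = FALSE])
    out
  })
}

#' Assemble a GIV matrix from its four segments
#'
#' @param nd,diff,tf,lig blocks with equal column counts (`ngene`);
#'   `tf`/`lig` may be `NULL` for zero-width segments.
#' @return matrix (`ncif_total` x `ngene`) with a `segments` attribute.
#' @export
assemble_giv <- function(nd, diff, tf = NULL, lig = NULL) {
  ngene <- ncol(nd)
  tf <- tf %||% matrix(0, 0, ngene)
  lig <- lig %||% matrix(0, 0, ngene)
  if (!all(vapply(list(diff, tf, lig), ncol, 0L) == ngene))
    stop("segment column counts disagree")
  m <- rbind(nd, diff, tf, lig)
  attr(m, "segments") <- c(nd = nrow(nd), diff = nrow(diff),
                           tf = nrow(tf), lig = nrow(lig))
  m
}

# Full GIV set for the three kinetic parameters.
#  - kon/koff: nd+diff zero-inflated Gaussian; tf/lig zero (regulation
#    affects s only).
#  - s: nd from the mixture; diff GRN-aware; tf = GRN effect matrix;
#    lig = CCI effect matrix (receptor columns).
build_giv_set <- function(cfg, lig_effect = NULL, stream = NULL) {
  with_stream(stream, {
    ngene <- cfg$ngene
    ntf <- if (is.null(cfg$grn)) 0L else length(cfg$grn$tfs)
    nlig <- if (is.null(lig_effect)) 0L else nrow(lig_effect)
    mk_plain <- function() assemble_giv(
      sample_giv(cfg$n_nd, ngene, cfg$giv_p0, cfg$giv_mean, cfg$giv_sd),
      sample_giv(cfg$n_diff, ngene, cfg$giv_p0, cfg$giv_mean, cfg$giv_sd),
      matrix(0, ntf, ngene), matrix(0, nlig, ngene))
    kon <- mk_plain()
    koff <- mk_plain()
    s_diff <- if (is.null(cfg$grn) || cfg$n_diff < 2)
      sample_giv(cfg$n_diff, ngene, cfg$giv_p0, cfg$giv_mean, cfg$giv_sd)
    else
      build_diff_giv(cfg$grn, cfg$n_diff, ngene, p0 = cfg$giv_p0,
                     giv_mean = cfg$giv_mean, giv_sd = cfg$giv_sd)
    s_tf <- if (ntf) cfg$grn$effect_matrix else matrix(0, 0, ngene)
    s_lig <- lig_effect %||% matrix(0, 0, ngene)
    s <- assemble_giv(
      sample_giv(cfg$n_nd, ngene, cfg$giv_p0, cfg$giv_mean, cfg$giv_sd),
      s_diff, s_tf, s_lig)
    list(kon = kon, koff = koff, s = s)
  })
}
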