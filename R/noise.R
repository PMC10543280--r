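# Technical noise and batch effects --------------------------------------
#
# True counts are converted to observed counts by simulating the library
# prep: per-cell capture (binomial thinning at efficiency alpha), several
# rounds of amplification (each molecule duplicates with a per-round
# success probability), multinomial allocation of a per-cell sequencing
# depth over amplicons, and UMI collapse (a molecule is counted once if any
# of its amplicons is read) or non-UMI read counting.

#' Technical-noise configuration
#'
#' Defaults mirror the stock benchmark setting: non-UMI protocol, capture
#' efficiency `alpha ~ Normal(0.1, 0.02)`, depth `~ Normal(1e5, 3000)`,
#' 8 amplification rounds with per-round success 0.7, ATAC observation
#' probability 0.3.
#'
#' @param protocol `"nonUMI"` or `"UMI"`.
#' @param alpha_mean,alpha_sd per-cell capture efficiency distribution
#'   (truncated to (0, 1]).
#' @param depth_mean,depth_sd per-cell sequencing depth distribution.
#' @param amp_rounds,amp_p amplification rounds and per-round success.
#' @param atac_obs_prob ATAC entry observation probability.
#' @param nbatch number of batches.
#' @param eb batch-effect strength (half-width of the per-gene shift
#'   uniform).
#' @return a `noise_config` list.
#' @export
noise_config <- function(protocol = c("nonUMI", "UMI"),
                         alpha_mean = 0.1, alpha_sd = 0.02,
                         depth_mean = 1e5, depth_sd = 3000,
                         amp_rounds = 8, amp_p = 0.7,
                         atac_obs_prob = 0.3, nbatch = 1, eb = 1) {
  protocol <- match.arg(protocol)
  stopifnot(alpha_mean > 0, depth_mean > 0, amp_rounds >= 0,
            amp_p >= 0, amp_p <= 1, atac_obs_prob >= 0, atac_obs_prob <= 1,
            nbatch >= 1, eb >= 0)
  structure(list(protocol = protocol, alpha_mean = alpha_mean,
                 alpha_sd = alpha_sd, depth_mean = depth_mean,
                 depth_sd = depth_sd, amp_rounds = as.integer(amp_rounds),
                 amp_p = amp_p, atac_obs_prob = atac_obs_prob,
                 nbatch = as.integer(nbatch), eb = eb),
            class = "noise_config")
}

#' Add RNA technical noise
#'
#' @param true_counts cell x gene nonnegative matrix (real values are
#'   floored).
#' @param config a [noise_config()].
#' @param stream optional integer seed.
#' @return cell x gene matrix of observed nonnegative integer counts.
#' @export
add_rna_technical_noise <- function(true_counts, config = noise_config(),
                                    stream = NULL) {
  stopifnot(inherits(config, "noise_config"), all(true_counts >= 0))
  tc <- floor(true_counts)
  ncell <- nrow(tc); ngene <- ncol(tc)
  with_stream(stream, {
    alpha <- pmin(pmax(rnorm(ncell, config$alpha_mean, config$alpha_sd),
                       1e-4), 1)
    depth <- pmax(rnorm(ncell, config$depth_mean, config$depth_sd), 1)
    out <- matrix(0L, ncell, ngene)
    for (i in seq_len(ncell)) {
      cap <- rbinom(ngene, size = tc[i, ], prob = alpha[i])
      tot <- sum(cap)
      if (tot == 0L) next
      gene_of <- rep.int(seq_len(ngene), cap)   # one entry per molecule
      amp <- rep.int(1L, tot)
      for (r in seq_len(config$amp_rounds))
        amp <- amp + rbinom(tot, size = amp, prob = config$amp_p)
      reads <- rmultinom(1L, size = round(depth[i]),
                         prob = amp / sum(amp))[, 1]
      if (config$protocol == "UMI") {
        got <- reads > 0L
        out[i, ] <- as.integer(tabulate(gene_of[got], nbins = ngene))
      } else {
        per_gene <- rowsum(as.numeric(reads), gene_of)
        o <- numeric(ngene)
        o[as.integer(rownames(per_gene))] <- per_gene[, 1]
        out[i, ] <- as.integer(o)
      }
    }
    out
  })
}

#' Add batch effects
#'
#' Cells are partitioned round-robin into `nbatch` batches; for each gene j
#' and batch i a shift factor is drawn from `Unif(mu_j - eb, mu_j + eb)`
#' with a gene-wide center `mu_j ~ N(0, 1)`, and counts are multiplied by
#' `exp(shift)` and re-rounded.
#'
#' @param counts cell x gene matrix.
#' @param nbatch number of batches (>= 1).
#' @param eb batch-effect strength (>= 0).
#' @param stream optional integer seed.
#' @return list with `counts` (shifted) and integer `batch` labels.
#' @export
add_batch_effects <- function(counts, nbatch, eb, stream = NULL) {
  stopifnot(nbatch >= 1, eb >= 0)
  ncell <- nrow(counts); ngene <- ncol(counts)
  with_stream(stream, {
    batch <- (seq_len(ncell) - 1L) %% nbatch + 1L
    mu <- rnorm(ngene, 0, 1)
    shift <- matrix(runif(nbatch * ngene, rep(mu, each = nbatch) - eb,
                          rep(mu, each = nbatch) + eb), nbatch, ngene)
    out <- round(counts * exp(shift[batch, , drop = FALSE]))
    list(counts = out, batch = batch, shift = shift, mu = mu)
  })
}

#' Add observational noise and batch effects to accessibility data
#'
#' Entries are independently retained with probability `observation_prob`
#' (otherwise zeroed); batch shifts are applied as for RNA.
#'
#' @param atac_matrix cell x region matrix.
#' @param observation_prob retention probability in `[0, 1]`.
#' @param nbatch number of batches.
#' @param eb batch-effect strength.
#' @param stream optional integer seed.
#' @return list with `atac` and `batch`.
#' @export
add_atac_noise <- function(atac_matrix, observation_prob = 0.3,
                           nbatch = 1, eb = 0, stream = NULL) {
  stopifnot(observation_prob >= 0, observation_prob <= 1)
  with_stream(stream, {
    keep <- matrix(runif(length(atac_matrix)) < observation_prob,
                   nrow(atac_matrix), ncol(atac_matrix))
    obs <- atac_matrix * keep
    if (eb > 0 || nbatch > 1) {
      be <- add_batch_effects(obs, nbatch, eb)
      list(atac = be$counts, batch = be$batch)
    } else {
      list(atac = obs, batch = rep(1L, nrow(obs)))
    }
  })
}
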