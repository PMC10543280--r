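# Shared tiny fixtures, built in code.

tiny_grn <- function(ngene = 10) {
  load_grn(data.frame(regulator = c(1L, 1L, 2L),
                      target = c(3L, 4L, 5L),
                      effect = c(2, 1, 3)), ngene)
}

tiny_lr <- function(ngene = 12) {
  load_lr_db(data.frame(ligand = c(11L, 12L),
                        receptor = c(3L, 5L),
                        effect = c(3, 3)), ngene)
}

small_config <- function(seed = 11, grn = NULL, ...) {
  sim_config(ncell = 60, ngene = 30, tree = "Phyla3",
             grn = grn, seed = seed, ...)
}

with_seed_grn <- function(s) {
  set.seed(s)
  ngene <- 20
  load_grn(data.frame(regulator = sample(1:5, 8, replace = TRUE),
                      target = sample(6:20, 8),
                      effect = runif(8, 1, 5)), ngene)
}
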