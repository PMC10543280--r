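# Dataset grids and the M{p}{c}{s} label scheme --------------------------
#
# The benchmark datasets are organized in enumerable grids. The main grid
# crosses three population structures (L: linear/Phyla1, T: tree/Phyla3,
# D: discrete/Phyla5) with 12 parameter configurations (sigma_cif in
# {0.1, 0.5} x cells in {500, 800} x genes in {110, 200, 500}) and 4 seeds,
# giving 144 datasets labelled M{p}{c}{s}, e.g. MD5c = discrete,
# sigma_cif 0.1, 800 cells, 200 genes, seed 3.

main_grid_configs <- function() {
  cfg <- expand.grid(ngene = c(110L, 200L, 500L), ncell = c(500L, 800L),
                     sigma_cif = c(0.1, 0.5), KEEP.OUT.ATTRS = FALSE)
  cfg$config <- seq_len(nrow(cfg))
  cfg
}

pop_letters <- c(L = "Phyla1", T = "Phyla3", D = "Phyla5")
seed_letters <- c(a = 1L, b = 2L, c = 3L, d = 4L)

#' Enumerate a dataset grid
#'
#' Produces the complete, deterministically ordered (population,
#' configuration index, seed) enumeration of one of the unambiguous dataset
#' grids: `main` (144 entries), `velocity` (72), `grn_aux` (16),
#' `cci_aux` (8) and `sc_cci_aux` (8).
#'
#' @param grid grid name.
#' @return a data frame with one row per dataset: `label`, `population`,
#'   `tree`, `mode`, `sigma_cif`, `ncell`, `ngene`, `ncif`, `rd`,
#'   `sigma_i`, `seed`, `velocity`, `grn`, `cci`.
#' @export
enumerate_grid <- function(grid = c("main", "velocity", "grn_aux",
                                    "cci_aux", "sc_cci_aux")) {
  grid <- match.arg(grid)
  row <- function(label, population, tree, mode, sigma_cif, ncell, ngene,
                  ncif, rd, sigma_i, seed, velocity, grn, cci)
    data.frame(label = label, population = population, tree = tree,
               mode = mode, sigma_cif = sigma_cif, ncell = ncell,
               ngene = ngene, ncif = ncif, rd = rd, sigma_i = sigma_i,
               seed = seed, velocity = velocity, grn = grn, cci = cci,
               stringsAsFactors = FALSE)
  out <- list()
  if (grid == "main") {
    cfgs <- main_grid_configs()
    for (p in names(pop_letters)) for (ci in cfgs$config)
      for (s in names(seed_letters)) {
        cc <- cfgs[cfgs$config == ci, ]
        out[[length(out) + 1L]] <- row(
          paste0("M", p, ci, s), p, pop_letters[[p]],
          if (p == "D") "discrete" else "continuous",
          cc$sigma_cif, cc$ncell, cc$ngene, 20L, 0.8, 1,
          seed_letters[[s]], FALSE, TRUE, TRUE)
      }
  } else if (grid == "velocity") {
    cfgs <- expand.grid(grn = c(TRUE, FALSE), ngene = c(100L, 200L, 500L),
                        ncell = c(500L, 750L, 1000L), KEEP.OUT.ATTRS = FALSE)
    for (ci in seq_len(nrow(cfgs))) for (si in 1:4) {
      cc <- cfgs[ci, ]
      out[[length(out) + 1L]] <- row(
        paste0("V", ci, names(seed_letters)[si]), "V", "Phyla5",
        "continuous", 0.1, cc$ncell, cc$ngene, 20L, 0.8, 1,
        4L + si, TRUE, cc$grn, TRUE)
    }
  } else if (grid == "grn_aux") {
    for (ci in seq_along(c(110L, 500L))) for (s in 1:8) {
      ng <- c(110L, 500L)[ci]
      out[[length(out) + 1L]] <- row(
        paste0("G", ci, letters[s]), "G", "Phyla1", "continuous",
        0.1, 1000L, ng, 50L, 0.2, 1, s, FALSE, TRUE, FALSE)
    }
  } else if (grid == "cci_aux") {
    for (s in 1:8)
      out[[length(out) + 1L]] <- row(
        paste0("C1", letters[s]), "C", "Phyla1", "continuous",
        0.1, 500L, 160L, 50L, 0.8, 1, s, FALSE, TRUE, TRUE)
  } else if (grid == "sc_cci_aux") {
    for (s in 1:8)
      out[[length(out) + 1L]] <- row(
        paste0("S1", letters[s]), "S", "Phyla1", "continuous",
        0.1, 400L, 120L, 50L, 0.8, 1, s, FALSE, TRUE, TRUE)
  }
  do.call(rbind, out)
}

#' Resolve a dataset label to its simulation configuration
#'
#' Labels follow the M\{p\}\{c\}\{s\} scheme for the main grid (and the
#' analogous V/G/C/S labels for the auxiliary grids): `p` is the population
#' letter (L linear, T tree, D discrete), `c` the configuration index and
#' `s` the seed letter.
#'
#' @param label e.g. `"MD5c"`.
#' @param build if `TRUE` (default) return a full [sim_config()] (with the
#'   bundled GRN and, where the grid enables it, the stock CCI pair list);
#'   otherwise the grid row.
#' @return a `sim_config` or a one-row data frame.
#' @export
resolve_dataset_label <- function(label, build = TRUE) {
  stopifnot(is.character(label), length(label) == 1L)
  grid <- switch(substr(label, 1, 1),
                 M = "main", V = "velocity", G = "grn_aux",
                 C = "cci_aux", S = "sc_cci_aux",
                 stop("unknown grid letter in label '", label, "'"))
  rows <- enumerate_grid(grid)
  hit <- rows[rows$label == label, ]
  if (nrow(hit) == 0L)
    stop("label '", label, "' does not match any ", grid, " grid entry")
  if (nrow(hit) > 1L) stop("label '", label, "' is ambiguous")
  if (!build) return(hit)
  grid_row_config(hit)
}

# Build a full sim_config from a grid row.
grid_row_config <- function(row) {
  ngene <- row$ngene
  grn <- if (row$grn) grn_100_subset(ngene) else NULL
  lr <- NULL
  tree <- row$tree
  if (row$cci) {
    if (identical(row$population, "C") || identical(row$population, "S")) {
      fx <- dataset_c_fixture(seed = row$seed, ngene = ngene)
      grn <- fx$grn
      lr <- fx$lr
      tree <- fx$tree
    } else {
      mc <- build_main_cci(ngene)
      ngene <- mc$ngene
      grn <- if (row$grn) grn_100_subset(ngene) else NULL
      lr <- mc$lr_db
    }
  }
  sim_config(ncell = row$ncell, ngene = ngene, tree = tree,
             mode = row$mode, ncif = row$ncif, rd = row$rd,
             sigma_cif = row$sigma_cif, sigma_i = row$sigma_i,
             grn = grn, lr_db = lr, velocity = row$velocity,
             spatial = isTRUE(row$cci), seed = row$seed)
}

# The bundled 100-gene network restricted/embedded into ngene genes.
grn_100_subset <- function(ngene) {
  g <- grn_100()
  if (ngene >= 100) return(load_grn(g$edges, ngene))
  keep <- g$edges$regulator <= ngene & g$edges$target <= ngene
  load_grn(g$edges[keep, ], ngene)
}
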