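# Simulation configuration -----------------------------------------------

#' Create a simulation configuration
#'
#' Collects every knob of the generative model. Ranges are validated here;
#' all downstream stages trust the config.
#'
#' @param ncell number of cells.
#' @param ngene number of genes.
#' @param tree a `diff_tree` (or builtin tree name).
#' @param mode `"continuous"` (trajectory) or `"discrete"` (leaf clusters).
#' @param ncif total width of the population segments of the cell identity
#'   factors (non-diff + diff).
#' @param rd diff-to-nondiff ratio in `[0, 1]`; `n_diff = round(rd * ncif)`.
#' @param sigma_cif standard deviation of the cell identity factors: sd of
#'   the non-diff heterogeneity and, in discrete mode, the spread of cells
#'   around their type mean. The tree walk itself is scaled by tree
#'   distance, so a larger `sigma_cif` means more noise relative to the
#'   fixed-scale population signal.
#' @param sigma_i intrinsic-noise weight in `[0, 1]`; 0 returns the
#'   theoretical mean of the promoter kinetic model, 1 the full
#'   Beta-Poisson sample.
#' @param grn a `grn_spec`, or `NULL` to simulate without a GRN.
#' @param lr_db an `lr_db` ligand-receptor database (required for CCI).
#' @param ea ATAC effect in `[0, 1]`: weight of chromatin accessibility on
#'   the promoter activation rate kon.
#' @param bimod bimodality factor B >= 0; kon and koff are divided by
#'   `10^B`, increasing expression bimodality.
#' @param scale_s linear scaling (> 0) of the synthesis rate s (cell size).
#' @param velocity simulate spliced/unspliced counts and ground-truth RNA
#'   velocity via the full kinetic model.
#' @param spatial enable the spatial grid and cell-cell interactions.
#' @param atac_p_zero zero mass of the default ATAC reference distribution.
#' @param atac_density rate scale of the default ATAC reference.
#' @param giv_p0,giv_mean,giv_sd gene identity vector mixture: an entry is
#'   0 with probability `giv_p0`, else Gaussian(`giv_mean`, `giv_sd`).
#' @param riv_p0,riv_mean,riv_sd region identity vector mixture.
#' @param region_dist length-3 probability vector: chance of a gene being
#'   controlled by 1, 2 or 3 consecutive chromatin regions.
#' @param pn cell-type affinity: probability that a newborn cell is placed
#'   next to a same-type cell.
#' @param nnbs maximum number of interacting neighbors per cell.
#' @param layout spatial layout: `"default"`, `"layers"` or `"islands"`.
#' @param tc extra settling steps after all cells are placed.
#' @param cci_fraction fraction of implied cell-pair interaction edges kept
#'   in the single-cell-level ground truth.
#' @param grid_capacity grid capacity as percent of `ncell` (>= 100).
#' @param kinetic_ref reference kinetic distributions, see
#'   [default_kinetic_reference()].
#' @param eta_l cell-cycle length factor for the full kinetic model: the
#'   simulated time per cell is `eta_l * (1/kon + 1/koff)`. The default
#'   0.2 leaves cells partially relaxed toward their own steady state
#'   (cells in transit), which is what makes the ground-truth velocity
#'   point along the trajectory; at 1 (a full cycle) cells equilibrate
#'   and velocity degenerates to steady-state noise.
#' @param seed single global seed; every stage derives its own child
#'   stream via [derive_seed()].
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(ncell = 500, ngene = 200, tree = "Phyla5",
                       mode = c("continuous", "discrete"),
                       ncif = 20, rd = 0.8, sigma_cif = 0.1, sigma_i = 1,
                       grn = NULL, lr_db = NULL,
                       ea = 0.5, bimod = 0, scale_s = 1,
                       velocity = FALSE, spatial = FALSE,
                       atac_p_zero = 0.7, atac_density = 1,
                       giv_p0 = 0.7, giv_mean = 0, giv_sd = 1,
                       riv_p0 = 0.5, riv_mean = 0, riv_sd = 1,
                       region_dist = c(0.1, 0.5, 0.4),
                       pn = 0.8, nnbs = 4, layout = "default", tc = 10,
                       cci_fraction = 0.8, grid_capacity = 250,
                       kinetic_ref = NULL, eta_l = 0.2, seed = 1) {
  mode <- match.arg(mode)
  if (is.character(tree)) tree <- builtin_tree(tree)
  stopifnot(inherits(tree, "diff_tree"),
            ncell >= 1, ngene >= 1, ncif >= 1,
            rd >= 0, rd <= 1, sigma_cif >= 0,
            sigma_i >= 0, sigma_i <= 1,
            ea >= 0, ea <= 1, bimod >= 0, scale_s > 0,
            giv_p0 >= 0, giv_p0 <= 1, riv_p0 >= 0, riv_p0 <= 1,
            length(region_dist) == 3, all(region_dist >= 0),
            pn >= 0, pn <= 1, nnbs >= 1, tc >= 0,
            cci_fraction >= 0, cci_fraction <= 1,
            grid_capacity >= 100, eta_l > 0)
  if (abs(sum(region_dist) - 1) > 1e-9)
    stop("region_dist must sum to 1")
  if (!is.null(grn)) stopifnot(inherits(grn, "grn_spec"))
  if (!is.null(lr_db)) stopifnot(inherits(lr_db, "lr_db"))
  if (spatial && is.null(lr_db))
    stop("spatial/CCI simulation requires a ligand-receptor database")
  n_diff <- round(rd * ncif)
  if (mode == "continuous" && n_diff == 0)
    warning("n_diff is 0: the trajectory will not be encoded in the CIFs")
  cfg <- list(ncell = as.integer(ncell), ngene = as.integer(ngene),
              tree = tree, mode = mode, ncif = as.integer(ncif), rd = rd,
              n_diff = as.integer(n_diff),
              n_nd = as.integer(ncif - n_diff),
              sigma_cif = sigma_cif, sigma_i = sigma_i,
              grn = grn, lr_db = lr_db, ea = ea, bimod = bimod,
              scale_s = scale_s, velocity = velocity, spatial = spatial,
              atac_p_zero = atac_p_zero, atac_density = atac_density,
              giv_p0 = giv_p0, giv_mean = giv_mean, giv_sd = giv_sd,
              riv_p0 = riv_p0, riv_mean = riv_mean, riv_sd = riv_sd,
              region_dist = region_dist, pn = pn, nnbs = as.integer(nnbs),
              layout = layout, tc = as.integer(tc),
              cci_fraction = cci_fraction, grid_capacity = grid_capacity,
              kinetic_ref = kinetic_ref, eta_l = eta_l,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$ncell, " cells x ", x$ngene, " genes, ", x$mode,
      " population, ncif=", x$ncif, " (diff ", x$n_diff, "), sigma_cif=",
      x$sigma_cif, ", seed=", x$seed, "\n", sep = "")
  invisible(x)
}

#' Read a simulation configuration from YAML
#'
#' Field names mirror the [sim_config()] arguments; `tree` may be a builtin
#' name or a Newick string, `grn`/`lr_db` paths to headered TSV files.
#'
#' @param path YAML file path.
#' @return a `sim_config`.
#' @export
read_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$tree) && grepl("[();]", y$tree)) y$tree <- parse_tree(y$tree)
  ngene <- y$ngene %||% 200
  if (!is.null(y$grn) && is.character(y$grn)) y$grn <- load_grn(y$grn, ngene)
  if (!is.null(y$lr_db) && is.character(y$lr_db))
    y$lr_db <- load_lr_db(y$lr_db, ngene)
  do.call(sim_config, y)
}

# Echo a config to a YAML-serializable list (trees as Newick, tables inline).
config_to_list <- function(cfg) {
  out <- cfg[setdiff(names(cfg), c("tree", "grn", "lr_db", "kinetic_ref"))]
  out$tree <- serialize_tree(cfg$tree)
  if (!is.null(cfg$grn)) out$grn_edges <- cfg$grn$edges
  if (!is.null(cfg$lr_db)) out$lr_pairs <- cfg$lr_db$pairs
  out
}
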