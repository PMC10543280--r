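# Procedurally constructed benchmark inputs ------------------------------
#
# The auxiliary CCI benchmark (datasets C and S) uses a layered GRN over
# 160 genes: TFs 1-6 feed a first target layer 7-53, wired consecutively
# into a second layer 54-100 and a third layer 110-156, guaranteeing every
# receptor a depth-3 downstream chain. Ligands are genes 101-106;
# receptors are genes 2, 6, 10, 8, 20, 30. Genes 107-109 and 157-160 carry
# no edges; they pad the gene set to the 160-gene total.

#' Layered GRN for the CCI benchmark datasets
#'
#' 70 random TF edges (genes 1-6 to genes 7-53) plus two consecutive
#' layers: 7->54 ... 53->100 and 54->110 ... 100->156 (164 edges total).
#'
#' @param stream optional integer seed.
#' @param ngene simulated gene total (default 160).
#' @return a `grn_spec`.
#' @export
build_dataset_c_grn <- function(stream = NULL, ngene = 160) {
  with_stream(stream, {
    all_tf_edges <- expand.grid(regulator = 1:6, target = 7:53)
    pick <- all_tf_edges[sample.int(nrow(all_tf_edges), 70L), ]
    edges <- rbind(
      data.frame(regulator = pick$regulator, target = pick$target,
                 effect = round(runif(70, 1, 5), 2)),
      data.frame(regulator = 7:53, target = 54:100,
                 effect = round(runif(47, 1, 5), 2)),
      data.frame(regulator = 54:100, target = 110:156,
                 effect = round(runif(47, 1, 5), 2)))
    load_grn(edges, ngene)
  })
}

#' Ligand-receptor database for the CCI benchmark datasets
#'
#' Ligands 101-106 paired with receptors 2, 6, 10, 8, 20, 30.
#'
#' @param ngene simulated gene total (default 160).
#' @param effect interaction strength applied to every pair (default 3).
#' @return an `lr_db` with 6 rows.
#' @export
dataset_c_lr_db <- function(ngene = 160, effect = 3) {
  load_lr_db(data.frame(ligand = 101:106,
                        receptor = c(2L, 6L, 10L, 8L, 20L, 30L),
                        effect = effect), ngene)
}

#' Type-level CCI truth for the CCI benchmark datasets
#'
#' A linear trajectory divided into 5 sections (cell types); between each
#' of the 10 distinct type pairs, 3-6 of the 6 ligand-receptor rows are
#' sampled.
#'
#' @param lr_db the database (default [dataset_c_lr_db()]).
#' @param stream optional integer seed.
#' @return data frame (`type_a`, `type_b`, `lr_row`).
#' @export
build_dataset_c_cci <- function(lr_db = dataset_c_lr_db(), stream = NULL) {
  sample_cci_truth(lr_db, paste0("type", 1:5), pairs_range = c(3L, 6L),
                   include_same_type = FALSE, stream = stream)
}

# Linear 5-section differentiation chain used by the C and S datasets:
# root -> type1 -> ... -> type5, unit branch lengths.
dataset_c_tree <- function() {
  nodes <- c("root", paste0("type", 1:5))
  parent <- setNames(nodes[-length(nodes)], nodes[-1])
  blen <- setNames(rep(1, 5), nodes[-1])
  new_diff_tree(nodes, parent, blen, "root")
}

#' Assemble the full dataset-C fixture
#'
#' @param seed fixture seed.
#' @param ngene gene total (160 for dataset C, 120 for dataset S).
#' @return list with `grn`, `lr`, `tree`, `type_truth`, `ngene`.
#' @export
dataset_c_fixture <- function(seed = 1, ngene = 160) {
  grn <- build_dataset_c_grn(stream = derive_seed(seed, "fixture.grn"),
                             ngene = max(ngene, 160))
  if (ngene < 160) {
    keep <- grn$edges$regulator <= ngene & grn$edges$target <= ngene
    grn <- load_grn(grn$edges[keep, ], ngene)
  }
  lr <- dataset_c_lr_db(ngene)
  list(grn = grn, lr = lr, tree = dataset_c_tree(),
       type_truth = build_dataset_c_cci(lr, derive_seed(seed, "fixture.cci")),
       ngene = ngene)
}

#' Stock ligand-receptor pair list for the main datasets
#'
#' Connects each cell's genes 99, 101-104 to a neighbor's genes 91, 2, 6,
#' 10 (TFs) and 8 (non-TF). Ligand genes beyond the 100-gene network are
#' appended to the simulated gene set where needed.
#'
#' @param ngene requested gene total; raised to 104 if smaller.
#' @param effect interaction strength per pair (default 3).
#' @return list with `lr_db`, `ngene` (possibly raised) and
#'   `external_ligands` (ligand ids outside 1-100).
#' @export
build_main_cci <- function(ngene = 110, effect = 3) {
  lig <- c(99L, 101L, 102L, 103L, 104L)
  rec <- c(91L, 2L, 6L, 10L, 8L)
  ngene2 <- max(ngene, max(lig, rec))
  list(lr_db = load_lr_db(data.frame(ligand = lig, receptor = rec,
                                     effect = effect), ngene2),
       ngene = ngene2, external_ligands = lig[lig > 100])
}
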