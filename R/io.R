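# Output bundles ---------------------------------------------------------

write_mtx <- function(m, path) {
  Matrix::writeMM(Matrix::Matrix(t(m), sparse = TRUE), path)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a simulation result and its ground truths to a directory
#'
#' Matrices go out as MatrixMarket files (genes/regions in rows, cells in
#' columns) with `genes.tsv` / `regions.tsv` / `cells.tsv` sidecars;
#' velocity (signed) as dense TSV; tables as headered TSV; the
#' configuration echo as YAML. A `manifest.tsv` lists every file with its
#' md5 checksum. A partial write is cleaned up before erroring.
#'
#' @param result an `msim_result`.
#' @param dir output directory (created).
#' @param observed optional list with `counts` and/or `atac` observed
#'   matrices and `batch` labels.
#' @param dense also write dense TSV copies of the count matrices.
#' @return (invisibly) the manifest data frame.
#' @export
write_bundle <- function(result, dir, observed = NULL, dense = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(fn, writer) {
    path <- file.path(dir, fn)
    writer(path)
    written <<- c(written, path)
    path
  }
  ok <- FALSE
  on.exit(if (!ok) unlink(written))
  ncell <- nrow(result$counts)
  ngene <- ncol(result$counts)
  emit("cells.tsv", function(p) write_tsv(
    data.frame(cell = seq_len(ncell)), p))
  emit("genes.tsv", function(p) write_tsv(
    data.frame(gene = seq_len(ngene)), p))
  emit("counts_rna.mtx", function(p) write_mtx(result$counts, p))
  if (dense) emit("counts_rna.tsv", function(p)
    write_tsv(as.data.frame(result$counts), p))
  if (!is.null(result$atac)) {
    emit("regions.tsv", function(p) write_tsv(
      data.frame(region = seq_len(ncol(result$atac))), p))
    emit("counts_atac.mtx", function(p) write_mtx(result$atac, p))
  }
  if (!is.null(result$region_map)) {
    rg <- which(result$region_map == 1, arr.ind = TRUE)
    emit("region_to_gene.tsv", function(p) write_tsv(
      data.frame(region = rg[, 1], gene = rg[, 2]), p))
  }
  meta <- result$meta
  if (!is.null(observed$batch)) meta$batch <- observed$batch
  emit("cell_meta.tsv", function(p) write_tsv(meta, p))
  if (!is.null(result$grn))
    emit("grn_truth.tsv", function(p) write_tsv(result$grn$edges, p))
  if (!is.null(result$velocity)) {
    emit("spliced.mtx", function(p) write_mtx(result$xs, p))
    emit("unspliced.mtx", function(p) write_mtx(result$xu, p))
    emit("velocity.tsv", function(p) write_tsv(
      as.data.frame(result$velocity), p))
    emit("splice_rates.tsv", function(p) write_tsv(
      data.frame(gene = seq_len(ngene), beta = result$beta, d = result$d), p))
  }
  if (!is.null(result$spatial)) {
    emit("cci_type_truth.tsv", function(p)
      write_tsv(result$spatial$type_truth, p))
    emit("cci_cell_truth.tsv", function(p)
      write_tsv(result$spatial$cell_truth, p))
  }
  if (!is.null(observed$counts))
    emit("counts_rna_observed.mtx", function(p)
      write_mtx(observed$counts, p))
  if (!is.null(observed$atac))
    emit("counts_atac_observed.mtx", function(p)
      write_mtx(observed$atac, p))
  if (!is.null(result$config))
    emit("config.yaml", function(p)
      yaml::write_yaml(config_to_list(result$config), p))
  manifest <- data.frame(file = basename(written),
                         md5 = unname(tools::md5sum(written)))
  write_tsv(manifest, file.path(dir, "manifest.tsv"))
  ok <- TRUE
  invisible(manifest)
}

#' Read a count matrix written by [write_bundle()]
#'
#' @param path an `.mtx` file.
#' @return a dense cell x gene matrix.
#' @export
read_bundle_matrix <- function(path) {
  t(as.matrix(Matrix::readMM(path)))
}
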