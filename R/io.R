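#' Read an expression matrix from disk
#'
#' Supports the 10x-style Matrix Market triplet directory layout
#' (`matrix.mtx` genes x cells, `features.tsv` or `genes.tsv`, and
#' `barcodes.tsv`), dense CSV/TSV with cells in rows (header = gene ids,
#' first column = cell ids), and a simple HDF5 layout written by
#' [write_matrix()] (requires the `rhdf5` package). Values are validated to
#' be non-negative and finite; the returned set records `units =
#' "raw_counts"`.
#'
#' @param path File (csv/tsv/h5) or directory (mtx_dir) to read.
#' @param format One of `"mtx_dir"`, `"csv"`, `"tsv"`, `"h5"`.
#' @param batch Batch labels: a vector (one per cell), a single value, or the
#'   path to a two-column TSV (cell_id, label). For `"h5"`, labels embedded in
#'   the file are used when `batch` is `NULL`.
#' @param celltype Optional cell-type labels in the same forms as `batch`.
#' @return An [expr_set] with `units = "raw_counts"`.
#' @export
load_matrix <- function(path, format = c("mtx_dir", "csv", "tsv", "h5"),
                        batch = NULL, celltype = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("path does not exist: ", path)
  out <- switch(format,
    mtx_dir = read_mtx_dir(path),
    csv = read_dense(path, sep = ","),
    tsv = read_dense(path, sep = "\t"),
    h5 = read_h5(path)
  )
  if (is.null(batch)) batch <- out$batch %||% "batch1"
  batch <- resolve_labels(batch, out$cell_ids, "batch")
  if (is.null(celltype)) celltype <- out$celltype
  if (!is.null(celltype)) celltype <- resolve_labels(celltype, out$cell_ids, "celltype")
  expr_set(out$matrix, out$cell_ids, out$gene_ids,
           batch = batch, celltype = celltype, units = "raw_counts")
}

# Accepts a per-cell vector, a single value, or a two-column TSV path.
resolve_labels <- function(x, cell_ids, what) {
  if (length(x) == 1L && is.character(x) && file.exists(x)) {
    tab <- utils::read.table(x, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    if (ncol(tab) < 2L) stop(what, " label file must have two columns")
    idx <- match(cell_ids, as.character(tab[[1L]]))
    if (anyNA(idx))
      stop(what, " label file is missing ", sum(is.na(idx)), " cell ids")
    return(as.character(tab[[2L]])[idx])
  }
  if (length(x) == 1L) x <- rep(x, length(cell_ids))
  if (length(x) != length(cell_ids))
    stop(what, " labels length (", length(x), ") does not match ",
         length(cell_ids), " cells")
  as.character(x)
}

read_mtx_dir <- function(path) {
  if (!dir.exists(path)) stop("mtx_dir must be a directory: ", path)
  mtx <- first_existing(path, c("matrix.mtx", "matrix.mtx.gz"))
  feat <- first_existing(path, c("features.tsv", "genes.tsv",
                                 "features.tsv.gz", "genes.tsv.gz"))
  bar <- first_existing(path, c("barcodes.tsv", "barcodes.tsv.gz"))
  m <- Matrix::readMM(mtx)
  genes <- utils::read.table(feat, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)[[1L]]
  cells <- utils::read.table(bar, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)[[1L]]
  # 10x convention: rows are genes, columns are cells
  if (nrow(m) != length(genes) || ncol(m) != length(cells))
    stop("matrix dimensions (", nrow(m), " x ", ncol(m), ") do not match ",
         length(genes), " features and ", length(cells), " barcodes")
  list(matrix = t(as.matrix(m)), cell_ids = cells, gene_ids = genes)
}

first_existing <- function(dir, names) {
  for (nm in names) {
    p <- file.path(dir, nm)
    if (file.exists(p)) return(p)
  }
  stop("none of ", paste(names, collapse = ", "), " found in ", dir)
}

read_dense <- function(path, sep) {
  tab <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1L,
                           check.names = FALSE, stringsAsFactors = FALSE)
  list(matrix = as.matrix(tab), cell_ids = rownames(tab),
       gene_ids = colnames(tab))
}

require_rhdf5 <- function() {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("HDF5 support requires the 'rhdf5' package")
}

read_h5 <- function(path) {
  require_rhdf5()
  ls <- rhdf5::h5ls(path)$name
  out <- list(
    matrix = t(rhdf5::h5read(path, "matrix")),  # stored genes x cells
    cell_ids = as.character(rhdf5::h5read(path, "cell_ids")),
    gene_ids = as.character(rhdf5::h5read(path, "gene_ids"))
  )
  if ("batch" %in% ls) out$batch <- as.character(rhdf5::h5read(path, "batch"))
  if ("celltype" %in% ls)
    out$celltype <- as.character(rhdf5::h5read(path, "celltype"))
  out
}

#' Write an expression set to disk
#'
#' Inverse of [load_matrix()]: writes the 10x-style triplet directory, dense
#' CSV/TSV, or the package's HDF5 layout. Batch (and cell-type, when present)
#' labels are written as sidecar `*_labels.tsv` files for text formats and
#' embedded for HDF5.
#'
#' @param es An [expr_set].
#' @param path Output file (csv/tsv/h5) or directory (mtx_dir).
#' @param format One of `"mtx_dir"`, `"csv"`, `"tsv"`, `"h5"`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(es, path, format = c("mtx_dir", "csv", "tsv", "h5")) {
  stopifnot(inherits(es, "expr_set"))
  format <- match.arg(format)
  if (format == "mtx_dir") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(methods::as(Matrix::Matrix(t(es$matrix), sparse = TRUE),
                                "generalMatrix"),
                    file.path(path, "matrix.mtx"))
    utils::write.table(data.frame(es$gene_ids, es$gene_ids),
                       file.path(path, "features.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    writeLines(es$cell_ids, file.path(path, "barcodes.tsv"))
    write_labels(es, file.path(path, "labels.tsv"))
  } else if (format %in% c("csv", "tsv")) {
    sep <- if (format == "csv") "," else "\t"
    df <- as.data.frame(es$matrix, check.names = FALSE)
    utils::write.table(df, path, sep = sep, quote = FALSE,
                       row.names = TRUE, col.names = NA)
    write_labels(es, paste0(path, ".labels.tsv"))
  } else {
    require_rhdf5()
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    rhdf5::h5write(t(es$matrix), path, "matrix")
    rhdf5::h5write(es$cell_ids, path, "cell_ids")
    rhdf5::h5write(es$gene_ids, path, "gene_ids")
    rhdf5::h5write(es$batch, path, "batch")
    if (!is.null(es$celltype)) rhdf5::h5write(es$celltype, path, "celltype")
    rhdf5::h5closeAll()
  }
  invisible(path)
}

write_labels <- function(es, path) {
  df <- data.frame(cell_id = es$cell_ids, batch = es$batch,
                   stringsAsFactors = FALSE)
  if (!is.null(es$celltype)) df$celltype <- es$celltype
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
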