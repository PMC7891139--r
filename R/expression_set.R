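#' Labelled expression set
#'
#' The basic data container of the package: a dense cells x genes expression
#' matrix together with unique cell and gene identifiers, a batch label per
#' cell, optional cell-type labels, and a units tag recording whether the
#' values are raw counts or log-TPM-like.
#'
#' @param matrix Numeric cells x genes matrix, non-negative and finite.
#' @param cell_ids Character vector of unique cell identifiers (defaults to
#'   rownames of `matrix`).
#' @param gene_ids Character vector of unique gene identifiers (defaults to
#'   colnames of `matrix`).
#' @param batch Character or factor batch label per cell. A single value is
#'   recycled.
#' @param celltype Optional character or factor cell-type label per cell.
#' @param units Either `"raw_counts"` or `"log_tpm"`.
#' @return An object of class `expr_set`.
#' @export
expr_set <- function(matrix, cell_ids = rownames(matrix),
                     gene_ids = colnames(matrix), batch,
                     celltype = NULL, units = "raw_counts") {
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(matrix)))
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(matrix)))
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != nrow(matrix))
    stop("cell_ids length (", length(cell_ids), ") does not match the ",
         nrow(matrix), " matrix rows")
  if (length(gene_ids) != ncol(matrix))
    stop("gene_ids length (", length(gene_ids), ") does not match the ",
         ncol(matrix), " matrix columns")
  if (anyDuplicated(cell_ids)) stop("duplicate cell ids")
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids")
  if (anyNA(matrix) || any(!is.finite(matrix)))
    stop("expression matrix contains NA or non-finite values")
  if (any(matrix < 0)) stop("expression matrix contains negative values")
  if (length(batch) == 1L) batch <- rep(batch, nrow(matrix))
  batch <- as.character(batch)
  if (length(batch) != nrow(matrix))
    stop("batch labels length does not match the number of cells")
  if (!is.null(celltype)) {
    celltype <- as.character(celltype)
    if (length(celltype) != nrow(matrix))
      stop("celltype labels length does not match the number of cells")
  }
  units <- match.arg(units, c("raw_counts", "log_tpm"))
  dimnames(matrix) <- list(cell_ids, gene_ids)
  structure(list(matrix = matrix, cell_ids = cell_ids, gene_ids = gene_ids,
                 batch = batch, celltype = celltype, units = units),
            class = "expr_set")
}

#' @export
dim.expr_set <- function(x) dim(x$matrix)

#' @export
print.expr_set <- function(x, ...) {
  cat("expr_set:", nrow(x$matrix), "cells x", ncol(x$matrix), "genes\n")
  cat("  units:", x$units, "\n")
  tab <- table(x$batch)
  cat("  batches:", paste0(names(tab), " (", tab, ")", collapse = ", "), "\n")
  if (!is.null(x$celltype))
    cat("  cell types:", paste(sort(unique(x$celltype)), collapse = ", "), "\n")
  invisible(x)
}

#' Subset an expression set by cells and/or genes
#'
#' @param es An [expr_set].
#' @param cells Integer, logical or character index of cells to keep.
#' @param genes Integer, logical or character index of genes to keep.
#' @return A new [expr_set].
#' @export
subset_cells <- function(es, cells) {
  stopifnot(inherits(es, "expr_set"))
  if (is.character(cells)) cells <- match(cells, es$cell_ids)
  if (anyNA(cells)) stop("unknown cell ids in subset")
  expr_set(es$matrix[cells, , drop = FALSE],
           es$cell_ids[cells], es$gene_ids,
           batch = es$batch[cells],
           celltype = if (!is.null(es$celltype)) es$celltype[cells],
           units = es$units)
}

#' @rdname subset_cells
#' @export
subset_genes <- function(es, genes) {
  stopifnot(inherits(es, "expr_set"))
  if (is.character(genes)) genes <- match(genes, es$gene_ids)
  if (anyNA(genes)) stop("unknown gene ids in subset")
  expr_set(es$matrix[, genes, drop = FALSE],
           es$cell_ids, es$gene_ids[genes],
           batch = es$batch,
           celltype = es$celltype,
           units = es$units)
}

#' Split an expression set into one set per batch
#'
#' @param es An [expr_set].
#' @return Named list of single-batch [expr_set] objects, ordered by batch id.
#' @export
split_batches <- function(es) {
  stopifnot(inherits(es, "expr_set"))
  ids <- sort(unique(es$batch))
  out <- lapply(ids, function(b) subset_cells(es, which(es$batch == b)))
  names(out) <- ids
  out
}

#' Stack several expression sets sharing a gene space
#'
#' @param sets List of [expr_set] objects over identical gene ids.
#' @return A single combined [expr_set].
#' @export
bind_sets <- function(sets) {
  stopifnot(length(sets) >= 1L, all(vapply(sets, inherits, TRUE, "expr_set")))
  g <- sets[[1]]$gene_ids
  for (s in sets) {
    if (!identical(s$gene_ids, g)) stop("gene spaces differ between sets")
  }
  ct <- lapply(sets, function(s) s$celltype %||% rep(NA_character_, nrow(s$matrix)))
  expr_set(do.call(rbind, lapply(sets, `[[`, "matrix")),
           unlist(lapply(sets, `[[`, "cell_ids"), use.names = FALSE),
           g,
           batch = unlist(lapply(sets, `[[`, "batch"), use.names = FALSE),
           celltype = if (all(vapply(sets, function(s) is.null(s$celltype), TRUE)))
             NULL else unlist(ct, use.names = FALSE),
           units = sets[[1]]$units)
}
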