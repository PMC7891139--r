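#' Quality-control filter on raw counts
#'
#' Removes low-quality cells: those whose library size (total count) exceeds
#' `max_library_size` or whose fraction of counts on mitochondrial genes
#' exceeds `max_mito_fraction`. The gene set is never changed.
#'
#' @param es An [expr_set] with `units = "raw_counts"`.
#' @param max_library_size Upper bound on per-cell total counts
#'   (default `Inf`, i.e. no library-size filtering).
#' @param max_mito_fraction Upper bound on the mitochondrial count fraction,
#'   in `[0, 1]` (default 0.2).
#' @param mito_gene_prefix Prefix identifying mitochondrial gene ids
#'   (default `"MT-"`). A prefix matching no gene yields mito fraction 0 for
#'   every cell.
#' @return The filtered [expr_set].
#' @export
qc_filter <- function(es, max_library_size = Inf, max_mito_fraction = 0.2,
                      mito_gene_prefix = "MT-") {
  stopifnot(inherits(es, "expr_set"))
  if (es$units != "raw_counts")
    stop("qc_filter expects raw counts, got units = ", es$units)
  lib <- rowSums(es$matrix)
  mito <- startsWith(es$gene_ids, mito_gene_prefix)
  mito_frac <- if (any(mito)) {
    rowSums(es$matrix[, mito, drop = FALSE]) / pmax(lib, 1)
  } else {
    numeric(nrow(es$matrix))
  }
  keep <- lib <= max_library_size & mito_frac <= max_mito_fraction
  if (!any(keep)) {
    culprit <- if (all(lib > max_library_size)) "max_library_size"
               else "max_mito_fraction"
    stop("qc_filter removed every cell; threshold responsible: ", culprit)
  }
  subset_cells(es, which(keep))
}

#' Log-TPM-like transform
#'
#' Rescales each cell's counts to sum to `scale` and applies `log(1 + x)`.
#' This is the input representation expected by both model stages.
#'
#' @param es An [expr_set] with `units = "raw_counts"` and positive per-cell
#'   totals.
#' @param scale Per-cell total after rescaling (default `1e5`).
#' @return An [expr_set] with `units = "log_tpm"`.
#' @export
log_tpm_transform <- function(es, scale = 1e5) {
  stopifnot(inherits(es, "expr_set"), scale > 0)
  if (es$units != "raw_counts")
    stop("log_tpm_transform expects raw counts, got units = ", es$units)
  lib <- rowSums(es$matrix)
  if (any(lib == 0))
    stop(sum(lib == 0), " cells have zero total counts; run qc_filter first")
  m <- log1p(es$matrix / lib * scale)
  expr_set(m, es$cell_ids, es$gene_ids, batch = es$batch,
           celltype = es$celltype, units = "log_tpm")
}

#' Genes measured in every batch
#'
#' Returns the genes expressed (nonzero in at least one cell) in every one of
#' the supplied sets, in the gene order of the first set.
#'
#' @param sets List of at least two [expr_set] objects.
#' @return Character vector of gene ids.
#' @export
shared_genes <- function(sets) {
  stopifnot(length(sets) >= 2L, all(vapply(sets, inherits, TRUE, "expr_set")))
  expressed <- lapply(sets, function(s) s$gene_ids[colSums(s$matrix > 0) > 0])
  out <- Reduce(intersect, expressed[-1L], expressed[[1L]])
  if (length(out) == 0L) stop("no gene is expressed in every batch")
  out
}

#' Per-batch highly variable genes, combined across batches
#'
#' Ranks genes within each batch by a binned normalised dispersion statistic
#' (dispersion = variance/mean of the expression values, z-scored within 20
#' mean-expression bins) and takes the top `n_top_per_batch` per batch. The
#' per-batch lists are combined by union (default) or intersection, returned
#' in the gene order of the first set.
#'
#' @param sets List of [expr_set] objects restricted to a common gene space,
#'   with `units = "log_tpm"`.
#' @param n_top_per_batch Number of genes to take per batch. Values larger
#'   than the number of genes are clipped with a warning.
#' @param n_bins Number of mean-expression bins (default 20).
#' @param combine `"union"` or `"intersection"` of the per-batch lists.
#' @return Character vector of gene ids.
#' @export
select_hvg_union <- function(sets, n_top_per_batch, n_bins = 20,
                             combine = c("union", "intersection")) {
  stopifnot(length(sets) >= 1L, all(vapply(sets, inherits, TRUE, "expr_set")))
  combine <- match.arg(combine)
  genes <- sets[[1]]$gene_ids
  for (s in sets) {
    if (!identical(s$gene_ids, genes))
      stop("sets must be restricted to a common gene space first")
  }
  if (n_top_per_batch > length(genes)) {
    warning("n_top_per_batch (", n_top_per_batch, ") exceeds the ",
            length(genes), " available genes; clipping")
    n_top_per_batch <- length(genes)
  }
  per_batch <- lapply(sets, function(s) {
    nd <- normalized_dispersion(s$matrix, n_bins = n_bins)
    genes[order(-nd, seq_along(genes))[seq_len(n_top_per_batch)]]
  })
  keep <- if (combine == "union") {
    Reduce(union, per_batch)
  } else {
    Reduce(intersect, per_batch)
  }
  genes[genes %in% keep]
}

# Dispersion (variance / mean) z-scored within equal-frequency bins of mean
# expression. Genes in degenerate bins (sd 0) get a normalised dispersion of
# 0; all-zero genes rank last. Ranking falls back to the raw dispersion to
# break within-bin ties deterministically.
normalized_dispersion <- function(m, n_bins = 20) {
  mu <- colMeans(m)
  v <- apply(m, 2L, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  # equal-frequency bins, at least ~5 genes per bin so the within-bin
  # z-score is meaningful on small gene sets
  n_bins <- max(1L, min(n_bins, length(mu) %/% 5L))
  bins <- cut(rank(mu, ties.method = "first"), breaks = n_bins,
              labels = FALSE)
  nd <- numeric(length(mu))
  for (b in unique(bins)) {
    idx <- which(bins == b)
    s <- stats::sd(disp[idx])
    nd[idx] <- if (is.na(s) || s == 0) 0 else (disp[idx] - mean(disp[idx])) / s
  }
  nd[mu == 0] <- -Inf
  nd + 1e-9 * rank(disp) / length(disp)
}

#' Randomly partition genes into near-equal chunks
#'
#' Used for whole-transcriptome correction: the gene list is randomly
#' permuted under `seed` and split into `n_chunks` disjoint chunks whose
#' sizes differ by at most one.
#'
#' @param genes Character vector of gene ids.
#' @param n_chunks Number of chunks (default 10).
#' @param seed Integer seed for the permutation.
#' @return An object of class `gene_partition`: list with `chunks` (list of
#'   gene-id vectors) and `seed`.
#' @export
chunk_genes <- function(genes, n_chunks = 10, seed = 1) {
  stopifnot(n_chunks >= 1)
  if (n_chunks > length(genes))
    stop("n_chunks (", n_chunks, ") exceeds the number of genes (",
         length(genes), ")")
  perm <- with_seed(seed, sample(genes))
  sizes <- rep(length(genes) %/% n_chunks, n_chunks)
  extra <- length(genes) %% n_chunks
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  chunks <- Map(function(a, b) perm[a:b], starts, ends)
  structure(list(chunks = chunks, seed = seed), class = "gene_partition")
}

#' One-call preprocessing pipeline
#'
#' Convenience wrapper running [qc_filter()], [log_tpm_transform()],
#' [shared_genes()] and [select_hvg_union()] over a multi-batch set, in that
#' order, and returning the combined log-TPM set restricted to the selected
#' genes.
#'
#' @param es A multi-batch [expr_set] of raw counts.
#' @param hvg_n Highly variable genes per batch (default 2000).
#' @param scale Log-TPM scale constant (default `1e5`).
#' @param hvg_combine `"union"` or `"intersection"`.
#' @param ... Further arguments passed to [qc_filter()].
#' @return A combined [expr_set] with `units = "log_tpm"`, restricted to the
#'   selected genes; the full shared-gene log-TPM set is attached as attribute
#'   `"full"`.
#' @export
preprocess <- function(es, hvg_n = 2000, scale = 1e5,
                       hvg_combine = "union", ...) {
  stopifnot(inherits(es, "expr_set"))
  es <- qc_filter(es, ...)
  es <- log_tpm_transform(es, scale = scale)
  sets <- split_batches(es)
  genes <- if (length(sets) >= 2L) shared_genes(sets) else sets[[1]]$gene_ids
  sets <- lapply(sets, subset_genes, genes)
  hvg <- select_hvg_union(sets, n_top_per_batch = hvg_n,
                          combine = hvg_combine)
  full <- bind_sets(sets)
  out <- subset_genes(full, hvg)
  attr(out, "full") <- full
  out
}
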