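#' Single-cell batch-mixing evaluation
#'
#' Implements the two-classifier, single-cell-level evaluation of batch
#' mixing. First every cell is classified *positive* or *negative* by local
#' cell-type purity: with `k = min(k_cap, N_y)` (`N_y` = number of cells of
#' the cell's type), a cell is positive iff at least 50% of its `k` nearest
#' neighbours (self excluded) carry its own type. Positive cells are then
#' classified *true positive* by a three-sigma batch-composition rule: for a
#' cell of type `y`, with `N_1..N_n` cells of type `y` per batch and
#' `p_i = N_i / sum_j N_j`, the cell is true positive iff for every batch `i`
#' its neighbourhood batch count `k_i` lies in
#' `[max(0, k p_i - 3 sqrt(k p_i (1 - p_i))), k p_i + 3 sqrt(k p_i (1 - p_i))]`.
#' Cells of types with fewer than two cells are excluded from the summary
#' proportions and counted in a side tally.
#'
#' The rule is space-agnostic: `embedding` may be corrected expression, a PCA,
#' or an external 2-D embedding; the choice is recorded in the report.
#'
#' @param embedding Cells x coordinates matrix.
#' @param celltypes Cell-type label per cell.
#' @param batches Batch label per cell.
#' @param k_cap Neighbourhood size cap (default 100).
#' @param space Free-text tag recording what `embedding` is.
#' @return An object of class `mixture_report`: data frame with per-cell
#'   `label` (`"negative"`, `"false_positive"`, `"true_positive"`),
#'   `k_used`, and one `k_<batch>` neighbourhood count column per batch;
#'   summary proportions are attached as attributes and printed by
#'   [summary.mixture_report()].
#' @export
mixing_report <- function(embedding, celltypes, batches, k_cap = 100,
                          space = "user-supplied") {
  embedding <- as.matrix(embedding)
  celltypes <- as.character(celltypes)
  batches <- as.character(batches)
  stopifnot(nrow(embedding) == length(celltypes),
            nrow(embedding) == length(batches))
  pos <- classify_positive(embedding, celltypes, k_cap = k_cap)
  rep <- classify_true_positive(pos, embedding, celltypes, batches,
                                k_cap = k_cap)
  attr(rep, "space") <- space
  rep
}

# Neighbour index lists ordered by distance (ties by index), self excluded,
# truncated at k_max.
ordered_neighbors <- function(embedding, k_max) {
  d2 <- cross_dist2(embedding, embedding)
  n <- nrow(d2)
  out <- matrix(0L, n, k_max)
  for (i in seq_len(n)) {
    di <- d2[i, ]
    di[i] <- Inf
    out[i, ] <- order(di, seq_len(n))[seq_len(k_max)]
  }
  out
}

#' Classify cells as positive by neighbourhood type purity
#'
#' @inheritParams mixing_report
#' @return Data frame with logical `positive` and integer `k_used` per cell.
#' @export
classify_positive <- function(embedding, celltypes, k_cap = 100) {
  embedding <- as.matrix(embedding)
  celltypes <- as.character(celltypes)
  stopifnot(nrow(embedding) == length(celltypes))
  type_sizes <- table(celltypes)
  if (any(type_sizes < 2))
    warning("cell types with a single cell are marked negative: ",
            paste(names(type_sizes)[type_sizes < 2], collapse = ", "))
  n <- nrow(embedding)
  k_used <- pmin(k_cap, as.integer(type_sizes[celltypes]))
  k_max <- min(max(k_used), n - 1L)
  k_used <- pmin(k_used, n - 1L)
  nb <- ordered_neighbors(embedding, k_max)
  positive <- logical(n)
  for (i in seq_len(n)) {
    if (type_sizes[[celltypes[i]]] < 2) next
    k <- k_used[i]
    same <- sum(celltypes[nb[i, seq_len(k)]] == celltypes[i])
    positive[i] <- same >= 0.5 * k
  }
  data.frame(positive = positive, k_used = k_used)
}

#' Classify positive cells as true positive by the three-sigma rule
#'
#' @param positive Data frame from [classify_positive()] computed on the same
#'   `embedding` and `k_cap`.
#' @inheritParams mixing_report
#' @return A `mixture_report` (see [mixing_report()]).
#' @export
classify_true_positive <- function(positive, embedding, celltypes, batches,
                                   k_cap = 100) {
  embedding <- as.matrix(embedding)
  celltypes <- as.character(celltypes)
  batches <- as.character(batches)
  n <- nrow(embedding)
  stopifnot(nrow(positive) == n, length(celltypes) == n, length(batches) == n)
  batch_ids <- sort(unique(batches))
  nb_count <- length(batch_ids)
  k_used <- positive$k_used
  k_max <- min(max(k_used), n - 1L)
  nb <- ordered_neighbors(embedding, k_max)
  # global per-type batch proportions
  type_batch <- table(celltypes, batches)
  comp <- matrix(0L, n, nb_count,
                 dimnames = list(NULL, paste0("k_", batch_ids)))
  label <- rep("negative", n)
  for (i in seq_len(n)) {
    k <- k_used[i]
    nbi <- nb[i, seq_len(k)]
    ki <- tabulate(match(batches[nbi], batch_ids), nbins = nb_count)
    comp[i, ] <- ki
    if (!positive$positive[i]) next
    Ni <- type_batch[celltypes[i], batch_ids]
    p <- Ni / sum(Ni)
    sdev <- sqrt(k * p * (1 - p))
    lo <- pmax(0, k * p - 3 * sdev)
    hi <- k * p + 3 * sdev
    label[i] <- if (all(ki >= lo & ki <= hi)) "true_positive"
                else "false_positive"
  }
  evaluated <- as.integer(table(celltypes)[celltypes]) >= 2L
  out <- data.frame(label = label, k_used = k_used, celltype = celltypes,
                    batch = batches)
  out <- cbind(out, as.data.frame(comp))
  structure(out,
            evaluated = evaluated,
            n_excluded_singletons = sum(!evaluated),
            class = c("mixture_report", "data.frame"))
}

#' Summary proportions of a mixture report
#'
#' @param report A `mixture_report`.
#' @return Named numeric vector with `positive` and `true_positive`
#'   proportions over all evaluated cells.
#' @export
mixing_summary <- function(report) {
  stopifnot(inherits(report, "mixture_report"))
  ev <- attr(report, "evaluated")
  lab <- report$label[ev]
  c(positive = mean(lab != "negative"),
    true_positive = mean(lab == "true_positive"))
}

#' @export
summary.mixture_report <- function(object, ...) {
  s <- mixing_summary(object)
  cat("mixture report over", sum(attr(object, "evaluated")), "cells",
      if (attr(object, "n_excluded_singletons") > 0)
        paste0("(", attr(object, "n_excluded_singletons"),
               " singleton-type cells excluded)"), "\n")
  cat(sprintf("  positive:      %.3f\n", s["positive"]))
  cat(sprintf("  true positive: %.3f\n", s["true_positive"]))
  invisible(s)
}

#' Write a mixture report as TSV (plus a summary line)
#'
#' @param report A `mixture_report`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_mixture_report <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Principal-component evaluation embedding
#'
#' The package's standard coordinate space for neighbourhood-based
#' evaluation: principal components of the (centred) expression matrix.
#' Nearest-neighbour statistics on a handful of components are far less
#' dominated by per-gene count noise than the same statistics in full gene
#' space, which is the convention for kNN-based mixing metrics.
#'
#' @param x An [expr_set] or a cells x genes matrix.
#' @param n_pcs Number of components (default 30, clipped to the data rank).
#' @return Cells x `n_pcs` matrix of principal-component coordinates.
#' @export
pca_embedding <- function(x, n_pcs = 30) {
  m <- if (inherits(x, "expr_set")) x$matrix else as.matrix(x)
  n_pcs <- min(n_pcs, nrow(m) - 1L, ncol(m))
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE, rank. = n_pcs)
  pc$x[, seq_len(n_pcs), drop = FALSE]
}
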