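#' Specify a multi-batch simulation
#'
#' Describes a seeded multi-batch scRNA-seq-like count simulation with shared
#' and batch-specific cell types, planted marker genes and parameterised
#' gene-wise batch distortions. By default every type draws its own
#' log-normal mean profile (`sdlog = mean_log_sd`) and the
#' `markers_per_type` planted marker genes are amplified `marker_fold`-fold
#' on top; setting `type_jitter_sd` instead makes all types share one base
#' profile with a small per-type jitter, in which case the markers are the
#' dominant type signal. Per batch, a gene-wise additive shift
#' on the log-scale mean (`N(0, shift_sd)`), a gene-wise multiplicative
#' factor (`exp(N(0, mult_sd))`) and an extra dropout probability distort the
#' measurements. Counts are negative binomial with the given dispersion, then
#' thinned by the batch dropout.
#'
#' @param n_genes Number of genes.
#' @param presence Types x batches logical matrix: which types appear in
#'   which batch. At least one type must be present in two or more batches.
#' @param cells Types x batches integer matrix of cell counts (0 where
#'   absent).
#' @param markers_per_type Planted marker genes per type (default 5).
#' @param marker_fold Fold change of marker genes over their base mean
#'   (default 4).
#' @param mean_log_sd sdlog of the log-normal mean profiles (default 1).
#' @param type_jitter_sd `NULL` (default): independent per-type profiles;
#'   a number: per-type log-normal modulation of a single shared base
#'   profile (markers then dominate type identity).
#' @param dispersion Negative-binomial dispersion (`size = 1/dispersion`,
#'   default 0.3).
#' @param shift_sd Per-batch sd of the gene-wise additive log-scale shift
#'   (vector, one per batch; 0 = undistorted reference batch).
#' @param mult_sd Per-batch sd of the gene-wise log multiplicative factor.
#' @param dropout Per-batch extra dropout probability in `[0, 1]`.
#' @param diagnostic_genes Per-batch count of designated batch-diagnostic
#'   genes: genes expressed at their normal level in the designated batch
#'   but suppressed by `diagnostic_shift` log-units everywhere else — a
#'   presence/absence platform signature that adds no extra counts to any
#'   library. Recorded in the ground truth so interpretability checks can
#'   look for them (default 0 per batch).
#' @param diagnostic_shift Log-scale suppression of designated diagnostic
#'   genes outside their batch (default 6).
#' @param base_mean Location (meanlog) of the log-normal type means
#'   (default 0).
#' @return An object of class `simulation_design`.
#' @export
simulation_design <- function(n_genes, presence, cells,
                              markers_per_type = 5, marker_fold = 4,
                              mean_log_sd = 1, type_jitter_sd = NULL,
                              dispersion = 0.3,
                              shift_sd = rep(0, ncol(presence)),
                              mult_sd = rep(0, ncol(presence)),
                              dropout = rep(0, ncol(presence)),
                              diagnostic_genes = rep(0L, ncol(presence)),
                              diagnostic_shift = 6,
                              base_mean = 0) {
  presence <- as.matrix(presence)
  cells <- as.matrix(cells)
  stopifnot(identical(dim(presence), dim(cells)),
            all(cells[!presence] == 0), all(cells[presence] >= 1),
            all(dropout >= 0 & dropout <= 1),
            length(shift_sd) == ncol(presence),
            length(mult_sd) == ncol(presence),
            length(dropout) == ncol(presence),
            length(diagnostic_genes) == ncol(presence),
            all(diagnostic_genes >= 0),
            dispersion > 0, markers_per_type >= 0, marker_fold > 0)
  if (ncol(presence) >= 2 && max(rowSums(presence)) < 2)
    stop("at least one cell type must be present in two or more batches")
  if (is.null(rownames(presence)))
    rownames(presence) <- rownames(cells) <- paste0("type", seq_len(nrow(presence)))
  if (is.null(colnames(presence)))
    colnames(presence) <- colnames(cells) <- paste0("batch", seq_len(ncol(presence)))
  structure(list(n_genes = n_genes, presence = presence, cells = cells,
                 markers_per_type = markers_per_type,
                 marker_fold = marker_fold, mean_log_sd = mean_log_sd,
                 type_jitter_sd = type_jitter_sd,
                 dispersion = dispersion, shift_sd = shift_sd,
                 mult_sd = mult_sd, dropout = dropout,
                 diagnostic_genes = as.integer(diagnostic_genes),
                 diagnostic_shift = diagnostic_shift,
                 base_mean = base_mean),
            class = "simulation_design")
}

#' Named benchmark designs
#'
#' Fixed designs at three scales: `tiny` (2 batches x 80 cells, 60 genes, 3
#' shared types), `small` (2 batches x 400 cells, 200 genes, 4 types with one
#' batch-specific type per batch), `medium` (3 batches x 1000 cells, 2000
#' genes, 6 types with mixed presence). The non-reference batches carry
#' additive (sd 1 log-unit), multiplicative (sd 0.3) and dropout (0.1)
#' distortions — a strong but realistic cross-platform batch effect.
#'
#' @param scale `"tiny"`, `"small"` or `"medium"`.
#' @return A `simulation_design`.
#' @export
default_benchmark_design <- function(scale = c("tiny", "small", "medium")) {
  scale <- match.arg(scale)
  if (scale == "tiny") {
    presence <- matrix(TRUE, 3, 2)
    cells <- matrix(c(30, 30, 20, 30, 30, 20), 3, 2)
    return(simulation_design(60, presence, cells,
                             shift_sd = c(0, 1), mult_sd = c(0, 0.3),
                             dropout = c(0, 0.1), base_mean = 1))
  }
  if (scale == "small") {
    presence <- matrix(c(TRUE, TRUE, TRUE, FALSE,
                         TRUE, TRUE, FALSE, TRUE), 4, 2)
    cells <- matrix(c(150, 150, 100, 0,
                      150, 150, 0, 100), 4, 2)
    return(simulation_design(200, presence, cells,
                             shift_sd = c(0, 1), mult_sd = c(0, 0.3),
                             dropout = c(0, 0.1), base_mean = 1))
  }
  presence <- matrix(TRUE, 6, 3)
  presence[4, 2:3] <- FALSE
  presence[5, c(1, 3)] <- FALSE
  presence[6, 1:2] <- FALSE
  cells <- matrix(0L, 6, 3)
  for (b in 1:3) {
    present <- which(presence[, b])
    cells[present, b] <- diff(round(seq(0, 1000, length.out = length(present) + 1)))
  }
  simulation_design(2000, presence, cells,
                    shift_sd = c(0, 1, 0.7), mult_sd = c(0, 0.3, 0.3),
                    dropout = c(0, 0.1, 0.05), base_mean = 1)
}

#' Simulate a multi-batch count dataset
#'
#' Draws the dataset described by a [simulation_design()] under a seed and
#' returns both the counts and every piece of ground truth needed to evaluate
#' downstream results exactly.
#'
#' @param design A `simulation_design`.
#' @param seed Integer seed.
#' @return A list with `data` (an [expr_set] of raw counts with batch and
#'   cell-type labels) and `truth` (list: `type_means` genes x types matrix,
#'   `markers` per-type gene-id list, `batch_shift`, `batch_mult` genes x
#'   batches matrices, `dropout` per batch).
#' @export
simulate_batches <- function(design, seed = 1) {
  stopifnot(inherits(design, "simulation_design"))
  with_seed(seed, {
    G <- design$n_genes
    types <- rownames(design$presence)
    batches <- colnames(design$presence)
    gene_ids <- paste0("gene", seq_len(G))
    type_means <- if (is.null(design$type_jitter_sd)) {
      sapply(types, function(t)
        stats::rlnorm(G, meanlog = design$base_mean,
                      sdlog = design$mean_log_sd))
    } else {
      base_profile <- stats::rlnorm(G, meanlog = design$base_mean,
                                    sdlog = design$mean_log_sd)
      sapply(types, function(t)
        base_profile * exp(stats::rnorm(G, 0, design$type_jitter_sd)))
    }
    rownames(type_means) <- gene_ids
    markers <- list()
    if (design$markers_per_type > 0) {
      free <- seq_len(G)
      for (t in types) {
        mk <- sample(free, min(design$markers_per_type, length(free)))
        free <- setdiff(free, mk)
        type_means[mk, t] <- type_means[mk, t] * design$marker_fold
        markers[[t]] <- gene_ids[mk]
      }
    }
    batch_shift <- sapply(seq_along(batches), function(b)
      if (design$shift_sd[b] > 0) stats::rnorm(G, 0, design$shift_sd[b])
      else numeric(G))
    batch_mult <- sapply(seq_along(batches), function(b)
      if (design$mult_sd[b] > 0) exp(stats::rnorm(G, 0, design$mult_sd[b]))
      else rep(1, G))
    colnames(batch_shift) <- colnames(batch_mult) <- batches
    rownames(batch_shift) <- rownames(batch_mult) <- gene_ids
    diagnostic <- list()
    if (any(design$diagnostic_genes > 0)) {
      marker_idx <- match(unlist(markers), gene_ids)
      # a detectable platform signature: designate only well-expressed genes
      expressed <- which(rowMeans(type_means) >= stats::median(rowMeans(type_means)))
      free_dg <- setdiff(expressed, marker_idx)
      for (b in seq_along(batches)) {
        if (design$diagnostic_genes[b] == 0) next
        dg <- sample(free_dg, design$diagnostic_genes[b])
        free_dg <- setdiff(free_dg, dg)
        batch_shift[dg, -b] <- batch_shift[dg, -b] - design$diagnostic_shift
        diagnostic[[batches[b]]] <- gene_ids[dg]
      }
    }
    size <- 1 / design$dispersion
    rows <- list(); blab <- list(); tlab <- list()
    for (b in seq_along(batches)) {
      for (t in seq_along(types)) {
        n_ct <- design$cells[t, b]
        if (n_ct == 0) next
        mu <- type_means[, t] * batch_mult[, b] * exp(batch_shift[, b])
        m <- matrix(stats::rnbinom(n_ct * G, mu = rep(mu, each = n_ct),
                                   size = size), n_ct, G)
        if (design$dropout[b] > 0) {
          m[matrix(stats::runif(n_ct * G) < design$dropout[b], n_ct, G)] <- 0
        }
        rows[[length(rows) + 1L]] <- m
        blab[[length(blab) + 1L]] <- rep(batches[b], n_ct)
        tlab[[length(tlab) + 1L]] <- rep(types[t], n_ct)
      }
    }
    counts <- do.call(rbind, rows)
    data <- expr_set(counts,
                     cell_ids = paste0("cell", seq_len(nrow(counts))),
                     gene_ids = gene_ids,
                     batch = unlist(blab), celltype = unlist(tlab),
                     units = "raw_counts")
    list(data = data,
         truth = list(type_means = type_means, markers = markers,
                      diagnostic = diagnostic,
                      batch_shift = batch_shift, batch_mult = batch_mult,
                      dropout = design$dropout))
  })
}
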