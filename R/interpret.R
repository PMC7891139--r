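# Probe classifiers and gene-importance attribution. A probe is a small
# three-layer classifier trained on top of either the frozen stage-one
# encoder's codes (cell-type probe: which genes build the representations) or
# raw expression (batch probe: which genes carry the batch signal).
# Attributions are computed with an expected-gradients backend: integrated
# gradients averaged over a background sample of cells.

# Train a softmax classifier mlp (in -> widths -> n_classes) with Adam and a
# seeded 80/20 split; returns net, class levels, and held-out accuracy.
train_probe_net <- function(X, labels, seed, widths = c(256, 64),
                            epochs = 200, minibatch_size = 32, lr = 1e-3,
                            weight_decay = 1e-3, holdout = 0.2) {
  labels <- as.character(labels)
  sizes <- table(labels)
  if (any(sizes < 5)) {
    drop <- names(sizes)[sizes < 5]
    warning("classes with fewer than 5 cells excluded: ",
            paste(drop, collapse = ", "))
    keep <- !(labels %in% drop)
    X <- X[keep, , drop = FALSE]
    labels <- labels[keep]
  }
  classes <- sort(unique(labels))
  y <- match(labels, classes)
  n <- nrow(X)
  with_seed(seed, {
    net <- mlp_init(c(ncol(X), widths, length(classes)),
                    c(rep("mish", length(widths)), "linear"))
    ord <- sample.int(n)
    n_test <- max(1L, floor(holdout * n))
    test <- ord[seq_len(n_test)]
    train <- ord[-seq_len(n_test)]
    state <- adam_init(net)
    for (ep in seq_len(epochs)) {
      sh <- sample(train)
      for (mb in split(sh, ceiling(seq_along(sh) / minibatch_size))) {
        fwd <- mlp_forward(net, X[mb, , drop = FALSE], cache = TRUE)
        p <- softmax_rows(fwd$out)
        Y <- one_hot(y[mb], length(classes))
        back <- mlp_backward(net, fwd, (p - Y) / length(mb), need_dx = FALSE)
        up <- adam_step(net, list(gW = back$gW, gb = back$gb), state, lr,
                        beta1 = 0.9)
        net <- up$net; state <- up$state
        if (weight_decay > 0)  # decoupled decay concentrates the probe's
          net$W <- lapply(net$W, function(w) w * (1 - lr * weight_decay))
      }
    }
    pred <- max.col(mlp_forward(net, X[test, , drop = FALSE]),
                    ties.method = "first")
    list(net = net, classes = classes, accuracy = mean(pred == y[test]))
  })
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Train a cell-type probe on frozen encoder codes
#'
#' Attaches a three-layer softmax classifier to the output of the trained
#' stage-one encoder and trains it to predict cell types; the encoder's
#' parameters are never updated. Attributions computed from this probe are
#' composed through the encoder, scoring each gene's contribution to the
#' content representations.
#'
#' @param model A trained [build_stage1()] model (the encoder is used frozen).
#' @param X Cells x genes expression matrix (the encoder's input space).
#' @param celltypes Cell-type label per cell; classes with fewer than 5 cells
#'   are excluded with a warning.
#' @param seed Integer seed (split, initialisation, shuffling).
#' @param ... Tuning arguments: `widths` (default `c(256, 64)`), `epochs`
#'   (200), `minibatch_size` (32), `lr` (1e-3), `weight_decay` (1e-3,
#'   decoupled; concentrates attributions on the strongest features),
#'   `holdout` (0.2).
#' @return An object of class `probe_classifier` with elements `net`,
#'   `encoder` (or `NULL`), `classes`, `accuracy`.
#' @export
train_celltype_probe <- function(model, X, celltypes, seed = 1, ...) {
  stopifnot(inherits(model, "stage1_model"))
  codes <- encode(model, X)
  fit <- train_probe_net(codes, celltypes, seed = seed, ...)
  structure(list(net = fit$net, encoder = model$E, classes = fit$classes,
                 accuracy = fit$accuracy, input = "codes"),
            class = "probe_classifier")
}

#' Train a batch-origin probe on expression
#'
#' Trains a three-layer softmax classifier to predict each cell's batch from
#' its (uncorrected) expression profile. Gene attributions from this probe
#' grade each gene's contribution to the batch signal that stage two must
#' remove.
#'
#' @param X Cells x genes expression matrix.
#' @param batches Batch label per cell.
#' @inheritParams train_celltype_probe
#' @return A `probe_classifier`.
#' @export
train_batch_probe <- function(X, batches, seed = 1, ...) {
  fit <- train_probe_net(as.matrix(X), batches, seed = seed, ...)
  structure(list(net = fit$net, encoder = NULL, classes = fit$classes,
                 accuracy = fit$accuracy, input = "expression"),
            class = "probe_classifier")
}

#' @export
print.probe_classifier <- function(x, ...) {
  cat("probe_classifier on", x$input, "->",
      paste(x$classes, collapse = "/"), "\n")
  cat(sprintf("  held-out accuracy: %.3f\n", x$accuracy))
  invisible(x)
}

# Logits and input gradients of the probe chain (optional encoder + probe)
# for a per-row target class.
chain_logit_grad <- function(probe, X, class_idx) {
  fwd_enc <- if (!is.null(probe$encoder))
    mlp_forward(probe$encoder, X, cache = TRUE)
  H <- if (is.null(fwd_enc)) X else fwd_enc$out
  fwd <- mlp_forward(probe$net, H, cache = TRUE)
  d_out <- matrix(0, nrow(X), ncol(fwd$out))
  d_out[cbind(seq_len(nrow(X)), class_idx)] <- 1
  back <- mlp_backward(probe$net, fwd, d_out, need_dx = TRUE)
  grad <- if (is.null(fwd_enc)) back$dX
          else mlp_backward(probe$encoder, fwd_enc, back$dX, need_dx = TRUE)$dX
  list(score = fwd$out[cbind(seq_len(nrow(X)), class_idx)], grad = grad)
}

# Predicted class index per row.
chain_predict <- function(probe, X) {
  H <- if (is.null(probe$encoder)) X else mlp_forward(probe$encoder, X)
  max.col(mlp_forward(probe$net, H), ties.method = "first")
}

#' Per-gene, per-cell importance scores
#'
#' Attributes the probe's predicted-class logit back to input genes with an
#' expected-gradients backend: for each cell, integrated gradients along the
#' straight path from each background cell to the cell (midpoint rule,
#' `n_steps` points) are averaged over the background sample. For additive
#' completeness, per-cell attributions sum to
#' `score(cell) - mean(score(background))` up to quadrature error. When the
#' probe was trained on encoder codes the gradients are composed through the
#' frozen encoder, so scores are still per *gene*.
#'
#' @param probe A `probe_classifier`.
#' @param X Cells x genes matrix of cells to score.
#' @param background Matrix of background cells (same gene space). A sample
#'   of 25-100 cells is typical.
#' @param method Attribution backend; only `"expected_gradients"` is built
#'   in.
#' @param n_steps Quadrature points along each path (default 50).
#' @param target `"predicted"` (default) or an index/name of a fixed class.
#' @return An object of class `importance_table`: cells x genes matrix of
#'   signed scores with the scored class per cell in attribute `"class"`.
#' @export
gene_importance <- function(probe, X, background,
                            method = "expected_gradients", n_steps = 50,
                            target = "predicted") {
  stopifnot(inherits(probe, "probe_classifier"))
  if (!identical(method, "expected_gradients"))
    stop("unknown attribution backend '", method,
         "'; available: expected_gradients")
  X <- as.matrix(X)
  background <- as.matrix(background)
  if (nrow(background) == 0L) stop("background must be nonempty")
  class_idx <- if (identical(target, "predicted")) {
    chain_predict(probe, X)
  } else {
    if (is.character(target)) target <- match(target, probe$classes)
    rep(as.integer(target), nrow(X))
  }
  n <- nrow(X)
  attr_mat <- matrix(0, n, ncol(X))
  alphas <- (seq_len(n_steps) - 0.5) / n_steps
  for (j in seq_len(nrow(background))) {
    bgj <- rep(background[j, ], each = n)
    dim(bgj) <- c(n, ncol(X))
    diff <- X - bgj
    g_acc <- matrix(0, n, ncol(X))
    for (a in alphas) {
      g_acc <- g_acc + chain_logit_grad(probe, bgj + a * diff, class_idx)$grad
    }
    attr_mat <- attr_mat + (g_acc / n_steps) * diff
  }
  attr_mat <- attr_mat / nrow(background)
  colnames(attr_mat) <- colnames(X)
  structure(attr_mat, class = "importance_table",
            scored_class = probe$classes[class_idx])
}

#' Aggregate importance scores by group
#'
#' Per-gene median of the attribution scores within each cell group (for
#' example cell type x batch).
#'
#' @param imp An `importance_table`.
#' @param groups Grouping label per scored cell.
#' @return Data frame with columns `gene`, `group`, `median_score`.
#' @export
aggregate_importance <- function(imp, groups) {
  stopifnot(inherits(imp, "importance_table"))
  m <- unclass(imp)
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(m))
  out <- do.call(rbind, lapply(sort(unique(groups)), function(g) {
    data.frame(gene = colnames(m) %||% paste0("g", seq_len(ncol(m))),
               group = g,
               median_score = apply(m[groups == g, , drop = FALSE], 2L,
                                    stats::median))
  }))
  rownames(out) <- NULL
  out
}

#' Rank genes by overall importance
#'
#' @param imp An `importance_table`.
#' @return Character vector of gene ids ordered by decreasing median absolute
#'   attribution.
#' @export
rank_importance <- function(imp) {
  stopifnot(inherits(imp, "importance_table"))
  m <- abs(unclass(imp))
  med <- apply(m, 2L, stats::median)
  (colnames(m) %||% paste0("g", seq_len(ncol(m))))[order(-med)]
}

#' Write importance scores as TSV
#'
#' Long-format per-cell table (`gene`, `cell`, `score`), plus an optional
#' aggregated per-group table when `groups` is given.
#'
#' @param imp An `importance_table`.
#' @param path Output TSV path.
#' @param cell_ids Optional cell identifiers (default row numbers).
#' @param groups Optional grouping labels; when given, a second file
#'   `<path>.groups.tsv` with per-gene group medians is written.
#' @return `path`, invisibly.
#' @export
write_importance <- function(imp, path, cell_ids = NULL, groups = NULL) {
  stopifnot(inherits(imp, "importance_table"))
  m <- unclass(imp)
  genes <- colnames(m) %||% paste0("g", seq_len(ncol(m)))
  cells <- cell_ids %||% as.character(seq_len(nrow(m)))
  long <- data.frame(gene = rep(genes, each = nrow(m)),
                     cell = rep(cells, ncol(m)),
                     score = as.vector(m))
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(groups)) {
    utils::write.table(aggregate_importance(imp, groups),
                       paste0(path, ".groups.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
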