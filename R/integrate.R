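#' Plan the integration order
#'
#' Computes each batch's total variance (sum of per-gene variances of its
#' log-TPM matrix over the model genes), selects the batch with the largest
#' total variance as the anchor — the batch whose profiles are left
#' uncorrected — and orders the remaining batches by decreasing total
#' variance. Ties break lexicographically by batch id. User overrides are
#' honoured verbatim.
#'
#' @param sets Named list of single-batch [expr_set] objects on a common gene
#'   space, or one multi-batch [expr_set].
#' @param override_anchor Optional batch id to use as anchor.
#' @param override_order Optional explicit ordering of the non-anchor batches.
#' @return An object of class `integration_plan`: list with `anchor`, `order`,
#'   `variances`, `user_override`.
#' @export
plan_integration <- function(sets, override_anchor = NULL,
                             override_order = NULL) {
  if (inherits(sets, "expr_set")) sets <- split_batches(sets)
  stopifnot(length(sets) >= 2L, all(vapply(sets, inherits, TRUE, "expr_set")))
  ids <- names(sets) %||% vapply(sets, function(s) s$batch[1], "")
  names(sets) <- ids
  variances <- vapply(sets, function(s)
    sum(apply(s$matrix, 2L, stats::var)), 0)
  ranked <- ids[order(-variances, ids)]
  anchor <- ranked[1L]
  if (!is.null(override_anchor)) {
    if (!override_anchor %in% ids)
      stop("override_anchor names an unknown batch: ", override_anchor)
    anchor <- override_anchor
  }
  order_ids <- setdiff(ids[order(-variances, ids)], anchor)
  if (!is.null(override_order)) {
    if (!setequal(override_order, setdiff(ids, anchor)))
      stop("override_order must list every non-anchor batch exactly once")
    order_ids <- override_order
  }
  structure(list(anchor = anchor, order = order_ids, variances = variances,
                 user_override = !is.null(override_anchor) ||
                   !is.null(override_order)),
            class = "integration_plan")
}

#' @export
print.integration_plan <- function(x, ...) {
  cat("integration_plan: anchor =", x$anchor,
      if (x$user_override) "(user override)", "\n")
  cat("  order:", paste(x$order, collapse = " -> "), "\n")
  cat("  total variances:",
      paste(names(x$variances), round(x$variances, 2), sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

# Pair one source batch against the anchor pool in code space and train a
# stage-two GAN on the rwMNN pairs. Returns NULL when no seed pairs exist.
pair_and_train <- function(src_expr, src_codes, pool_expr, pool_codes,
                           config, seed, verbose = FALSE) {
  sub_src <- with_seed(derive_seed(seed, "subsample_src"),
                       subsample_cells(nrow(src_expr), config$s))
  sub_pool <- with_seed(derive_seed(seed, "subsample_pool"),
                        subsample_cells(nrow(pool_expr), config$s))
  pp <- pair_params(s = config$s, n_a = length(sub_src),
                    n_b = length(sub_pool), m = config$m)
  seeds <- mutual_nn_pairs(src_codes[sub_src, , drop = FALSE],
                           pool_codes[sub_pool, , drop = FALSE],
                           k = pp$k, exact = config$exact)
  if (nrow(seeds) == 0L) return(NULL)
  knn_a <- knn_within(src_codes[sub_src, , drop = FALSE], pp$k1,
                      exact = config$exact)
  knn_b <- knn_within(pool_codes[sub_pool, , drop = FALSE], pp$k1,
                      exact = config$exact)
  pairs <- with_seed(derive_seed(seed, "walk"),
                     random_walk_extend(seeds, knn_a, knn_b, m = pp$m,
                                        dedup = config$dedup))
  gan <- build_gan(d = ncol(src_expr), l = config$l_gan,
                   widths = config$widths_gan,
                   learning_rate = config$lr_stage2,
                   critic_lr = config$critic_lr,
                   betas = config$betas_stage2,
                   gp_weight = config$gp_weight,
                   critic_steps = config$critic_steps,
                   seed = derive_seed(seed, "gan_init"))
  fit <- train_stage2(gan, pairs,
                      X_source = src_expr[sub_src, , drop = FALSE],
                      X_anchor = pool_expr[sub_pool, , drop = FALSE],
                      epochs = config$epochs_stage2,
                      minibatch_size = config$minibatch_stage2,
                      seed = derive_seed(seed, "gan_train"),
                      verbose = verbose)
  list(model = fit$model, log = fit$log, n_seeds = attr(pairs, "M_seeds"),
       n_pairs = nrow(pairs))
}

integration_config <- function(l = 256, widths = c(1024, 512),
                               l_gan = l, widths_gan = c(widths, 512),
                               lambda_c = 3, lambda_r = 1,
                               lr_stage1 = 5e-4, lr_stage2 = 2e-4,
                               critic_lr = lr_stage2,
                               betas_stage2 = c(0.5, 0.999),
                               epochs_stage1 = 150, epochs_stage2 = 150,
                               minibatch_stage1 = 256, minibatch_stage2 = 256,
                               s = 3000, m = 50, gp_weight = 10,
                               critic_steps = 5, exact = TRUE,
                               dedup = FALSE) {
  as.list(environment())
}

#' Integrate batches by two-stage adversarial correction
#'
#' The end-to-end pipeline: stage one is trained once, jointly on all
#' batches, to produce batch-ignorant content codes; then, following the
#' integration plan, each non-anchor batch is paired against the current
#' anchor pool (mutual nearest neighbours in code space, extended by random
#' walks), a fresh stage-two GAN is trained on the pairs, the whole batch is
#' transformed by the trained generator, and the corrected cells are appended
#' to the anchor pool for subsequent rounds. Anchor cells pass through
#' unchanged.
#'
#' If a batch yields no seed pairs against the anchor pool it is appended
#' uncorrected with a warning and flagged in the provenance table.
#'
#' @param es A preprocessed multi-batch [expr_set] (`units = "log_tpm"`,
#'   restricted to the model genes; see [preprocess()]).
#' @param anchor,order Optional overrides forwarded to [plan_integration()].
#' @param epochs_stage1,epochs_stage2 Training epochs per stage (default 150
#'   each).
#' @param l Content-code dimension (default 256).
#' @param widths Hidden widths `c(w1, w2)` shared by the stage-one networks
#'   and the generator (default `c(1024, 512)`).
#' @param w3 Critic hidden width (default 512).
#' @param seed Global seed; every stochastic component derives its own seed
#'   from it.
#' @param verbose Print progress.
#' @param ... Further settings overriding `integration_config()` defaults
#'   (`s`, `m`, `gp_weight`, `critic_steps`, `minibatch_stage1`,
#'   `minibatch_stage2`, `lambda_c`, `lambda_r`, `lr_stage1`, `lr_stage2`,
#'   `exact`, `dedup`).
#' @return An object of class `batch_integration` with elements `corrected`
#'   (an [expr_set] in the input cell order), `stage1`, `stage1_report`,
#'   `codes`, `plan`, `rounds` (per-round pair counts, GAN models and logs),
#'   `provenance` (data frame: cell_id, batch, round, corrected), `config`,
#'   `seed`.
#' @export
integrate_batches <- function(es, anchor = NULL, order = NULL,
                              epochs_stage1 = 150, epochs_stage2 = 150,
                              l = 256, widths = c(1024, 512), w3 = 512,
                              seed = 1, verbose = FALSE, ...) {
  stopifnot(inherits(es, "expr_set"))
  if (es$units != "log_tpm")
    stop("integrate_batches expects log-TPM input; run preprocess() first")
  config <- utils::modifyList(
    integration_config(l = l, widths = widths, widths_gan = c(widths, w3),
                       epochs_stage1 = epochs_stage1,
                       epochs_stage2 = epochs_stage2),
    list(...))
  sets <- split_batches(es)
  if (length(sets) < 2L) stop("need at least two batches to integrate")
  plan <- plan_integration(sets, override_anchor = anchor,
                           override_order = order)

  # Stage one: joint training over all batches
  d <- ncol(es$matrix)
  n <- length(sets)
  s1 <- build_stage1(d = d, n = n, l = config$l, widths = config$widths,
                     lambda_c = config$lambda_c, lambda_r = config$lambda_r,
                     learning_rate = config$lr_stage1,
                     seed = derive_seed(seed, "stage1_init"))
  s1_fit <- train_stage1(s1, es, epochs = config$epochs_stage1,
                         minibatch_size = config$minibatch_stage1,
                         seed = derive_seed(seed, "stage1_train"),
                         verbose = verbose)
  s1 <- s1_fit$model
  codes <- encode(s1, es$matrix)

  # Incremental stage two over the plan; the anchor pool grows each round.
  pool_idx <- which(es$batch == plan$anchor)
  corrected <- es$matrix
  prov <- data.frame(cell_id = es$cell_ids, batch = es$batch,
                     round = ifelse(es$batch == plan$anchor, 0L, NA_integer_),
                     corrected = FALSE)
  rounds <- list()
  for (r in seq_along(plan$order)) {
    bid <- plan$order[r]
    src_idx <- which(es$batch == bid)
    if (verbose) message("round ", r, ": integrating ", bid)
    res <- pair_and_train(
      src_expr = es$matrix[src_idx, , drop = FALSE],
      src_codes = codes[src_idx, , drop = FALSE],
      pool_expr = corrected[pool_idx, , drop = FALSE],
      pool_codes = codes[pool_idx, , drop = FALSE],
      config = config, seed = derive_seed(seed, paste0("round", r)),
      verbose = verbose)
    if (is.null(res)) {
      warning("batch ", bid, " yielded no seed pairs against the anchor ",
              "pool; appended uncorrected")
      rounds[[bid]] <- list(n_seeds = 0L, n_pairs = 0L, model = NULL,
                            log = NULL, corrected = FALSE)
    } else {
      corrected[src_idx, ] <- gan_transform(res$model,
                                            es$matrix[src_idx, , drop = FALSE])
      prov$corrected[src_idx] <- TRUE
      rounds[[bid]] <- c(res, list(corrected = TRUE))
    }
    prov$round[src_idx] <- r
    pool_idx <- c(pool_idx, src_idx)
  }
  out_es <- expr_set(corrected, es$cell_ids, es$gene_ids, batch = es$batch,
                     celltype = es$celltype, units = "log_tpm")
  structure(list(corrected = out_es, stage1 = s1,
                 stage1_report = s1_fit$report, codes = codes, plan = plan,
                 rounds = rounds, provenance = prov, config = config,
                 seed = seed),
            class = "batch_integration")
}

#' @export
print.batch_integration <- function(x, ...) {
  cat("batch_integration of", length(x$rounds) + 1L, "batches,",
      nrow(x$corrected$matrix), "cells x", ncol(x$corrected$matrix),
      "genes\n")
  cat("  anchor:", x$plan$anchor, "(uncorrected)\n")
  for (bid in names(x$rounds)) {
    r <- x$rounds[[bid]]
    cat("  ", bid, ": ", r$n_seeds, " seed pairs, ", r$n_pairs,
        " rwMNN pairs", if (!r$corrected) " [NOT corrected]", "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.batch_integration <- function(object, ...) {
  print(object)
  rep <- object$stage1_report
  if (nrow(rep) > 0)
    cat(sprintf("  stage-1 loss: %.4f (first epoch) -> %.4f (last)\n",
                rep$total[1], rep$total[nrow(rep)]))
  for (bid in names(object$rounds)) {
    lg <- object$rounds[[bid]]$log
    if (!is.null(lg) && nrow(lg) > 0)
      cat(sprintf("  %s critic loss: %.4f -> %.4f over %d steps\n", bid,
                  lg$critic_loss[1], lg$critic_loss[nrow(lg)], nrow(lg)))
  }
  invisible(object)
}

#' @export
plot.batch_integration <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  rep <- x$stage1_report
  if (nrow(rep) > 0) {
    graphics::matplot(rep$epoch, cbind(rep$L_r, rep$L_c), type = "l",
                      lty = 1, col = c("black", "red"),
                      xlab = "epoch", ylab = "loss", main = "stage 1")
    graphics::legend("topright", c("L_r", "L_c"), lty = 1,
                     col = c("black", "red"), bty = "n")
  }
  logs <- Filter(Negate(is.null), lapply(x$rounds, `[[`, "log"))
  if (length(logs) > 0) {
    lg <- logs[[1]]
    graphics::plot(lg$step, lg$critic_loss, type = "l", xlab = "step",
                   ylab = "critic loss", main = "stage 2 (first round)")
  }
  invisible(x)
}

#' Correct new cells with a fitted integration
#'
#' Applies the stage-two generator trained for `batch` to new expression
#' rows; with no `newdata`, returns the corrected matrix of the fit.
#'
#' @param object A `batch_integration`.
#' @param newdata Optional cells x genes matrix on the model gene space.
#' @param batch Which trained round's generator to apply (batch id; required
#'   with `newdata`).
#' @param ... Unused.
#' @return Corrected matrix.
#' @export
predict.batch_integration <- function(object, newdata = NULL, batch = NULL,
                                      ...) {
  if (is.null(newdata)) return(object$corrected$matrix)
  if (is.null(batch)) stop("specify which batch's generator to apply")
  r <- object$rounds[[batch]]
  if (is.null(r)) stop("no trained round for batch ", batch,
                       " (is it the anchor?)")
  if (!r$corrected) stop("batch ", batch, " was appended uncorrected")
  gan_transform(r$model, newdata)
}

#' Whole-transcriptome correction by gene chunking
#'
#' Corrects the full (shared) gene space instead of only the highly variable
#' genes: the genes are randomly partitioned into `n_chunks` near-equal
#' chunks, the rwMNN pairs are computed once per integration round from the
#' stage-one codes (trained on the HVGs), and one independent stage-two GAN
#' is trained per chunk and per round. Corrected chunks are reassembled in
#' the original gene order.
#'
#' @param es_full Multi-batch [expr_set] over the full shared gene list
#'   (log-TPM).
#' @param fit A `batch_integration` fitted on the HVG set of the same cells
#'   (provides codes and plan).
#' @param n_chunks Number of gene chunks (default 10).
#' @param seed Global seed.
#' @param verbose Print progress.
#' @param ... Config overrides as in [integrate_batches()].
#' @return A `batch_integration`-like list with the corrected full
#'   [expr_set], provenance and per-round per-chunk pair counts.
#' @export
correct_full_transcriptome <- function(es_full, fit, n_chunks = 10, seed = 1,
                                       verbose = FALSE, ...) {
  stopifnot(inherits(es_full, "expr_set"), inherits(fit, "batch_integration"))
  if (!identical(es_full$cell_ids, fit$corrected$cell_ids))
    stop("es_full must contain exactly the cells of the fit")
  config <- utils::modifyList(fit$config, list(...))
  partition <- chunk_genes(es_full$gene_ids, n_chunks = n_chunks,
                           seed = derive_seed(seed, "chunks"))
  if (any(lengths(partition$chunks) < 2))
    stop("a chunk has fewer than 2 genes; use fewer chunks")
  codes <- fit$codes
  plan <- fit$plan
  pool_idx <- which(es_full$batch == plan$anchor)
  corrected <- es_full$matrix
  prov <- data.frame(cell_id = es_full$cell_ids, batch = es_full$batch,
                     round = ifelse(es_full$batch == plan$anchor, 0L,
                                    NA_integer_),
                     corrected = FALSE)
  rounds <- list()
  for (r in seq_along(plan$order)) {
    bid <- plan$order[r]
    src_idx <- which(es_full$batch == bid)
    rseed <- derive_seed(seed, paste0("round", r))
    sub_src <- with_seed(derive_seed(rseed, "subsample_src"),
                         subsample_cells(length(src_idx), config$s))
    sub_pool <- with_seed(derive_seed(rseed, "subsample_pool"),
                          subsample_cells(length(pool_idx), config$s))
    pp <- pair_params(s = config$s, n_a = length(sub_src),
                      n_b = length(sub_pool), m = config$m)
    src_codes <- codes[src_idx[sub_src], , drop = FALSE]
    pool_codes <- codes[pool_idx[sub_pool], , drop = FALSE]
    seeds <- mutual_nn_pairs(src_codes, pool_codes, k = pp$k,
                             exact = config$exact)
    if (nrow(seeds) == 0L) {
      warning("batch ", bid, " yielded no seed pairs; appended uncorrected")
      rounds[[bid]] <- list(n_seeds = 0L, n_pairs = 0L, corrected = FALSE)
      prov$round[src_idx] <- r
      pool_idx <- c(pool_idx, src_idx)
      next
    }
    knn_a <- knn_within(src_codes, pp$k1, exact = config$exact)
    knn_b <- knn_within(pool_codes, pp$k1, exact = config$exact)
    pairs <- with_seed(derive_seed(rseed, "walk"),
                       random_walk_extend(seeds, knn_a, knn_b, m = pp$m,
                                          dedup = config$dedup))
    chunk_info <- integer(length(partition$chunks))
    for (ci in seq_along(partition$chunks)) {
      gidx <- match(partition$chunks[[ci]], es_full$gene_ids)
      gan <- build_gan(d = length(gidx), l = config$l_gan,
                       widths = config$widths_gan,
                       learning_rate = config$lr_stage2,
                       critic_lr = config$critic_lr,
                       betas = config$betas_stage2,
                       gp_weight = config$gp_weight,
                       critic_steps = config$critic_steps,
                       seed = derive_seed(rseed, paste0("gan_init", ci)))
      gfit <- train_stage2(
        gan, pairs,
        X_source = es_full$matrix[src_idx[sub_src], gidx, drop = FALSE],
        X_anchor = corrected[pool_idx[sub_pool], gidx, drop = FALSE],
        epochs = config$epochs_stage2,
        minibatch_size = config$minibatch_stage2,
        seed = derive_seed(rseed, paste0("gan_train", ci)),
        verbose = verbose)
      corrected[src_idx, gidx] <-
        gan_transform(gfit$model, es_full$matrix[src_idx, gidx, drop = FALSE])
      chunk_info[ci] <- length(gidx)
    }
    prov$corrected[src_idx] <- TRUE
    prov$round[src_idx] <- r
    rounds[[bid]] <- list(n_seeds = attr(pairs, "M_seeds"),
                          n_pairs = nrow(pairs), chunk_sizes = chunk_info,
                          corrected = TRUE)
    pool_idx <- c(pool_idx, src_idx)
  }
  list(corrected = expr_set(corrected, es_full$cell_ids, es_full$gene_ids,
                            batch = es_full$batch,
                            celltype = es_full$celltype, units = "log_tpm"),
       plan = plan, partition = partition, rounds = rounds,
       provenance = prov, seed = seed)
}
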