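#' Build the stage-one disentangling model
#'
#' Constructs the three feed-forward networks of the first stage: the content
#' encoder `E` (d -> w1 -> w2 -> l), the measurement-noise generator `G1`
#' (n -> w2 -> w1 -> d) and the reconstruction generator `G2`
#' ((n + l) -> w2 -> w1 -> d). The first two layers of every network use the
#' Mish activation and the last layer is linear. The full reconstruction is
#' `G(E(x), b) = f(G1(b) + G2(E(x), b))` with `f` an elementwise
#' non-negativity map (ReLU by default), so reconstructed profiles live on
#' the same non-negative scale as the log-TPM inputs.
#'
#' @param d Number of input genes.
#' @param n Number of batches (length of the one-hot batch indicator).
#' @param l Content-code dimension (default 256).
#' @param widths Hidden widths `c(w1, w2)` (default `c(1024, 512)`).
#' @param lambda_c Weight of the content loss (default 3).
#' @param lambda_r Weight of the reconstruction loss (default 1).
#' @param learning_rate Adam learning rate (default 5e-4).
#' @param seed Integer seed for parameter initialisation.
#' @return An object of class `stage1_model`.
#' @export
build_stage1 <- function(d, n, l = 256, widths = c(1024, 512),
                         lambda_c = 3, lambda_r = 1,
                         learning_rate = 5e-4, seed = 1) {
  stopifnot(d >= 1, n >= 1, l >= 1, length(widths) == 2, all(widths >= 1),
            lambda_c > 0, lambda_r > 0, learning_rate > 0)
  w1 <- widths[1]; w2 <- widths[2]
  nets <- with_seed(seed, list(
    E = mlp_init(c(d, w1, w2, l), c("mish", "mish", "linear")),
    G1 = mlp_init(c(n, w2, w1, d), c("mish", "mish", "linear")),
    G2 = mlp_init(c(n + l, w2, w1, d), c("mish", "mish", "linear"))
  ))
  structure(list(E = nets$E, G1 = nets$G1, G2 = nets$G2, f = "relu",
                 lambda_c = lambda_c, lambda_r = lambda_r,
                 learning_rate = learning_rate,
                 dims = c(d = d, n = n, l = l, w1 = w1, w2 = w2),
                 batch_levels = NULL, seed = seed),
            class = "stage1_model")
}

#' @export
print.stage1_model <- function(x, ...) {
  d <- x$dims
  cat("stage1_model: encoder", d["d"], "->", d["w1"], "->", d["w2"], "->",
      d["l"], "\n")
  cat("  generators G1:", d["n"], "-> ... ->", d["d"],
      " G2:", d["n"] + d["l"], "-> ... ->", d["d"], "\n")
  cat("  lambda_c =", x$lambda_c, ", lambda_r =", x$lambda_r,
      ", lr =", x$learning_rate, "\n")
  if (!is.null(x$batch_levels))
    cat("  trained on batches:", paste(x$batch_levels, collapse = ", "), "\n")
  invisible(x)
}

# One-hot matrix (rows = cells) from integer batch indices.
one_hot <- function(idx, n) {
  m <- matrix(0, length(idx), n)
  m[cbind(seq_along(idx), idx)] <- 1
  m
}

#' Sample a random one-hot batch indicator
#'
#' Draws the hot index uniformly from `1..n` using the current RNG stream.
#' These resampled indicators drive the content loss: a well-trained model
#' must fabricate a plausible cell with the same biological content under any
#' batch indicator.
#'
#' @param n Number of batches.
#' @param size Number of indicators to draw (default 1).
#' @return A `size` x `n` binary matrix with exactly one 1 per row.
#' @export
sample_random_batch_indicator <- function(n, size = 1) {
  stopifnot(n >= 1, size >= 1)
  one_hot(sample.int(n, size, replace = TRUE), n)
}

#' Reconstruct expression profiles
#'
#' Computes `f(G1(b) + G2(E(x), b))` for each row of `x`; the output is
#' non-negative elementwise.
#'
#' @param model A [build_stage1()] model.
#' @param x Expression vector or cells x genes matrix (log-TPM scale).
#' @param b One-hot batch indicator vector or matrix with matching rows.
#' @return Reconstructed matrix with the shape of `x`.
#' @export
reconstruct <- function(model, x, b) {
  stopifnot(inherits(model, "stage1_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (is.null(dim(b))) b <- matrix(b, nrow = 1L)
  if (ncol(x) != model$dims[["d"]])
    stop("x has ", ncol(x), " genes but the model expects ", model$dims[["d"]])
  if (ncol(b) != model$dims[["n"]])
    stop("b has length ", ncol(b), " but the model expects ", model$dims[["n"]])
  if (nrow(b) != nrow(x)) stop("x and b disagree on the number of cells")
  C <- mlp_forward(model$E, x)
  pre <- mlp_forward(model$G1, b) + mlp_forward(model$G2, cbind(C, b))
  act_apply(model$f, pre)
}

#' Encode cells into content codes
#'
#' Applies the encoder row-wise; the resulting l-dimensional codes are the
#' pairing space for stage two.
#'
#' @param model A [build_stage1()] model.
#' @param X Cells x genes matrix.
#' @return Cells x l code matrix.
#' @export
encode <- function(model, X) {
  stopifnot(inherits(model, "stage1_model"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (ncol(X) != model$dims[["d"]])
    stop("X has ", ncol(X), " genes but the model expects ", model$dims[["d"]])
  mlp_forward(model$E, X)
}

#' Stage-one losses
#'
#' `reconstruction_loss` is the minibatch mean of the squared Euclidean
#' distance between `G(E(x), b)` and `x`; `content_loss` is the minibatch
#' mean of the squared distance between the code of the fabricated cell,
#' `E(G(E(x), b_tilde))`, and the original code `E(x)`.
#'
#' @param model A [build_stage1()] model.
#' @param X Minibatch matrix (cells x genes).
#' @param B One-hot indicator matrix: true indicators for
#'   `reconstruction_loss`, randomly resampled ones for `content_loss`.
#' @return A non-negative scalar.
#' @export
reconstruction_loss <- function(model, X, B) {
  R <- reconstruct(model, X, B)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  mean(rowSums((R - X)^2))
}

#' @rdname reconstruction_loss
#' @export
content_loss <- function(model, X, B) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  C <- encode(model, X)
  fab <- reconstruct(model, X, B)
  Ct <- encode(model, fab)
  mean(rowSums((Ct - C)^2))
}

# Forward + backward pass for one stage-one minibatch. Returns the two loss
# values and parameter gradients for E, G1, G2 (E accumulates gradients from
# both of its applications; no stop-gradient on the content-loss target).
stage1_grads <- function(model, X, Bmat, Btil) {
  B <- nrow(X)
  lc <- model$lambda_c; lr <- model$lambda_r
  fE <- mlp_forward(model$E, X, cache = TRUE)
  C <- fE$out
  # reconstruction path (true indicator)
  fG1r <- mlp_forward(model$G1, Bmat, cache = TRUE)
  fG2r <- mlp_forward(model$G2, cbind(C, Bmat), cache = TRUE)
  Sr <- fG1r$out + fG2r$out
  R <- act_apply(model$f, Sr)
  L_r <- mean(rowSums((R - X)^2))
  # fabrication path (random indicator)
  fG1t <- mlp_forward(model$G1, Btil, cache = TRUE)
  fG2t <- mlp_forward(model$G2, cbind(C, Btil), cache = TRUE)
  St <- fG1t$out + fG2t$out
  Rt <- act_apply(model$f, St)
  fEt <- mlp_forward(model$E, Rt, cache = TRUE)
  Ct <- fEt$out
  L_c <- mean(rowSums((Ct - C)^2))

  l <- model$dims[["l"]]
  # backward: reconstruction term
  dR <- 2 * lr * (R - X) / B
  dSr <- dR * act_deriv(model$f, Sr)
  bG2r <- mlp_backward(model$G2, fG2r, dSr, need_dx = TRUE)
  bG1r <- mlp_backward(model$G1, fG1r, dSr, need_dx = FALSE)
  dC <- bG2r$dX[, seq_len(l), drop = FALSE]
  # backward: content term
  dCt <- 2 * lc * (Ct - C) / B
  bEt <- mlp_backward(model$E, fEt, dCt, need_dx = TRUE)
  dSt <- bEt$dX * act_deriv(model$f, St)
  bG2t <- mlp_backward(model$G2, fG2t, dSt, need_dx = TRUE)
  bG1t <- mlp_backward(model$G1, fG1t, dSt, need_dx = FALSE)
  dC <- dC + bG2t$dX[, seq_len(l), drop = FALSE] - dCt
  bE <- mlp_backward(model$E, fE, dC, need_dx = FALSE)

  list(L_r = L_r, L_c = L_c,
       gE = grads_add(list(gW = bE$gW, gb = bE$gb),
                      list(gW = bEt$gW, gb = bEt$gb)),
       gG1 = grads_add(list(gW = bG1r$gW, gb = bG1r$gb),
                       list(gW = bG1t$gW, gb = bG1t$gb)),
       gG2 = grads_add(list(gW = bG2r$gW, gb = bG2r$gb),
                       list(gW = bG2t$gW, gb = bG2t$gb)))
}

#' Train the stage-one model
#'
#' Minimises `lambda_c * L_c + lambda_r * L_r` with Adam
#' (betas 0.5/0.999). Each minibatch uses every cell's true batch indicator
#' for the reconstruction loss and a freshly resampled random indicator for
#' the content loss.
#'
#' @param model A [build_stage1()] model.
#' @param data An [expr_set] (log-TPM, restricted to the training genes) or a
#'   list with elements `X` (matrix) and `batch` (labels).
#' @param epochs Number of passes over the cells (default 150).
#' @param minibatch_size Cells per minibatch (default 256).
#' @param seed Integer seed controlling shuffling and indicator resampling.
#' @param engine `"cpp"` (default, compiled fast path) or `"R"` (pure-R
#'   reference implementation; same arithmetic, used for verification).
#' @param verbose Print per-epoch losses.
#' @return A list with the trained `model` and a `report` data frame with
#'   per-epoch columns `epoch`, `L_r`, `L_c`, `total`.
#' @export
train_stage1 <- function(model, data, epochs = 150, minibatch_size = 256,
                         seed = 1, engine = c("cpp", "R"), verbose = FALSE) {
  stopifnot(inherits(model, "stage1_model"), epochs >= 0)
  engine <- match.arg(engine)
  if (inherits(data, "expr_set")) {
    X <- data$matrix; batch <- data$batch
  } else {
    X <- data$X; batch <- data$batch
  }
  levels <- model$batch_levels %||% sort(unique(batch))
  if (length(levels) != model$dims[["n"]])
    stop("data has ", length(levels), " batches but the model expects ",
         model$dims[["n"]])
  model$batch_levels <- levels
  bidx <- match(batch, levels)
  if (anyNA(bidx)) stop("batch labels not covered by the model's batches")
  n <- model$dims[["n"]]
  report <- data.frame(epoch = integer(), L_r = numeric(), L_c = numeric(),
                       total = numeric())
  if (epochs == 0) return(list(model = model, report = report))
  if (engine == "cpp") {
    res <- with_seed(seed,
      cpp_train_stage1(model$E, model$G1, model$G2, X, bidx, n,
                       model$lambda_c, model$lambda_r, model$learning_rate,
                       epochs, minibatch_size, 0.5, 0.999))
    for (nm in c("E", "G1", "G2")) {
      model[[nm]]$W <- lapply(res[[nm]]$W, identity)
      model[[nm]]$b <- lapply(res[[nm]]$b, as.vector)
    }
    report <- data.frame(epoch = seq_len(epochs), L_r = res$L_r, L_c = res$L_c,
                         total = model$lambda_c * res$L_c +
                           model$lambda_r * res$L_r)
    if (verbose)
      message(sprintf("stage 1: L_r %.4f -> %.4f over %d epochs",
                      report$L_r[1], report$L_r[epochs], epochs))
    return(list(model = model, report = report))
  }
  states <- list(E = adam_init(model$E), G1 = adam_init(model$G1),
                 G2 = adam_init(model$G2))
  model <- with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(nrow(X))
      splits <- split(ord, ceiling(seq_along(ord) / minibatch_size))
      lr_sum <- lc_sum <- 0
      for (mb in splits) {
        Bmat <- one_hot(bidx[mb], n)
        Btil <- sample_random_batch_indicator(n, length(mb))
        g <- stage1_grads(model, X[mb, , drop = FALSE], Bmat, Btil)
        if (!is.finite(g$L_r) || !is.finite(g$L_c))
          stop("non-finite stage-one loss at epoch ", ep)
        up <- adam_step(model$E, g$gE, states$E, model$learning_rate)
        model$E <- up$net; states$E <- up$state
        up <- adam_step(model$G1, g$gG1, states$G1, model$learning_rate)
        model$G1 <- up$net; states$G1 <- up$state
        up <- adam_step(model$G2, g$gG2, states$G2, model$learning_rate)
        model$G2 <- up$net; states$G2 <- up$state
        lr_sum <- lr_sum + g$L_r * length(mb)
        lc_sum <- lc_sum + g$L_c * length(mb)
      }
      L_r <- lr_sum / nrow(X); L_c <- lc_sum / nrow(X)
      report[ep, ] <- list(ep, L_r, L_c,
                           model$lambda_c * L_c + model$lambda_r * L_r)
      if (verbose)
        message(sprintf("epoch %d: L_r %.4f L_c %.4f", ep, L_r, L_c))
    }
    model
  })
  list(model = model, report = report)
}
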