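#' Build the stage-two GAN
#'
#' The generator is a residual map `G'(x) = f(F(x) + x)` where `F` is an
#' autoencoder-shaped network `d -> w1 -> w2 -> l -> w2 -> w1 -> d` with Mish
#' activations on the hidden layers, a linear bottleneck and a linear output
#' (the residual must be able to take any sign to push expression both up and
#' down), and `f` is an elementwise ReLU, so corrected profiles are
#' non-negative. The critic
#' is a three-layer network `d -> w3 -> w3 -> 1` (Mish, Mish, linear). The
#' adversarial game is trained with the Wasserstein objective plus a gradient
#' penalty pushing the critic towards unit gradient norm on real/fake
#' interpolates.
#'
#' @param d Number of genes.
#' @param l Bottleneck dimension of the generator (default 256).
#' @param widths Hidden widths `c(w1, w2, w3)` (default `c(1024, 512, 512)`).
#' @param learning_rate Adam learning rate for the generator (default 2e-4).
#' @param critic_lr Adam learning rate for the critic (defaults to
#'   `learning_rate`).
#' @param betas Adam moment parameters shared by both networks (default
#'   `c(0.5, 0.999)`).
#' @param gp_weight Gradient-penalty coefficient (default 10).
#' @param critic_steps Critic updates per generator update (default 5).
#' @param seed Integer seed for parameter initialisation.
#' @return An object of class `gan_model`.
#' @export
build_gan <- function(d, l = 256, widths = c(1024, 512, 512),
                      learning_rate = 2e-4, critic_lr = learning_rate,
                      betas = c(0.5, 0.999), gp_weight = 10,
                      critic_steps = 5, seed = 1) {
  stopifnot(d >= 1, l >= 1, length(widths) == 3, all(widths >= 1),
            learning_rate > 0, critic_lr > 0, gp_weight >= 0,
            critic_steps >= 1)
  w1 <- widths[1]; w2 <- widths[2]; w3 <- widths[3]
  nets <- with_seed(seed, list(
    F = mlp_init(c(d, w1, w2, l, w2, w1, d),
                 c("mish", "mish", "linear", "mish", "mish", "linear")),
    D = mlp_init(c(d, w3, w3, 1), c("mish", "mish", "linear"))
  ))
  structure(list(F = nets$F, D = nets$D, f = "relu",
                 learning_rate = learning_rate, critic_lr = critic_lr,
                 betas = betas, gp_weight = gp_weight,
                 critic_steps = critic_steps,
                 dims = c(d = d, l = l, w1 = w1, w2 = w2, w3 = w3),
                 seed = seed),
            class = "gan_model")
}

#' @export
print.gan_model <- function(x, ...) {
  d <- x$dims
  cat("gan_model: generator G'(x) = relu(F(x) + x), F:",
      paste(c(d["d"], d["w1"], d["w2"], d["l"], d["w2"], d["w1"], d["d"]),
            collapse = " -> "), "\n")
  cat("  critic:", d["d"], "->", d["w3"], "->", d["w3"], "-> 1\n")
  cat("  lr =", x$learning_rate, ", gp_weight =", x$gp_weight,
      ", critic_steps =", x$critic_steps, "\n")
  invisible(x)
}

#' Transform cells with the trained generator
#'
#' Applies `G'(x) = relu(F(x) + x)` row-wise to every cell, including cells
#' that never appeared in any training pair.
#'
#' @param model A [build_gan()] model.
#' @param X Cells x genes matrix on the source batch's scale.
#' @return Corrected matrix of the same shape, non-negative elementwise.
#' @export
gan_transform <- function(model, X) {
  stopifnot(inherits(model, "gan_model"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (ncol(X) != model$dims[["d"]])
    stop("X has ", ncol(X), " genes but the model expects ", model$dims[["d"]])
  act_apply(model$f, mlp_forward(model$F, X) + X)
}

#' @export
predict.gan_model <- function(object, newdata, ...) gan_transform(object, newdata)

#' Wasserstein critic objective with gradient penalty
#'
#' Computes `mean(D'(fake)) - mean(D'(real))` plus
#' `gp_weight * mean((||grad D'(xhat)|| - 1)^2)` where each interpolate
#' `xhat` is drawn uniformly on the segment between a paired real and fake
#' sample.
#'
#' @param model A [build_gan()] model.
#' @param x_real Anchor-batch minibatch (rows match `x_fake`).
#' @param x_fake Generated minibatch.
#' @param gp_weight Gradient-penalty coefficient (defaults to the model's).
#' @param eps Optional interpolation coefficients in `[0,1]`, one per row;
#'   drawn from the current RNG stream when `NULL`.
#' @return List with `loss`, `wasserstein` and `gp` (the weighted penalty).
#' @export
critic_objective <- function(model, x_real, x_fake,
                             gp_weight = model$gp_weight, eps = NULL) {
  stopifnot(inherits(model, "gan_model"))
  if (is.null(dim(x_real))) x_real <- matrix(x_real, nrow = 1L)
  if (is.null(dim(x_fake))) x_fake <- matrix(x_fake, nrow = 1L)
  if (nrow(x_real) != nrow(x_fake))
    stop("x_real and x_fake must have the same number of rows")
  wass <- mean(mlp_forward(model$D, x_fake)) -
    mean(mlp_forward(model$D, x_real))
  if (is.null(eps)) eps <- stats::runif(nrow(x_real))
  xhat <- eps * x_real + (1 - eps) * x_fake
  gn <- sqrt(rowSums(critic_input_grad(model$D, xhat)$G^2))
  gp <- gp_weight * mean((gn - 1)^2)
  list(loss = wass + gp, wasserstein = wass, gp = gp)
}

# One critic update: Wasserstein gradients plus the analytic gradient-penalty
# backward pass, applied with Adam.
critic_update <- function(model, state, x_real, x_fake) {
  B <- nrow(x_real)
  ff <- mlp_forward(model$D, x_fake, cache = TRUE)
  fr <- mlp_forward(model$D, x_real, cache = TRUE)
  bf <- mlp_backward(model$D, ff, matrix(1 / B, B, 1), need_dx = FALSE)
  br <- mlp_backward(model$D, fr, matrix(-1 / B, B, 1), need_dx = FALSE)
  eps <- stats::runif(B)
  xhat <- eps * x_real + (1 - eps) * x_fake
  gpg <- critic_gp_grads(model$D, xhat, model$gp_weight)
  grads <- grads_add(grads_add(list(gW = bf$gW, gb = bf$gb),
                               list(gW = br$gW, gb = br$gb)),
                     gpg$grads)
  up <- adam_step(model$D, grads, state, model$critic_lr,
                  beta1 = model$betas[1], beta2 = model$betas[2])
  model$D <- up$net
  wass <- mean(ff$out) - mean(fr$out)
  list(model = model, state = up$state, wass = wass, gp = gpg$penalty,
       loss = wass + gpg$penalty)
}

# One generator update: minimise -mean(D'(G'(x))) through the residual
# shortcut and the final ReLU.
generator_update <- function(model, state, x_src) {
  B <- nrow(x_src)
  fF <- mlp_forward(model$F, x_src, cache = TRUE)
  pre <- fF$out + x_src
  fake <- act_apply(model$f, pre)
  fD <- mlp_forward(model$D, fake, cache = TRUE)
  bD <- mlp_backward(model$D, fD, matrix(-1 / B, B, 1), need_dx = TRUE)
  dPre <- bD$dX * act_deriv(model$f, pre)
  bF <- mlp_backward(model$F, fF, dPre, need_dx = FALSE)
  up <- adam_step(model$F, list(gW = bF$gW, gb = bF$gb), state,
                  model$learning_rate,
                  beta1 = model$betas[1], beta2 = model$betas[2])
  model$F <- up$net
  list(model = model, state = up$state, gen_loss = -mean(fD$out))
}

#' Train the stage-two GAN on rwMNN pairs
#'
#' Alternating optimisation: `critic_steps` critic updates followed by one
#' generator update, with minibatches of *pairs* sampled uniformly with
#' replacement from the pair list; the batch-A member feeds the generator and
#' the batch-B member is the critic's "real" sample. One epoch is
#' `ceiling(n_pairs / minibatch_size)` generator updates. Only cells that
#' appear in pairs are ever used for training.
#'
#' @param model A [build_gan()] model.
#' @param pairs A `pair_set`; `index_a` indexes `X_source`, `index_b` indexes
#'   `X_anchor`.
#' @param X_source Source-batch matrix (cells x genes).
#' @param X_anchor Anchor-batch matrix (cells x genes).
#' @param epochs Training epochs (default 150).
#' @param minibatch_size Pairs per minibatch (default 256).
#' @param seed Integer seed.
#' @param engine `"cpp"` (default, compiled fast path) or `"R"` (pure-R
#'   reference implementation; same arithmetic, used for verification).
#' @param verbose Print progress.
#' @return List with the trained `model` and a `log` data frame with per-step
#'   `gen_loss`, `critic_loss`, `gp`.
#' @export
train_stage2 <- function(model, pairs, X_source, X_anchor, epochs = 150,
                         minibatch_size = 256, seed = 1,
                         engine = c("cpp", "R"), verbose = FALSE) {
  stopifnot(inherits(model, "gan_model"), inherits(pairs, "pair_set"),
            epochs >= 0)
  engine <- match.arg(engine)
  if (max(pairs$index_a) > nrow(X_source) ||
      max(pairs$index_b) > nrow(X_anchor))
    stop("pair indices exceed the supplied matrices")
  if (epochs == 0)
    return(list(model = model,
                log = data.frame(step = integer(), gen_loss = numeric(),
                                 critic_loss = numeric(), gp = numeric())))
  n_pairs <- nrow(pairs)
  if (engine == "cpp") {
    res <- with_seed(seed,
      cpp_train_stage2(model$F, model$D,
                       pairs$index_a - 1L, pairs$index_b - 1L,
                       X_source, X_anchor, epochs, minibatch_size,
                       model$critic_steps, model$gp_weight,
                       model$learning_rate, model$critic_lr,
                       model$betas[1], model$betas[2]))
    model$F$W <- lapply(res$F$W, identity)
    model$F$b <- lapply(res$F$b, as.vector)
    model$D$W <- lapply(res$D$W, identity)
    model$D$b <- lapply(res$D$b, as.vector)
    log <- data.frame(step = seq_along(res$gen_loss),
                      gen_loss = as.vector(res$gen_loss),
                      critic_loss = as.vector(res$critic_loss),
                      gp = as.vector(res$gp))
    if (verbose)
      message(sprintf("stage 2: critic %.4f -> %.4f over %d steps",
                      log$critic_loss[1], log$critic_loss[nrow(log)],
                      nrow(log)))
    return(list(model = model, log = log))
  }
  steps_per_epoch <- ceiling(n_pairs / minibatch_size)
  n_steps <- epochs * steps_per_epoch
  gen_v <- crit_v <- gp_v <- numeric(n_steps)
  states <- list(F = adam_init(model$F), D = adam_init(model$D))
  step <- 0L
  model <- with_seed(seed, {
    for (ep in seq_len(epochs)) {
      for (it in seq_len(steps_per_epoch)) {
        c_loss <- gp_val <- NA_real_
        for (cs in seq_len(model$critic_steps)) {
          mb <- sample.int(n_pairs, min(minibatch_size, n_pairs),
                           replace = TRUE)
          x_src <- X_source[pairs$index_a[mb], , drop = FALSE]
          x_real <- X_anchor[pairs$index_b[mb], , drop = FALSE]
          x_fake <- gan_transform(model, x_src)
          cu <- critic_update(model, states$D, x_real, x_fake)
          model <- cu$model; states$D <- cu$state
          c_loss <- cu$loss; gp_val <- cu$gp
        }
        mb <- sample.int(n_pairs, min(minibatch_size, n_pairs),
                         replace = TRUE)
        gu <- generator_update(model, states$F,
                               X_source[pairs$index_a[mb], , drop = FALSE])
        model <- gu$model; states$F <- gu$state
        step <- step + 1L
        if (!is.finite(gu$gen_loss) || !is.finite(c_loss))
          stop("non-finite stage-two loss at step ", step)
        gen_v[step] <- gu$gen_loss; crit_v[step] <- c_loss; gp_v[step] <- gp_val
      }
      if (verbose)
        message(sprintf("epoch %d: gen %.4f critic %.4f", ep,
                        gen_v[step], crit_v[step]))
    }
    model
  })
  list(model = model,
       log = data.frame(step = seq_len(n_steps), gen_loss = gen_v,
                        critic_loss = crit_v, gp = gp_v))
}
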