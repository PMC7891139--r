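# Minimal vectorised multi-layer-perceptron toolkit: Mish/ReLU activations,
# seeded initialisation, forward/backward passes and an Adam optimiser.
# All heavy operations are dense matrix products (BLAS), batched over cells.
# This file is internal machinery; the user-facing model constructors live in
# stage1.R and stage2.R.

# --- activations -----------------------------------------------------------

# Numerically stable softplus log(1 + exp(x)).
softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Mish activation
#'
#' Smooth self-regularising activation `x * tanh(softplus(x))` used by all
#' hidden layers of the networks in this package.
#'
#' @param x Numeric vector or matrix.
#' @return Object of the same shape as `x`.
#' @export
mish <- function(x) x * tanh(softplus(x))

# Mish value and first/second derivatives sharing the transcendental
# intermediates (the training hot path).
mish_all <- function(x, value = TRUE, d1 = TRUE, d2 = FALSE) {
  tv <- tanh(softplus(x))
  s <- sigmoid(x)
  out <- list()
  if (value) out$h <- x * tv
  if (d1 || d2) {
    tp <- (1 - tv^2) * s
    if (d1) out$d1 <- tv + x * tp
    if (d2) out$d2 <- 2 * tp + x * ((1 - tv^2) * s * (1 - s) - 2 * tv * tp * s)
  }
  out
}

# First derivative of Mish.
mish_d1 <- function(x) mish_all(x, value = FALSE)$d1

# Second derivative of Mish (needed by the gradient-penalty backward pass).
mish_d2 <- function(x) mish_all(x, value = FALSE, d1 = FALSE, d2 = TRUE)$d2

relu <- function(x) pmax(x, 0)

act_apply <- function(name, z) {
  switch(name,
    mish = mish(z),
    relu = relu(z),
    linear = z,
    stop("unknown activation: ", name)
  )
}

act_deriv <- function(name, z) {
  switch(name,
    mish = mish_d1(z),
    relu = (z > 0) * 1,
    linear = array(1, dim = dim(z)) ,
    stop("unknown activation: ", name)
  )
}

# --- network container -----------------------------------------------------

# An mlp is a list with $W (list of in x out matrices), $b (list of numeric
# vectors) and $acts (character vector, one activation name per layer).
# Initialisation follows the uniform fan-in rule U(-1/sqrt(in), 1/sqrt(in))
# and consumes the caller's RNG stream (callers seed via with_seed()).
mlp_init <- function(dims, acts) {
  n_layers <- length(dims) - 1L
  stopifnot(n_layers >= 1L, length(acts) == n_layers, all(dims >= 1L))
  W <- b <- vector("list", n_layers)
  for (i in seq_len(n_layers)) {
    bound <- 1 / sqrt(dims[i])
    W[[i]] <- matrix(stats::runif(dims[i] * dims[i + 1L], -bound, bound),
                     nrow = dims[i])
    b[[i]] <- stats::runif(dims[i + 1L], -bound, bound)
  }
  structure(list(W = W, b = b, acts = acts, dims = dims), class = "bg_mlp")
}

# Forward pass. With cache = TRUE returns activations H and the activation
# derivatives D (computed alongside the values to share the transcendental
# intermediates) for use by mlp_backward; otherwise just the output matrix.
mlp_forward <- function(net, X, cache = FALSE) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (ncol(X) != net$dims[1L])
    stop("input has ", ncol(X), " columns but the network expects ",
         net$dims[1L])
  L <- length(net$W)
  D <- H <- if (cache) vector("list", L) else NULL
  h <- X
  for (i in seq_len(L)) {
    z <- h %*% net$W[[i]]
    z <- z + rep(net$b[[i]], each = nrow(z))
    a <- net$acts[i]
    if (cache) {
      if (a == "mish") {
        ma <- mish_all(z)
        h <- ma$h
        D[[i]] <- ma$d1
      } else if (a == "relu") {
        h <- relu(z)
        D[[i]] <- (z > 0) * 1
      } else {
        h <- z
        D[i] <- list(NULL)  # identity derivative, skipped in backward
      }
      H[[i]] <- h
    } else {
      h <- act_apply(a, z)
    }
  }
  if (cache) list(out = h, D = D, H = H, X = X) else h
}

# Backward pass: given dL/d(output), return per-layer parameter gradients and
# (optionally) dL/d(input).
mlp_backward <- function(net, fwd, d_out, need_dx = TRUE) {
  L <- length(net$W)
  gW <- gb <- vector("list", L)
  dH <- d_out
  for (i in rev(seq_len(L))) {
    dZ <- if (is.null(fwd$D[[i]])) dH else dH * fwd$D[[i]]
    h_prev <- if (i > 1L) fwd$H[[i - 1L]] else fwd$X
    gW[[i]] <- crossprod(h_prev, dZ)
    gb[[i]] <- colSums(dZ)
    if (i > 1L || need_dx) dH <- tcrossprod(dZ, net$W[[i]])
  }
  list(gW = gW, gb = gb, dX = if (need_dx) dH else NULL)
}

grads_zero <- function(net) {
  list(gW = lapply(net$W, function(w) array(0, dim = dim(w))),
       gb = lapply(net$b, function(b) numeric(length(b))))
}

grads_add <- function(g1, g2) {
  list(gW = Map(`+`, g1$gW, g2$gW), gb = Map(`+`, g1$gb, g2$gb))
}

# --- Adam optimiser --------------------------------------------------------

adam_init <- function(net) {
  list(mW = lapply(net$W, function(w) array(0, dim = dim(w))),
       vW = lapply(net$W, function(w) array(0, dim = dim(w))),
       mb = lapply(net$b, function(b) numeric(length(b))),
       vb = lapply(net$b, function(b) numeric(length(b))),
       t = 0L)
}

adam_step <- function(net, grads, state, lr,
                      beta1 = 0.5, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (i in seq_along(net$W)) {
    state$mW[[i]] <- beta1 * state$mW[[i]] + (1 - beta1) * grads$gW[[i]]
    state$vW[[i]] <- beta2 * state$vW[[i]] + (1 - beta2) * grads$gW[[i]]^2
    net$W[[i]] <- net$W[[i]] -
      lr * (state$mW[[i]] / c1) / (sqrt(state$vW[[i]] / c2) + eps)
    state$mb[[i]] <- beta1 * state$mb[[i]] + (1 - beta1) * grads$gb[[i]]
    state$vb[[i]] <- beta2 * state$vb[[i]] + (1 - beta2) * grads$gb[[i]]^2
    net$b[[i]] <- net$b[[i]] -
      lr * (state$mb[[i]] / c1) / (sqrt(state$vb[[i]] / c2) + eps)
  }
  list(net = net, state = state)
}

# --- gradient penalty machinery -------------------------------------------
# The critic is a fixed-shape network d -> w3 -> w3 -> 1 with Mish on the two
# hidden layers and a linear output. For the WGAN-GP penalty we need both the
# critic's gradient with respect to its *input* and the derivative of the
# penalty with respect to the critic's *parameters* (a double-backward pass),
# which is implemented analytically below.

# Per-row gradient of the scalar critic output with respect to the input.
# Returns a list with the gradient matrix and the intermediates reused by
# critic_gp_grads.
# Activation value + first/second derivative for the smooth activations the
# critic admits (Mish hidden layers, or linear for degenerate test critics).
act_pack <- function(name, z, second = FALSE) {
  if (name == "mish") return(mish_all(z, d2 = second))
  if (name == "linear")
    return(list(h = z, d1 = array(1, dim = dim(z)),
                d2 = if (second) array(0, dim = dim(z))))
  stop("critic layers must be mish or linear, got ", name)
}

critic_input_grad <- function(net, X, second = FALSE) {
  stopifnot(length(net$W) == 3L, net$acts[3] == "linear")
  B <- nrow(X)
  z1 <- X %*% net$W[[1]]; z1 <- z1 + rep(net$b[[1]], each = B)
  m1 <- act_pack(net$acts[1], z1, second = second)
  z2 <- m1$h %*% net$W[[2]]; z2 <- z2 + rep(net$b[[2]], each = B)
  m2 <- act_pack(net$acts[2], z2, second = second)
  w3 <- as.vector(net$W[[3]])
  Q <- m2$d1 * rep(w3, each = B)          # B x h2
  P <- tcrossprod(Q, net$W[[2]]) * m1$d1  # B x h1
  G <- tcrossprod(P, net$W[[1]])          # B x d
  list(G = G, a1 = m1$h, p1 = m1$d1, p2 = m2$d1,
       p1dd = m1$d2, p2dd = m2$d2, w3 = w3)
}

# Gradient of gp_weight * mean((||grad_x D(xhat)|| - 1)^2) with respect to the
# critic parameters, evaluated at interpolates Xhat. Returns the penalty value
# and parameter gradients in mlp_backward layout.
critic_gp_grads <- function(net, Xhat, gp_weight) {
  B <- nrow(Xhat)
  ig <- critic_input_grad(net, Xhat, second = TRUE)
  gn <- sqrt(rowSums(ig$G^2))
  penalty <- gp_weight * mean((gn - 1)^2)
  # outer derivative of the penalty wrt the input-gradient rows
  u <- ig$G * (2 * (gn - 1) / pmax(gn, 1e-12)) * (gp_weight / B)
  w3row <- rep(ig$w3, each = B)
  v1 <- u %*% net$W[[1]]          # B x h1
  s <- v1 * ig$p1
  tt <- s %*% net$W[[2]]          # B x h2
  p2dd <- ig$p2dd
  p1dd <- ig$p1dd
  gW3 <- matrix(colSums(tt * ig$p2), ncol = 1L)
  dz2 <- tt * p2dd * w3row
  gW2 <- crossprod(s, ig$p2 * w3row) + crossprod(ig$a1, dz2)
  gb2 <- colSums(dz2)
  da1 <- tcrossprod(dz2, net$W[[2]])
  ds <- tcrossprod(ig$p2 * w3row, net$W[[2]])  # d scalar / d s
  dz1 <- ds * v1 * p1dd + da1 * ig$p1
  gW1 <- crossprod(u, ds * ig$p1) + crossprod(Xhat, dz1)
  gb1 <- colSums(dz1)
  list(penalty = penalty,
       grads = list(gW = list(gW1, gW2, gW3),
                    gb = list(gb1, gb2, 0)))
}
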