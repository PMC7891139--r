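test_that("build_gan is seeded and the generator is a non-negative residual map", {
  g <- build_gan(d = 20, l = 4, widths = c(16, 8, 8), seed = 3)
  expect_identical(g$F$dims, c(20, 16, 8, 4, 8, 16, 20))
  expect_identical(g$D$dims, c(20, 8, 8, 1))
  expect_identical(build_gan(d = 20, l = 4, widths = c(16, 8, 8), seed = 3)$F$W,
                   g$F$W)
  # G'(0) = relu(F(0)) >= 0
  expect_true(all(gan_transform(g, matrix(0, 1, 20)) >= 0))
  # zeroed F: exact identity on non-negative inputs
  g0 <- g
  g0$F <- zero_net(g0$F)
  X <- matrix(abs(rnorm(100)), 5, 20)
  expect_identical(gan_transform(g0, X), X)
  # shape and row independence
  Xc <- gan_transform(g, X)
  expect_identical(dim(Xc), dim(X))
  expect_true(all(Xc >= 0))
  expect_equal(gan_transform(g, rbind(X, X)), rbind(Xc, Xc))
  expect_error(gan_transform(g, X[, 1:3]), "genes")
})

test_that("critic objective matches closed forms for degenerate critics", {
  g <- build_gan(d = 6, l = 3, widths = c(8, 4, 5), seed = 2)
  xr <- matrix(abs(rnorm(24)), 4, 6)
  xf <- matrix(abs(rnorm(24)), 4, 6)
  # constant critic: zero weights, bias c -> Wasserstein 0, gp = weight * 1
  gc <- g
  gc$D <- zero_net(gc$D)
  gc$D$b[[3]] <- 5
  got <- critic_objective(gc, xr, xf, gp_weight = 10, eps = rep(0.5, 4))
  expect_equal(got$wasserstein, 0)
  expect_equal(got$gp, 10)
  expect_equal(got$loss, 10)
  # linear critic with unit-norm input gradient: gp exactly 0
  gl <- g
  v <- c(1, rep(0, 5))
  gl$D$acts <- c("linear", "linear", "linear")
  gl$D$W <- list(cbind(v, matrix(0, 6, 7)), rbind(1, matrix(0, 7, 4)),
                 matrix(c(1, 0, 0, 0), 4, 1))
  gl$D$b <- list(numeric(8), numeric(4), 0)
  gotl <- critic_objective(gl, xr, xf, gp_weight = 10, eps = runif(4))
  expect_identical(gotl$gp, 0)
  expect_equal(gotl$wasserstein, mean(xf[, 1]) - mean(xr[, 1]))
})

test_that("critic objective equals an independent recomputation on a frozen net", {
  g <- build_gan(d = 5, l = 2, widths = c(6, 4, 7), seed = 11)
  xr <- matrix(abs(rnorm(20)), 4, 5)
  xf <- matrix(abs(rnorm(20)), 4, 5)
  eps <- c(0.1, 0.4, 0.7, 0.95)
  got <- critic_objective(g, xr, xf, gp_weight = 10, eps = eps)
  # independent route: per-neuron forward + numerical input gradients
  d_scores <- function(X) oracle_forward(g$D, X)[, 1]
  wass <- mean(d_scores(xf)) - mean(d_scores(xr))
  xhat <- eps * xr + (1 - eps) * xf
  gp <- 0
  for (i in 1:4) {
    grad <- numeric(5)
    for (j in 1:5) {
      hp <- hm <- xhat
      hp[i, j] <- hp[i, j] + 1e-5
      hm[i, j] <- hm[i, j] - 1e-5
      grad[j] <- (d_scores(hp[i, , drop = FALSE]) -
                  d_scores(hm[i, , drop = FALSE])) / 2e-5
    }
    gp <- gp + (sqrt(sum(grad^2)) - 1)^2 / 4
  }
  expect_equal(got$wasserstein, wass, tolerance = 1e-5)
  expect_equal(got$gp, 10 * gp, tolerance = 1e-5)
  expect_equal(got$loss, wass + 10 * gp, tolerance = 1e-5)
})

test_that("critic parameter gradients (incl. gradient penalty) match finite differences", {
  set.seed(13)
  g <- build_gan(d = 6, l = 3, widths = c(8, 5, 7), seed = 4)
  xr <- matrix(abs(rnorm(24)), 4, 6)
  xf <- matrix(abs(rnorm(24)), 4, 6)
  eps <- runif(4)
  xhat <- eps * xr + (1 - eps) * xf
  ff <- batchgan:::mlp_forward(g$D, xf, cache = TRUE)
  fr <- batchgan:::mlp_forward(g$D, xr, cache = TRUE)
  bf <- batchgan:::mlp_backward(g$D, ff, matrix(1 / 4, 4, 1), need_dx = FALSE)
  br <- batchgan:::mlp_backward(g$D, fr, matrix(-1 / 4, 4, 1), need_dx = FALSE)
  gpg <- batchgan:::critic_gp_grads(g$D, xhat, 10)
  ga <- batchgan:::grads_add(batchgan:::grads_add(
    list(gW = bf$gW, gb = bf$gb), list(gW = br$gW, gb = br$gb)), gpg$grads)
  obj <- function(D) {
    g2 <- g; g2$D <- D
    critic_objective(g2, xr, xf, gp_weight = 10, eps = eps)$loss
  }
  for (li in 1:3) {
    W <- g$D$W[[li]]
    for (i in sample(length(W), 4)) {
      D1 <- g$D; D1$W[[li]][i] <- W[i] + 1e-6
      D2 <- g$D; D2$W[[li]][i] <- W[i] - 1e-6
      expect_equal(ga$gW[[li]][i], (obj(D1) - obj(D2)) / 2e-6,
                   tolerance = 1e-4)
    }
  }
})

test_that("train_stage2 closes the critic gap on a shifted-Gaussian fixture", {
  set.seed(1)
  n <- 200; d <- 10
  src <- matrix(abs(rnorm(n * d, 3, 1)), n, d)
  anchor <- matrix(abs(rnorm(n * d, 3, 1) + rep(rnorm(d, 0, 1.5), each = n)),
                   n, d)
  pairs <- make_pair_set(1:n, 1:n)
  gan <- build_gan(d = d, l = 4, widths = c(32, 16, 16), seed = 2)
  ft <- train_stage2(gan, pairs, src, anchor, epochs = 60,
                     minibatch_size = 64, seed = 3)
  out <- gan_transform(ft$model, src)
  pre_err <- sqrt(sum((colMeans(src) - colMeans(anchor))^2))
  post_err <- sqrt(sum((colMeans(out) - colMeans(anchor))^2))
  expect_lt(post_err, pre_err / 2)
  lg <- ft$log
  expect_lt(abs(mean(tail(lg$critic_loss, 20))),
            abs(mean(lg$critic_loss[1:20])))
  expect_true(all(is.finite(as.matrix(lg[, -1]))))
  expect_true(all(lg$gp >= 0))
})

test_that("train_stage2 is deterministic and no-ops at 0 epochs", {
  set.seed(5)
  src <- matrix(abs(rnorm(30 * 8)), 30, 8)
  anchor <- src + 1
  pairs <- make_pair_set(1:30, 1:30)
  gan <- build_gan(d = 8, l = 2, widths = c(8, 4, 4), seed = 1)
  f1 <- train_stage2(gan, pairs, src, anchor, epochs = 3,
                     minibatch_size = 8, seed = 7)
  f2 <- train_stage2(gan, pairs, src, anchor, epochs = 3,
                     minibatch_size = 8, seed = 7)
  expect_identical(f1$log, f2$log)
  expect_identical(f1$model$F$W, f2$model$F$W)
  f0 <- train_stage2(gan, pairs, src, anchor, epochs = 0, seed = 7)
  expect_identical(f0$model$F$W, gan$F$W)
  expect_equal(nrow(f0$log), 0)
  expect_error(train_stage2(gan, make_pair_set(31, 1), src, anchor, 1),
               "indices")
})
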