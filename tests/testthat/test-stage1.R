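test_that("build_stage1 produces the documented shapes, seeded", {
  m <- build_stage1(d = 2000, n = 2, seed = 7)
  expect_identical(sapply(m$E$W, dim)[1, ], c(2000L, 1024L, 512L))
  expect_identical(sapply(m$E$W, dim)[2, ], c(1024L, 512L, 256L))
  expect_identical(sapply(m$G1$W, dim)[1, ], c(2L, 512L, 1024L))
  expect_identical(ncol(m$G2$W[[1]]), 512L)
  expect_identical(nrow(m$G2$W[[1]]), 2L + 256L)
  m2 <- build_stage1(d = 2000, n = 2, seed = 7)
  expect_identical(m$E$W, m2$E$W)
  # tiny model gives finite outputs
  t1 <- build_stage1(d = 10, n = 2, l = 2, widths = c(8, 4), seed = 1)
  out <- reconstruct(t1, matrix(runif(30), 3, 10), one_hot_rows(c(1, 2, 1), 2))
  expect_true(all(is.finite(out)))
})

test_that("reconstruct is non-negative and follows the additive structure", {
  set.seed(3)
  m <- build_stage1(d = 12, n = 3, l = 4, widths = c(8, 6), seed = 5)
  X <- matrix(abs(rnorm(6 * 12, 2)), 6, 12)
  B <- one_hot_rows(sample(3, 6, replace = TRUE), 3)
  expect_true(min(reconstruct(m, X, B)) >= 0)
  # zeroed generators: reconstruction is exactly the zero vector
  m0 <- m
  m0$G1 <- zero_net(m0$G1)
  m0$G2 <- zero_net(m0$G2)
  expect_true(all(reconstruct(m0, X, B) == 0))
  # composition matches an independent per-neuron forward pass
  want <- pmax(oracle_forward(m$G1, B) +
               oracle_forward(m$G2, cbind(oracle_forward(m$E, X), B)), 0)
  expect_equal(reconstruct(m, X, B), want, tolerance = 1e-10)
  expect_error(reconstruct(m, X[, 1:5], B), "genes")
  expect_error(reconstruct(m, X, B[, 1:2]), "model expects")
})

test_that("losses match hand arithmetic and vanish on the identity model", {
  # zero networks: reconstruction is 0, so L_r is the mean squared input norm
  m <- build_stage1(d = 2, n = 2, l = 2, widths = c(4, 3), seed = 1)
  m$G1 <- zero_net(m$G1); m$G2 <- zero_net(m$G2)
  B <- one_hot_rows(c(1, 2), 2)
  expect_equal(reconstruction_loss(m, matrix(c(1, 1), 1), B[1, , drop = FALSE]), 2)
  X2 <- rbind(c(1, 1), c(2, 0))  # squared norms 2 and 4 -> mean 3
  expect_equal(reconstruction_loss(m, X2, B), 3)
  # exact identity construction: both losses are exactly zero
  id <- identity_stage1(d = 3, n = 2)
  Xi <- matrix(abs(rnorm(12)), 4, 3)
  Bi <- one_hot_rows(c(1, 2, 1, 2), 2)
  expect_identical(reconstruction_loss(id, Xi, Bi), 0)
  expect_identical(content_loss(id, Xi, Bi), 0)
  # content loss equals an independent double forward pass on a 3-cell fixture
  m3 <- build_stage1(d = 5, n = 2, l = 3, widths = c(6, 4), seed = 9)
  X3 <- matrix(abs(rnorm(15)), 3, 5)
  B3 <- one_hot_rows(c(2, 1, 2), 2)
  codes <- oracle_forward(m3$E, X3)
  fab <- pmax(oracle_forward(m3$G1, B3) +
              oracle_forward(m3$G2, cbind(codes, B3)), 0)
  want <- mean(rowSums((oracle_forward(m3$E, fab) - codes)^2))
  expect_equal(content_loss(m3, X3, B3), want, tolerance = 1e-10)
})

test_that("training gradients match finite differences", {
  set.seed(42)
  m <- build_stage1(d = 7, n = 3, l = 4, widths = c(6, 5), seed = 9)
  X <- matrix(abs(rnorm(5 * 7)), 5, 7)
  Bm <- one_hot_rows(sample(3, 5, replace = TRUE), 3)
  Bt <- one_hot_rows(sample(3, 5, replace = TRUE), 3)
  g <- batchgan:::stage1_grads(m, X, Bm, Bt)
  loss_fn <- function(mm) {
    mm$lambda_r * reconstruction_loss(mm, X, Bm) +
      mm$lambda_c * content_loss(mm, X, Bt)
  }
  for (net in c("E", "G1", "G2")) {
    li <- 2L
    W <- m[[net]]$W[[li]]
    idx <- sample(length(W), 5)
    for (i in idx) {
      m1 <- m; m1[[net]]$W[[li]][i] <- W[i] + 1e-6
      m2 <- m; m2[[net]]$W[[li]][i] <- W[i] - 1e-6
      num <- (loss_fn(m1) - loss_fn(m2)) / 2e-6
      expect_equal(g[[paste0("g", net)]]$gW[[li]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("random batch indicators are one-hot, uniform and seeded", {
  expect_identical(with_seed(1, sample_random_batch_indicator(1)),
                   matrix(1, 1, 1))
  draws <- with_seed(2, sample_random_batch_indicator(3, 30000))
  expect_true(all(rowSums(draws) == 1))
  freq <- colMeans(draws)
  expect_true(all(freq > 0.32 & freq < 0.35))
  expect_identical(with_seed(5, sample_random_batch_indicator(4, 10)),
                   with_seed(5, sample_random_batch_indicator(4, 10)))
})

test_that("train_stage1 descends, is deterministic, and no-ops at 0 epochs", {
  sim <- simulate_batches(default_benchmark_design("tiny"), seed = 8)
  es <- log_tpm_transform(qc_filter(sim$data, mito_gene_prefix = "none"))
  sub <- subset_cells(es, c(1:40, 81:120))  # 40 cells per batch
  finals <- initials <- numeric(3)
  for (s in 1:3) {
    m <- build_stage1(d = ncol(sub$matrix), n = 2, l = 4, widths = c(16, 8),
                      seed = s)
    fit <- train_stage1(m, sub, epochs = 30, minibatch_size = 16, seed = s)
    expect_equal(nrow(fit$report), 30)
    initials[s] <- fit$report$total[1]
    finals[s] <- fit$report$total[30]
  }
  expect_lt(median(finals), median(initials))
  # determinism
  m <- build_stage1(d = ncol(sub$matrix), n = 2, l = 4, widths = c(16, 8),
                    seed = 1)
  f1 <- train_stage1(m, sub, epochs = 5, minibatch_size = 16, seed = 3)
  f2 <- train_stage1(m, sub, epochs = 5, minibatch_size = 16, seed = 3)
  expect_identical(f1$report, f2$report)
  expect_identical(f1$model$E$W, f2$model$E$W)
  # epochs = 0
  f0 <- train_stage1(m, sub, epochs = 0, seed = 1)
  expect_identical(f0$model$E$W, m$E$W)
  expect_equal(nrow(f0$report), 0)
})

test_that("encode is row-independent and matches per-cell application", {
  m <- build_stage1(d = 8, n = 2, l = 3, widths = c(6, 4), seed = 2)
  X <- matrix(abs(rnorm(40)), 5, 8)
  C <- encode(m, X)
  expect_identical(dim(C), c(5L, 3L))
  expect_identical(encode(m, rbind(X, X)), rbind(C, C))
  looped <- t(sapply(seq_len(5), function(i) encode(m, X[i, ])))
  expect_equal(C, looped, tolerance = 1e-12)
  expect_error(encode(m, X[, 1:3]), "genes")
})

test_that("trained codes pair cells across batches more readily than raw profiles", {
  # the operative property of the content codes: mutual nearest neighbours
  # computed on codes are more numerous and at least as type-pure as MNN
  # pairs on raw log-TPM profiles (shared run from helper-acceptance.R)
  r <- acc_run(1, with_gan = FALSE)
  expect_gte(r$n_seeds_codes, r$n_seeds_raw)
  ct_src <- r$es$celltype[r$i_src]
  ct_anc <- r$es$celltype[r$i_anc]
  purity <- mean(ct_src[r$seeds_codes$index_a] ==
                 ct_anc[r$seeds_codes$index_b])
  expect_gte(purity, 0.9)
})
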