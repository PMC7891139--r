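# Linearly separable codes: two Gaussian clouds along the first axis.
separable_fixture <- function(n = 120, d = 6, gap = 6, seed = 1) {
  batchgan:::with_seed(seed, {
    y <- rep(c("a", "b"), each = n / 2)
    X <- matrix(rnorm(n * d), n, d)
    X[y == "b", 1] <- X[y == "b", 1] + gap
    list(X = X, y = y)
  })
}

test_that("probes learn separable labels and stay at chance on shuffled ones", {
  fx <- separable_fixture()
  p <- train_batch_probe(fx$X, fx$y, seed = 2, widths = c(16, 8))
  expect_gte(p$accuracy, 0.95)
  # permutation null: accuracy within 3 sigma of 1/2
  accs <- sapply(1:5, function(s) {
    ysh <- batchgan:::with_seed(100 + s, sample(fx$y))
    train_batch_probe(fx$X, ysh, seed = s, widths = c(16, 8),
                      epochs = 30)$accuracy
  })
  n_test <- floor(0.2 * nrow(fx$X))
  expect_lt(abs(median(accs) - 0.5), 3 * sqrt(0.25 / n_test))
})

test_that("the cell-type probe never touches the encoder", {
  sim <- simulate_batches(default_benchmark_design("tiny"), seed = 3)
  es <- log_tpm_transform(sim$data)
  m <- build_stage1(d = ncol(es$matrix), n = 2, l = 4, widths = c(16, 8),
                    seed = 1)
  fit <- train_stage1(m, es, epochs = 10, minibatch_size = 32, seed = 2)
  before <- fit$model$E
  probe <- train_celltype_probe(fit$model, es$matrix, es$celltype, seed = 4,
                                widths = c(16, 8), epochs = 30)
  expect_identical(fit$model$E, before)
  expect_identical(probe$input, "codes")
  expect_s3_class(probe, "probe_classifier")
  # determinism under a fixed seed
  probe2 <- train_celltype_probe(fit$model, es$matrix, es$celltype, seed = 4,
                                 widths = c(16, 8), epochs = 30)
  expect_identical(probe$net$W, probe2$net$W)
})

test_that("small classes are excluded with a warning", {
  fx <- separable_fixture(n = 40)
  y <- fx$y
  y[1:3] <- "rare"
  expect_warning(p <- train_batch_probe(fx$X, y, seed = 1,
                                        widths = c(8, 4), epochs = 10),
                 "rare")
  expect_false("rare" %in% p$classes)
})

test_that("attributions satisfy completeness and ignore dead genes", {
  fx <- separable_fixture(n = 80, d = 5)
  # a probe that cannot see gene 5: zero its first-layer weights after training
  p <- train_batch_probe(fx$X, fx$y, seed = 3, widths = c(12, 6), epochs = 40)
  p$net$W[[1]][5, ] <- 0
  bg <- fx$X[seq(1, 80, by = 8), ]
  imp <- gene_importance(p, fx$X[1:20, ], bg, n_steps = 256)
  expect_identical(dim(unclass(imp)), c(20L, 5L))
  expect_true(all(abs(unclass(imp)[, 5]) < 1e-10))
  # completeness: attributions sum to score(x) - mean score(background)
  cls <- batchgan:::chain_predict(p, fx$X[1:20, ])
  sc_x <- batchgan:::chain_logit_grad(p, fx$X[1:20, ], cls)$score
  sc_bg <- sapply(seq_len(nrow(bg)), function(j)
    batchgan:::chain_logit_grad(p, bg[j, , drop = FALSE], cls)$score)
  want <- sc_x - rowMeans(sc_bg)
  got <- rowSums(unclass(imp))
  expect_lt(max(abs(got - want) / pmax(abs(want), 1e-6)), 1e-3)
})

test_that("a linear probe yields attributions proportional to the deviation", {
  # single informative gene, hand-built linear chain
  p <- structure(list(
    net = structure(list(W = list(matrix(c(2, 0, 0), 3, 1)),
                         b = list(0), acts = "linear", dims = c(3, 1)),
                    class = "bg_mlp"),
    encoder = NULL, classes = "score", accuracy = NA, input = "expression"),
    class = "probe_classifier")
  X <- matrix(rnorm(30), 10, 3)
  bg <- matrix(rnorm(15), 5, 3)
  imp <- gene_importance(p, X, bg, n_steps = 8, target = 1)
  want <- 2 * (X[, 1] - mean(bg[, 1]))
  expect_equal(unclass(imp)[, 1], want, tolerance = 1e-10)
  expect_true(all(unclass(imp)[, 2:3] == 0))
})

test_that("planted batch-diagnostic genes rank first in batch-probe importance", {
  ranks <- sapply(1:3, function(s) {
    n <- 150; d <- 20
    X <- batchgan:::with_seed(s, matrix(abs(rnorm(n * d, 3, 1)), n, d))
    batches <- rep(c("b1", "b2"), length.out = n)
    X[batches == "b2", 3] <- X[batches == "b2", 3] + 4  # planted gene 3
    colnames(X) <- paste0("g", 1:d)
    p <- train_batch_probe(X, batches, seed = s, widths = c(16, 8))
    bg <- X[seq(1, n, by = 10), ]
    which(rank_importance(gene_importance(p, X[1:50, ], bg,
                                          n_steps = 16)) == "g3")
  })
  expect_lte(median(ranks), 2)
})

test_that("aggregation computes per-gene group medians", {
  m <- matrix(c(1, 2, 3, 4, 10, 20, 30, 40), 4, 2,
              dimnames = list(NULL, c("gA", "gB")))
  imp <- structure(m, class = "importance_table")
  agg <- aggregate_importance(imp, c("x", "x", "y", "y"))
  expect_equal(agg$median_score[agg$group == "x" & agg$gene == "gA"], 1.5)
  expect_equal(agg$median_score[agg$group == "y" & agg$gene == "gB"], 35)
  # aggregating a constant column returns the constant
  impc <- structure(matrix(7, 5, 1, dimnames = list(NULL, "gC")),
                    class = "importance_table")
  expect_equal(aggregate_importance(impc, rep("g", 5))$median_score, 7)
  expect_error(gene_importance(structure(list(), class = "probe_classifier"),
                               m, m, method = "nope"), "expected_gradients")
})

test_that("importance tables export as long-format TSV", {
  m <- matrix(1:6, 2, 3, dimnames = list(NULL, c("gA", "gB", "gC")))
  imp <- structure(m, class = "importance_table")
  path <- file.path(tempdir(), "imp.tsv")
  write_importance(imp, path, cell_ids = c("c1", "c2"),
                   groups = c("x", "x"))
  long <- read.table(path, header = TRUE, sep = "\t")
  expect_identical(nrow(long), 6L)
  expect_equal(long$score[long$gene == "gB" & long$cell == "c2"], 4)
  agg <- read.table(paste0(path, ".groups.tsv"), header = TRUE, sep = "\t")
  expect_equal(agg$median_score[agg$gene == "gC"], 5.5)
})
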