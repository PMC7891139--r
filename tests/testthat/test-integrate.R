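make_log_es <- function(mats, batches, celltypes = NULL) {
  m <- do.call(rbind, mats)
  expr_set(m, paste0("c", seq_len(nrow(m))), paste0("g", seq_len(ncol(m))),
           batch = rep(batches, vapply(mats, nrow, 1L)),
           celltype = celltypes, units = "log_tpm")
}

test_that("plan_integration picks the anchor by total variance", {
  set.seed(1)
  mk <- function(sd) matrix(abs(rnorm(40, 5, sd)), 10, 4)
  es <- make_log_es(list(mk(3), mk(1), mk(0.2)), c("A", "B", "C"))
  plan <- plan_integration(es)
  expect_identical(plan$anchor, "A")
  expect_identical(plan$order, c("B", "C"))
  expect_false(plan$user_override)
  # override contracts
  p2 <- plan_integration(es, override_anchor = "C")
  expect_identical(p2$anchor, "C")
  expect_true(p2$user_override)
  expect_setequal(p2$order, c("A", "B"))
  p3 <- plan_integration(es, override_order = c("C", "B"))
  expect_identical(p3$order, c("C", "B"))
  expect_error(plan_integration(es, override_anchor = "Z"), "unknown batch")
  expect_error(plan_integration(es, override_order = c("B")), "every")
})

test_that("equal variances tie-break lexicographically and deterministically", {
  m <- matrix(abs(rnorm(40, 5, 1)), 10, 4)
  es <- make_log_es(list(m, m), c("beta", "alpha"))
  for (i in 1:3) {
    plan <- plan_integration(es)
    expect_identical(plan$anchor, "alpha")
    expect_identical(plan$order, "beta")
  }
  # permuting input order does not change the plan
  es2 <- make_log_es(list(m, m), c("alpha", "beta"))
  expect_identical(plan_integration(es2)$anchor, "alpha")
})

tiny_fit <- function(seed = 7) {
  sim <- simulate_batches(default_benchmark_design("tiny"), seed = 4)
  es <- preprocess(sim$data, hvg_n = 40, mito_gene_prefix = "none")
  list(es = es,
       fit = integrate_batches(es, epochs_stage1 = 8, epochs_stage2 = 8,
                               l = 4, widths = c(16, 8), w3 = 8, seed = seed,
                               minibatch_stage1 = 32, minibatch_stage2 = 32,
                               m = 5))
}

test_that("integration passes the anchor through bit-exactly and conserves cells", {
  tf <- tiny_fit()
  es <- tf$es; fit <- tf$fit
  anchor <- fit$plan$anchor
  expect_identical(fit$corrected$matrix[es$batch == anchor, ],
                   es$matrix[es$batch == anchor, ])
  expect_identical(nrow(fit$corrected$matrix), nrow(es$matrix))
  expect_identical(fit$corrected$cell_ids, es$cell_ids)
  expect_true(all(is.finite(fit$corrected$matrix)))
  expect_true(all(fit$corrected$matrix >= 0))
  expect_identical(sum(fit$provenance$corrected),
                   sum(es$batch != anchor))
  expect_s3_class(fit, "batch_integration")
  expect_identical(length(fit$rounds), 1L)
  expect_gte(fit$rounds[[1]]$n_seeds, 1)
  # corrected cells differ from their inputs (the generator did something)
  expect_false(identical(fit$corrected$matrix[es$batch != anchor, ],
                         es$matrix[es$batch != anchor, ]))
})

test_that("integration is reproducible under a fixed seed", {
  f1 <- tiny_fit(seed = 11)$fit
  f2 <- tiny_fit(seed = 11)$fit
  expect_identical(f1$corrected$matrix, f2$corrected$matrix)
  expect_identical(f1$rounds[[1]]$n_pairs, f2$rounds[[1]]$n_pairs)
})

test_that("three batches train exactly two GANs in plan order", {
  pres <- matrix(TRUE, 2, 3)
  cells <- matrix(30, 2, 3)
  des <- simulation_design(40, pres, cells, shift_sd = c(0, 0.8, 0.4),
                           base_mean = 1)
  sim <- simulate_batches(des, seed = 2)
  es <- preprocess(sim$data, hvg_n = 30, mito_gene_prefix = "none")
  fit <- integrate_batches(es, epochs_stage1 = 5, epochs_stage2 = 5,
                           l = 4, widths = c(16, 8), w3 = 8, seed = 3,
                           minibatch_stage1 = 32, minibatch_stage2 = 32,
                           m = 5)
  expect_identical(names(fit$rounds), fit$plan$order)
  expect_identical(length(fit$rounds), 2L)
  trained <- vapply(fit$rounds, function(r) r$corrected, TRUE)
  expect_true(all(trained))
  expect_identical(sort(unique(fit$provenance$round)), 0:2)
})

test_that("an anchor missing cell types does not abort the run", {
  small <- default_benchmark_design("small")
  sim <- simulate_batches(small, seed = 5)
  es <- preprocess(sim$data, hvg_n = 60, mito_gene_prefix = "none")
  # force the anchor to batch2, which lacks type3 entirely
  fit <- integrate_batches(es, anchor = "batch2", epochs_stage1 = 4,
                           epochs_stage2 = 4, l = 4, widths = c(16, 8),
                           w3 = 8, seed = 6, minibatch_stage1 = 64,
                           minibatch_stage2 = 64, m = 5)
  expect_identical(fit$plan$anchor, "batch2")
  expect_true(fit$rounds[["batch1"]]$corrected)
})

test_that("chunked whole-transcriptome correction reassembles gene order", {
  sim <- simulate_batches(default_benchmark_design("tiny"), seed = 4)
  es <- preprocess(sim$data, hvg_n = 30, mito_gene_prefix = "none")
  full <- attr(es, "full")
  fit <- integrate_batches(es, epochs_stage1 = 5, epochs_stage2 = 3,
                           l = 4, widths = c(16, 8), w3 = 8, seed = 7,
                           minibatch_stage1 = 32, minibatch_stage2 = 32,
                           m = 5)
  out <- correct_full_transcriptome(full, fit, n_chunks = 3, seed = 8,
                                    epochs_stage2 = 3)
  expect_identical(out$corrected$gene_ids, full$gene_ids)
  expect_identical(out$corrected$cell_ids, full$cell_ids)
  expect_true(all(out$corrected$matrix >= 0))
  anchor <- fit$plan$anchor
  expect_identical(out$corrected$matrix[full$batch == anchor, ],
                   full$matrix[full$batch == anchor, ])
  expect_identical(length(out$partition$chunks), 3L)
  expect_setequal(unlist(out$partition$chunks), full$gene_ids)
  expect_error(correct_full_transcriptome(full, fit,
                                          n_chunks = ncol(full$matrix)),
               "fewer chunks")
})

test_that("predict and summaries expose the fitted objects", {
  tf <- tiny_fit()
  fit <- tf$fit
  expect_identical(predict(fit), fit$corrected$matrix)
  src <- tf$es$matrix[tf$es$batch == names(fit$rounds)[1], , drop = FALSE]
  pr <- predict(fit, newdata = src, batch = names(fit$rounds)[1])
  expect_identical(dim(pr), dim(src))
  expect_error(predict(fit, newdata = src, batch = fit$plan$anchor), "anchor|round")
  expect_output(print(fit), "anchor")
  expect_output(summary(fit), "stage-1 loss")
})
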