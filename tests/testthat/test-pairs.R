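test_that("pair_params applies the s/100 and k1/2 calibration", {
  p <- pair_params(s = 3000, n_a = 3000, n_b = 3000, m = 50)
  expect_identical(p[c("k1", "k", "m")], list(k1 = 30L, k = 15L, m = 50L))
  p2 <- pair_params(s = 3000, n_a = 400, n_b = 500)
  expect_identical(p2$k1, 4L)
  expect_identical(p2$k, 2L)
  # floors at 1
  expect_identical(pair_params(s = 50, n_a = 50, n_b = 50)$k1, 1L)
  expect_identical(pair_params(s = 150, n_a = 150, n_b = 150)$k, 1L)
})

test_that("subsample_cells caps only above s and is seeded", {
  expect_identical(with_seed(1, subsample_cells(100, 3000)), 1:100)
  big <- with_seed(1, subsample_cells(5000, 3000))
  expect_length(big, 3000)
  expect_false(anyDuplicated(big) > 0)
  expect_identical(with_seed(9, subsample_cells(5000, 3000)),
                   with_seed(9, subsample_cells(5000, 3000)))
})

test_that("knn_within matches hand geometry and the exhaustive oracle", {
  pts <- matrix(c(0, 1, 10), ncol = 1)
  expect_identical(as.vector(knn_within(pts, 1)), c(2L, 1L, 2L))
  set.seed(11)
  X <- matrix(rnorm(200 * 5), 200, 5)
  expect_identical(knn_within(X, 10), oracle_knn(X, 10))
  # duplicated points: nearest neighbour at distance zero
  Xd <- rbind(X[1:5, ], X[1:5, ])
  nb <- knn_within(Xd, 1)
  d0 <- sapply(1:10, function(i) sum((Xd[i, ] - Xd[nb[i, 1], ])^2))
  expect_true(all(d0 == 0))
  expect_error(knn_within(pts, 3), "smaller")
})

test_that("approximate knn recovers most exact neighbours", {
  set.seed(21)
  X <- matrix(rnorm(300 * 8), 300, 8)
  exact <- knn_within(X, 5)
  approx <- with_seed(2, knn_within(X, 5, exact = FALSE))
  recall <- mean(sapply(seq_len(nrow(X)), function(i)
    length(intersect(exact[i, ], approx[i, ])) / 5))
  expect_gte(recall, 0.8)
  expect_identical(dim(approx), dim(exact))
})

test_that("mutual_nn_pairs matches the exhaustive oracle", {
  set.seed(31)
  for (i in 1:5) {
    A <- matrix(rnorm(40 * 3), 40, 3)
    B <- matrix(rnorm(50 * 3), 50, 3)
    got <- mutual_nn_pairs(A, B, k = 3)
    want <- oracle_mnn(A, B, k = 3)
    expect_equal(got$index_a, want$index_a)
    expect_equal(got$index_b, want$index_b)
    expect_true(all(got$origin == "seed"))
    expect_true(all(got$walk_step == 0L))
  }
  # identical point sets, k = 1, distinct points: a perfect matching
  P <- matrix(seq_len(20), ncol = 1)
  same <- mutual_nn_pairs(P, P, k = 1)
  expect_equal(same$index_a, 1:20)
  expect_equal(same$index_b, 1:20)
  # one point per batch: forced mutuality
  one <- mutual_nn_pairs(matrix(0), matrix(5), k = 1)
  expect_equal(nrow(one), 1L)
  expect_equal(one$index_a, 1L)
})

test_that("distant clusters pair only through the overlapping cell", {
  set.seed(41)
  A <- matrix(rnorm(30 * 2, 0, 0.1), 30, 2)
  B <- rbind(matrix(rnorm(29 * 2, 1e6, 0.1), 29, 2), c(0, 0))
  got <- mutual_nn_pairs(A, B, k = 1)
  expect_true(all(got$index_b == 30L))
  want <- oracle_mnn(A, B, 1)
  expect_equal(got$index_a, want$index_a)
  expect_equal(got$index_b, want$index_b)
})

test_that("random_walk_extend has M(m+1) cardinality and valid chained steps", {
  set.seed(51)
  A <- matrix(rnorm(60 * 4), 60, 4)
  B <- matrix(rnorm(60 * 4), 60, 4)
  seeds <- mutual_nn_pairs(A, B, k = 2)
  knn_a <- knn_within(A, 5)
  knn_b <- knn_within(B, 5)
  # m = 0 is a no-op
  expect_identical(with_seed(1, random_walk_extend(seeds, knn_a, knn_b, 0)),
                   seeds)
  out <- with_seed(1, random_walk_extend(seeds, knn_a, knn_b, 50))
  expect_equal(nrow(out), nrow(seeds) * 51)
  expect_equal(sum(out$origin == "seed"), nrow(seeds))
  # two seeds, m = 50 -> 102 pairs
  two <- make_pair_set(seeds$index_a[1:2], seeds$index_b[1:2])
  expect_equal(nrow(with_seed(2, random_walk_extend(two, knn_a, knn_b, 50))),
               102L)
  # path validity: every walk member is a k1-neighbour of its predecessor,
  # within its own batch
  M <- nrow(seeds)
  for (step in 1:3) {
    prev <- out[out$walk_step == step - 1L, ]
    cur <- out[out$walk_step == step, ]
    for (s in seq_len(M)) {
      expect_true(cur$index_a[s] %in% knn_a[prev$index_a[s], ])
      expect_true(cur$index_b[s] %in% knn_b[prev$index_b[s], ])
    }
  }
  # indices always stay inside their own batch's table
  expect_true(all(out$index_a >= 1 & out$index_a <= nrow(A)))
  expect_true(all(out$index_b >= 1 & out$index_b <= nrow(B)))
  # determinism and dedup
  expect_identical(out, with_seed(1, random_walk_extend(seeds, knn_a, knn_b, 50)))
  dd <- with_seed(1, random_walk_extend(seeds, knn_a, knn_b, 50, dedup = TRUE))
  expect_false(any(duplicated(dd[, c("index_a", "index_b")])))
  expect_lte(nrow(dd), nrow(out))
  expect_error(random_walk_extend(seeds, knn_a, knn_b, -1), "non-negative")
})

test_that("every seed pair passes the symmetric membership test", {
  set.seed(61)
  A <- matrix(rnorm(80 * 3), 80, 3)
  B <- matrix(rnorm(70 * 3), 70, 3)
  k <- 4
  seeds <- mutual_nn_pairs(A, B, k)
  nn_ab <- oracle_knn_cross(A, B, k)
  nn_ba <- oracle_knn_cross(B, A, k)
  for (r in seq_len(nrow(seeds))) {
    expect_true(seeds$index_b[r] %in% nn_ab[seeds$index_a[r], ])
    expect_true(seeds$index_a[r] %in% nn_ba[seeds$index_b[r], ])
  }
})

test_that("seed-anchored walks draw every step from the original seed", {
  set.seed(71)
  A <- matrix(rnorm(50 * 3), 50, 3)
  B <- matrix(rnorm(50 * 3), 50, 3)
  seeds <- mutual_nn_pairs(A, B, k = 2)
  ka <- knn_within(A, 4)
  kb <- knn_within(B, 4)
  out <- with_seed(3, random_walk_extend(seeds, ka, kb, m = 10,
                                         chain = FALSE))
  M <- nrow(seeds)
  for (step in 1:10) {
    cur <- out[out$walk_step == step, ]
    for (s in seq_len(M)) {
      expect_true(cur$index_a[s] %in% ka[seeds$index_a[s], ])
      expect_true(cur$index_b[s] %in% kb[seeds$index_b[s], ])
    }
  }
})
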