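# Shared fixtures and independent oracles. Oracles are deliberately written
# as naive, loop-based recomputations so they share no code path with the
# package implementations they check.

with_seed <- batchgan:::with_seed

make_counts_es <- function(n_cells = 6, n_genes = 4, batch = "b1",
                           seed = 1, celltype = NULL) {
  m <- batchgan:::with_seed(seed,
    matrix(rpois(n_cells * n_genes, 5), n_cells, n_genes))
  expr_set(m, paste0("c", seq_len(n_cells)), paste0("g", seq_len(n_genes)),
           batch = batch, celltype = celltype, units = "raw_counts")
}

# Naive exhaustive kNN: full double loop over pairwise distances.
oracle_knn <- function(X, k, self = FALSE) {
  n <- nrow(X)
  out <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    d <- numeric(n)
    for (j in seq_len(n)) d[j] <- sqrt(sum((X[i, ] - X[j, ])^2))
    if (!self) d[i] <- Inf
    out[i, ] <- order(d, seq_len(n))[seq_len(k)]
  }
  out
}

oracle_knn_cross <- function(A, B, k) {
  out <- matrix(0L, nrow(A), k)
  for (i in seq_len(nrow(A))) {
    d <- numeric(nrow(B))
    for (j in seq_len(nrow(B))) d[j] <- sqrt(sum((A[i, ] - B[j, ])^2))
    out[i, ] <- order(d, seq_len(nrow(B)))[seq_len(k)]
  }
  out
}

oracle_mnn <- function(A, B, k) {
  nn_ab <- oracle_knn_cross(A, B, k)
  nn_ba <- oracle_knn_cross(B, A, k)
  res <- NULL
  for (i in seq_len(nrow(A))) for (j in nn_ab[i, ]) {
    if (i %in% nn_ba[j, ]) res <- rbind(res, c(i, j))
  }
  if (is.null(res)) return(data.frame(index_a = integer(), index_b = integer()))
  res <- res[order(res[, 1], res[, 2]), , drop = FALSE]
  data.frame(index_a = res[, 1], index_b = res[, 2])
}

# Naive positive / true-positive classification straight from the rule.
oracle_mixture <- function(emb, types, batches, k_cap = 100) {
  n <- nrow(emb)
  type_n <- table(types)
  batch_ids <- sort(unique(batches))
  label <- character(n)
  for (i in seq_len(n)) {
    if (type_n[[types[i]]] < 2) { label[i] <- "negative"; next }
    k <- min(k_cap, type_n[[types[i]]], n - 1)
    d <- numeric(n)
    for (j in seq_len(n)) d[j] <- sqrt(sum((emb[i, ] - emb[j, ])^2))
    d[i] <- Inf
    nb <- order(d, seq_len(n))[seq_len(k)]
    if (sum(types[nb] == types[i]) < 0.5 * k) { label[i] <- "negative"; next }
    Ni <- sapply(batch_ids, function(b) sum(types == types[i] & batches == b))
    p <- Ni / sum(Ni)
    ok <- TRUE
    for (bi in seq_along(batch_ids)) {
      ki <- sum(batches[nb] == batch_ids[bi])
      sdev <- sqrt(k * p[bi] * (1 - p[bi]))
      if (ki < max(0, k * p[bi] - 3 * sdev) || ki > k * p[bi] + 3 * sdev) {
        ok <- FALSE; break
      }
    }
    label[i] <- if (ok) "true_positive" else "false_positive"
  }
  label
}

# Independent MLP forward: per-sample, per-neuron loops, no shared code with
# mlp_forward.
oracle_forward <- function(net, X) {
  acts <- list(
    mish = function(v) v * tanh(log(1 + exp(v))),
    relu = function(v) ifelse(v > 0, v, 0),
    linear = function(v) v
  )
  do.call(rbind, lapply(seq_len(nrow(X)), function(r) {
    h <- X[r, ]
    for (li in seq_along(net$W)) {
      z <- numeric(ncol(net$W[[li]]))
      for (o in seq_along(z)) z[o] <- sum(h * net$W[[li]][, o]) + net$b[[li]][o]
      h <- acts[[net$acts[li]]](z)
    }
    matrix(h, nrow = 1)
  }))
}

# Exact identity construction: E(x) = x, G1 = 0, G2([c, b]) = c, all layers
# linear, so reconstruction is relu(x) = x for x >= 0 and both stage-one
# losses vanish exactly.
identity_stage1 <- function(d, n) {
  m <- build_stage1(d = d, n = n, l = d, widths = c(d, d), seed = 1)
  eye <- diag(d)
  lin3 <- function(net, W1, W2, W3) {
    net$acts <- c("linear", "linear", "linear")
    net$W <- list(W1, W2, W3)
    net$b <- lapply(net$W, function(w) numeric(ncol(w)))
    net
  }
  m$E <- lin3(m$E, eye, eye, eye)
  m$G1 <- lin3(m$G1, matrix(0, n, d), eye, eye)
  m$G2 <- lin3(m$G2, rbind(eye, matrix(0, n, d)), eye, eye)
  m
}

# Set every weight and bias of an mlp to zero.
zero_net <- function(net) {
  net$W <- lapply(net$W, function(w) array(0, dim = dim(w)))
  net$b <- lapply(net$b, function(b) numeric(length(b)))
  net
}

one_hot_rows <- function(idx, n) batchgan:::one_hot(idx, n)

make_pair_set <- function(index_a, index_b) {
  structure(data.frame(index_a = index_a, index_b = index_b,
                       origin = "seed",
                       walk_step = integer(length(index_a))),
            M_seeds = length(index_a), class = c("pair_set", "data.frame"))
}
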