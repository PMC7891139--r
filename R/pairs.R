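#' Pairing hyperparameters
#'
#' Computes the stage-two pairing defaults from the subsample cap and the
#' batch sizes: with `s_eff = min(s, n_a, n_b)`, the within-batch walk
#' neighbourhood is `k1 = max(1, floor(s_eff / 100))` and the MNN
#' neighbourhood is `k = max(1, floor(k1 / 2))`; the walk length is `m`.
#'
#' @param s Subsample cap per batch (default 3000).
#' @param n_a,n_b Number of cells in the two batches being paired.
#' @param m Random-walk length (default 50).
#' @return List with `s`, `k1`, `k`, `m`.
#' @export
pair_params <- function(s = 3000, n_a = s, n_b = s, m = 50) {
  stopifnot(s >= 1, n_a >= 1, n_b >= 1, m >= 0)
  s_eff <- min(s, n_a, n_b)
  k1 <- max(1L, s_eff %/% 100L)
  k <- max(1L, k1 %/% 2L)
  list(s = s, k1 = as.integer(k1), k = as.integer(k), m = as.integer(m))
}

#' Subsample cell indices
#'
#' Returns all indices (in order) when the batch is no larger than the cap
#' `s`, otherwise `s` distinct indices drawn uniformly without replacement
#' from the current RNG stream.
#'
#' @param n_cells Number of cells in the batch.
#' @param s Subsample cap.
#' @return Integer vector of cell indices.
#' @export
subsample_cells <- function(n_cells, s = 3000) {
  stopifnot(n_cells >= 1, s >= 1)
  if (n_cells <= s) seq_len(n_cells) else sort(sample.int(n_cells, s))
}

# Squared Euclidean cross-distances, blocked to bound memory.
cross_dist2 <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

# k smallest entries per row of a distance matrix, ties broken by column
# index; optionally excluding the diagonal (self).
knn_from_dist <- function(d2, k, exclude_self = FALSE) {
  n <- nrow(d2)
  out <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    di <- d2[i, ]
    if (exclude_self) di[i] <- Inf
    out[i, ] <- order(di, seq_along(di))[seq_len(k)]
  }
  out
}

# Candidate neighbours from a random-hyperplane LSH index: cells sharing a
# hash bucket in any of n_tables tables are candidates; candidates are then
# ranked exactly. Used when exact = FALSE.
lsh_candidates <- function(X, n_tables = 10L, n_bits = NULL) {
  n <- nrow(X)
  # target an average bucket occupancy of ~16 cells
  if (is.null(n_bits)) n_bits <- max(2L, ceiling(log2(n / 16)))
  cand <- vector("list", n)
  for (tb in seq_len(n_tables)) {
    H <- matrix(stats::rnorm(ncol(X) * n_bits), ncol(X))
    bits <- (X %*% H) > 0
    key <- apply(bits, 1L, function(r) paste(as.integer(r), collapse = ""))
    buckets <- split(seq_len(n), key)
    for (b in buckets) {
      if (length(b) > 1L) for (i in b) cand[[i]] <- c(cand[[i]], b)
    }
  }
  lapply(cand, unique)
}

#' Within-batch k-nearest-neighbour lists
#'
#' For each cell, the `k1` nearest other cells of the same batch by Euclidean
#' distance in content-code space (self excluded; ties broken by cell index).
#' With `exact = FALSE` an approximate random-hyperplane LSH index proposes
#' candidates that are re-ranked exactly and padded by exact search when too
#' few; with `exact = TRUE` the search is exhaustive.
#'
#' @param codes Cells x l code matrix of one batch.
#' @param k1 Neighbourhood size; must be smaller than the number of cells.
#' @param exact Use exhaustive search (default `TRUE`).
#' @return Integer cells x `k1` matrix of neighbour indices.
#' @export
knn_within <- function(codes, k1, exact = TRUE) {
  codes <- as.matrix(codes)
  n <- nrow(codes)
  if (k1 >= n) stop("k1 (", k1, ") must be smaller than the number of cells (",
                    n, ")")
  d2 <- cross_dist2(codes, codes)
  if (exact) return(knn_from_dist(d2, k1, exclude_self = TRUE))
  cand <- lsh_candidates(codes)
  out <- matrix(0L, n, k1)
  for (i in seq_len(n)) {
    cc <- setdiff(cand[[i]], i)
    if (length(cc) < k1) {
      di <- d2[i, ]; di[i] <- Inf
      out[i, ] <- order(di, seq_len(n))[seq_len(k1)]
    } else {
      o <- order(d2[i, cc], cc)
      out[i, ] <- cc[o][seq_len(k1)]
    }
  }
  out
}

# k nearest neighbours in `ref` for each row of `query` (no self notion).
knn_cross <- function(query, ref, k) {
  if (k > nrow(ref)) stop("k exceeds the number of reference cells")
  d2 <- cross_dist2(as.matrix(query), as.matrix(ref))
  knn_from_dist(d2, k, exclude_self = FALSE)
}

#' Mutual nearest-neighbour pairs between two batches
#'
#' A pair `(i, j)` is included iff cell `j` of batch B is among the `k`
#' nearest across-batch neighbours of cell `i` of batch A *and* vice versa.
#' Pairs are returned in lexicographic `(i, j)` order with `origin = "seed"`
#' and `walk_step = 0`.
#'
#' @param codes_a,codes_b Code matrices of the two batches.
#' @param k Across-batch neighbourhood size.
#' @param exact Use exhaustive search (default `TRUE`; the approximate path
#'   re-ranks LSH candidates).
#' @return An object of class `pair_set`: data frame with columns `index_a`,
#'   `index_b`, `origin`, `walk_step`, plus attribute `M_seeds`.
#' @export
mutual_nn_pairs <- function(codes_a, codes_b, k, exact = TRUE) {
  codes_a <- as.matrix(codes_a); codes_b <- as.matrix(codes_b)
  if (k > min(nrow(codes_a), nrow(codes_b)))
    stop("k must not exceed the batch sizes")
  nn_ab <- knn_cross(codes_a, codes_b, k)   # for each a, k nearest b
  nn_ba <- knn_cross(codes_b, codes_a, k)   # for each b, k nearest a
  in_ba <- matrix(FALSE, nrow(codes_b), nrow(codes_a))
  in_ba[cbind(rep(seq_len(nrow(codes_b)), k), as.vector(nn_ba))] <- TRUE
  ia <- rep(seq_len(nrow(codes_a)), k)
  ib <- as.vector(nn_ab)
  keep <- in_ba[cbind(ib, ia)]
  pairs <- data.frame(index_a = ia[keep], index_b = ib[keep])
  pairs <- pairs[order(pairs$index_a, pairs$index_b), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs$origin <- rep("seed", nrow(pairs))
  pairs$walk_step <- integer(nrow(pairs))
  if (nrow(pairs) == 0L)
    warning("no mutual nearest-neighbour pairs found")
  structure(pairs, M_seeds = nrow(pairs),
            class = c("pair_set", "data.frame"))
}

#' Expand seed pairs by within-batch random walks
#'
#' For every seed pair `(a1, a2)` and `m` steps: from the current pair, pick
#' uniformly one of the `k1` within-batch neighbours of the batch-A member
#' and, independently, one of the batch-B member's neighbours; the new pair
#' is recorded and (with `chain = TRUE`, the default) becomes the next walk
#' state, so the walk diffuses outwards over the shared type's
#' distribution. With `chain = FALSE` every step is drawn afresh from the
#' original seed's neighbourhood instead. The output contains the seeds
#' followed by all extensions, `M * (m + 1)` pairs in total before optional
#' deduplication.
#'
#' @param seeds A `pair_set` of seed pairs (from [mutual_nn_pairs()]).
#' @param knn_a,knn_b Within-batch neighbour tables from [knn_within()] built
#'   on the same cells the seed indices refer to.
#' @param m Walk length (number of extension steps per seed).
#' @param dedup Drop duplicated pairs after the walk (default `FALSE`:
#'   duplicates reweight dense regions).
#' @param chain Chain each step from the previous extension (default) or
#'   restart every step at the original seed.
#' @return A `pair_set` with `origin` `"seed"` or `"walk"` and the walk step.
#' @export
random_walk_extend <- function(seeds, knn_a, knn_b, m, dedup = FALSE,
                               chain = TRUE) {
  stopifnot(inherits(seeds, "pair_set"))
  if (m < 0) stop("walk length m must be non-negative")
  M <- nrow(seeds)
  if (M == 0L) stop("cannot extend an empty seed set")
  if (m == 0L && !dedup) return(seeds)
  k1a <- ncol(knn_a); k1b <- ncol(knn_b)
  cur_a <- seeds$index_a; cur_b <- seeds$index_b
  ext_a <- ext_b <- vector("list", m)
  for (step in seq_len(m)) {
    from_a <- if (chain) cur_a else seeds$index_a
    from_b <- if (chain) cur_b else seeds$index_b
    cur_a <- knn_a[cbind(from_a, sample.int(k1a, M, replace = TRUE))]
    cur_b <- knn_b[cbind(from_b, sample.int(k1b, M, replace = TRUE))]
    ext_a[[step]] <- cur_a
    ext_b[[step]] <- cur_b
  }
  out <- data.frame(
    index_a = c(seeds$index_a, unlist(ext_a)),
    index_b = c(seeds$index_b, unlist(ext_b)),
    origin = c(rep("seed", M), rep("walk", M * m)),
    walk_step = c(integer(M), rep(seq_len(m), each = M))
  )
  if (dedup) out <- out[!duplicated(out[, c("index_a", "index_b")]), ]
  rownames(out) <- NULL
  structure(out, M_seeds = attr(seeds, "M_seeds"),
            class = c("pair_set", "data.frame"))
}

#' Export a pair set as TSV
#'
#' @param pairs A `pair_set`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  stopifnot(inherits(pairs, "pair_set"))
  utils::write.table(as.data.frame(pairs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
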