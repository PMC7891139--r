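#' Derive a component seed from a global seed
#'
#' Deterministically fans a single user-supplied seed out to independent
#' per-component seeds so that every stochastic step of the pipeline is
#' reproducible and can be re-run in isolation. The result always lies in
#' `[1, 2^31 - 2]`.
#'
#' @param seed Integer global seed.
#' @param tag Character label naming the component (e.g. `"stage1"`,
#'   `"pairs:round1"`).
#' @return An integer seed.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  h <- as.double(seed %% 2147483647)
  for (code in utf8ToInt(tag)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h %% 2147483646) + 1L
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
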