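#' Keyed reproducible normal draws
#'
#' Monte Carlo REML requires that every round of sampling can replay the exact
#' same sequence of standard normal deviates: the restricted log-likelihood and
#' the trace estimators must only change because the variance components
#' change, never because of fresh Monte Carlo noise. Instead of relying on the
#' global R RNG state (which would make the draw sequence depend on evaluation
#' order), every draw site is keyed by a `(base_seed, site)` pair that is
#' hashed to a 31-bit seed. Reusing a key reproduces the draws bit for bit.
#'
#' @param base_seed integer base seed of the sampling stream.
#' @param site character label of the draw site, e.g. `"s12:gene_drop"`.
#' @param n,m dimensions of the matrix of N(0, 1) draws to return.
#' @return An `n` by `m` numeric matrix of independent standard normals.
#' @examples
#' a <- keyed_normals(1, "s1:gd", 4, 2)
#' b <- keyed_normals(1, "s1:gd", 4, 2)
#' identical(a, b)
#' @export
keyed_normals <- function(base_seed, site, n, m = 1L) {
  seed <- site_seed(base_seed, site)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  matrix(rnorm(n * m), nrow = n, ncol = m)
}

# Deterministic 31-bit seed from (base_seed, site). FNV-style byte mix done in
# double precision; all intermediates stay below 2^52 so the arithmetic is
# exact, and the result is reduced mod (2^31 - 1).
site_seed <- function(base_seed, site) {
  mod <- 2147483647
  h <- (as.numeric(base_seed) %% mod + 1) * 2654435761 %% mod
  bytes <- utf8ToInt(as.character(site))
  for (b in bytes) {
    h <- (h * 131 + b) %% mod
  }
  h <- (h * 2654435761 + 88172645) %% mod
  as.integer(h)
}

# Stream key helper: MC sample draws are keyed per (sample index, site name) so
# that the per-sample and blocked sampling paths consume identical numbers, and
# so that rounds reuse the sequence when `reuse_sequence` is on.
mc_site <- function(sample_index, site, round = NULL, reuse_sequence = TRUE) {
  if (reuse_sequence || is.null(round)) {
    sprintf("s%d:%s", sample_index, site)
  } else {
    sprintf("r%d:s%d:%s", round, sample_index, site)
  }
}
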