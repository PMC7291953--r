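# Internal helpers shared across modules.

# Derive a child seed from a master seed and an integer key. Keeps every
# result below 2^31 - 1 so set.seed() always accepts it. The multipliers are
# primes; exactness is guaranteed because all intermediates stay < 2^53.
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(as.double(seed)) * 48271 + as.double(key) * 1299721 + 12345) %%
               2147483646) + 1L
}

# Lower-triangle vector of a dist or square matrix, in a fixed order.
dist_vec <- function(d) {
  m <- as.matrix(d)
  m[lower.tri(m)]
}

# All sample pairs (i < j) of n samples, as a 2-column integer matrix.
sample_pairs <- function(n) {
  if (n < 2L) stop("need at least two samples to form pairs", call. = FALSE)
  t(utils::combn(n, 2L))
}

# All permutations of 1..n as an n! x n matrix (exhaustive significance tests).
all_permutations <- function(n) {
  if (n > 8L) stop("exhaustive enumeration limited to n <= 8", call. = FALSE)
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (r in seq_len(nrow(sub))) {
    for (pos in seq_len(n)) {
      out[row, ] <- as.integer(append(sub[r, ], n, after = pos - 1L))
      row <- row + 1L
    }
  }
  out
}

# Validate a dissimilarity object; returns it as a "dist".
as_dist_checked <- function(d, what = "distance matrix") {
  if (inherits(d, "dist")) return(d)
  m <- as.matrix(d)
  if (nrow(m) != ncol(m)) stop(what, " must be square", call. = FALSE)
  if (max(abs(m - t(m))) > 1e-12) stop(what, " must be symmetric", call. = FALSE)
  if (any(abs(diag(m)) > 1e-12)) stop(what, " must have a zero diagonal", call. = FALSE)
  stats::as.dist(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr under a local RNG seed, restoring the caller's RNG state
# afterwards so package internals never perturb user-level randomness.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
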