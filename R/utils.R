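# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. seed = NULL leaves the stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Moore-Penrose pseudoinverse via SVD; tolerance relative to the largest
# singular value, as in standard numerical practice.
pinv <- function(A, tol = sqrt(.Machine$double.eps)) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d[1L], .Machine$double.eps)
  if (!any(keep)) {
    return(matrix(0, ncol(A), nrow(A)))
  }
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# Row variances of a numeric matrix (sample variance, n - 1 denominator).
row_vars <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a reproducible sub-seed from a base seed and stage offsets,
# kept within the 32-bit integer range.
derive_seed <- function(seed, ...) {
  offs <- sum(unlist(list(...)))
  as.integer((as.double(seed) + offs) %% .Machine$integer.max)
}
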