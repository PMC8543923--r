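#' @keywords internal
"_PACKAGE"

# Rank of a matrix by SVD; singular values below tol * max are treated as zero.
mat_rank <- function(M, tol = 1e-8) {
  if (length(M) == 0L) return(0L)
  d <- svd(M, nu = 0, nv = 0)$d
  sum(d > tol * max(d, .Machine$double.eps))
}

# Moore-Penrose pseudo-inverse of a (possibly rank-deficient) matrix.
mp_pinv <- function(M, tol = 1e-8) {
  M <- as.matrix(M)
  s <- svd(M)
  keep <- s$d > tol * max(s$d, .Machine$double.eps)
  if (!any(keep)) return(matrix(0, ncol(M), nrow(M)))
  s$v[, keep, drop = FALSE] %*% ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}

# Orthonormal basis (rows) of the left null space of A: all c with t(c) %*% A = 0.
left_null_basis <- function(A, tol = 1e-8) {
  A <- as.matrix(A)
  s <- svd(A, nu = nrow(A))
  r <- sum(s$d > tol * max(s$d, .Machine$double.eps))
  if (r >= nrow(A)) return(matrix(0, 0L, nrow(A)))
  t(s$u[, seq.int(r + 1L, nrow(A)), drop = FALSE])
}

expit <- function(x) 1 / (1 + exp(-x))

# Canonical label for a design: its sorted treatment set joined by ":".
design_label <- function(treatments) paste(sort(unique(treatments)), collapse = ":")

# Deterministic per-replicate substream seed derived from a root seed.
# Keeps values in [1, 2^31 - 2] so set.seed() always accepts them, and makes
# replicate i independent of how many replicates precede it.
substream_seed <- function(seed, i) {
  as.integer((as.double(seed) %% 2147483647 * 48271 + i * 16807) %% 2147483646 + 1)
}
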