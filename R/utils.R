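# Internal numerical helpers. Node states are stored as dense `d x (n*P)`
# matrices (hidden unit fastest, then node, then patient: column
# (p-1)*n + u holds node u of patient p). In this layout a per-node linear
# map is one BLAS product W %*% H, and neighbour aggregation is one sparse
# product (A %x% I_d) %*% H after a free dim change to (d*n) x P, so the
# hot path never reshapes data.

# Sparse Kronecker A %x% I_d used for per-patient aggregation.
kron_id <- function(A, d) {
  methods::as(Matrix::kronecker(A, Matrix::Diagonal(d)), "CsparseMatrix")
}

# Apply an aggregation operator K = A %x% I_d to states H (d x (n_src*P)),
# returning d x (n_dst*P).
agg_apply <- function(K, H, d) {
  P <- (ncol(H) * d) %/% ncol(K)
  dim(H) <- c(ncol(K), P)
  out <- as.matrix(K %*% H)
  dim(out) <- c(d, length(out) %/% d)
  out
}

# Column-wise softmax of an n x P score matrix.
col_softmax <- function(S) {
  S <- sweep(S, 2L, apply(S, 2L, max), "-")
  E <- exp(S)
  sweep(E, 2L, colSums(E), "/")
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Deterministic substream seeds derived from one root seed; kept < 2^31.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

`%||%` <- rlang::`%||%`
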