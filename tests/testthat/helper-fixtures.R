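# Shared fixtures and small oracles used across the test files.

# Largest principal angle (radians) between the column spaces of A and B,
# computed through the sine (accurate near zero, unlike acos of a cosine).
principal_angle <- function(A, B) {
  QA <- qr.Q(qr(A)); QB <- qr.Q(qr(B))
  s <- svd(QB - QA %*% crossprod(QA, QB))$d
  asin(min(max(s), 1))
}

rand_tensor <- function(shape, sd = 1) {
  array(stats::rnorm(prod(shape), sd = sd), dim = shape)
}

rand_orthonormal <- function(n, k) {
  qr.Q(qr(matrix(stats::rnorm(n * k), n, k)))
}

# Cohort of exactly multilinear-rank tensors with known generating factors.
lowrank_cohort <- function(M, shape, ranks, seed = 1) {
  set.seed(seed)
  U <- mapply(rand_orthonormal, shape, ranks, SIMPLIFY = FALSE)
  samples <- lapply(seq_len(M), function(i) {
    tucker_reconstruct(rand_tensor(ranks), U)
  })
  list(samples = samples, factors = U)
}
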