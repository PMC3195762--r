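test_that("unfold follows the documented column-ordering convention", {
  a <- array(as.numeric(1:8), c(2, 2, 2))   # entry = i1 + 2(i2-1) + 4(i3-1)
  expect_identical(unfold(a, 1), matrix(c(1, 2, 3, 4, 5, 6, 7, 8), 2))
  # enumerate all index tuples for mode 2: columns are (i1, i3) pairs,
  # i1 fastest
  m2 <- matrix(0, 2, 4)
  for (i1 in 1:2) for (i2 in 1:2) for (i3 in 1:2) {
    m2[i2, i1 + 2 * (i3 - 1)] <- a[i1, i2, i3]
  }
  expect_identical(unfold(a, 2), m2)
  expect_identical(unfold(array(0, c(3, 4, 5)), 2), matrix(0, 4, 15))
  expect_error(unfold(a, 4), "1\\.\\.3")
  expect_error(unfold(a, 0), "1\\.\\.3")
})

test_that("fold inverts unfold exactly for all modes and small shapes", {
  set.seed(1)
  t1 <- rand_tensor(c(3, 5, 7))
  expect_identical(fold(unfold(t1, 2), 2, dim(t1)), t1)
  m <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8), 2)
  expect_identical(fold(m, 1, c(2, 2, 2)), array(as.numeric(1:8), c(2, 2, 2)))
  # exhaustive sweep over shapes up to 9x9x9 (coarse grid of extents)
  for (i in c(1, 2, 4, 9)) for (j in c(1, 3, 5, 9)) for (k in c(1, 2, 7, 9)) {
    t <- rand_tensor(c(i, j, k))
    for (mode in 1:3) {
      expect_identical(fold(unfold(t, mode), mode, dim(t)), t)
    }
  }
  expect_error(fold(matrix(0, 2, 5), 1, c(2, 2, 2)), "expected")
})

test_that("mode product matches direct contraction and commutes across modes", {
  set.seed(2)
  t <- rand_tensor(c(3, 3, 3))
  expect_equal(ttm(t, diag(3), 2), t, tolerance = 1e-15)
  # all-ones row vector gives mode-n sums (brute-force summation oracle)
  ones <- matrix(1, 1, 3)
  s2 <- apply(t, c(1, 3), sum)
  expect_equal(drop(ttm(t, ones, 2)), s2, tolerance = 1e-12)
  # products on distinct modes commute
  A <- matrix(rnorm(12), 4, 3); B <- matrix(rnorm(6), 2, 3)
  expect_equal(ttm(ttm(t, A, 1), B, 2), ttm(ttm(t, B, 2), A, 1),
               tolerance = 1e-12)
  expect_error(ttm(t, matrix(0, 2, 4), 1), "columns")
})

test_that("orthonormal square mode products preserve the Frobenius norm", {
  set.seed(3)
  for (rep in 1:5) {
    t <- rand_tensor(c(4, 6, 5))
    Q <- rand_orthonormal(6, 6)
    expect_equal(fnorm(ttm(t, Q, 2)), fnorm(t), tolerance = 1e-12)
  }
})

test_that("tucker_reconstruct handles identity, outer-product and zero cores", {
  set.seed(4)
  t <- rand_tensor(c(3, 4, 2))
  ids <- lapply(dim(t), diag)
  expect_equal(tucker_reconstruct(t, ids), t, tolerance = 1e-15)
  # rank-1 core: explicit outer-product oracle
  u <- rnorm(5); u <- u / sqrt(sum(u^2))
  v <- rnorm(4); v <- v / sqrt(sum(v^2))
  w <- rnorm(3); w <- w / sqrt(sum(w^2))
  core <- array(2, c(1, 1, 1))
  rec <- tucker_reconstruct(core, list(matrix(u), matrix(v), matrix(w)))
  expect_equal(rec, 2 * outer(outer(u, v), w), tolerance = 1e-12)
  expect_equal(tucker_reconstruct(array(0, c(2, 2, 2)),
                                  list(matrix(rnorm(8), 4), matrix(rnorm(6), 3),
                                       matrix(rnorm(4), 2))),
               array(0, c(4, 3, 2)), tolerance = 1e-15)
  expect_error(tucker_reconstruct(t, ids[1:2]), "factor")
})

test_that("tucker_reconstruct is linear in the core", {
  set.seed(5)
  U <- lapply(c(5, 4, 3), function(n) matrix(rnorm(n * 2), n, 2))
  b1 <- rand_tensor(c(2, 2, 2)); b2 <- rand_tensor(c(2, 2, 2))
  expect_equal(tucker_reconstruct(2 * b1 - 3 * b2, U),
               2 * tucker_reconstruct(b1, U) - 3 * tucker_reconstruct(b2, U),
               tolerance = 1e-12)
})

test_that("fnorm equals the vector 2-norm of the flattened tensor", {
  expect_identical(fnorm(array(0, c(2, 3, 4))), 0)
  t <- array(0, c(3, 3, 3)); t[1, 1, 1] <- 3; t[2, 2, 2] <- 4
  expect_equal(fnorm(t), 5)
  set.seed(6)
  t <- rand_tensor(c(4, 4, 4))
  expect_equal(fnorm(t), sqrt(sum(as.vector(t)^2)))
})

test_that("normalized correlation behaves as a Pearson correlation", {
  set.seed(7)
  t <- rand_tensor(c(5, 5, 4))
  expect_equal(normalized_correlation(t, t), 1)
  expect_equal(normalized_correlation(t, -t + 3), -1)
  a <- rand_tensor(c(50, 50, 40)); b <- rand_tensor(c(50, 50, 40))
  expect_lt(abs(normalized_correlation(a, b)), 0.02)
  expect_error(normalized_correlation(t, array(1, dim(t))), "zero-variance")
  expect_error(normalized_correlation(t, rand_tensor(c(5, 5, 5))), "shape")
})
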