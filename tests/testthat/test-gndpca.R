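test_that("centering produces a zero-sum cohort and keeps the mean", {
  set.seed(1)
  t <- rand_tensor(c(3, 4, 2))
  ctr <- tensor_center(list(t, -t))
  expect_equal(ctr$mean, array(0, dim(t)), tolerance = 1e-12)
  expect_equal(ctr$centered[[1]], t, tolerance = 1e-12)
  ctr1 <- tensor_center(list(t))
  expect_equal(ctr1$mean, t)
  expect_equal(ctr1$centered[[1]], array(0, dim(t)), tolerance = 1e-12)
  samples <- replicate(5, rand_tensor(c(3, 4, 2)), simplify = FALSE)
  s <- Reduce(`+`, tensor_center(samples)$centered)
  expect_lt(max(abs(s)), 1e-10 * max(abs(samples[[1]])))
  expect_error(tensor_center(list()), "non-empty")
  expect_error(tensor_center(list(t, rand_tensor(c(3, 4, 3)))), "shape")
})

test_that("HOSVD initialization recovers exact multilinear subspaces", {
  lr <- lowrank_cohort(1, c(8, 7, 6), c(2, 2, 2), seed = 2)
  f <- init_factors(lr$samples, c(2, 2, 2))
  for (n in 1:3) {
    expect_lt(principal_angle(f[[n]], lr$factors[[n]]), 1e-8)
  }
  # full ranks give square orthonormal matrices
  ff <- init_factors(lr$samples, c(8, 7, 6))
  for (n in 1:3) {
    expect_equal(dim(ff[[n]]), c(dim(lr$samples[[1]])[n], dim(lr$samples[[1]])[n]))
    expect_lt(max(abs(crossprod(ff[[n]]) - diag(ncol(ff[[n]])))), 1e-10)
  }
  # a tensor supported on the first mode-3 slice has U3 spanning e1
  t <- array(0, c(4, 4, 3)); t[, , 1] <- matrix(rnorm(16), 4)
  f3 <- init_factors(list(t), c(2, 2, 1))[[3]]
  expect_lt(principal_angle(f3, matrix(c(1, 0, 0))), 1e-10)
  expect_error(init_factors(lr$samples, c(9, 2, 2)), "exceed")
})

test_that("fit recovers exactly low-rank cohorts at the true ranks", {
  lr <- lowrank_cohort(10, c(16, 16, 8), c(4, 4, 2), seed = 3)
  fit <- gndpca(lr$samples, ranks = c(4, 4, 2))
  energy <- sum(vapply(lr$samples, function(t) sum(t^2), numeric(1)))
  expect_lt(utils::tail(fit$fit_history, 1), 1e-16 * energy)
  for (n in 1:3) {
    expect_lt(principal_angle(fit$factors[[n]], lr$factors[[n]]), 1e-6)
  }
  # training samples reconstruct to near machine precision
  rec <- predict(fit, lr$samples[[1]], type = "reconstruction")
  expect_lt(fnorm(rec - lr$samples[[1]]), 1e-10 * fnorm(lr$samples[[1]]))
})

test_that("full-rank models are complete bases: zero cost after one sweep", {
  set.seed(4)
  samples <- replicate(4, rand_tensor(c(5, 6, 4)), simplify = FALSE)
  fit <- gndpca(samples, ranks = c(5, 6, 4), max_iter = 1)
  energy <- sum(vapply(samples, function(t) sum(t^2), numeric(1)))
  expect_lt(fit$fit_history[1], 1e-12 * energy)
  expect_equal(gndpca_cost(fit, samples), 0, tolerance = 1e-8 * energy)
  t <- rand_tensor(c(5, 6, 4))
  expect_equal(predict(fit, t, type = "reconstruction"), t,
               tolerance = 1e-10)
})

test_that("with two singleton modes the fit equals classical PCA", {
  set.seed(5)
  M <- 12; I1 <- 20
  samples <- replicate(M, rand_tensor(c(I1, 1, 1)), simplify = FALSE)
  fit <- gndpca(samples, ranks = c(3, 1, 1))
  # direct eigendecomposition of the vector scatter as oracle
  X <- vapply(samples, as.vector, numeric(I1))
  Xc <- X - rowMeans(X)
  eo <- eigen(tcrossprod(Xc), symmetric = TRUE)
  expect_lt(principal_angle(fit$factors[[1]], eo$vectors[, 1:3]), 1e-8)
})

test_that("cost history is non-increasing and orthonormality holds", {
  set.seed(6)
  for (rep in 1:6) {
    M <- sample(3:6, 1)
    shape <- sample(4:9, 3, replace = TRUE)
    ranks <- pmax(1, shape - sample(1:3, 3, replace = TRUE))
    samples <- replicate(M, rand_tensor(shape), simplify = FALSE)
    fit <- gndpca(samples, ranks = ranks, max_iter = 20)
    expect_true(all(diff(fit$fit_history) <= 1e-9 * fit$fit_history[1]))
    for (U in fit$factors) {
      expect_lt(max(abs(crossprod(U) - diag(ncol(U)))), 1e-8)
    }
  }
})

test_that("iteration controls behave: max_iter caps sweeps, seeds reproduce", {
  set.seed(7)
  samples <- replicate(4, rand_tensor(c(6, 6, 4)), simplify = FALSE)
  fit1 <- gndpca(samples, ranks = c(3, 3, 2), max_iter = 1)
  expect_length(fit1$fit_history, 1)
  expect_false(fit1$converged)
  r1 <- gndpca(samples, ranks = c(3, 3, 2), init = "random", seed = 9)
  r2 <- gndpca(samples, ranks = c(3, 3, 2), init = "random", seed = 9)
  expect_identical(r1$factors, r2$factors)
  expect_error(gndpca(samples, ranks = c(7, 3, 2)), "exceed")
  expect_error(gndpca(samples, ranks = c(3, 3)), "per mode")
  bad <- samples; bad[[2]][1] <- NA
  expect_error(gndpca(bad, ranks = c(3, 3, 2)), "non-finite")
})

test_that("projection and reconstruction are mutually consistent", {
  lr <- lowrank_cohort(8, c(10, 9, 6), c(3, 3, 2), seed = 8)
  fit <- gndpca(lr$samples, ranks = c(3, 3, 2))
  # the model mean projects to the zero core
  expect_equal(project(fit, fit$mean), array(0, c(3, 3, 2)),
               tolerance = 1e-10)
  # exact-recovery roundtrip on a training sample
  t <- lr$samples[[3]]
  expect_equal(reconstruct(fit, project(fit, t)), t, tolerance = 1e-10)
  # projection is linear in (t - mean)
  a <- rand_tensor(c(10, 9, 6)); b <- rand_tensor(c(10, 9, 6))
  pa <- project(fit, a) - project(fit, fit$mean)
  pb <- project(fit, b) - project(fit, fit$mean)
  pab <- project(fit, a + b - fit$mean) - project(fit, fit$mean)
  expect_equal(pab, pa + pb, tolerance = 1e-9)
  # zero core reconstructs the mean
  expect_equal(reconstruct(fit, array(0, c(3, 3, 2))), fit$mean,
               tolerance = 1e-12)
  expect_error(project(fit, rand_tensor(c(10, 9, 5))), "shape")
  expect_error(reconstruct(fit, array(0, c(3, 3, 3))), "ranks")
})

test_that("the projected core minimizes reconstruction error at fixed ranks", {
  set.seed(9)
  samples <- replicate(6, rand_tensor(c(8, 8, 5)), simplify = FALSE)
  fit <- gndpca(samples, ranks = c(3, 3, 2))
  t <- rand_tensor(c(8, 8, 5))
  best <- fnorm(reconstruct(fit, project(fit, t)) - t)
  for (i in 1:200) {
    other <- fnorm(reconstruct(fit, rand_tensor(c(3, 3, 2), sd = 2)) - t)
    expect_gte(other, best - 1e-10)
  }
})

test_that("the cost is invariant to within-subspace rotation of a factor", {
  set.seed(10)
  samples <- replicate(5, rand_tensor(c(7, 6, 5)), simplify = FALSE)
  fit <- gndpca(samples, ranks = c(3, 3, 2))
  c0 <- gndpca_cost(fit, samples)
  R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  rot <- fit
  rot$factors[[1]] <- fit$factors[[1]] %*% R
  expect_equal(gndpca_cost(rot, samples), c0, tolerance = 1e-9 * (c0 + 1))
})

test_that("model archives roundtrip through write_model/read_model", {
  lr <- lowrank_cohort(4, c(6, 6, 4), c(2, 2, 2), seed = 11)
  fit <- gndpca(lr$samples, ranks = c(2, 2, 2))
  path <- tempfile(fileext = ".rds")
  write_model(fit, path)
  back <- read_model(path)
  expect_identical(back$factors, fit$factors)
  expect_identical(back$mean, fit$mean)
  expect_identical(class(back), "gndpca")
  saveRDS(list(1), path)
  expect_error(read_model(path), "model")
})
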