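test_that("the cubic B-spline kernel has its defining values and properties", {
  expect_equal(bspline_kernel(0), 2 / 3)
  expect_equal(bspline_kernel(c(-1, 1)), c(1 / 6, 1 / 6))
  expect_equal(bspline_kernel(c(-2, 2, 3)), c(0, 0, 0))
  # evaluate the piecewise cubic directly as oracle at a few points
  expect_equal(bspline_kernel(0.5), (4 - 6 * 0.25 + 3 * 0.125) / 6)
  expect_equal(bspline_kernel(1.5), (2 - 1.5)^3 / 6)
  set.seed(1)
  a <- runif(1000, -50, 50)
  expect_equal(bspline_kernel(a), bspline_kernel(-a))
  # partition of unity over the 4 active integer shifts
  pu <- vapply(a, function(x) {
    sum(bspline_kernel(x - (floor(x) + (-2:2))))
  }, numeric(1))
  expect_lt(max(abs(pu - 1)), 1e-12)
  expect_true(all(bspline_kernel(runif(100, -3, 3)) >= 0))
})

test_that("rigid transforms compose, rotate about the stated center and invert", {
  p <- c(3, -1, 2)
  expect_equal(rigid_apply(p, rigid_params()), p)
  # 90 degrees about z maps center+(d,0,0) to center+(0,d,0)
  ctr <- c(10, 20, 5)
  out <- rigid_apply(ctr + c(4, 0, 0), rigid_params(theta = c(0, 0, pi / 2)),
                     center = ctr)
  expect_equal(out, ctr + c(0, 4, 0), tolerance = 1e-12)
  # roundtrip through the inverse parameters
  params <- rigid_params(theta = c(0.1, -0.2, 0.3), t = c(1, -2, 0.5))
  R <- gndpca:::rotation_matrix(params$theta)
  q <- rigid_apply(p, params, center = ctr)
  back <- drop(t(R) %*% (q - ctr - params$t)) + ctr
  expect_equal(back, p, tolerance = 1e-10)
})

test_that("FFD displacement reproduces zero, constant and single-point fields", {
  ref <- volume(array(0, c(20, 20, 10)))
  g <- bspline_grid(c(4, 4, 2), ref)
  p <- cbind(runif(30, 0, 19), runif(30, 0, 19), runif(30, 0, 9))
  expect_equal(ffd_displacement(p, g), matrix(0, 30, 3))
  # constant coefficients: partition of unity in 3D gives exactly c
  g$lambda[, , , 1] <- 1.5; g$lambda[, , , 2] <- -2; g$lambda[, , , 3] <- 0.25
  d <- ffd_displacement(p, g)
  expect_equal(d, matrix(rep(c(1.5, -2, 0.25), each = 30), 30),
               tolerance = 1e-12)
  # single nonzero coefficient: displacement at its knot is lambda * (2/3)^3
  g2 <- bspline_grid(c(4, 4, 2), ref)
  g2$lambda[4, 4, 3, ] <- c(3, 0, -1)   # padded index: control point (2,2,1)
  knot <- c(2 * g2$rho[1], 2 * g2$rho[2], 1 * g2$rho[3])
  expect_equal(ffd_displacement(knot, g2), c(3, 0, -1) * (2 / 3)^3,
               tolerance = 1e-12)
  expect_error(ffd_displacement(c(-50, 0, 0), g2), "outside")
  expect_equal(ffd_displacement(c(-50, 0, 0), g2, outside = "zero"),
               c(0, 0, 0))
})

test_that("composite transforms add the rigid and local parts", {
  ref <- volume(array(0, c(16, 16, 8)))
  p <- cbind(runif(10, 2, 13), runif(10, 2, 13), runif(10, 1, 6))
  expect_equal(composite_apply(p, composite_transform()), p)
  g <- bspline_grid(c(3, 3, 2), ref)
  g$lambda[, , , 2] <- 0.75
  tr <- composite_transform(ffd = g)
  expect_equal(composite_apply(p, tr),
               p + matrix(rep(c(0, 0.75, 0), each = 10), 10),
               tolerance = 1e-12)
  rp <- rigid_params(t = c(1, 2, 3))
  expect_equal(composite_apply(p, composite_transform(rp)),
               sweep(p, 2, c(1, 2, 3), `+`), tolerance = 1e-12)
})

test_that("transforms serialize losslessly to JSON", {
  ref <- volume(array(0, c(12, 12, 6)), spacing = c(1, 1, 2),
                origin = c(-3, 0, 1))
  g <- bspline_grid(c(3, 3, 2), ref)
  set.seed(2)
  g$lambda <- array(rnorm(length(g$lambda)), dim = dim(g$lambda))
  tr <- composite_transform(rigid_params(theta = c(0.1, 0, -0.2),
                                         t = c(1, 2, 3)),
                            ffd = g, center = c(5, 5, 5))
  path <- tempfile(fileext = ".json")
  write_transform(tr, path)
  back <- read_transform(path)
  expect_equal(back$rigid$theta, tr$rigid$theta)
  expect_equal(back$rigid$t, tr$rigid$t)
  expect_equal(back$center, tr$center)
  expect_equal(back$ffd$lambda, tr$ffd$lambda)
  expect_equal(back$ffd$rho, tr$ffd$rho)
  p <- cbind(runif(5, 1, 10), runif(5, 1, 10), runif(5, 2, 8))
  expect_equal(composite_apply(p, back), composite_apply(p, tr),
               tolerance = 1e-12)
})

test_that("lattice construction validates its inputs", {
  ref <- volume(array(0, c(10, 10, 5)))
  expect_error(bspline_grid(c(0, 3, 2), ref), ">= 1")
  expect_error(bspline_grid(c(3, 3, 2), ref, lambda = array(0, c(2, 2, 2, 3))),
               "shape")
  g <- bspline_grid(c(3, 3, 2), ref)
  expect_equal(dim(g$lambda), c(6L, 6L, 5L, 3L))
  expect_equal(g$rho, (c(10, 10, 5) - 1) / c(3, 3, 2))
})
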