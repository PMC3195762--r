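test_that("the template is a deterministic phantom with plausible foreground", {
  tmpl <- make_template(c(32, 32, 16))
  frac <- mean(tmpl$data > 0)
  expect_gte(frac, 0.15)
  expect_lte(frac, 0.55)
  expect_true(all(tmpl$data >= 0))
  # the foreground mask is bilaterally symmetric in every axis
  mask <- tmpl$data > 0
  expect_identical(mask, mask[rev(seq_len(32)), , ])
  expect_identical(mask, mask[, rev(seq_len(32)), ])
  expect_identical(mask, mask[, , rev(seq_len(16))])
  expect_identical(make_template(c(32, 32, 16))$data, tmpl$data)
})

test_that("samples are bit-reproducible from (seed, index, abnormal)", {
  spec <- cohort_spec(shape = c(24, 24, 12), seed = 5)
  a <- sample_volume(spec, 2, abnormal = TRUE)
  b <- sample_volume(spec, 2, abnormal = TRUE)
  expect_identical(a$data, b$data)
  expect_identical(attr(a, "truth")$texture_coefs,
                   attr(b, "truth")$texture_coefs)
  c_ <- sample_volume(spec, 3, abnormal = TRUE)
  expect_false(identical(a$data, c_$data))
})

test_that("lesions add intensity only inside their mask, in the foreground", {
  spec <- cohort_spec(shape = c(32, 32, 16), seed = 7, noise_sd = 0,
                      shape_deform_sd = 0)
  s <- sample_volume(spec, 1, abnormal = TRUE)
  truth <- attr(s, "truth")
  tmpl <- make_template(spec$shape)
  modes <- cohort_texture_modes(spec)
  expected <- tmpl$data
  for (k in seq_along(modes)) {
    expected <- expected + truth$texture_coefs[k] * modes[[k]]
  }
  extra <- s$data - expected
  expect_true(all(extra >= -1e-10))
  expect_gt(max(extra), 1)
  # all added intensity lies within the lesion balls (+ soft edge margin)
  idx <- which(extra > 1e-8, arr.ind = TRUE)
  ok <- rep(FALSE, nrow(idx))
  for (l in truth$lesions) {
    d <- sqrt(colSums((t(idx) - l$center)^2))
    ok <- ok | d <= l$radius + 0.5
  }
  expect_true(all(ok))
  expect_true(all(extra[tmpl$data == 0] == 0))
})

test_that("a zero-noise undeformed cohort is captured almost exactly", {
  spec <- cohort_spec(n_normal = 9, n_abnormal = 0, shape = c(24, 24, 12),
                      seed = 11, noise_sd = 0, shape_deform_sd = 0,
                      texture_sd = 2)
  coh <- generate_cohort(spec)
  tens <- lapply(coh$volumes, function(v) v$data)
  fit <- gndpca(tens[1:8], ranks = c(12, 12, 8))
  held <- tens[[9]]
  rec <- predict(fit, held, type = "reconstruction")
  expect_gt(normalized_correlation(rec, held), 0.999)
})

test_that("written cohorts carry a faithful manifest and reload bit-identically", {
  spec <- cohort_spec(n_normal = 2, n_abnormal = 1, shape = c(16, 16, 8),
                      seed = 3)
  dir <- tempfile("cohort")
  manifest <- write_cohort(spec, dir)
  expect_equal(nrow(manifest), 3)
  expect_equal(manifest$label, c("normal", "normal", "abnormal"))
  coh <- generate_cohort(spec)
  for (i in seq_len(3)) {
    back <- read_volume(file.path(dir, manifest$file[i]))
    expect_identical(back$data, coh$volumes[[i]]$data)
    tr <- read_transform(file.path(dir, manifest$truth[i]))
    expect_equal(tr$ffd$lambda, attr(coh$volumes[[i]], "truth")$deform$lambda)
  }
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  expect_equal(mf$seed, 3)
  expect_equal(mf$samples$label, manifest$label)
})
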