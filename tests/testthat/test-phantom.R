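test_that("noiseless phantoms are exactly piecewise constant", {
  spec <- phantom_spec(shape = c(64, 64), gaussian_sigma = 0,
                       impulse_fraction = 0, seed = 1)
  ph <- generate_phantom(spec)
  expect_identical(sort(unique(as.vector(ph$image))), c(30, 120, 200))
  # per-class mean equals the tissue mean exactly
  for (k in 0:2)
    expect_equal(mean(ph$image[ph$truth == k]), spec$tissue_means[k + 1])
  expect_identical(ph$lesion, ph$truth == 2L)
  expect_identical(dim(ph$image), dim(ph$truth))
})

test_that("impulse corruption touches exactly round(f * x) pixels", {
  spec <- phantom_spec(shape = c(100, 100), gaussian_sigma = 0,
                       impulse_fraction = 0.05, seed = 2)
  ph <- generate_phantom(spec)
  clean <- generate_phantom(phantom_spec(shape = c(100, 100),
                                         gaussian_sigma = 0,
                                         impulse_fraction = 0, seed = 2))
  changed <- sum(ph$image != clean$image)
  # corrupted pixels are set to the range extremes; a few may coincide with
  # their original value only if a tissue mean equals an extreme (none here)
  expect_identical(changed, 500L)
  expect_equal(sum(ph$image == 0) + sum(ph$image == 255) -
                 sum(clean$image == 0) - sum(clean$image == 255), 500L)
  # half pepper, half salt
  expect_identical(sum(ph$image == 0), 250L)
  expect_identical(sum(ph$image == 255), 250L)
})

test_that("phantom generation is seed-deterministic", {
  spec <- phantom_spec(shape = c(48, 48), impulse_fraction = 0.03, seed = 7)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$image, b$image)
  expect_identical(a$truth, b$truth)
})

test_that("noise sweep varies only the impulse fraction", {
  base <- phantom_spec(shape = c(48, 48), seed = 9)
  fr <- seq(0, 0.05, by = 0.01)
  sweep_ <- noise_sweep(base, fr)
  expect_length(sweep_, 6L)
  truths <- lapply(sweep_, `[[`, "truth")
  for (t in truths) expect_identical(t, truths[[1L]])
  expect_length(noise_sweep(base, numeric(0)), 0L)
  # all-zero fractions: identical images under the shared seed
  z <- noise_sweep(base, c(0, 0, 0))
  expect_identical(z[[1L]]$image, z[[2L]]$image)
  expect_identical(z[[2L]]$image, z[[3L]]$image)
})

test_that("phantom spec validation catches bad geometry and parameters", {
  expect_error(phantom_spec(tissue_means = c(30, 30, 200)), "distinct")
  expect_error(phantom_spec(impulse_fraction = 1.2), "\\[0, 1\\]")
  expect_error(phantom_spec(gaussian_sigma = -1), "non-negative")
  # lesion poking outside the organ is rejected at generation time
  bad <- phantom_spec(shape = c(64, 64),
                      lesion_center = c(5, 5), lesion_axes = c(6, 6))
  expect_error(generate_phantom(bad), "inside the organ")
})

test_that("3-D phantoms generate with consistent geometry", {
  spec <- phantom_spec(shape = c(24, 24, 16), gaussian_sigma = 0, seed = 3)
  ph <- generate_phantom(spec)
  expect_identical(dim(ph$image), c(24L, 24L, 16L))
  expect_identical(sort(unique(as.vector(ph$image))), c(30, 120, 200))
  expect_true(all(ph$truth[ph$lesion] == 2L))
})

test_that("FCM recovers the tissue parameters of a clean phantom", {
  ph <- generate_phantom(phantom_spec(shape = c(128, 128), gaussian_sigma = 0,
                                      seed = 5))
  fit <- fcm_fit(as_feature_set(ph$image), fit_config(c = 3, fuzzifier = 2))
  centers <- sort(fit$model$centers)
  expect_equal(centers, c(30, 120, 200), tolerance = 0.02)
  lab <- labels_from(fit$u, dim(ph$image))
  for (k in 0:2) {
    cl <- which.min(abs(fit$model$centers - c(30, 120, 200)[k + 1])) - 1L
    d <- dice(region_masks(ph$truth == k, lab == cl))
    expect_gte(d, 0.99)
  }
})
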