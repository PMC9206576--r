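test_that("quantize_image passes integer images through and scales floats", {
  img <- matrix(c(0, 3, 255, 128), 2)
  expect_identical(quantize_image(img, 256), matrix(c(0L, 3L, 255L, 128L), 2))
  # floats are min-max scaled to 0..N-1
  q <- quantize_image(matrix(c(0.5, 1.5), 1), 256)
  expect_identical(as.vector(q), c(0L, 255L))
  # constant image maps to level 0
  expect_true(all(quantize_image(matrix(3.7, 4, 4), 256) == 0L))
  expect_error(quantize_image(matrix(NA_real_, 2, 2), 256), "finite")
  expect_error(quantize_image(img, 1), ">= 2")
})

test_that("compute_histogram counts levels and normalizes", {
  h <- compute_histogram(matrix(c(0, 0, 255, 255), 2), 256)
  expect_equal(h$probs[1], 0.5)
  expect_equal(h$probs[256], 0.5)
  expect_equal(sum(h$probs), 1)
  # constant image: a single nonzero bin
  hc <- compute_histogram(matrix(7, 4, 4), 256)
  expect_equal(hc$probs[8], 1)
  expect_equal(sum(hc$probs > 0), 1L)
  # any image normalizes
  set.seed(1)
  ha <- compute_histogram(random_mixture_image(16, 16), 256)
  expect_equal(sum(ha$probs), 1, tolerance = 1e-12)
})

test_that("histogram objective equals the expanded pixel objective", {
  set.seed(2)
  img <- random_mixture_image(12, 12, n_modes = 2, range_max = 31)
  h <- compute_histogram(img, 32)
  centers <- c(5, 20)
  u_level <- fcm_update_membership(feature_set(0:31),
                                   new_cluster_model(centers, fuzzifier = 2))
  j_hist <- histogram_objective(h, u_level, centers, r = 2)
  # expansion oracle: every pixel contributes its gray level's term
  u_pix <- pixel_memberships_from_levels(h$quantized, u_level)
  j_pix <- fcm_objective(as_feature_set(img), u_pix,
                         new_cluster_model(centers, fuzzifier = 2))
  expect_equal(j_hist, j_pix / length(img), tolerance = 1e-9)
  # concentrated histogram at the centers with hard memberships scores 0
  img0 <- matrix(c(5, 5, 20, 20), 2)
  h0 <- compute_histogram(img0, 32)
  u0 <- harden(fcm_update_membership(feature_set(0:31),
                                     new_cluster_model(centers, 2)))
  expect_equal(histogram_objective(h0, u0, centers, r = 2), 0)
})

test_that("histogram FCM equals pixel-domain FCM on integer images", {
  set.seed(3)
  for (rep in 1:5) {
    img <- random_mixture_image(32, 32)
    cfg <- fit_config(c = 3, fuzzifier = 2)
    pix <- fcm_fit(as_feature_set(img), cfg)
    h <- compute_histogram(img, 256)
    lev <- histogram_fcm_fit(h, cfg)
    expect_equal(lev$model$centers, pix$model$centers, tolerance = 1e-6)
    expect_identical(lev$model$iterations, pix$model$iterations)
    u_pix <- pixel_memberships_from_levels(h$quantized, lev$u)
    expect_identical(labels_from(u_pix, dim(img)),
                     labels_from(pix$u, dim(img)))
    expect_nonincreasing(lev$model$objective_trace)
  }
})

test_that("histogram FCM trivial and degenerate cases", {
  # {0,0,0,10,10,10}: centers converge to the two modes
  h <- compute_histogram(c(0, 0, 0, 10, 10, 10), 11)
  fit <- histogram_fcm_fit(h, fit_config(c = 2, fuzzifier = 2))
  expect_equal(fit$model$centers, c(0, 10), tolerance = 1e-3)
  # single nonempty bin, c = 1: center at that level
  h1 <- compute_histogram(matrix(42, 3, 3), 256)
  fit1 <- histogram_fcm_fit(h1, fit_config(c = 1, fuzzifier = 2))
  expect_equal(fit1$model$centers, 42)
  # fewer nonempty bins than c
  expect_error(histogram_fcm_fit(h1, fit_config(c = 2, fuzzifier = 2)),
               "degenerate")
})

test_that("per-iteration work scales with the gray levels, not the pixels", {
  # tiling an image 4x changes the pixel count but not the histogram; the
  # level-domain fit must be unchanged in every respect (trace, iterations,
  # memberships), demonstrating the per-iteration problem size is N
  set.seed(4)
  img <- random_mixture_image(16, 16)
  big <- rbind(img, img, img, img)
  h_small <- compute_histogram(img, 256)
  h_big <- compute_histogram(big, 256)
  expect_equal(h_small$probs, h_big$probs, tolerance = 1e-12)
  cfg <- fit_config(c = 3, fuzzifier = 2)
  f_small <- histogram_fcm_fit(h_small, cfg)
  f_big <- histogram_fcm_fit(h_big, cfg)
  expect_identical(f_small$model$centers, f_big$model$centers)
  expect_identical(f_small$model$iterations, f_big$model$iterations)
  expect_identical(dim(f_small$u), dim(f_big$u))
  expect_identical(ncol(f_small$u), 256L)
})

test_that("pixel membership inheritance commutes with hardening", {
  set.seed(5)
  img <- random_mixture_image(10, 10, n_modes = 2, range_max = 63)
  h <- compute_histogram(img, 64)
  fit <- histogram_fcm_fit(h, fit_config(c = 2, fuzzifier = 2))
  a <- harden(pixel_memberships_from_levels(h$quantized, fit$u))
  b <- pixel_memberships_from_levels(h$quantized, harden(fit$u))
  expect_equal(unclass(a), unclass(b), ignore_attr = TRUE)
  # constant image: all pixels share one membership column
  hc <- compute_histogram(matrix(9, 3, 3), 64)
  u <- matrix(0.5, 2, 64)
  u[1, ] <- seq(0, 1, length.out = 64)
  u[2, ] <- 1 - u[1, ]
  up <- pixel_memberships_from_levels(hc$quantized, u)
  expect_equal(nrow(unique(t(unclass(up)))), 1L)
  # two-level image: exactly two distinct columns appear
  h2 <- compute_histogram(matrix(c(3, 3, 40, 40), 2), 64)
  up2 <- pixel_memberships_from_levels(h2$quantized, u)
  expect_equal(nrow(unique(t(unclass(up2)))), 2L)
  # out-of-range pixels are rejected
  expect_error(pixel_memberships_from_levels(matrix(99, 2, 2), u),
               "0..N-1")
})
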