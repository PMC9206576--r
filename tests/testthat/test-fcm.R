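test_that("fcm_update_membership matches hand-computed affiliations", {
  m <- new_cluster_model(centers = c(0, 10), fuzzifier = 2)
  # s = 2: d1 = 2, d2 = 8; with r = 2 the weights are inverse squared
  # distances -> (64, 4)/68 = (16/17, 1/17)
  u <- fcm_update_membership(feature_set(2), m)
  expect_equal(as.vector(u), c(16 / 17, 1 / 17), tolerance = 1e-12)
  # sample exactly at a center: unit mass there
  u0 <- fcm_update_membership(feature_set(10), m)
  expect_equal(as.vector(u0), c(0, 1))
  # equidistant sample splits evenly
  u5 <- fcm_update_membership(feature_set(5), m)
  expect_equal(as.vector(u5), c(0.5, 0.5))
  # sample coinciding with two identical centers splits between them
  m2 <- new_cluster_model(centers = c(3, 3, 9), fuzzifier = 2)
  u3 <- fcm_update_membership(feature_set(3), m2)
  expect_equal(as.vector(u3), c(0.5, 0.5, 0))
})

test_that("membership columns always sum to 1", {
  set.seed(8)
  for (rep in 1:20) {
    centers <- sort(runif(sample(2:5, 1), 0, 100))
    r <- runif(1, 1.3, 4)
    v <- c(runif(40, 0, 100), centers[1])  # include an exact center hit
    u <- fcm_update_membership(feature_set(v),
                               new_cluster_model(centers, fuzzifier = r))
    expect_equal(colSums(u), rep(1, length(v)), tolerance = 1e-9)
    expect_true(all(u >= 0 & u <= 1))
  }
})

test_that("fcm_update_centers is the mu^r-weighted mean", {
  f <- feature_set(c(0, 10))
  # hard memberships reduce to per-cluster means for any r
  hard <- one_hot(c(0, 1))
  expect_equal(fcm_update_centers(f, hard, r = 2), c(0, 10))
  expect_equal(fcm_update_centers(f, hard, r = 3.7), c(0, 10))
  # uniform memberships collapse every center onto the global mean
  unif <- matrix(0.5, 2, 2)
  expect_equal(fcm_update_centers(f, unif, r = 2), c(5, 5))
  # hand oracle on the (16/17, 1/17) column pattern
  u <- rbind(c(16 / 17, 1 / 17), c(1 / 17, 16 / 17))
  s <- c(2, 8)
  expected <- as.vector((u^2 %*% s) / rowSums(u^2))
  expect_equal(fcm_update_centers(feature_set(s), u, r = 2), expected,
               tolerance = 1e-12)
  expect_equal(expected,
               c((16^2 * 2 + 1 * 8) / (16^2 + 1),
                 (1 * 2 + 16^2 * 8) / (16^2 + 1)) / 1,
               tolerance = 1e-12)
})

test_that("fcm_objective evaluates the fuzzified criterion", {
  f <- feature_set(c(0, 10))
  expect_equal(fcm_objective(f, one_hot(c(0, 1)),
                             new_cluster_model(c(0, 10), fuzzifier = 2)), 0)
  # uniform membership, centers {0,10}, r = 2: (1/4)(0+100+100+0) = 50
  unif <- matrix(0.5, 2, 2)
  expect_equal(fcm_objective(f, unif,
                             new_cluster_model(c(0, 10), fuzzifier = 2)), 50)
})

test_that("a converged fit beats random memberships at its own centers", {
  set.seed(21)
  v <- c(rnorm(30, 10, 2), rnorm(30, 40, 3))
  fit <- fcm_fit(feature_set(v), fit_config(c = 2, fuzzifier = 2))
  j_fit <- fcm_objective(feature_set(v), fit$u, fit$model)
  for (rep in 1:100) {
    u_rand <- random_membership(2, length(v))
    expect_lte(j_fit,
               fcm_objective(feature_set(v), u_rand, fit$model) + 1e-9)
  }
})

test_that("fcm_fit converges to the separated-cluster solution", {
  fit <- fcm_fit(feature_set(c(0, 0, 0, 10, 10, 10)),
                 fit_config(c = 2, fuzzifier = 2))
  expect_equal(fit$model$centers, c(0, 10), tolerance = 1e-3)
  expect_true(fit$model$converged)
  expect_nonincreasing(fit$model$objective_trace)

  # symmetric data give symmetric centers
  fit_s <- fcm_fit(feature_set(c(-4, -4, 4, 4)),
                   fit_config(c = 2, fuzzifier = 2))
  expect_equal(fit_s$model$centers[1], -fit_s$model$centers[2],
               tolerance = 1e-8)

  # c = 1: center is the plain mean, membership all 1
  fit1 <- fcm_fit(feature_set(c(1, 2, 6)), fit_config(c = 1, fuzzifier = 2))
  expect_equal(fit1$model$centers, 3)
  expect_true(all(fit1$u == 1))
})

test_that("near-crisp fuzzifier reproduces HCM labels on separated data", {
  set.seed(13)
  v <- c(rnorm(40, 0, 1), rnorm(40, 50, 1))
  h <- hcm_fit(feature_set(v), fit_config(c = 2))
  f <- suppressWarnings(fcm_fit(feature_set(v),
                                fit_config(c = 2, fuzzifier = 1.1)))
  expect_identical(labels_from(f$u, length(v)), labels_from(h$u, length(v)))
})

test_that("permuting initial centers permutes the solution coherently", {
  set.seed(4)
  v <- c(rnorm(25, 5), rnorm(25, 25), rnorm(25, 60))
  cfg <- fit_config(c = 3, fuzzifier = 2)
  init <- init_centers(feature_set(v), cfg)$centers
  perm <- c(3, 1, 2)
  fit_a <- fcm_fit(feature_set(v), cfg, centers = init)
  fit_b <- fcm_fit(feature_set(v), cfg, centers = init[perm])
  expect_equal(fit_b$model$centers, fit_a$model$centers[perm],
               tolerance = 1e-9)
  expect_equal(unclass(fit_b$u), unclass(fit_a$u)[perm, ],
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(fit_b$model$objective_trace[length(fit_b$model$objective_trace)],
               fit_a$model$objective_trace[length(fit_a$model$objective_trace)],
               tolerance = 1e-9)
})

test_that("identical config and data give bit-identical fits", {
  set.seed(2)
  v <- rnorm(80, 20, 10)
  cfg <- fit_config(c = 3, fuzzifier = 2, seed = 7, init = "random")
  a <- fcm_fit(feature_set(v), cfg)
  b <- fcm_fit(feature_set(v), cfg)
  expect_identical(a$model$centers, b$model$centers)
  expect_identical(unclass(a$u), unclass(b$u))
})

test_that("degenerate all-zero cluster membership raises an error", {
  expect_error(fcm_update_centers(feature_set(c(1, 2)),
                                  rbind(c(1, 1), c(0, 0)), r = 2),
               "degenerate")
})
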