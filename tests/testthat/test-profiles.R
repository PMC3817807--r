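test_that("EM log-likelihood is non-decreasing and the mixture is proper", {
  p <- normal_points3(1500, seed = 5)
  fit <- gmm_fit(p$points, k = 3, seed = 1)
  expect_true(all(diff(fit$loglik) >= -1e-6 * abs(fit$loglik[-1])))
  expect_equal(sum(fit$weights), 1, tolerance = 1e-12)
  expect_true(all(fit$weights >= 0))
  for (s in fit$covs) {
    expect_equal(s, t(s))
    expect_true(all(eigen(s, symmetric = TRUE,
                          only.values = TRUE)$values > 0))
  }
})

test_that("build_profile recovers well-separated generating means", {
  p <- normal_points3(3000, seed = 6)
  prof <- build_profile(p, "Normal", seed = 1)
  true_means <- attr(p, "true_means")
  fitted <- t(vapply(prof$ellipsoids, function(e) e$mean, numeric(3)))
  err <- vapply(1:3, function(c) {
    min(sqrt(rowSums(sweep(fitted, 2, true_means[c, ], "-")^2)))
  }, numeric(1))
  expect_lt(max(err), 0.5)
  expect_equal(prof$t_index,
               which.min(vapply(prof$ellipsoids,
                                function(e) e$mean[2], 0)))
})

test_that("an independent mixture fitter agrees on the component means", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  p <- normal_points3(2000, seed = 7)
  prof <- build_profile(p, "Normal", seed = 1)
  mc <- Mclust(p$points, G = 3, modelNames = "VVV", verbose = FALSE)
  ours <- t(vapply(prof$ellipsoids, function(e) e$mean, numeric(3)))
  theirs <- t(mc$parameters$mean)
  err <- vapply(1:3, function(c) {
    min(sqrt(rowSums(sweep(theirs, 2, ours[c, ], "-")^2)))
  }, numeric(1))
  expect_lt(max(err), 0.3)
})

test_that("requesting k = 2 on one Gaussian still yields a proper mixture", {
  withr::with_seed(8, {
    pts <- rmvn(500, c(0, 5, 0), diag(1, 3))
  })
  prof <- build_profile(point3_table(pts), "CLL", seed = 1)
  expect_equal(sum(prof$weights), 1, tolerance = 1e-12)
  expect_length(prof$ellipsoids, 2L)
})

test_that("patient profiles identify dominance and the T-cell component", {
  cll <- quick_case("CLL", n = 1000, seed = 31, dominance = "kappa")
  prof <- build_profile(cll, "CLL", seed = 1)
  expect_identical(prof$dominance, "kappa")
  b_index <- setdiff(1:2, prof$t_index)
  expect_gt(prof$ellipsoids[[b_index]]$mean[1], 0)
  expect_lt(prof$ellipsoids[[prof$t_index]]$mean[2],
            prof$ellipsoids[[b_index]]$mean[2])

  lam <- quick_case("FL", n = 1000, seed = 32, dominance = "lambda")
  prof_l <- build_profile(lam, "FL", seed = 1)
  expect_identical(prof_l$dominance, "lambda")
})

test_that("ellipsoid membership is boundary-inclusive Mahalanobis", {
  e <- ellipsoid(c(0, 0, 0), diag(1, 3), m = 2)
  expect_true(contains(e, c(2, 0, 0)))
  expect_false(contains(e, c(2.001, 0, 0)))
  expect_true(contains(e, c(0, 0, 0)))
})

test_that("contains() agrees with an eigendecomposition oracle", {
  withr::with_seed(9, {
    sigma <- random_spd3()
    mu <- rnorm(3)
    e <- ellipsoid(mu, sigma, m = 2)
    pts <- rmvn(1000, mu, sigma * 4)
    # oracle: project onto principal axes, compare scaled radii
    eg <- eigen(sigma, symmetric = TRUE)
    centered <- sweep(pts, 2, mu, "-") %*% eg$vectors
    oracle <- rowSums(sweep(centered^2, 2, eg$values, "/")) <= 4
    expect_identical(unname(contains(e, pts)), oracle)
  })
})

test_that("capture of a matched Gaussian follows the chi-square law", {
  withr::with_seed(10, {
    sigma <- random_spd3()
    mu <- c(1, -2, 3)
    pts <- rmvn(40000, mu, sigma)
    for (m in c(1, 2, 3)) {
      frac <- mean(contains(ellipsoid(mu, sigma, m = m), pts))
      expect_equal(frac, stats::pchisq(m^2, df = 3), tolerance = 0.02)
    }
  })
})

test_that("merging training cases pools events and keeps provenance", {
  a <- point3_table(matrix(rnorm(300), 100, 3), case_id = "a")
  b <- point3_table(matrix(rnorm(600), 200, 3), case_id = "b")
  merged <- merge_training_cases(list(a, b))
  expect_equal(nrow(merged$points), 300L)
  expect_equal(as.vector(table(attr(merged, "source"))), c(100L, 200L))
  expect_equal(merge_training_cases(list(a))$points, a$points)
  expect_error(merge_training_cases(list()), "no training cases")
})

test_that("merge order does not change the profile after canonical sort", {
  a <- normal_points3(400, seed = 11)
  b <- normal_points3(400, seed = 12)
  canon <- function(p) {
    pts <- p$points
    point3_table(pts[order(pts[, 1], pts[, 2], pts[, 3]), ])
  }
  p1 <- build_profile(canon(merge_training_cases(list(a, b))),
                      "Normal", seed = 1)
  p2 <- build_profile(canon(merge_training_cases(list(b, a))),
                      "Normal", seed = 1)
  for (c in 1:3) {
    expect_equal(p1$ellipsoids[[c]]$mean, p2$ellipsoids[[c]]$mean)
  }
})
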