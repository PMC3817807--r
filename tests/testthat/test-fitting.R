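test_that("the CD19 split recovers the T-cell population", {
  case <- quick_case("Normal", n = 1200, seed = 41)
  sp <- split_t_cells(case)
  truth_t <- case$truth$population == "T"
  expect_gte(mean(sp$is_t == truth_t), 0.99)
  expect_equal(length(sp$is_t), nrow(case$points))
})

test_that("degenerate CD19 distributions are refused", {
  pts <- cbind(rnorm(50), rep(2, 50), rnorm(50))
  expect_error(split_t_cells(point3_table(pts)), "no T/B separation")
  expect_error(split_t_cells(point3_table(cbind(1, 1, 1))), "at least 20")
})

test_that("divisive clustering partitions every event", {
  case <- quick_case("Normal", n = 800, seed = 42)
  asg <- assign_clusters(case, k = 3)
  expect_setequal(unique(asg$labels), 1:3)
  expect_equal(length(asg$labels), nrow(case$points))
  expect_equal(sum(table(asg$labels)), nrow(case$points))
})

test_that("B-cell clustering finds opposite-sign light-chain centers", {
  case <- quick_case("Normal", n = 1000, seed = 43)
  sp <- split_t_cells(case)
  cb <- cluster_b_cells(case$points[!sp$is_t, , drop = FALSE], 2L)
  expect_gt(cb$centers[1, 1], 0)   # kappa side first
  expect_lt(cb$centers[2, 1], 0)
})

test_that("single-cluster centers are exact means and order-invariant", {
  withr::with_seed(44, {
    pts <- rmvn(200, c(3, 8, 1), diag(0.5, 3))
  })
  cb <- cluster_b_cells(pts, 1L)
  expect_equal(cb$centers[1, ], colMeans(pts))
  perm <- sample(200)
  cb2 <- cluster_b_cells(pts[perm, ], 2L)
  cb1 <- cluster_b_cells(pts, 2L)
  expect_equal(cb1$centers, cb2$centers)
})

test_that("alignment recovers constructed shifts and spares covariances", {
  case <- quick_case("Normal", n = 3000, seed = 45)
  prof <- build_profile(case, "Normal", seed = 1)
  asg <- assign_clusters(case, 3L)
  aligned <- align_profile(prof, asg)
  # self-fit: the profile was built from this very case
  expect_lt(sqrt(sum(attr(aligned, "delta")^2)), 0.1)
  for (c in 1:3) {
    expect_identical(aligned$ellipsoids[[c]]$cov, prof$ellipsoids[[c]]$cov)
  }
  shift <- c(2, -1, 3)
  shifted <- point3_table(sweep(case$points, 2, shift, "+"))
  asg2 <- assign_clusters(shifted, 3L)
  d2 <- align_profile(prof, asg2)
  expect_equal(attr(d2, "delta") - attr(aligned, "delta"), shift,
               tolerance = 1e-8)
})

test_that("capture rate hits its bounds on constructed cases", {
  prof <- build_profile(normal_points3(900, seed = 13), "Normal",
                        seed = 1)
  b_index <- setdiff(1:3, prof$t_index)[1]
  b_mean <- prof$ellipsoids[[b_index]]$mean
  t_mean <- prof$ellipsoids[[prof$t_index]]$mean
  near <- rbind(matrix(rep(b_mean, 30), ncol = 3, byrow = TRUE),
                matrix(rep(t_mean, 30), ncol = 3, byrow = TRUE))
  asg <- structure(list(labels = rep(c(1L, 3L), each = 30),
                        centers = rbind(b_mean, b_mean, t_mean), k = 3L),
                   class = "cluster_assignment")
  expect_equal(compute_ccr(prof, near, asg), 1.0)
  far <- near
  far[1:30, ] <- far[1:30, ] + 1000
  expect_equal(compute_ccr(prof, far, asg), 0.0)
  # zero B cells is an error
  asg0 <- structure(list(labels = rep(3L, 60),
                         centers = asg$centers, k = 3L),
                    class = "cluster_assignment")
  expect_error(compute_ccr(prof, near, asg0), "no B cells")
})

test_that("a case resampled from the profile mixture captures chi2(3) mass", {
  prof <- build_profile(normal_points3(5000, seed = 14), "Normal",
                        seed = 1)
  withr::with_seed(15, {
    counts <- as.vector(stats::rmultinom(1, 5000, prof$weights))
    pts <- do.call(rbind, lapply(1:3, function(c) {
      rmvn(counts[c], prof$ellipsoids[[c]]$mean, prof$ellipsoids[[c]]$cov)
    }))
  })
  ccr <- fit_case(prof, point3_table(pts))
  expect_equal(ccr, stats::pchisq(4, df = 3), tolerance = 0.02)
})

test_that("the numerator equals a brute-force per-event membership check", {
  case <- quick_case("Normal", n = 500, seed = 46)
  prof <- build_profile(normal_points3(1200, seed = 16), "Normal",
                        seed = 1)
  asg <- assign_clusters(case, 3L)
  aligned <- align_profile(prof, asg)
  ccr <- compute_ccr(aligned, case, asg)
  b_pts <- case$points[asg$labels != 3L, , drop = FALSE]
  b_ell <- aligned$ellipsoids[setdiff(1:3, aligned$t_index)]
  inside <- vapply(seq_len(nrow(b_pts)), function(i) {
    any(vapply(b_ell, function(e) {
      dv <- b_pts[i, ] - e$mean
      sqrt(drop(t(dv) %*% solve(e$cov) %*% dv)) <= e$m
    }, TRUE))
  }, TRUE)
  expect_equal(ccr, sum(inside) / nrow(b_pts))
})

test_that("capture is exactly invariant to global translation", {
  case <- quick_case("Normal", n = 700, seed = 47)
  prof <- build_profile(normal_points3(1500, seed = 17), "Normal",
                        seed = 1)
  base <- fit_case(prof, case)
  withr::with_seed(18, {
    for (i in 1:10) {
      v <- if (i <= 5) sample(-20:20, 3, replace = TRUE) else
        runif(3, -15, 15)
      shifted <- point3_table(sweep(case$points, 2, v, "+"))
      expect_identical(fit_case(prof, shifted), base)
    }
  })
})

test_that("capture grows weakly with the ellipsoid size multiplier", {
  case <- quick_case("Normal", n = 600, seed = 48)
  train <- normal_points3(1500, seed = 19)
  ccrs <- vapply(c(1, 2, 3), function(m) {
    fit_case(build_profile(train, "Normal", m = m, seed = 1), case)
  }, numeric(1))
  expect_true(all(diff(ccrs) >= 0))
  expect_true(all(ccrs >= 0 & ccrs <= 1))
})

test_that("mirroring rescues an opposite-dominance patient case", {
  kappa_prof <- build_profile(quick_case("CLL", n = 1200, seed = 49,
                                         dominance = "kappa"),
                              "CLL", seed = 1)
  lambda_case <- quick_case("CLL", n = 900, seed = 50,
                            dominance = "lambda")
  asg <- assign_clusters(lambda_case, 2L)
  unmirrored <- compute_ccr(align_profile(kappa_prof, asg),
                            lambda_case, asg)
  res <- fit_case(kappa_prof, lambda_case, details = TRUE)
  expect_true(res$mirrored)
  expect_gt(res$ccr, unmirrored)
})

test_that("cohort-matched capture dominates end to end", {
  normal_prof <- build_profile(quick_case("Normal", n = 2500, seed = 51),
                               "Normal", seed = 1)
  cll_prof <- build_profile(quick_case("CLL", n = 1200, seed = 52),
                            "CLL", seed = 1)
  healthy <- quick_case("Normal", n = 900, seed = 53)
  expect_gte(fit_case(normal_prof, healthy), 0.6)
  expect_lte(fit_case(cll_prof, healthy), 0.3)
})
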