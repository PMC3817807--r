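test_that("the cross-validation plan reproduces the printed bookkeeping", {
  plan <- make_cv_plan(seed = 1)
  expect_equal(plan$counts$normal_ccr, 180L)
  expect_equal(plan$counts$cll_ccr, 1491L)
  expect_equal(plan$counts$fl_ccr, 1065L)
  expect_equal(plan$counts$cll_ccr_per_round, 71L)
  expect_equal(unname(plan$counts$diagnoses),
               c(22680L, 18900L, 13230L))
  expect_equal(plan$counts$total_diagnoses, 54810L)
  # folds are disjoint sets of 12 donors
  expect_equal(lengths(plan$folds), rep(12L, 3))
  expect_equal(sort(unlist(plan$folds)), 1:36)
})

test_that("impossible plan sizes are refused", {
  expect_error(make_cv_plan(n_normal = 30, fold_size = 12),
               "three disjoint folds")
})

test_that("selection picks the case nearest the mean T-to-B distance", {
  dists <- c(2, 4, 6, 9, 14)
  cases <- lapply(dists, function(d) {
    withr::with_seed(round(100 + d), {
      t_cl <- rmvn(60, c(0, 0, 0), diag(1e-4, 3))
      b_cl <- rmvn(60, c(0, d, 0), diag(1e-4, 3))
    })
    point3_table(rbind(t_cl, b_cl), cohort = "CLL")
  })
  sel <- select_training_cases(cases, fraction = 0.15)
  # brute-force oracle over the 5 constructed distances
  oracle <- which.min(abs(dists - mean(dists)))
  expect_equal(sel$indices, oracle)
  expect_equal(sel$distances, dists, tolerance = 0.01)
  # a fraction large enough to select all is the identity subset
  all_sel <- select_training_cases(cases, fraction = 0.95)
  expect_equal(all_sel$indices, 1:5)
})

test_that("selection counts mirror the 15% training design", {
  expect_equal(flowccr:::n_selected(44, 0.15), 7L)
  expect_equal(flowccr:::n_selected(21, 0.15), 3L)
  expect_equal(flowccr:::n_selected(15, 0.15), 2L)
  expect_equal(flowccr:::n_selected(2, 0.15), 1L)
})

test_that("single-profile screening ranks healthy cases highest", {
  train <- lapply(1:3, function(s) quick_case("Normal", n = 900,
                                              seed = 70 + s))
  prof <- build_profile(merge_training_cases(train), "Normal", seed = 1)
  cases <- c(lapply(1:4, function(s) quick_case("Normal", n = 600,
                                                seed = 80 + s)),
             lapply(1:4, function(s) quick_case("CLL", n = 500,
                                                seed = 90 + s)),
             lapply(1:4, function(s) quick_case("FL", n = 450,
                                                seed = 95 + s)))
  res <- run_single_profile(cases, prof)
  expect_equal(nrow(res$records), 12L)
  expect_gt(res$summary$Normal$median, res$summary$CLL$median)
  expect_gt(res$summary$Normal$median, res$summary$FL$median)
})

test_that("a single case yields a single record", {
  prof <- build_profile(quick_case("Normal", n = 1200, seed = 74),
                        "Normal", seed = 1)
  res <- run_single_profile(list(quick_case("Normal", n = 500,
                                            seed = 75)), prof)
  expect_equal(nrow(res$records), 1L)
})

test_that("box statistics match a sorted-percentile oracle", {
  withr::with_seed(76, {
    for (i in 1:100) {
      v <- rnorm(sample(20:200, 1))
      bs <- flowccr:::box_stats(v)
      s <- sort(v)
      pct <- function(p) {
        h <- (length(s) - 1) * p + 1
        lo <- floor(h)
        s[lo] + (h - lo) * (s[min(lo + 1, length(s))] - s[lo])
      }
      expect_equal(bs$q1, pct(0.25))
      expect_equal(bs$median, pct(0.5))
      expect_equal(bs$q3, pct(0.75))
      iqr <- bs$q3 - bs$q1
      expect_equal(sort(bs$outliers),
                   sort(v[v < bs$q1 - 1.5 * iqr | v > bs$q3 + 1.5 * iqr]))
    }
  })
})

test_that("the cross-validated grid bookkeeping is exact at small scale", {
  plan <- make_cv_plan(n_normal = 9, n_cll = 4, n_fl = 3, fold_size = 3,
                       seed = 2)
  expect_equal(plan$counts$normal_ccr, 3L * (6L + 4L + 3L))
  expect_equal(plan$counts$n_triples, 36L)
  cases <- generate_cohorts(9, 4, 3, master_seed = 7,
                            events_range = list(Normal = c(350, 450),
                                                CLL = c(300, 400),
                                                FL = c(300, 400)))
  points <- lapply(cases, preprocess_case)
  res <- run_multi_profile(plan, points, seed = 1)
  expect_equal(unname(res$n_ccr),
               unname(c(plan$counts$normal_ccr, plan$counts$cll_ccr,
                        plan$counts$fl_ccr)))
  expect_equal(unname(res$n_diagnoses),
               unname(plan$counts$diagnoses))
  expect_equal(unname(rowSums(res$confusion)),
               unname(plan$counts$diagnoses))
})

test_that("no case is evaluated against a profile trained on it", {
  # the CCR matrices are NA exactly on the training pairs, so the count
  # identity above is the leakage check; here the structural guarantee:
  plan <- make_cv_plan(n_normal = 6, n_cll = 2, n_fl = 2, fold_size = 2,
                       seed = 3)
  for (f in seq_along(plan$folds)) {
    held_out <- setdiff(1:6, plan$folds[[f]])
    expect_length(intersect(plan$folds[[f]], held_out), 0L)
  }
})
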