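# Shared fixtures: small multivariate-normal samplers and ready-made cases.

# Cholesky-based MVN sampler, independent of the package's generator.
rmvn <- function(n, mean, sigma) {
  d <- length(mean)
  z <- matrix(rnorm(n * d), n, d)
  sweep(z %*% chol(sigma), 2L, mean, "+")
}

# A random symmetric positive-definite 3x3 covariance.
random_spd3 <- function(scale = 1) {
  a <- matrix(rnorm(9), 3L, 3L)
  crossprod(a) * scale + diag(0.1, 3L)
}

# Three well-separated Gaussian clusters in the 3-D model layout
# (kappa-B, lambda-B, T), with per-point truth labels attached.
normal_points3 <- function(n = 3000, sd = 0.8, seed = 1) {
  withr::with_seed(seed, {
    means <- rbind(c(5, 8, 0), c(-5, 8, 0), c(0, 1, 0))
    sizes <- c(round(n * 0.25), round(n * 0.25),
               n - 2L * round(n * 0.25))
    pts <- do.call(rbind, lapply(1:3, function(c) {
      rmvn(sizes[c], means[c, ], diag(sd^2, 3L))
    }))
    p <- point3_table(pts, case_id = "sim-normal", cohort = "Normal")
    attr(p, "true_means") <- means
    attr(p, "true_labels") <- rep(1:3, sizes)
    p
  })
}

# One preprocessed case per cohort, cached per test file.
quick_case <- function(cohort, n = 900, seed = 11, dominance = "kappa",
                       shift = c(0, 0, 0)) {
  preprocess_case(generate_case(cohort_spec(
    cohort, n_events = n, seed = seed, dominance = dominance,
    global_shift = shift)))
}
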