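#' K-means-initialized Gaussian mixture fit by expectation-maximization
#'
#' Fits a `k`-component Gaussian mixture with full (unconstrained)
#' covariances. Initialization is K-means with k-means++ seeding
#' (`restarts` runs, best within-cluster sum of squares kept); the mixture
#' is then refined by EM until the relative log-likelihood change falls
#' below `tol` or `max_iter` iterations. The per-iteration log-likelihood
#' trace is returned so callers can verify the EM monotonicity guarantee.
#'
#' Near-singular component covariances are regularized with a ridge of
#' `1e-6 * trace(S)/d` on the diagonal. A component that collapses to zero
#' responsibility triggers one re-seeded restart before failing.
#'
#' @param x Numeric matrix, observations x dimensions.
#' @param k Number of components.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Iteration cap.
#' @param restarts K-means++ restarts for initialization.
#' @param seed Integer seed making the fit reproducible; `NULL` uses the
#'   current RNG stream.
#' @return List with `weights` (length `k`, sums to 1), `means` (`k x d`),
#'   `covs` (list of `k` symmetric positive-definite `d x d` matrices),
#'   `loglik` (per-iteration trace), `labels` (maximum-responsibility
#'   assignment), `iterations`, `converged`.
#' @export
gmm_fit <- function(x, k, tol = 1e-6, max_iter = 500L, restarts = 10L,
                    seed = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  d <- ncol(x)
  if (n < k) stop("fewer observations than mixture components")
  with_seed(seed, {
    fit <- tryCatch(gmm_em(x, kmeans_init(x, k, restarts), tol, max_iter),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      # one re-seeded attempt before giving up (empty-component recovery)
      fit <- tryCatch(gmm_em(x, kmeans_init(x, k, restarts), tol, max_iter),
                      error = function(e) {
                        stop("EM failed: ", conditionMessage(e))
                      })
    }
    fit
  })
}

# k-means++ seeding + Lloyd iterations; best of `restarts` by total
# within-cluster sum of squares.
kmeans_init <- function(x, k, restarts = 10L) {
  best <- NULL
  for (r in seq_len(restarts)) {
    centers <- kmeanspp_centers(x, k)
    km <- tryCatch(
      stats::kmeans(x, centers = centers, iter.max = 100L,
                    algorithm = "Lloyd"),
      error = function(e) NULL,
      warning = function(w) suppressWarnings(
        stats::kmeans(x, centers = centers, iter.max = 100L,
                      algorithm = "Lloyd"))
    )
    if (is.null(km) || any(km$size == 0L)) next
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  if (is.null(best)) stop("k-means initialization failed for k = ", k)
  best
}

kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1L] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(x, 2L, x[idx[1L], ], "-")^2)
  for (j in seq_len(k - 1L)) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    idx[j + 1L] <- sample.int(n, 1L, prob = prob)
    d2 <- pmin(d2, rowSums(sweep(x, 2L, x[idx[j + 1L], ], "-")^2))
  }
  x[idx, , drop = FALSE]
}

# Ensure symmetry and positive definiteness; ridge = 1e-6 * trace/d.
regularize_cov <- function(s) {
  s <- (s + t(s)) / 2
  d <- ncol(s)
  ridge <- 1e-6 * sum(diag(s)) / d
  if (ridge <= 0 || !is.finite(ridge)) ridge <- 1e-8
  for (i in 1:12) {
    ch <- tryCatch(chol(s), error = function(e) NULL)
    if (!is.null(ch) && all(diag(ch) > 0)) return(s)
    s <- s + diag(ridge, d)
    ridge <- ridge * 10
  }
  stop("covariance could not be regularized to positive definite")
}

# Row-wise log density of N(mu, sigma); sigma must be PD.
log_dmvnorm <- function(x, mu, sigma) {
  ch <- chol(sigma)
  z <- backsolve(ch, t(x) - mu, transpose = TRUE)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) -
    0.5 * ncol(x) * log(2 * pi)
}

gmm_em <- function(x, km, tol, max_iter) {
  n <- nrow(x)
  d <- ncol(x)
  k <- nrow(km$centers)
  means <- unname(km$centers)
  weights <- km$size / n
  covs <- lapply(seq_len(k), function(c) {
    xc <- x[km$cluster == c, , drop = FALSE]
    s <- if (nrow(xc) > d) stats::cov(xc) else diag(1, d)
    regularize_cov(s)
  })

  loglik <- numeric(0)
  converged <- FALSE
  logdens <- matrix(0, n, k)
  for (iter in seq_len(max_iter)) {
    for (c in seq_len(k)) {
      logdens[, c] <- log(weights[c]) + log_dmvnorm(x, means[c, ], covs[[c]])
    }
    mx <- apply(logdens, 1L, max)
    lse <- mx + log(rowSums(exp(logdens - mx)))
    ll <- sum(lse)
    loglik <- c(loglik, ll)
    resp <- exp(logdens - lse)

    nk <- colSums(resp)
    if (any(nk < d + 1e-8)) stop("component collapsed to zero weight")
    weights <- nk / n
    means <- crossprod(resp, x) / nk
    for (c in seq_len(k)) {
      xc <- sweep(x, 2L, means[c, ], "-")
      covs[[c]] <- regularize_cov(crossprod(xc * resp[, c], xc) / nk[c])
    }
    if (iter > 1L) {
      rel <- abs(ll - loglik[iter - 1L]) /
        max(abs(loglik[iter - 1L]), .Machine$double.eps)
      if (rel < tol) {
        converged <- TRUE
        break
      }
    }
  }
  list(weights = as.numeric(weights), means = unname(means), covs = covs,
       loglik = loglik, labels = max.col(resp),
       iterations = length(loglik), converged = converged)
}
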