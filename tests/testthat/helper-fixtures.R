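# Shared fixture builders. Everything is generated in code under fixed seeds.

# random symmetric positive-definite matrix
rand_spd <- function(k, scale = 1) {
  M <- matrix(rnorm(k * k, sd = scale), k, k)
  crossprod(M) + diag(k) * scale
}

# a generative-model instance with informative covariates; returns the
# simulation output plus its sample covariance and subspace split
rand_instance <- function(n, d, p, m = 2000, seed = 1, sigma2 = 1) {
  B <- if (d > 0) {
    withr::with_seed(seed + 77L, rand_spd(d, 1.5) + diag(d))
  } else NULL
  A <- if (p > 0) {
    withr::with_seed(seed + 88L, sort(runif(p, 2, 6), decreasing = TRUE))
  } else NULL
  sim <- simulate_expression(simulation_spec(
    n = n, m = m, d = d, p = p, B = B, A = A, sigma2 = sigma2, seed = seed))
  sim$C <- sample_covariance(sim$Y)
  sim$split <- subspace_split(sim$Z, n = n)
  sim
}

# sample covariance object with a prescribed spectrum (eigenvectors random
# orthonormal under the seed)
cov_with_spectrum <- function(lambda, seed = 1) {
  n <- length(lambda)
  U <- withr::with_seed(seed, qr.Q(qr(matrix(rnorm(n * n), n, n))))
  remlvc:::as_sample_cov(U %*% (lambda * t(U)))
}

expect_orthonormal <- function(X, tol = 1e-10) {
  expect_lt(max(abs(crossprod(X) - diag(ncol(X)))), tol)
}
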