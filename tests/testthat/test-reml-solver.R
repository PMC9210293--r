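test_that("restricted_ppca returns complement eigenvectors mapped to sample space", {
  C <- remlvc:::as_sample_cov(diag(c(4, 2, 1)))
  sp <- subspace_split(matrix(c(1, 0, 0)))
  rp <- restricted_ppca(C, sp, 1)
  expect_equal(abs(rp$latent), matrix(c(0, 1, 0)), tolerance = 1e-12)
  expect_equal(rp$spectrum2, c(2, 1))
  expect_equal(max(abs(crossprod(rp$latent, sp$Q1))), 0)
  expect_error(restricted_ppca(C, sp, 3), "complement dimension")
})

test_that("restricted_ppca agrees with brute-force eigenvectors of P2 C P2", {
  withr::with_seed(41, {
    C <- remlvc:::as_sample_cov(rand_spd(6))
    Z <- matrix(rnorm(12), 6, 2)
    sp <- subspace_split(Z)
    rp <- restricted_ppca(C, sp, 2)
    # oracle: eigendecomposition of the projected matrix P2 C P2
    e <- eigen(sp$P2 %*% C$values %*% sp$P2, symmetric = TRUE)
    oracle <- e$vectors[, 1:2]
    for (j in 1:2) {
      expect_equal(abs(cosine_similarity(rp$latent[, j], oracle[, j])), 1,
                   tolerance = 1e-8)
    }
    expect_orthonormal(rp$latent)
    expect_lt(max(abs(crossprod(rp$latent, Z))), 1e-10)
  })
})

test_that("select_p picks the smallest p reaching the target fraction", {
  C <- cov_with_spectrum(c(4, 2, 1, 1), seed = 6)
  sp0 <- subspace_split(NULL, n = 4)
  expect_equal(select_p(C, sp0, 0.5), 1L)     # 4/8
  expect_equal(select_p(C, sp0, 0.74), 2L)    # 6/8 = 0.75
  # a known covariate already explaining 4/8 lowers the needed p
  Cd <- remlvc:::as_sample_cov(diag(c(4, 2, 1, 1)))
  spz <- subspace_split(matrix(c(1, 0, 0, 0)))
  expect_equal(select_p(Cd, spz, 0.74), 1L)
  expect_error(select_p(C, sp0, 1), "rho")
  expect_error(select_p(remlvc:::as_sample_cov(matrix(0, 3, 3)), subspace_split(NULL, n = 3), 0.5),
               "tr\\(C\\) = 0")
})

test_that("enforce_existence raises p exactly until the condition holds", {
  Cd <- remlvc:::as_sample_cov(diag(c(4, 2, 1)))
  spz <- subspace_split(matrix(c(1, 0, 0)))
  expect_equal(enforce_existence(Cd, spz, 0), 0L)  # sigma2(0) = 1.5 < 4

  C2 <- remlvc:::as_sample_cov(diag(c(4, 1.2, 1.0, 0.9)))
  sp2 <- subspace_split(matrix(c(0, 1, 0, 0)))
  expect_equal(enforce_existence(C2, sp2, 0), 1L)  # 1.967 > 1.2 at p=0; 0.95 < 1.2 at p=1

  # without covariates the condition holds automatically for distinct eigenvalues
  expect_equal(enforce_existence(Cd, subspace_split(NULL, n = 3), 1), 1L)

  # unsatisfiable: covariate along the weakest direction can never beat sigma2
  C3 <- remlvc:::as_sample_cov(diag(c(4, 2, 1)))
  sp3 <- subspace_split(matrix(c(0, 0, 1)))
  expect_error(enforce_existence(C3, sp3, 0), "redundancy")
})

test_that("variance components are recovered blockwise given latent factors", {
  Cd <- remlvc:::as_sample_cov(diag(c(4, 2, 1)))
  spz <- subspace_split(matrix(c(1, 0, 0)))
  est <- estimate_variance_components(Cd, spz, matrix(c(0, 1, 0)))
  expect_equal(est$sigma2, 1)
  expect_equal(diag(est$components$A), 1)
  expect_equal(est$components$B, matrix(3))
  expect_equal(est$components$D, matrix(0))
  expect_equal(est$K_hat, diag(c(4, 2, 1)))

  # off-diagonal known-latent covariance lands in D
  c12 <- 0.6
  Cc <- rbind(c(4, c12, 0), c(c12, 2, 0), c(0, 0, 1))
  est2 <- estimate_variance_components(remlvc:::as_sample_cov(Cc), spz, matrix(c(0, 1, 0)))
  expect_equal(est2$components$D, matrix(c12))

  # no latent factors reduces to the known-covariate solution
  est0 <- estimate_variance_components(Cd, spz, matrix(0, 3, 0))
  ks <- known_covariate_solution(Cd, spz)
  expect_equal(est0$K_hat, ks$K_hat)
  expect_equal(est0$components$B, ks$B_hat)
})

test_that("estimated components reproduce K through build_K on random instances", {
  for (i in 1:6) {
    inst <- rand_instance(n = 12, d = 2, p = 2, m = 1500, seed = 500 + i)
    fit <- reml_fit(inst$Y, inst$Z, p = 2)
    expect_lt(max(abs(build_K(inst$Z, fit$latent, fit$components) - fit$K_hat)), 1e-8)
    # K restricted to span(Z) + span(X) equals the same restriction of C
    G <- cbind(inst$split$Q1, fit$latent)
    expect_lt(max(abs(crossprod(G, (fit$K_hat - inst$C$values) %*% G))), 1e-8)
  }
})

test_that("orthogonalize_latents preserves K while absorbing overlap", {
  # full absorption: latent direction identical to the known covariate
  vc <- variance_components(B = matrix(2), D = 0.5, A = 1.5, sigma2 = 1)
  K0 <- build_K(matrix(c(1, 0)), matrix(c(1, 0)), vc)
  ol <- orthogonalize_latents(matrix(c(1, 0)), matrix(c(1, 0)), vc)
  expect_equal(ol$components$p, 0L)
  expect_equal(ol$components$B, matrix(2 + 2 * 0.5 + 1.5))
  expect_equal(ol$K, K0)

  # already-orthogonal factors are a fixed point (up to rotation of A)
  Z <- matrix(c(1, 0, 0)); X <- matrix(c(0, 1, 0))
  vc2 <- variance_components(B = matrix(1), D = 0.2, A = 2, sigma2 = 0.5)
  ol2 <- orthogonalize_latents(Z, X, vc2)
  expect_equal(abs(ol2$latent), abs(X), tolerance = 1e-10)
  expect_equal(ol2$K, build_K(Z, X, vc2), tolerance = 1e-10)

  # random overlapping latents: K preserved, output orthogonal to Z
  withr::with_seed(51, {
    for (i in 1:5) {
      n <- 8
      Z <- qr.Q(qr(matrix(rnorm(n * 3), n, 3)))
      Xr <- matrix(rnorm(n * 2), n, 2)
      Xr <- sweep(Xr, 2, sqrt(colSums(Xr^2)), `/`)
      vcr <- variance_components(rand_spd(3), matrix(rnorm(6) * 0.1, 3, 2),
                                 c(2, 1), sigma2 = 0.5)
      Kraw <- build_K(Z, Xr, vcr)
      res <- orthogonalize_latents(Z, Xr, vcr)
      expect_lt(max(abs(res$K - Kraw)), 1e-8)
      if (res$components$p > 0) {
        expect_lt(max(abs(crossprod(res$latent, Z))), 1e-8)
      }
    }
  })
})

test_that("fit with no covariates reduces to probabilistic PCA", {
  inst <- rand_instance(n = 20, d = 0, p = 3, m = 1000, seed = 61)
  fit <- reml_fit(inst$Y, NULL, p = 3)
  pp <- ppca(inst$C, 3)
  expect_equal(fit$K_hat, pp$K_hat, tolerance = 1e-10)
  expect_equal(fit$sigma2, pp$sigma2, tolerance = 1e-12)
  expect_equal(abs(diag(crossprod(fit$latent, pp$latent))), rep(1, 3),
               tolerance = 1e-10)
})

test_that("with top expression PCs as covariates the next PCs come out latent", {
  inst <- rand_instance(n = 25, d = 0, p = 4, m = 1200, seed = 62)
  d <- 2; p <- 2
  Zpc <- inst$C$eigenvectors[, seq_len(d), drop = FALSE]
  fit <- reml_fit(inst$Y, Zpc, p = p)
  next_pcs <- inst$C$eigenvectors[, d + seq_len(p), drop = FALSE]
  for (j in seq_len(p)) {
    expect_equal(abs(cosine_similarity(fit$latent[, j], next_pcs[, j])), 1,
                 tolerance = 1e-8)
  }
})

test_that("log-likelihood curves shift by d when top-d PCs become covariates", {
  inst <- rand_instance(n = 20, d = 0, p = 4, m = 900, seed = 63)
  d <- 3
  Zpc <- inst$C$eigenvectors[, seq_len(d), drop = FALSE]
  pr0 <- loglik_profile(inst$Y, NULL, seq_len(9))
  prd <- loglik_profile(inst$Y, Zpc, seq_len(6))
  expect_lt(max(abs(prd$loglik - pr0$loglik[d + seq_len(6)])), 1e-8)
})

test_that("fitted latent factors are orthogonal to the covariates", {
  for (i in 1:8) {
    inst <- rand_instance(n = 15, d = 2, p = 2, m = 800, seed = 700 + i)
    fit <- reml_fit(inst$Y, inst$Z, p = 2)
    cosines <- abs(crossprod(fit$latent, apply(inst$Z, 2, function(z) z / sqrt(sum(z^2)))))
    expect_lt(max(cosines), 1e-10)
  }
})

test_that("variance ledger sums to tr(C) and rho_achieved meets the target", {
  inst <- rand_instance(n = 30, d = 2, p = 3, m = 1500, seed = 71)
  fit <- reml_fit(inst$Y, inst$Z, rho = 0.4)
  expect_equal(sum(fit$variance_ledger$variance), inst$C$trace, tolerance = 1e-8)
  expect_gte(fit$rho_achieved, 0.4)
  expect_equal(fit$loglik, sum(fit$loglik_terms), tolerance = 1e-10)
  # K_hat positive definite
  expect_gt(min(eigen(fit$K_hat, symmetric = TRUE, only.values = TRUE)$values), 0)
})

test_that("selected p is nonincreasing as informative covariates are added", {
  inst <- rand_instance(n = 30, d = 0, p = 5, m = 1500, seed = 72)
  rho <- 0.5
  p_prev <- Inf
  for (d in 0:3) {
    Z <- if (d > 0) inst$C$eigenvectors[, seq_len(d), drop = FALSE] else NULL
    sp <- subspace_split(Z, n = 30)
    p_d <- select_p(inst$C, sp, rho)
    expect_lte(p_d, p_prev)
    p_prev <- p_d
  }
})

test_that("REML factors leave no smaller residual than random frames", {
  inst <- rand_instance(n = 15, d = 2, p = 2, m = 800, seed = 73)
  fit <- reml_fit(inst$Y, inst$Z, p = 2)
  sp <- inst$split
  n <- 15; p <- 2; r <- sp$r
  withr::with_seed(74, {
    for (i in 1:50) {
      M <- sp$Q2 %*% matrix(rnorm((n - r) * p), n - r, p)
      Fr <- qr.Q(qr(M))[, 1:p, drop = FALSE]
      s2_rand <- (inst$C$trace - sum(diag(crossprod(cbind(sp$Q1, Fr), inst$C$values %*% cbind(sp$Q1, Fr))))) / (n - r - p)
      expect_gte(s2_rand, fit$sigma2 - 1e-12)
    }
  })
})

test_that("fit auto-centers uncentered input and validates arguments", {
  inst <- rand_instance(n = 10, d = 0, p = 1, m = 300, seed = 75)
  Yoff <- inst$Y + 3   # breaks row centering
  expect_message(f1 <- reml_fit(Yoff, NULL, p = 1), "centering")
  f2 <- reml_fit(inst$Y, NULL, p = 1)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-10)
  expect_error(reml_fit(inst$Y, NULL, rho = 1.2), "rho")
  expect_error(reml_fit(inst$Y, NULL, p = 10), "p must lie")
  # covariates spanning the whole sample space are rejected
  expect_error(reml_fit(inst$Y, diag(10), rho = 0.5), "span the sample space")
})

test_that("a noninformative covariate triggers existence enforcement", {
  inst <- rand_instance(n = 40, d = 0, p = 3, m = 2000, seed = 76)
  # covariate along a weak (bulk) eigendirection explains less than sigma2
  z_weak <- inst$C$eigenvectors[, 30, drop = FALSE]
  expect_warning(fit <- reml_fit(inst$Y, z_weak, rho = 0.3),
                 "existence condition raised")
  expect_gt(fit$p, fit$p_selected)
  expect_true(fit$existence_raised)
  expect_gt(fit$rho_achieved, 0.3)
})
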