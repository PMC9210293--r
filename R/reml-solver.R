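# Analytic REML solver. Latent factors are estimated by probabilistic PCA on
# the orthogonal complement of span(Z); the covariance parameters B, D, A and
# the residual variance sigma2 then follow in closed form by treating (Z, X)
# jointly as known covariates. No numeric optimization anywhere.

#' Probabilistic PCA solution for p latent factors (no known covariates)
#'
#' The maximum-likelihood solution with K constrained to X A X' + sigma2 I:
#' the latent factors are the top-p eigenvectors of C, sigma2 is the average
#' variance of the n - p excluded dimensions, A_ii = lambda_i - sigma2, and
#' K = P1 C P1 + sigma2 P2 with P1 the top-p eigenprojector.
#'
#' @param C a [sample_covariance()] object (or n x n matrix).
#' @param p number of latent factors, 0 <= p < n.
#' @return list with `latent` (n x p orthonormal), `A` (length-p diagonal),
#'   `sigma2`, `K_hat`, `loglik`.
#' @export
ppca <- function(C, p) {
  C <- as_sample_cov(C)
  n <- C$n
  p <- as.integer(p)
  if (p < 0 || p >= n) stop(sprintf("need 0 <= p < n = %d, got p = %d", n, p), call. = FALSE)
  lam <- C$eigenvalues
  sigma2 <- mean(lam[seq.int(p + 1L, n)])
  if (sigma2 <= 0) stop("residual variance is not positive; C is rank deficient below p", call. = FALSE)
  if (p > 0 && lam[p] <= sigma2) {
    stop(sprintf(paste0(
      "existence condition violated: eigenvalue %d of C (%.4g) does not exceed ",
      "the residual variance estimate %.4g"), p, lam[p], sigma2), call. = FALSE)
  }
  X <- C$eigenvectors[, seq_len(p), drop = FALSE]
  A <- lam[seq_len(p)] - sigma2
  P1 <- tcrossprod(X)
  K_hat <- P1 %*% C$values %*% P1 + sigma2 * (diag(n) - P1)
  K_hat <- (K_hat + t(K_hat)) / 2
  list(latent = X, A = A, sigma2 = sigma2, K_hat = K_hat,
       loglik = log_likelihood(K_hat, C))
}

#' Analytic solution with known covariates only (no latent factors)
#'
#' Maximum-likelihood estimate with K constrained to Z B Z' + sigma2 I:
#' K = P1 C P1 + sigma2 P2 with P1 the projector on span(Z), sigma2 the mean
#' variance in the complement, and B recovered in the original Z coordinates
#' by back-substitution through the SVD of Z. The maximizer exists only when
#' every principal axis of span(Z) explains more variance than sigma2.
#'
#' @param C a [sample_covariance()] object (or n x n matrix).
#' @param split a [subspace_split()] of the known covariates.
#' @return list with `B_hat` (d x d, zero rows/columns for dropped redundant
#'   directions), `sigma2`, `K_hat`, `loglik`.
#' @export
known_covariate_solution <- function(C, split) {
  C <- as_sample_cov(C)
  n <- C$n
  r <- split$r
  if (r == 0L) {
    sigma2 <- C$trace / n
    return(list(B_hat = matrix(0, split$d, split$d), sigma2 = sigma2,
                K_hat = diag(sigma2, n),
                loglik = log_likelihood(diag(sigma2, n), C)))
  }
  if (r >= n) stop("known covariates span the whole sample space", call. = FALSE)
  M1 <- crossprod(split$Q1, C$values %*% split$Q1)   # Q1' C Q1, r x r
  sigma2 <- (C$trace - sum(diag(M1))) / (n - r)
  ev1 <- eigen((M1 + t(M1)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev1) <= sigma2) {
    ax <- which.min(ev1)
    stop(sprintf(paste0(
      "existence condition violated: principal axis %d of span(Z) explains ",
      "variance %.4g, not greater than the residual variance estimate %.4g; ",
      "reconsider the relevance or redundancy of the known covariates"),
      ax, min(ev1), sigma2), call. = FALSE)
  }
  P1 <- split$P1
  K_hat <- P1 %*% C$values %*% P1 + sigma2 * split$P2
  K_hat <- (K_hat + t(K_hat)) / 2
  # solve Z B Z' + sigma2 P1 = P1 C P1 through Z = U S V':  S V' B V S = M1 - sigma2 I
  Sinv <- 1 / split$singular_values
  core <- (M1 - diag(sigma2, r)) * outer(Sinv, Sinv)
  B_hat <- split$V %*% core %*% t(split$V)
  B_hat <- (B_hat + t(B_hat)) / 2
  list(B_hat = B_hat, sigma2 = sigma2, K_hat = K_hat,
       loglik = log_likelihood(K_hat, C))
}

# eigendecomposition of C restricted to the orthogonal complement of span(Z)
complement_spectrum <- function(C, split) {
  C <- as_sample_cov(C)
  if (ncol(split$Q2) == 0L) {
    return(list(values = numeric(0), vectors = matrix(0, C$n, 0)))
  }
  C2 <- crossprod(split$Q2, C$values %*% split$Q2)
  e <- eigen((C2 + t(C2)) / 2, symmetric = TRUE)
  list(values = pmax(e$values, 0), vectors = e$vectors)
}

#' Probabilistic PCA restricted to the orthogonal complement of span(Z)
#'
#' Forms C2 = Q2' C Q2, takes its top-p eigenvectors, and maps them back to
#' sample space through Q2, so the returned factors are orthonormal and
#' exactly orthogonal to span(Z) by construction.
#'
#' @inheritParams known_covariate_solution
#' @param p number of latent factors, p <= n - r.
#' @return list with `latent` (n x p) and `spectrum2` (all n - r eigenvalues
#'   of C2, nonincreasing).
#' @export
restricted_ppca <- function(C, split, p) {
  C <- as_sample_cov(C)
  p <- as.integer(p)
  nr <- C$n - split$r
  if (p > nr) stop(sprintf("p = %d exceeds complement dimension n - r = %d", p, nr), call. = FALSE)
  e2 <- complement_spectrum(C, split)
  X <- split$Q2 %*% e2$vectors[, seq_len(p), drop = FALSE]
  list(latent = fix_signs(X), spectrum2 = e2$values)
}

#' Choose the number of latent factors from a target variance fraction
#'
#' Returns the smallest p such that the variance explained by span(Z) plus
#' the top-p complement eigenvalues reaches the fraction `rho` of tr(C),
#' capped at n - r - 1. The existence condition may subsequently raise p
#' further (see [enforce_existence()]).
#'
#' @inheritParams known_covariate_solution
#' @param rho target fraction of total variance explained, 0 < rho < 1.
#' @return integer p.
#' @export
select_p <- function(C, split, rho) {
  C <- as_sample_cov(C)
  if (!is.numeric(rho) || length(rho) != 1L || rho <= 0 || rho >= 1) {
    stop("rho must lie strictly between 0 and 1", call. = FALSE)
  }
  if (C$trace <= 0) stop("tr(C) = 0: no variance to explain", call. = FALSE)
  e2 <- complement_spectrum(C, split)
  explained_known <- C$trace - sum(e2$values)
  cap <- max(C$n - split$r - 1L, 0L)
  frac <- (explained_known + cumsum(c(0, e2$values))) / C$trace
  p <- which(frac >= rho)[1] - 1L
  if (is.na(p)) p <- cap
  min(as.integer(p), cap)
}

#' Raise p until the analytic maximizer exists
#'
#' The analytic solution exists only when the variance explained by every
#' retained direction — each principal axis of span(Z) and each retained
#' complement eigenvalue — strictly exceeds the residual variance estimate
#' sigma2(p) (the mean of the excluded complement eigenvalues). Including
#' more hidden covariates lowers sigma2, so this returns the smallest
#' p' >= p satisfying the condition, or errors if none exists below
#' n - r - 1 (a cue that the known covariates are noninformative or
#' redundant and should be re-screened).
#'
#' @inheritParams known_covariate_solution
#' @param p starting number of latent factors (e.g. from [select_p()]).
#' @return integer p' >= p.
#' @export
enforce_existence <- function(C, split, p) {
  C <- as_sample_cov(C)
  p <- as.integer(p)
  nr <- C$n - split$r
  e2 <- complement_spectrum(C, split)$values
  min_known <- if (split$r > 0) {
    M1 <- crossprod(split$Q1, C$values %*% split$Q1)
    min(eigen((M1 + t(M1)) / 2, symmetric = TRUE, only.values = TRUE)$values)
  } else Inf
  for (pp in seq.int(p, max(nr - 1L, p))) {
    if (pp > nr - 1L) break
    sigma2 <- mean(e2[seq.int(pp + 1L, nr)])
    ok_known <- min_known > sigma2
    ok_latent <- pp == 0L || e2[pp] > sigma2
    if (ok_known && ok_latent) return(as.integer(pp))
  }
  stop(paste0(
    "existence condition cannot be satisfied for any number of latent factors: ",
    "the relevance or possible redundancy of (some of) the known covariates ",
    "needs to be reconsidered"), call. = FALSE)
}

#' Analytic variance-component estimates given latent factors
#'
#' Treats (Z, X) jointly as known covariates and maximizes the remaining
#' likelihood terms in closed form: with G = [Q1, X] and projector
#' P = G G', the estimate is K = P C P + sigma2 (I - P), sigma2 the mean of
#' the excluded complement eigenvalues. The blocks of G' C G - sigma2 I give
#' A (diagonal after an in-span rotation of X), D, and B (back-transformed to
#' the original Z coordinates through the SVD of Z).
#'
#' @inheritParams known_covariate_solution
#' @param X n x p latent factors, orthonormal and orthogonal to span(Z).
#' @return list with `components` (a [variance_components()] object),
#'   `latent` (X, possibly rotated so A is diagonal), `K_hat`, `sigma2`.
#' @export
estimate_variance_components <- function(C, split, X) {
  C <- as_sample_cov(C)
  n <- C$n
  X <- as_design(X)
  if (length(X) == 0L) X <- matrix(0, n, 0)
  p <- ncol(X)
  r <- split$r
  if (p > 0) {
    if (split$r > 0 && max(abs(crossprod(X, split$Q1))) > 1e-8) {
      stop("latent factors must be orthogonal to span(Z)", call. = FALSE)
    }
    if (max(abs(crossprod(X) - diag(p))) > 1e-8) {
      stop("latent factors must be orthonormal", call. = FALSE)
    }
  }
  if (r + p >= n) stop("known plus latent factors span the whole sample space", call. = FALSE)
  if (p == 0L) {
    ks <- known_covariate_solution(C, split)
    vc <- variance_components(B = ks$B_hat, D = matrix(0, split$d, 0),
                              A = numeric(0), sigma2 = ks$sigma2)
    return(list(components = vc, latent = matrix(0, n, 0), K_hat = ks$K_hat,
                sigma2 = ks$sigma2))
  }
  # rotate X within its span so that X' C X is diagonal (rotational symmetry
  # of the latent factors); REML factors are already eigenvectors, so this is
  # then the identity up to sign
  MX <- crossprod(X, C$values %*% X)
  eX <- eigen((MX + t(MX)) / 2, symmetric = TRUE)
  X <- fix_signs(X %*% eX$vectors)
  lamX <- eX$values

  G <- cbind(split$Q1, X)
  MG <- crossprod(G, C$values %*% G)
  sigma2 <- (C$trace - sum(diag(MG))) / (n - r - p)
  if (sigma2 <= 0) stop("residual variance estimate is not positive", call. = FALSE)
  A <- lamX - sigma2
  if (any(A <= 0)) {
    stop(sprintf(paste0(
      "existence condition violated: latent factor %d explains variance %.4g, ",
      "not greater than the residual variance estimate %.4g"),
      which(A <= 0)[1], min(lamX), sigma2), call. = FALSE)
  }
  if (r > 0) {
    M11 <- MG[seq_len(r), seq_len(r), drop = FALSE] - diag(sigma2, r)
    evB <- eigen((M11 + t(M11)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(evB) <= 0) {
      stop(sprintf(paste0(
        "existence condition violated: principal axis %d of span(Z) explains ",
        "variance not greater than the residual variance estimate %.4g"),
        which.min(evB), sigma2), call. = FALSE)
    }
    Sinv <- 1 / split$singular_values
    B <- split$V %*% (M11 * outer(Sinv, Sinv)) %*% t(split$V)
    B <- (B + t(B)) / 2
    M12 <- MG[seq_len(r), r + seq_len(p), drop = FALSE]
    D <- split$V %*% (M12 * Sinv)
  } else {
    B <- matrix(0, split$d, split$d)
    D <- matrix(0, split$d, p)
  }
  vc <- variance_components(B = B, D = D, A = A, sigma2 = sigma2)
  P <- tcrossprod(G)
  K_hat <- P %*% C$values %*% P + sigma2 * (diag(n) - P)
  K_hat <- (K_hat + t(K_hat)) / 2
  list(components = vc, latent = X, K_hat = K_hat, sigma2 = sigma2)
}

#' Reparameterize arbitrary latent factors to be orthogonal to Z
#'
#' Any model of the covariance form K = Z B Z' + Z D X' + X D' Z' + X A X' +
#' sigma2 I with latent factors overlapping span(Z) can be rewritten with
#' orthogonal factors: the overlap is absorbed into the known-covariate
#' effect covariances B and D by a linear transformation, leaving K
#' unchanged. Latent directions entirely inside span(Z) are dropped; A is
#' re-diagonalized by rotation.
#'
#' @param Z n x d known covariates.
#' @param X_raw n x p latent factors, possibly overlapping span(Z).
#' @param vc_raw [variance_components()] for (Z, X_raw).
#' @return list with `latent` (orthonormal, orthogonal to span(Z)),
#'   `components`, and the reproduced `K` (equal to the input model's K).
#' @export
orthogonalize_latents <- function(Z, X_raw, vc_raw) {
  Z <- as_design(Z); X_raw <- as_design(X_raw)
  n <- max(nrow(Z), nrow(X_raw))
  K <- build_K(Z, X_raw, vc_raw)
  split <- subspace_split(Z, n = n)
  W <- K - diag(vc_raw$sigma2, n)    # the structured (low-rank) part
  # orthonormal basis of the complement component of the latent span
  X2 <- split$P2 %*% X_raw
  if (length(X2) > 0L) {
    sv <- svd(X2)
    keep <- sv$d > 1e-10 * max(sv$d, .Machine$double.eps)
    Xb <- sv$u[, keep, drop = FALSE]
  } else {
    Xb <- matrix(0, n, 0)
  }
  p2 <- ncol(Xb)
  if (p2 > 0) {
    # rotate so the latent-latent block of W is diagonal
    A22 <- crossprod(Xb, W %*% Xb)
    eA <- eigen((A22 + t(A22)) / 2, symmetric = TRUE)
    Xb <- fix_signs(Xb %*% eA$vectors)
    A <- eA$values
  } else {
    A <- numeric(0)
  }
  r <- split$r
  if (r > 0) {
    W11 <- crossprod(split$Q1, W %*% split$Q1)
    Sinv <- 1 / split$singular_values
    B <- split$V %*% (W11 * outer(Sinv, Sinv)) %*% t(split$V)
    B <- (B + t(B)) / 2
    D <- if (p2 > 0) split$V %*% (crossprod(split$Q1, W %*% Xb) * Sinv) else matrix(0, ncol(Z), 0)
  } else {
    B <- matrix(0, ncol(Z), ncol(Z))
    D <- matrix(0, ncol(Z), p2)
  }
  vc <- structure(list(B = B, D = D, A = diag(A, nrow = p2), sigma2 = vc_raw$sigma2,
                       d = ncol(Z), p = p2), class = "variance_components")
  list(latent = Xb, components = vc, K = build_K(Z, Xb, vc))
}
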