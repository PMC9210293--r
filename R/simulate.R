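# Generative-model simulator: draws expression data from
# Y = Z V + X W + eps with jointly normal effect vectors, for tests,
# examples and power studies.

#' Specify a simulation from the generative model
#'
#' @param n,m,d,p numbers of samples, genes, known covariates and latent
#'   factors.
#' @param B d x d known-effect covariance (scalar accepted when d = 1; may be
#'   omitted when d = 0).
#' @param D d x p known-latent effect covariance (default 0).
#' @param A length-p vector of latent effect variances (diagonal of A).
#' @param sigma2 residual variance.
#' @param Z_mode how Z is drawn: "orthonormal" (random orthonormal columns)
#'   or "correlated" (random Gaussian columns, unit-normalized but not
#'   orthogonal).
#' @param seed integer seed; all randomness in [simulate_expression()] flows
#'   through it.
#' @return object of class `simulation_spec`.
#' @export
simulation_spec <- function(n, m, d = 0, p = 0, B = NULL, D = NULL, A = NULL,
                            sigma2 = 1, Z_mode = c("orthonormal", "correlated"),
                            seed = 1L) {
  Z_mode <- match.arg(Z_mode)
  d <- as.integer(d); p <- as.integer(p)
  stopifnot(n >= 2, m >= 1, d >= 0, p >= 0, sigma2 > 0)
  B <- if (d == 0) matrix(0, 0, 0) else as.matrix(B)
  stopifnot(nrow(B) == d, ncol(B) == d)
  if (is.null(A)) A <- numeric(0)
  stopifnot(length(A) == p, all(A >= 0))
  D <- if (is.null(D)) matrix(0, d, p) else matrix(as.numeric(D), d, p)
  joint <- rbind(cbind(B, D), cbind(t(D), diag(A, nrow = p)))
  if (d + p > 0) {
    ev <- eigen((joint + t(joint)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10 * max(abs(ev), 1)) {
      stop("joint effect covariance [[B, D], [D', A]] is not positive semidefinite",
           call. = FALSE)
    }
  }
  structure(list(n = as.integer(n), m = as.integer(m), d = d, p = p,
                 B = B, D = D, A = as.numeric(A), sigma2 = sigma2,
                 Z_mode = Z_mode, seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Simulate expression data from the generative model
#'
#' Draws Z (per `Z_mode`), a true latent-factor matrix X orthonormal and
#' orthogonal to span(Z), per-gene effect vectors (v_i, w_i) jointly normal
#' with block covariance \[\[B, D\], \[D', A\]\], and i.i.d. Gaussian noise, then
#' row-centers Y = Z V + X W + eps like real data. Bit-reproducible under the
#' spec's seed.
#'
#' @param spec a [simulation_spec()].
#' @return list with `Y` (n x m, row-centered), `Z` (n x d), `X_true`
#'   (n x p), and the `spec`.
#' @export
simulate_expression <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n; m <- spec$m; d <- spec$d; p <- spec$p
    Z <- if (d > 0) {
      M <- matrix(rnorm(n * d), n, d)
      if (spec$Z_mode == "orthonormal") fix_signs(qr.Q(qr(M))[, seq_len(d), drop = FALSE])
      else sweep(M, 2, sqrt(colSums(M^2)), `/`)
    } else matrix(0, n, 0)
    X <- if (p > 0) {
      M <- matrix(rnorm(n * p), n, p)
      if (d > 0) M <- M - Z %*% solve(crossprod(Z), crossprod(Z, M))
      fix_signs(qr.Q(qr(M))[, seq_len(p), drop = FALSE])
    } else matrix(0, n, 0)
    Y <- matrix(0, n, m)
    if (d + p > 0) {
      joint <- rbind(cbind(spec$B, spec$D),
                     cbind(t(spec$D), diag(spec$A, nrow = p)))
      ej <- eigen((joint + t(joint)) / 2, symmetric = TRUE)
      root <- ej$vectors %*% (sqrt(pmax(ej$values, 0)) * t(ej$vectors))
      E <- root %*% matrix(rnorm((d + p) * m), d + p, m)   # rows: v then w
      if (d > 0) Y <- Y + Z %*% E[seq_len(d), , drop = FALSE]
      if (p > 0) Y <- Y + X %*% E[d + seq_len(p), , drop = FALSE]
    }
    Y <- Y + matrix(rnorm(n * m, sd = sqrt(spec$sigma2)), n, m)
    rownames(Y) <- paste0("sample_", seq_len(n))
    colnames(Y) <- paste0("gene_", seq_len(m))
    if (d > 0) {
      rownames(Z) <- rownames(Y); colnames(Z) <- paste0("covariate_", seq_len(d))
    }
    if (p > 0) {
      rownames(X) <- rownames(Y); colnames(X) <- paste0("factor_", seq_len(p))
    }
    list(Y = center_samples(Y), Z = Z, X_true = X, spec = spec)
  })
}

#' Numeric maximum-likelihood oracle (quasi-Newton)
#'
#' Maximizes L = -log det(K) - tr(K^-1 C) over covariances of the model form
#' by a BFGS optimizer with analytic gradient, using the factor
#' parameterization K = F F' + sigma2 I with the first rank(Z) columns of F
#' constrained to span(Z) and p free columns. Multiple random restarts; the
#' best solution is kept. This is a validation oracle for the analytic REML
#' solver, not a production path, and is limited to small n.
#'
#' @param C a [sample_covariance()] object or n x n matrix.
#' @param Z n x d known covariates (or NULL).
#' @param p number of free latent columns.
#' @param restarts number of random restarts.
#' @param seed integer seed for the restarts.
#' @return list with `K` (best covariance found), `loglik`, `converged`
#'   (TRUE if any restart converged).
#' @export
numeric_mle <- function(C, Z = NULL, p = 1, restarts = 10, seed = 1L) {
  C <- as_sample_cov(C)
  n <- C$n
  if (n > 20) stop("numeric oracle is restricted to n <= 20", call. = FALSE)
  split <- subspace_split(Z, n = n)
  r <- split$r
  if (r + p >= n) stop("need rank(Z) + p < n", call. = FALSE)
  Cm <- C$values
  npar <- r * r + n * p + 1L
  unpack <- function(theta) {
    G1 <- matrix(theta[seq_len(r * r)], r, r)
    H <- matrix(theta[r * r + seq_len(n * p)], n, p)
    s2 <- exp(theta[npar])
    Fm <- cbind(split$Q1 %*% G1, H)
    list(Fm = Fm, s2 = s2, G1 = G1, H = H)
  }
  negll <- function(theta) {
    par <- unpack(theta)
    K <- tcrossprod(par$Fm) + diag(par$s2, n)
    R <- chol(K)
    Kinv <- chol2inv(R)
    2 * sum(log(diag(R))) + sum(Kinv * Cm)
  }
  grad <- function(theta) {
    par <- unpack(theta)
    K <- tcrossprod(par$Fm) + diag(par$s2, n)
    R <- chol(K)
    Kinv <- chol2inv(R)
    M <- Kinv - Kinv %*% Cm %*% Kinv     # d(-L)/dK
    gF <- 2 * M %*% par$Fm
    gG1 <- crossprod(split$Q1, gF[, seq_len(r), drop = FALSE])
    gH <- gF[, r + seq_len(p), drop = FALSE]
    gs <- par$s2 * sum(diag(M))
    c(as.numeric(gG1), as.numeric(gH), gs)
  }
  best <- NULL
  converged <- FALSE
  withr::with_seed(seed, {
    for (i in seq_len(restarts)) {
      init <- c(rnorm(r * r, sd = sqrt(max(C$trace / n, 1))),
                rnorm(n * p, sd = sqrt(max(C$trace / n, 1))),
                log(max(C$trace / n / 2, 1e-3)))
      opt <- tryCatch(
        optim(init, fn = negll, gr = grad, method = "BFGS",
              control = list(maxit = 500, reltol = 1e-14)),
        error = function(e) NULL)
      if (is.null(opt)) next
      if (is.null(best) || opt$value < best$value) best <- opt
      if (opt$convergence == 0) converged <- TRUE
    }
  })
  if (is.null(best)) stop("numeric oracle failed on every restart", call. = FALSE)
  par <- unpack(best$par)
  K <- tcrossprod(par$Fm) + diag(par$s2, n)
  list(K = K, loglik = -best$value, converged = converged)
}
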