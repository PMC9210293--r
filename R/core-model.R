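# Random-effects model for expression data with known and latent variance
# components:
#
#   Y = Z V + X W + eps,   cols (v_i, w_i) ~ N(0, [[B, D], [D', A]]),
#   eps_ij ~ N(0, sigma2),
#
# so that the induced sample-by-sample covariance is
#
#   K = Z B Z' + Z D X' + X D' Z' + X A X' + sigma2 * I
#
# and the marginal log-likelihood (up to additive constants, per-gene
# contributions summed and scaled) is L = -log det(K) - tr(K^-1 C), with
# C = Y Y' / m the sample covariance matrix.

#' Coerce expression input to a samples-by-genes numeric matrix
#'
#' Accepts a numeric matrix, or a data frame whose numeric columns are genes
#' (row names, if present, become sample ids). Used internally by every
#' user-facing function so matrices and tibbles can be supplied
#' interchangeably.
#'
#' @param Y matrix or data frame, samples in rows.
#' @return numeric matrix with dimnames.
#' @keywords internal
as_expression_matrix <- function(Y) {
  if (is.data.frame(Y)) {
    num <- vapply(Y, is.numeric, logical(1))
    if (!all(num)) {
      ids <- NULL
      chr <- which(!num)
      if (length(chr) == 1L && chr == 1L && (is.character(Y[[1]]) || is.factor(Y[[1]]))) {
        ids <- as.character(Y[[1]])
        Y <- Y[, -1L, drop = FALSE]
      } else {
        stop("expression input must be all-numeric (optionally a leading id column)",
             call. = FALSE)
      }
      Y <- as.matrix(Y)
      rownames(Y) <- ids
    } else {
      Y <- as.matrix(Y)
    }
  }
  if (!is.matrix(Y) || !is.numeric(Y)) {
    stop("expression input must be a numeric matrix or data frame", call. = FALSE)
  }
  if (is.null(rownames(Y))) rownames(Y) <- paste0("sample_", seq_len(nrow(Y)))
  if (is.null(colnames(Y))) colnames(Y) <- paste0("var_", seq_len(ncol(Y)))
  Y
}

#' Center each sample (row) of an expression matrix to mean zero
#'
#' Centering is per sample, i.e. each row of the n x m matrix gets mean zero,
#' so that no fixed effects on the mean need to be included in the model.
#' Gene-wise (column) centering is deliberately not applied.
#'
#' @param Y numeric matrix or data frame, n samples x m genes.
#' @return numeric matrix with row means zero; dimnames preserved.
#' @examples
#' center_samples(rbind(a = c(1, 2, 3), b = c(5, 5, 5)))
#' @export
center_samples <- function(Y) {
  Y <- as_expression_matrix(Y)
  if (!all(is.finite(Y))) {
    bad <- which(!is.finite(Y), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite expression value at sample '%s', gene '%s'",
                 rownames(Y)[bad[1]], colnames(Y)[bad[2]]), call. = FALSE)
  }
  Y - rowMeans(Y)
}

is_row_centered <- function(Y, tol = 1e-8) {
  scale <- max(1, max(abs(Y)))
  max(abs(rowMeans(Y))) <= tol * scale
}

#' Sample covariance matrix with cached spectral decomposition
#'
#' Computes C = Y Y' / m for a row-centered n x m expression matrix and caches
#' its symmetric eigendecomposition (eigenvalues nonincreasing). When m <= n
#' the matrix is singular or ill-conditioned and the unconstrained
#' maximum-likelihood estimate K = C is not valid; a warning flag is set.
#'
#' @param Y numeric matrix or data frame, n samples x m genes, row-centered.
#' @return object of class `sample_cov`: list with `values` (C), `trace`,
#'   `eigenvalues`, `eigenvectors`, `n`, `m`, and logical `singular`.
#' @export
sample_covariance <- function(Y) {
  Y <- as_expression_matrix(Y)
  n <- nrow(Y)
  m <- ncol(Y)
  C <- tcrossprod(Y) / m
  C <- (C + t(C)) / 2
  eig <- eigen(C, symmetric = TRUE)
  tr <- sum(diag(C))
  clip <- -1e-10 * max(tr, .Machine$double.eps) / n
  if (any(eig$values < clip)) {
    stop(sprintf(
      "sample covariance has eigenvalue %.3e far below zero; input is corrupt",
      min(eig$values)), call. = FALSE)
  }
  eig$values <- pmax(eig$values, 0)
  singular <- m < n
  if (singular) {
    warning("fewer genes than samples (m < n): C is singular and the ",
            "unconstrained optimum K = C is not attainable", call. = FALSE)
  }
  structure(
    list(values = C, trace = tr, eigenvalues = eig$values,
         eigenvectors = fix_signs(eig$vectors), n = n, m = m,
         singular = singular, sample_ids = rownames(Y)),
    class = "sample_cov")
}

#' @export
print.sample_cov <- function(x, ...) {
  cat(sprintf("<sample_cov> n = %d samples, m = %d genes, tr(C) = %.4g\n",
              x$n, x$m, x$trace))
  cat(sprintf("  leading eigenvalues: %s\n",
              paste(signif(utils::head(x$eigenvalues, 5), 4), collapse = ", ")))
  invisible(x)
}

as_sample_cov <- function(C) {
  if (inherits(C, "sample_cov")) return(C)
  C <- as.matrix(C)
  stopifnot(nrow(C) == ncol(C))
  C <- (C + t(C)) / 2
  eig <- eigen(C, symmetric = TRUE)
  structure(
    list(values = C, trace = sum(diag(C)), eigenvalues = pmax(eig$values, 0),
         eigenvectors = fix_signs(eig$vectors), n = nrow(C), m = NA_integer_,
         singular = NA, sample_ids = rownames(C)),
    class = "sample_cov")
}

# Sign convention: in each column, the entry of largest absolute value is made
# positive, so eigenvectors/factors are reproducible across platforms.
fix_signs <- function(V) {
  if (length(V) == 0L || ncol(V) == 0L) return(V)
  s <- apply(V, 2, function(v) {
    piv <- v[which.max(abs(v))]
    if (piv < 0) -1 else 1
  })
  sweep(V, 2, s, `*`)
}

#' Variance components of the random-effects model
#'
#' Container for the covariance parameters of the joint normal prior on the
#' known-covariate effects and latent-factor effects: B (d x d, known-known),
#' D (d x p, known-latent), A (p x p diagonal, latent-latent) and the residual
#' variance sigma2.
#'
#' @param B d x d symmetric matrix (d may be 0).
#' @param D d x p matrix.
#' @param A p x p diagonal matrix, or a length-p vector of its diagonal.
#' @param sigma2 positive residual variance.
#' @return object of class `variance_components`.
#' @export
variance_components <- function(B, D, A, sigma2) {
  B <- as.matrix(B)
  if (length(B) == 0L) B <- matrix(0, 0, 0)
  if (is.vector(A) || is.null(dim(A))) A <- diag(as.numeric(A), nrow = length(A))
  A <- as.matrix(A)
  if (length(A) == 0L) A <- matrix(0, 0, 0)
  d <- nrow(B); p <- nrow(A)
  D <- matrix(as.numeric(D), nrow = d, ncol = p)
  stopifnot(ncol(B) == d, ncol(A) == p)
  if (!isTRUE(all.equal(B, t(B), tolerance = 1e-8))) {
    stop("B must be symmetric", call. = FALSE)
  }
  if (p > 0 && max(abs(A - diag(diag(A), p))) > 1e-8 * max(1, max(abs(A)))) {
    stop("A must be diagonal (latent factors carry rotational symmetry)",
         call. = FALSE)
  }
  if (!is.numeric(sigma2) || length(sigma2) != 1L || sigma2 <= 0) {
    stop("sigma2 must be a positive scalar", call. = FALSE)
  }
  structure(list(B = B, D = D, A = A, sigma2 = sigma2, d = d, p = p),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("<variance_components> d = %d known, p = %d latent, sigma2 = %.4g\n",
              x$d, x$p, x$sigma2))
  if (x$p > 0) cat("  diag(A):", paste(signif(diag(x$A), 4), collapse = ", "), "\n")
  if (x$d > 0) cat("  diag(B):", paste(signif(diag(x$B), 4), collapse = ", "), "\n")
  invisible(x)
}

#' Assemble the model covariance matrix K
#'
#' Builds K = Z B Z' + Z D X' + X D' Z' + X A X' + sigma2 * I from the design
#' matrices and variance components. The result is symmetrized to machine
#' precision.
#'
#' @param Z n x d known-covariate matrix (may have 0 columns).
#' @param X n x p latent-factor matrix (may have 0 columns).
#' @param vc a [variance_components()] object with conformable B, D, A.
#' @return n x n symmetric matrix.
#' @export
build_K <- function(Z, X, vc) {
  Z <- as_design(Z); X <- as_design(X)
  n <- if (nrow(Z) > 0) nrow(Z) else nrow(X)
  if (nrow(Z) == 0L) Z <- matrix(0, n, 0)
  if (nrow(X) == 0L) X <- matrix(0, n, 0)
  stopifnot(nrow(Z) == nrow(X))
  if (ncol(Z) != vc$d || ncol(X) != vc$p) {
    stop(sprintf("dimension mismatch: Z has %d columns but B is %d x %d; X has %d columns but A is %d x %d",
                 ncol(Z), vc$d, vc$d, ncol(X), vc$p, vc$p), call. = FALSE)
  }
  K <- diag(vc$sigma2, n)
  if (vc$d > 0) K <- K + Z %*% vc$B %*% t(Z)
  if (vc$d > 0 && vc$p > 0) {
    ZD <- Z %*% vc$D
    K <- K + tcrossprod(ZD, X) + tcrossprod(X, ZD)
  }
  if (vc$p > 0) K <- K + X %*% vc$A %*% t(X)
  (K + t(K)) / 2
}

as_design <- function(M) {
  if (is.null(M)) return(matrix(0, 0, 0))
  if (is.data.frame(M)) M <- as_expression_matrix(M)
  M <- as.matrix(M)
  if (length(M) == 0L && ncol(M) != 0L) M <- matrix(0, nrow(M), 0)
  storage.mode(M) <- "double"
  M
}

#' Model log-likelihood
#'
#' Evaluates L = -log det(K) - tr(K^-1 C) through the symmetric
#' eigendecomposition of K (no explicit inverse is ever formed). Additive
#' constants are omitted, so only differences between likelihood values are
#' meaningful.
#'
#' @param K n x n positive-definite model covariance.
#' @param C sample covariance: a [sample_covariance()] object or an n x n matrix.
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(K, C) {
  C <- as_sample_cov(C)
  K <- (as.matrix(K) + t(as.matrix(K))) / 2
  stopifnot(nrow(K) == C$n)
  eK <- eigen(K, symmetric = TRUE)
  lam <- eK$values
  if (min(lam) <= 1e-12 * max(lam)) {
    stop(sprintf("K is not positive definite: eigenvalue %d is %.3e (largest %.3e)",
                 which.min(lam), min(lam), max(lam)), call. = FALSE)
  }
  # tr(K^-1 C) = sum_i u_i' C u_i / lam_i
  M <- crossprod(eK$vectors, C$values %*% eK$vectors)
  -sum(log(lam)) - sum(diag(M) / lam)
}

#' Cosine similarity between two sample-space vectors
#'
#' Normalized inner product u'v / (||u|| ||v||); zero means the two directions
#' are orthogonal (non-redundant factors).
#'
#' @param u,v nonzero numeric vectors of equal length.
#' @return scalar in \[-1, 1\].
#' @export
cosine_similarity <- function(u, v) {
  u <- as.numeric(u); v <- as.numeric(v)
  stopifnot(length(u) == length(v))
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine similarity undefined for a zero vector", call. = FALSE)
  max(-1, min(1, sum(u * v) / (nu * nv)))
}
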