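# Orthogonal decomposition of sample space with respect to the known
# covariates: span(Z) and its orthogonal complement, with projectors P1, P2.

#' Split sample space into span(Z) and its orthogonal complement
#'
#' Computes, from the SVD of the known-covariate matrix Z, an orthonormal
#' basis Q1 of span(Z) (dropping singular values below `tol * s_max`, so
#' duplicated or near-collinear covariates do not inflate the rank), an
#' orthonormal basis Q2 of the orthogonal complement, and the corresponding
#' projectors P1 = Q1 Q1' and P2 = Q2 Q2' = I - P1. With no covariates
#' (d = 0), Q1 is empty and P2 = I.
#'
#' @param Z n x d covariate matrix or data frame (d may be 0), or NULL.
#' @param n number of samples; required when `Z` is NULL or has 0 columns.
#' @param tol relative singular-value tolerance for the rank of Z.
#' @return object of class `subspace_split`: list with `Q1`, `Q2`, `P1`,
#'   `P2`, `r` (effective rank), `singular_values`, `V` (right singular
#'   vectors of the retained directions), `d`, `n`, `covariate_ids`.
#' @export
subspace_split <- function(Z, n = NULL, tol = 1e-10) {
  Z <- as_design(Z)
  if (ncol(Z) == 0L || nrow(Z) == 0L) {
    if (is.null(n)) n <- nrow(Z)
    if (n < 1) stop("need n >= 1 samples", call. = FALSE)
    return(structure(list(
      Q1 = matrix(0, n, 0), Q2 = diag(n), P1 = matrix(0, n, n), P2 = diag(n),
      r = 0L, singular_values = numeric(0), V = matrix(0, 0, 0),
      d = 0L, n = n, covariate_ids = character(0)), class = "subspace_split"))
  }
  n <- nrow(Z)
  ids <- colnames(Z)
  if (is.null(ids)) ids <- paste0("covariate_", seq_len(ncol(Z)))
  sv <- svd(Z)
  r <- sum(sv$d > tol * sv$d[1])
  if (r == 0L) {
    return(subspace_split(NULL, n = n, tol = tol))
  }
  Q1 <- fix_signs(sv$u[, seq_len(r), drop = FALSE])
  # complete Q1 to a full orthonormal basis; trailing columns span the complement
  Qfull <- qr.Q(qr(Q1), complete = TRUE)
  Q2 <- Qfull[, seq.int(r + 1L, length.out = n - r), drop = FALSE]
  structure(list(
    Q1 = Q1, Q2 = Q2, P1 = tcrossprod(Q1), P2 = tcrossprod(Q2),
    r = as.integer(r), singular_values = sv$d[seq_len(r)],
    V = sv$v[, seq_len(r), drop = FALSE] * rep(attr_sign(sv$u, r), each = ncol(Z)),
    d = ncol(Z), n = n, covariate_ids = ids), class = "subspace_split")
}

# signs applied to the first r left singular vectors by fix_signs; the right
# singular vectors must flip in step so that Z = U S V' still holds
attr_sign <- function(U, r) {
  vapply(seq_len(r), function(j) {
    v <- U[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
}

#' @export
print.subspace_split <- function(x, ...) {
  cat(sprintf("<subspace_split> n = %d, d = %d covariates, effective rank r = %d\n",
              x$n, x$d, x$r))
  invisible(x)
}
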