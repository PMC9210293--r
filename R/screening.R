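# Known-covariate preprocessing: genotype principal components and
# single-covariate variance screening against the threshold theta.

#' L2-normalized principal components of a genotype matrix
#'
#' Centers each sample (row) of the genotype matrix to mean zero and returns
#' the first k left-singular vectors as unit-norm candidate covariates,
#' together with the fraction of genotype variance each explains
#' (squared singular value over the total).
#'
#' @param G n x s numeric genotype matrix or data frame (samples in rows;
#'   values e.g. minor-allele counts).
#' @param k number of principal components, k <= min(n, s).
#' @return list with `pcs` (n x k orthonormal matrix, columns `PC1..PCk`) and
#'   `var_explained` (tibble with `pc`, `fraction`).
#' @export
genotype_pcs <- function(G, k) {
  G <- as_expression_matrix(G)
  k <- as.integer(k)
  if (k < 1 || k > min(dim(G))) {
    stop(sprintf("k must lie in [1, min(n, s)] = [1, %d]", min(dim(G))), call. = FALSE)
  }
  Gc <- G - rowMeans(G)
  sv <- svd(Gc, nu = k, nv = 0)
  if (sv$d[1] <= 0) stop("constant genotype matrix: no variation to decompose", call. = FALSE)
  pcs <- fix_signs(sv$u)
  rownames(pcs) <- rownames(G)
  colnames(pcs) <- paste0("PC", seq_len(k))
  frac <- sv$d^2 / sum(sv$d^2)
  list(pcs = pcs,
       var_explained = tibble::tibble(pc = colnames(pcs), fraction = frac[seq_len(k)]))
}

#' Variance explained by a single covariate
#'
#' Closed-form maximizer of the model log-likelihood with a single known
#' covariate, K = beta2 z z' + sigma2 I: sigma2 = (tr(C) - z'Cz) / (n - 1)
#' and beta2 = z'Cz - sigma2, clipped at zero. A clipped estimate means the
#' covariate explains less variance than the residual, i.e. the existence
#' condition fails for it.
#'
#' @param C a [sample_covariance()] object or n x n matrix.
#' @param z unit-norm covariate vector of length n.
#' @return list with `beta2`, `sigma2`, and logical `clipped`.
#' @export
single_covariate_variance <- function(C, z) {
  C <- as_sample_cov(C)
  z <- as.numeric(z)
  stopifnot(length(z) == C$n)
  nz <- sqrt(sum(z^2))
  if (nz == 0) stop("covariate has zero norm", call. = FALSE)
  if (abs(nz - 1) > 1e-8) z <- z / nz
  zCz <- drop(crossprod(z, C$values %*% z))
  sigma2 <- (C$trace - zCz) / (C$n - 1)
  beta2 <- zCz - sigma2
  clipped <- beta2 < 0
  list(beta2 = max(beta2, 0), sigma2 = sigma2, clipped = clipped)
}

#' Screen candidate covariates by variance explained
#'
#' Fits the single-covariate model to every candidate independently and
#' retains those explaining at least the fraction `theta` of the total
#' variance tr(C); candidate order is preserved. Screening is intended for
#' linearly independent candidates such as genotype principal components;
#' raw SNPs are accepted but a collinearity warning is emitted, since
#' one-at-a-time screening cannot detect joint redundancy.
#'
#' @param C a [sample_covariance()] object or n x n matrix.
#' @param Z_candidates n x q matrix or data frame of candidate covariates
#'   (columns normalized internally if needed).
#' @param theta minimum fraction of tr(C) a covariate must explain on its
#'   own, 0 < theta < 1.
#' @param raw_snps set TRUE when candidates are raw genotype markers rather
#'   than principal components.
#' @return list with `selected` (n x q' matrix of retained, unit-norm
#'   candidates) and `report` (tibble of class `screening_report`: columns
#'   `covariate`, `beta2`, `fraction`, `selected`, plus attribute `theta`).
#' @export
screen_covariates <- function(C, Z_candidates, theta, raw_snps = FALSE) {
  C <- as_sample_cov(C)
  Z <- as_design(Z_candidates)
  stopifnot(nrow(Z) == C$n)
  if (!is.numeric(theta) || theta <= 0 || theta >= 1) {
    stop("theta must lie strictly between 0 and 1 (fraction of tr(C))", call. = FALSE)
  }
  if (raw_snps) {
    warning("screening raw markers one at a time cannot detect collinearity; ",
            "consider genotype principal components instead", call. = FALSE)
  }
  ids <- colnames(Z)
  if (is.null(ids)) ids <- paste0("covariate_", seq_len(ncol(Z)))
  norms <- sqrt(colSums(Z^2))
  if (any(norms == 0)) stop("candidate covariate with zero norm", call. = FALSE)
  Zn <- sweep(Z, 2, norms, `/`)
  res <- lapply(seq_len(ncol(Zn)), function(j) single_covariate_variance(C, Zn[, j]))
  beta2 <- vapply(res, `[[`, numeric(1), "beta2")
  report <- tibble::tibble(
    covariate = ids, beta2 = beta2, fraction = beta2 / C$trace,
    selected = beta2 >= theta * C$trace)
  attr(report, "theta") <- theta
  class(report) <- c("screening_report", class(report))
  selected <- Zn[, report$selected, drop = FALSE]
  colnames(selected) <- ids[report$selected]
  list(selected = selected, report = report)
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("<screening_report> theta = %.3g; %d of %d candidates selected\n",
              attr(x, "theta"), sum(x$selected), nrow(x)))
  NextMethod()
}
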