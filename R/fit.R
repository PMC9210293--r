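# Top-level fitting interface: center -> sample covariance -> subspace split
# -> choose p -> existence enforcement -> restricted PPCA -> closed-form
# variance components.

#' Fit the latent variance-component model by analytic REML
#'
#' Estimates latent factors orthogonal to the known covariates by
#' probabilistic PCA on the orthogonal complement of span(Z), then the
#' variance components B, D, A and residual variance sigma2 in closed form.
#' The number of latent factors is chosen as the smallest p reaching the
#' target explained-variance fraction `rho`, and raised further if needed so
#' the analytic maximizer exists (in which case the achieved fraction exceeds
#' `rho` and a warning is emitted); alternatively a fixed `p` can be given.
#'
#' @param Y n x m expression matrix or data frame (samples in rows). Rows are
#'   centered to mean zero automatically (with a message if they were not).
#' @param Z n x d known-covariate matrix or data frame, or NULL for none.
#' @param rho target fraction of variance in Y explained by known plus latent
#'   components, 0 < rho < 1. Ignored when `p` is supplied.
#' @param p optional fixed number of latent factors; the existence condition
#'   is then checked but p is not raised.
#' @return an object of class `reml_fit`: list with `latent` (n x p), the
#'   `components` ([variance_components()]), `K_hat`, `loglik`,
#'   `loglik_terms` (L1, L2), `variance_ledger` (tibble summing to tr(C)),
#'   `p`, `p_selected`, `existence_raised`, `rho`, `rho_achieved`, `sigma2`,
#'   `rank_Z`, `n`, `m`, `d`.
#' @examples
#' sim <- simulate_expression(simulation_spec(n = 30, m = 400, d = 1, p = 2,
#'   B = 4, A = c(3, 2), sigma2 = 1, seed = 1))
#' fit <- reml_fit(sim$Y, sim$Z, rho = 0.5)
#' glance(fit)
#' @export
reml_fit <- function(Y, Z = NULL, rho = 0.5, p = NULL) {
  Y <- as_expression_matrix(Y)
  if (!is_row_centered(Y)) {
    message("centering Y so that each sample has mean zero")
    Y <- center_samples(Y)
  }
  C <- sample_covariance(Y)
  n <- C$n
  Z <- as_design(Z)
  if (length(Z) > 0L || ncol(Z) > 0L) stopifnot(nrow(Z) == n)
  split <- subspace_split(Z, n = n)
  if (split$r >= n) {
    stop("known covariates alone span the sample space: n linearly independent ",
         "covariates always explain all of the variation in Y; raise the ",
         "screening threshold", call. = FALSE)
  }
  if (is.null(p)) {
    p_sel <- select_p(C, split, rho)
    p_fit <- enforce_existence(C, split, p_sel)
    raised <- p_fit > p_sel
    if (raised) {
      warning(sprintf(paste0(
        "existence condition raised the number of latent factors from %d to %d; ",
        "total variance explained will exceed the target rho = %.3g ",
        "(noninformative or redundant known covariates?)"), p_sel, p_fit, rho),
        call. = FALSE)
    }
  } else {
    p_sel <- p_fit <- as.integer(p)
    raised <- FALSE
    if (p_fit < 0 || p_fit > n - split$r - 1L) {
      stop(sprintf("p must lie in [0, n - r - 1] = [0, %d]", n - split$r - 1L), call. = FALSE)
    }
  }
  rp <- restricted_ppca(C, split, p_fit)
  est <- estimate_variance_components(C, split, rp$latent)
  ll <- log_likelihood(est$K_hat, C)
  terms <- loglik_terms(C, split, est, p_fit)

  lam2 <- rp$spectrum2
  known_var <- if (split$r > 0) {
    diag(crossprod(split$Q1, C$values %*% split$Q1))
  } else numeric(0)
  latent_var <- lam2[seq_len(p_fit)]
  resid_var <- C$trace - sum(known_var) - sum(latent_var)
  ledger <- tibble::tibble(
    term = c(if (split$r > 0) paste0("covariate_axis_", seq_len(split$r)),
             if (p_fit > 0) paste0("latent_", seq_len(p_fit)),
             "residual"),
    component = c(rep("known", split$r), rep("latent", p_fit), "residual"),
    variance = c(known_var, latent_var, resid_var))
  ledger$fraction <- ledger$variance / C$trace
  rho_achieved <- 1 - resid_var / C$trace

  latent <- rp$latent
  if (p_fit > 0) {
    colnames(latent) <- paste0("latent_", seq_len(p_fit))
    rownames(latent) <- C$sample_ids
  }
  structure(list(
    latent = latent, components = est$components, K_hat = est$K_hat,
    loglik = ll, loglik_terms = terms, variance_ledger = ledger,
    p = p_fit, p_selected = p_sel, existence_raised = raised,
    rho = if (is.null(p)) rho else NA_real_, rho_achieved = rho_achieved,
    sigma2 = est$sigma2, rank_Z = split$r, split = split, C = C,
    n = n, m = C$m, d = split$d, call = match.call()), class = "reml_fit")
}

# L2 is the PPCA log-likelihood on the orthogonal complement of span(Z);
# L1 is the remainder, covering the known-covariate subspace and its
# interaction with the latent factors.
loglik_terms <- function(C, split, est, p) {
  lam2 <- complement_spectrum(C, split)$values
  nr <- C$n - split$r
  if (nr == 0L) return(c(L1 = log_likelihood(est$K_hat, C), L2 = 0))
  s2 <- est$sigma2
  kept <- lam2[seq_len(p)]
  excl <- lam2[seq.int(p + 1L, length.out = nr - p)]
  L2 <- -(sum(log(kept)) + (nr - p) * log(s2)) - (p + sum(excl) / s2)
  L1 <- log_likelihood(est$K_hat, C) - L2
  c(L1 = L1, L2 = L2)
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf("<reml_fit> n = %d samples, m = %s genes, d = %d covariates (rank %d)\n",
              x$n, ifelse(is.na(x$m), "?", x$m), x$d, x$rank_Z))
  cat(sprintf("  latent factors p = %d%s, sigma2 = %.4g\n", x$p,
              if (x$existence_raised) sprintf(" (raised from %d by the existence condition)", x$p_selected) else "",
              x$sigma2))
  cat(sprintf("  log-likelihood = %.6g (L1 = %.6g, L2 = %.6g)\n",
              x$loglik, x$loglik_terms[["L1"]], x$loglik_terms[["L2"]]))
  cat(sprintf("  variance explained: %.1f%% (target %s)\n", 100 * x$rho_achieved,
              ifelse(is.na(x$rho), "fixed p", sprintf("%.1f%%", 100 * x$rho))))
  invisible(x)
}

#' Log-likelihood profile over the number of latent factors
#'
#' Fits the model for each value of `p` and returns the log-likelihood curve,
#' the tool behind shift-identity diagnostics: with the top d expression PCs
#' supplied as known covariates, the curve coincides with the zero-covariate
#' curve shifted horizontally by d factors.
#'
#' @inheritParams reml_fit
#' @param p_values integer vector of latent-factor counts to profile.
#' @return tibble with columns `p`, `loglik`, `L1`, `L2`, `sigma2`,
#'   `rho_achieved`.
#' @export
loglik_profile <- function(Y, Z = NULL, p_values) {
  Y <- as_expression_matrix(Y)
  if (!is_row_centered(Y)) Y <- center_samples(Y)
  C <- sample_covariance(Y)
  split <- subspace_split(Z, n = C$n)
  rows <- lapply(as.integer(p_values), function(p) {
    rp <- restricted_ppca(C, split, p)
    est <- estimate_variance_components(C, split, rp$latent)
    terms <- loglik_terms(C, split, est, p)
    resid <- (C$n - split$r - p) * est$sigma2
    tibble::tibble(p = p, loglik = log_likelihood(est$K_hat, C),
                   L1 = terms[["L1"]], L2 = terms[["L2"]],
                   sigma2 = est$sigma2, rho_achieved = 1 - resid / C$trace)
  })
  dplyr::bind_rows(rows)
}
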