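# broom-style tidiers and ggplot2 autoplot methods.

#' Tidy a fitted latent variance-component model
#'
#' Returns the variance ledger: one row per known-covariate principal axis,
#' per latent factor, and the residual, with the variance attributed to each
#' and its fraction of tr(C). The rows sum to the total variance tr(C).
#'
#' @param x a `reml_fit` object.
#' @param ... unused.
#' @return tibble with columns `term`, `component`, `variance`, `fraction`.
#' @export
tidy.reml_fit <- function(x, ...) {
  x$variance_ledger
}

#' One-row summary of a fitted latent variance-component model
#'
#' @param x a `reml_fit` object.
#' @param ... unused.
#' @return one-row tibble: `n`, `m`, `d`, `rank_Z`, `p`, `sigma2`, `loglik`,
#'   `L1`, `L2`, `rho`, `rho_achieved`, `existence_raised`.
#' @export
glance.reml_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, m = x$m, d = x$d, rank_Z = x$rank_Z, p = x$p,
    sigma2 = x$sigma2, loglik = x$loglik,
    L1 = x$loglik_terms[["L1"]], L2 = x$loglik_terms[["L2"]],
    rho = x$rho, rho_achieved = x$rho_achieved,
    existence_raised = x$existence_raised)
}

#' Plot the variance ledger of a fitted model
#'
#' Bar chart of the fraction of total variance attributed to each known
#' covariate axis, each latent factor, and the residual.
#'
#' @param object a `reml_fit` object.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.reml_fit <- function(object, ...) {
  led <- object$variance_ledger
  led$term <- factor(led$term, levels = led$term)
  ggplot2::ggplot(led, ggplot2::aes(x = .data$term, y = .data$fraction,
                                    fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "fraction of tr(C)",
                  title = sprintf("Variance decomposition (p = %d, sigma2 = %.3g)",
                                  object$p, object$sigma2)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a covariate screening report
#'
#' Variance fraction explained by each candidate covariate, with the
#' selection threshold theta drawn as a horizontal line.
#'
#' @param object a `screening_report` tibble from [screen_covariates()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.screening_report <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$covariate <- factor(df$covariate, levels = df$covariate)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$covariate, y = .data$fraction,
                                   fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = attr(object, "theta"), linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "fraction of tr(C) explained",
                  title = "Single-covariate variance screening") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot log-likelihood profiles over the number of latent factors
#'
#' Draws one or more profiles from [loglik_profile()]; supply a named list to
#' compare covariate sets (e.g. none vs top expression PCs), which makes the
#' horizontal shift between curves visible.
#'
#' @param profiles a tibble from [loglik_profile()], or a named list of them.
#' @return a ggplot object.
#' @export
plot_loglik_profiles <- function(profiles) {
  if (is.data.frame(profiles)) profiles <- list(profile = profiles)
  df <- dplyr::bind_rows(profiles, .id = "covariates")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$p, y = .data$loglik,
                                   colour = .data$covariates)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "number of latent factors p", y = "log-likelihood") +
    ggplot2::theme_minimal()
}
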