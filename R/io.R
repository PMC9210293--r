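# Labeled delimited-matrix IO and the end-to-end run driver.

#' Read a labeled delimited matrix
#'
#' Reads a rectangular numeric matrix from a delimited text file whose first
#' row holds column labels and first column holds row labels. By default
#' samples are expected in rows (Y is n x m); set `genes_in_rows = TRUE` to
#' transpose on read for files shipped genes-by-samples.
#'
#' @param path file path.
#' @param genes_in_rows transpose after reading.
#' @param delimiter field delimiter; `"\t"` (default) or `","`.
#' @return numeric matrix with row and column names.
#' @export
read_matrix <- function(path, genes_in_rows = FALSE, delimiter = "\t") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = delimiter, check.names = FALSE,
                          row.names = NULL, colClasses = "character",
                          comment.char = "", quote = "\"")
  if (ncol(df) < 2L) stop(sprintf("%s: expected row labels plus at least one data column", path), call. = FALSE)
  rlab <- df[[1]]
  clab <- colnames(df)[-1]
  if (anyDuplicated(rlab)) {
    stop(sprintf("%s: duplicate row label '%s'", path, rlab[duplicated(rlab)][1]), call. = FALSE)
  }
  if (anyDuplicated(clab)) {
    stop(sprintf("%s: duplicate column label '%s'", path, clab[duplicated(clab)][1]), call. = FALSE)
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("%s: non-numeric cell '%s' at row '%s', column '%s'",
                 path, vals[bad[1, 1], bad[1, 2]], rlab[bad[1, 1]], clab[bad[1, 2]]),
         call. = FALSE)
  }
  if (anyNA(num) || any(!is.finite(num))) {
    bad <- which(is.na(num) | !is.finite(num), arr.ind = TRUE)
    stop(sprintf("%s: missing or non-finite value at row '%s', column '%s'",
                 path, rlab[bad[1, 1]], clab[bad[1, 2]]), call. = FALSE)
  }
  dimnames(num) <- list(rlab, clab)
  if (genes_in_rows) num <- t(num)
  num
}

#' Write a labeled delimited matrix
#'
#' Inverse of [read_matrix()]: writes the matrix at full precision with row
#' labels in the first column (header `id`).
#'
#' @param x numeric matrix with dimnames.
#' @param path output file path.
#' @param delimiter field delimiter.
#' @export
write_matrix <- function(x, path, delimiter = "\t") {
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- paste0("row_", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("col_", seq_len(ncol(x)))
  df <- data.frame(id = rownames(x),
                   format(x, digits = 17, trim = TRUE, scientific = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = delimiter, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble a run configuration
#'
#' @param expression path to the expression matrix (samples x genes unless
#'   `genes_in_rows`).
#' @param covariates optional path to the known-covariate matrix.
#' @param out output directory (created if missing).
#' @param rho target explained-variance fraction in (0, 1).
#' @param theta optional screening threshold in (0, 1); when given, candidate
#'   covariates are screened before fitting.
#' @param genes_in_rows transpose the expression file on read.
#' @param delimiter field delimiter for all files.
#' @param seed integer seed (recorded in the run summary).
#' @return list of class `run_config`.
#' @export
run_config <- function(expression, covariates = NULL, out = ".", rho = 0.5,
                       theta = NULL, genes_in_rows = FALSE, delimiter = "\t",
                       seed = 1L) {
  stopifnot(rho > 0, rho < 1)
  if (!is.null(theta)) stopifnot(theta > 0, theta < 1)
  structure(list(expression = expression, covariates = covariates, out = out,
                 rho = rho, theta = theta, genes_in_rows = genes_in_rows,
                 delimiter = delimiter, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full fitting workflow from files to files
#'
#' Reads the expression and covariate matrices, optionally screens the
#' covariates at threshold `theta`, fits the REML model at target `rho`, and
#' writes all artifacts to the output directory: `latent.tsv`,
#' `B.tsv`/`D.tsv`/`A.tsv`, `variance_ledger.tsv`, optional
#' `screening_report.tsv`, and `summary.json` with the scalar results
#' (sigma2, loglik, L1, L2, p, rho_achieved, rank of Z). Progress and the
#' existence-condition saturation warning, when triggered, go to the message
#' stream.
#'
#' @param config a [run_config()].
#' @return (invisibly) the fitted `reml_fit` object, with exit `status` 0
#'   attribute on success.
#' @export
run_fit <- function(config) {
  stopifnot(inherits(config, "run_config"))
  Y <- read_matrix(config$expression, config$genes_in_rows, config$delimiter)
  Z <- NULL
  screen_report <- NULL
  if (!is.null(config$covariates)) {
    Z <- read_matrix(config$covariates, FALSE, config$delimiter)
    if (nrow(Z) != nrow(Y)) stop("expression and covariate files disagree on samples", call. = FALSE)
  }
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  Yc <- center_samples(Y)
  if (!is.null(Z) && !is.null(config$theta)) {
    C <- sample_covariance(Yc)
    sc <- screen_covariates(C, Z, config$theta)
    screen_report <- sc$report
    message(sprintf("screening: %d of %d covariates retained at theta = %.3g",
                    sum(sc$report$selected), nrow(sc$report), config$theta))
    Z <- sc$selected
    readr::write_tsv(sc$report, file.path(config$out, "screening_report.tsv"))
  }
  fit <- withCallingHandlers(
    reml_fit(Yc, Z, rho = config$rho),
    warning = function(w) {
      message("warning: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  message(sprintf("effective rank of Z: %d; selected p = %d%s; rho achieved = %.4f",
                  fit$rank_Z, fit$p_selected,
                  if (fit$existence_raised) sprintf(" (raised to %d by the existence condition)", fit$p) else "",
                  fit$rho_achieved))
  if (fit$p > 0) write_matrix(fit$latent, file.path(config$out, "latent.tsv"))
  vc <- fit$components
  if (vc$d > 0) {
    dimnames(vc$B) <- list(colnames(Z), colnames(Z))
    write_matrix(vc$B, file.path(config$out, "B.tsv"))
  }
  if (vc$d > 0 && vc$p > 0) {
    dimnames(vc$D) <- list(colnames(Z), colnames(fit$latent))
    write_matrix(vc$D, file.path(config$out, "D.tsv"))
  }
  if (vc$p > 0) {
    A <- vc$A
    dimnames(A) <- list(colnames(fit$latent), colnames(fit$latent))
    write_matrix(A, file.path(config$out, "A.tsv"))
  }
  readr::write_tsv(fit$variance_ledger, file.path(config$out, "variance_ledger.tsv"))
  summary <- list(
    n = fit$n, m = fit$m, d = fit$d, rank_Z = fit$rank_Z,
    p_selected = fit$p_selected, p = fit$p,
    existence_raised = fit$existence_raised,
    rho = fit$rho, rho_achieved = fit$rho_achieved,
    sigma2 = fit$sigma2, loglik = fit$loglik,
    L1 = fit$loglik_terms[["L1"]], L2 = fit$loglik_terms[["L2"]],
    seed = config$seed)
  jsonlite::write_json(summary, file.path(config$out, "summary.json"),
                       auto_unbox = TRUE, digits = 17, pretty = TRUE)
  attr(fit, "status") <- 0L
  attr(fit, "screening_report") <- screen_report
  invisible(fit)
}
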