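#' Pearson correlation matrix of the criterion scores
#'
#' @param score_table Data frame whose numeric columns (by default the three
#'   criterion columns, if present) are correlated pairwise.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pearson_correlation_matrix <- function(score_table) {
  x <- as.data.frame(score_table)
  crit <- intersect(c("persistence", "breakpoint", "punished"), names(x))
  if (length(crit) == 3) x <- x[crit]
  x <- x[vapply(x, is.numeric, logical(1))]
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (nrow(x) < 3) {
    stop("need at least 3 complete rows.", call. = FALSE)
  }
  zero_var <- vapply(x, function(col) stats::sd(col) == 0, logical(1))
  if (any(zero_var)) {
    stop("zero-variance column(s): ",
         paste(names(x)[zero_var], collapse = ", "), call. = FALSE)
  }
  stats::cor(as.matrix(x))
}

#' Single-factor extraction with the eigenvalue-1 retention rule
#'
#' Principal-component extraction on a correlation matrix: loadings of the
#' first component are its eigenvector scaled by the square root of the
#' leading eigenvalue (sign fixed so the loading sum is non-negative), the
#' explained variance fraction is the leading eigenvalue over the trace, and
#' factors are retained when their eigenvalue is at least 1 (ties at exactly
#' 1 retain the factor).
#'
#' @param R Symmetric positive-semidefinite correlation matrix.
#' @return An object of class `factor_solution`: `correlation_matrix`,
#'   `eigenvalues` (descending), `loadings`, `variance_fraction`,
#'   `n_retained`.
#' @export
extract_single_factor <- function(R) {
  R <- validate_corr_matrix(R)
  e <- eigen(R, symmetric = TRUE)
  lambda <- e$values
  v1 <- e$vectors[, 1]
  loadings <- v1 * sqrt(max(lambda[1], 0))
  if (sum(loadings) < 0) loadings <- -loadings
  names(loadings) <- colnames(R) %||% paste0("v", seq_len(ncol(R)))
  structure(
    list(
      correlation_matrix = R,
      eigenvalues = lambda,
      loadings = loadings,
      variance_fraction = lambda[1] / sum(diag(R)),
      n_retained = sum(lambda >= 1 - 1e-12)
    ),
    class = "factor_solution"
  )
}

#' @export
print.factor_solution <- function(x, ...) {
  cat("<factor_solution>\n")
  cat("  eigenvalues:", paste(signif(x$eigenvalues, 4), collapse = ", "),
      "\n")
  cat("  retained (eigenvalue >= 1):", x$n_retained, "\n")
  cat("  first-factor loadings:\n")
  print(round(x$loadings, 3))
  cat("  variance explained:",
      sprintf("%.1f%%", 100 * x$variance_fraction), "\n")
  invisible(x)
}

#' Percent variance explained by a set of component loadings
#'
#' For component-style extraction the variance fraction of a factor equals
#' the mean of its squared loadings, so the percent variance is
#' `100 * mean(loadings^2)`.
#'
#' @param loadings Numeric vector of loadings in `[-1, 1]`.
#' @param digits Optional rounding of the returned percentage.
#' @return Percent variance explained.
#' @export
variance_from_loadings <- function(loadings, digits = NULL) {
  if (any(abs(loadings) > 1 + 1e-9)) {
    stop("loadings must lie in [-1, 1].", call. = FALSE)
  }
  out <- 100 * mean(loadings^2)
  if (!is.null(digits)) out <- round(out, digits)
  out
}
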