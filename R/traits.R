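criterion_names <- c("persistence", "breakpoint", "punished")

#' Inter-criterion correlation matrix implied by score-criterion correlations
#'
#' The addiction score is the sum of the three standardized criterion scores.
#' For standardized criteria with correlation matrix R, the correlation of the
#' sum with criterion j is (row sum of R)_j / sqrt(1'R1). Given the three
#' score-criterion correlations this relation inverts in closed form: the sum
#' of the three correlations equals sqrt(1'R1), which yields the row sums and
#' thence the off-diagonal entries by a linear solve.
#'
#' @param score_criterion_corrs Numeric length 3, each in (0, 1]: correlation
#'   of the composite score with persistence, breakpoint, and punished
#'   responding, in that order.
#' @return A 3x3 symmetric correlation matrix with unit diagonal.
#' @examples
#' implied_criterion_correlations(c(0.794, 0.818, 0.641))
#' @export
implied_criterion_correlations <- function(score_criterion_corrs) {
  r <- as.numeric(score_criterion_corrs)
  if (length(r) != 3 || anyNA(r) || any(r <= 0) || any(r > 1)) {
    stop("`score_criterion_corrs` must be three values in (0, 1].",
         call. = FALSE)
  }
  tot <- sum(r)^2              # 1'R1
  s <- r * sqrt(tot)           # row sums of R
  a <- s - 1
  off <- c(
    (a[1] + a[2] - a[3]) / 2,  # r12
    (a[1] + a[3] - a[2]) / 2,  # r13
    (a[2] + a[3] - a[1]) / 2   # r23
  )
  if (any(abs(off) > 1)) {
    pair <- c("persistence-breakpoint", "persistence-punished",
              "breakpoint-punished")[which(abs(off) > 1)]
    stop("implied correlation outside [-1, 1] for pair(s): ",
         paste(pair, collapse = ", "), call. = FALSE)
  }
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- off[1]
  R[1, 3] <- R[3, 1] <- off[2]
  R[2, 3] <- R[3, 2] <- off[3]
  dimnames(R) <- list(criterion_names, criterion_names)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    stop("implied correlation matrix is not positive semidefinite ",
         "(smallest eigenvalue ", signif(min(ev), 3), ")", call. = FALSE)
  }
  R
}

#' Correlations of the z-sum composite with its component criteria
#'
#' Forward companion of [implied_criterion_correlations()]: given the
#' inter-criterion correlation matrix, return the correlation of the summed
#' standardized score with each criterion.
#'
#' @param R 3x3 correlation matrix.
#' @return Numeric length 3.
#' @export
score_criterion_correlations <- function(R) {
  R <- validate_corr_matrix(R)
  rowSums(R) / sqrt(sum(R))
}

validate_corr_matrix <- function(R, tol = 1e-8) {
  R <- as.matrix(R)
  if (nrow(R) != ncol(R) || max(abs(R - t(R))) > tol ||
      max(abs(diag(R) - 1)) > tol) {
    stop("`R` must be a symmetric correlation matrix with unit diagonal.",
         call. = FALSE)
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol) {
    stop("`R` is not positive semidefinite.", call. = FALSE)
  }
  R
}

#' Cohort-level generator configuration
#'
#' Defines the generative model for per-rat criterion scores: one latent
#' standard-normal addiction liability per rat, loading on all three criteria,
#' plus an anxiety trait correlated with liability. Counts are negative
#' binomial on the margins (means and SDs on the count scale), coupled through
#' a Gaussian copula whose single-factor loadings are, by default, calibrated
#' so the count-scale inter-criterion correlations match the matrix implied by
#' the published score-criterion correlations (0.794, 0.818, 0.641).
#'
#' Default marginal means and SDs are the cohort-level values reconstructed
#' from the published per-group means/SEs and group sizes (25/14/13/7 of 59).
#'
#' @param n_rats Cohort size (>= 4; default 59).
#' @param factor_loadings Optional numeric length 3 in `[0, 1]`: latent-factor
#'   loadings on the Gaussian scale. When `NULL` they are calibrated from
#'   `target_score_corrs` via [calibrate_factor_loadings()].
#' @param target_score_corrs Score-criterion correlations used to calibrate
#'   default loadings.
#' @param criterion_means,criterion_dispersions Count-scale marginal means and
#'   SDs (presses / breakpoint requirement units) for persistence, breakpoint,
#'   punished responding. SD^2 must exceed the mean (overdispersed counts).
#' @param anxiety_liability_corr Correlation between the liability and anxiety
#'   latent traits, in `[-1, 1]`. Positive values make vulnerable rats more
#'   anxious.
#' @param seed Integer root seed; all per-stage streams derive from it.
#' @return An object of class `trait_config`.
#' @export
trait_config <- function(n_rats = 59,
                         factor_loadings = NULL,
                         target_score_corrs = c(0.794, 0.818, 0.641),
                         criterion_means = c(8.38, 34.02, 12.41),
                         criterion_dispersions = c(5.30, 14.49, 9.26),
                         anxiety_liability_corr = 0.7,
                         seed = 20170825) {
  if (length(n_rats) != 1 || n_rats < 4 || n_rats %% 1 != 0) {
    stop("`n_rats` must be a single integer >= 4 ",
         "(screening needs a distribution).", call. = FALSE)
  }
  if (length(criterion_means) != 3 || any(criterion_means <= 0)) {
    stop("`criterion_means` must be three positive values.", call. = FALSE)
  }
  if (length(criterion_dispersions) != 3 || any(criterion_dispersions <= 0)) {
    stop("`criterion_dispersions` must be three positive values.",
         call. = FALSE)
  }
  if (any(criterion_dispersions^2 <= criterion_means)) {
    stop("count marginals must be overdispersed: each SD^2 must exceed ",
         "the corresponding mean.", call. = FALSE)
  }
  if (abs(anxiety_liability_corr) > 1) {
    stop("`anxiety_liability_corr` must lie in [-1, 1].", call. = FALSE)
  }
  if (is.null(factor_loadings)) {
    target_R <- implied_criterion_correlations(target_score_corrs)
    factor_loadings <- calibrate_factor_loadings(
      target_R, criterion_means, criterion_dispersions
    )
  } else {
    if (length(factor_loadings) != 3 ||
        any(factor_loadings < 0) || any(factor_loadings > 1)) {
      stop("`factor_loadings` must be three values in [0, 1].", call. = FALSE)
    }
    # single-factor structure is PSD by construction; nothing more to check
  }
  structure(
    list(
      n_rats = as.integer(n_rats),
      factor_loadings = as.numeric(unname(unlist(factor_loadings))),
      criterion_means = as.numeric(unlist(criterion_means)),
      criterion_dispersions = as.numeric(unlist(criterion_dispersions)),
      anxiety_liability_corr = as.numeric(anxiety_liability_corr),
      seed = as.integer(seed)
    ),
    class = "trait_config"
  )
}

#' @export
print.trait_config <- function(x, ...) {
  cat("<trait_config>\n")
  cat("  n_rats:", x$n_rats, " seed:", x$seed, "\n")
  cat("  latent loadings:", paste(signif(x$factor_loadings, 3),
                                  collapse = ", "), "\n")
  cat("  count means:", paste(signif(x$criterion_means, 4), collapse = ", "),
      "\n")
  cat("  count SDs:  ", paste(signif(x$criterion_dispersions, 4),
                              collapse = ", "), "\n")
  cat("  corr(liability, anxiety):", x$anxiety_liability_corr, "\n")
  invisible(x)
}

#' Draw per-rat latent traits
#'
#' Samples the generative ground truth: a standard-normal addiction liability
#' and a standard-normal anxiety trait with the configured correlation.
#'
#' @param config A [trait_config()].
#' @param seed Optional integer overriding the derived per-stage seed.
#' @return A tibble with columns `rat_id`, `liability`, `anxiety`.
#' @export
sample_latent_traits <- function(config, seed = NULL) {
  stopifnot(inherits(config, "trait_config"))
  rho <- config$anxiety_liability_corr
  n <- config$n_rats
  seed <- seed %||% derive_seed(config$seed, "traits")
  withr::with_seed(seed, {
    liability <- rnorm(n)
    anxiety <- rho * liability + sqrt(1 - rho^2) * rnorm(n)
  })
  tibble::tibble(
    rat_id = sprintf("rat%03d", seq_len(n)),
    liability = liability,
    anxiety = anxiety
  )
}
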