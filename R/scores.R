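# Marginal quantile transforms for the three criteria. Breakpoints are snapped
# to the progressive-ratio grid so every generated score is a value a PR
# session can actually end on.
criterion_quantile_funs <- function(means, sds) {
  # Snapping a breakpoint draw down to the PR requirement grid removes, on
  # average, half the log-scale grid step of 0.2; the pre-snap negative
  # binomial is inflated by exp(0.1) so post-snap moments match the
  # configured marginal.
  m <- means; s <- sds
  m[2] <- m[2] * exp(0.1)
  s[2] <- s[2] * exp(0.1)
  sizes <- m^2 / (s^2 - m)  # NB size from mean/SD
  # clamp away from 0/1 so extreme-tail evaluations stay finite
  cl <- function(p) pmin(pmax(p, 1e-15), 1 - 1e-13)
  list(
    persistence = function(p) stats::qnbinom(cl(p), size = sizes[1],
                                             mu = m[1]),
    breakpoint = function(p) pr_snap(stats::qnbinom(cl(p), size = sizes[2],
                                                    mu = m[2])),
    punished = function(p) stats::qnbinom(cl(p), size = sizes[3],
                                          mu = m[3])
  )
}

#' Calibrate latent-factor loadings to a target count-scale correlation matrix
#'
#' The generator couples negative-binomial criterion counts through a Gaussian
#' copula with a single-factor latent structure. Monotone discretization
#' attenuates Pearson correlations slightly relative to the latent Gaussian
#' correlations, so latent loadings are calibrated numerically: for each
#' criterion pair the latent correlation that induces the target count-scale
#' correlation is found by root solving against a large common-random-numbers
#' evaluation of the copula (a fixed internal seed makes the procedure
#' deterministic and the induced correlation smooth in the latent
#' correlation), and loadings are recovered from the pairwise latent
#' correlations by the usual single-factor triad identity
#' l_j = sqrt(r_jk * r_jl / r_kl). Results are memoized per configuration.
#'
#' @param target_R 3x3 target correlation matrix on the count scale.
#' @param means,sds Count-scale marginal means and SDs.
#' @param n_mc Size of the common-random-numbers sample.
#' @return Numeric length 3 of latent loadings in `[0, 1]`.
#' @export
calibrate_factor_loadings <- function(target_R,
                                      means = c(8.38, 34.02, 12.41),
                                      sds = c(5.30, 14.49, 9.26),
                                      n_mc = 4e5) {
  target_R <- validate_corr_matrix(target_R)
  key <- paste(c(target_R[upper.tri(target_R)], means, sds, n_mc),
               collapse = "|")
  cached <- calibration_cache[[key]]
  if (!is.null(cached)) return(cached)
  qfs <- criterion_quantile_funs(means, sds)
  uw <- withr::with_seed(285713L, {
    list(u = rnorm(n_mc), w = rnorm(n_mc))
  })
  pair_corr <- function(rho, qf1, qf2) {
    x1 <- qf1(pnorm(uw$u))
    x2 <- qf2(pnorm(rho * uw$u + sqrt(1 - rho^2) * uw$w))
    stats::cor(x1, x2)
  }
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  latent <- vapply(pairs, function(jk) {
    target <- target_R[jk[1], jk[2]]
    if (target <= 0) {
      stop("calibration requires positive target correlations; pair (",
           jk[1], ",", jk[2], ") is ", signif(target, 3), call. = FALSE)
    }
    f <- function(rho) {
      pair_corr(rho, qfs[[jk[1]]], qfs[[jk[2]]]) - target
    }
    hi <- 0.9999
    if (f(hi) < 0) {
      stop("target correlation ", signif(target, 3), " for pair (", jk[1],
           ",", jk[2], ") is not attainable with these count marginals.",
           call. = FALSE)
    }
    stats::uniroot(f, c(1e-6, hi), tol = 1e-4)$root
  }, numeric(1))
  l <- c(
    sqrt(latent[1] * latent[2] / latent[3]),
    sqrt(latent[1] * latent[3] / latent[2]),
    sqrt(latent[2] * latent[3] / latent[1])
  )
  if (any(l > 1)) {
    stop("pairwise latent correlations are inconsistent with a single ",
         "factor (a loading would exceed 1).", call. = FALSE)
  }
  names(l) <- criterion_names
  calibration_cache[[key]] <- l
  l
}

calibration_cache <- new.env(parent = emptyenv())

#' Simulate per-rat criterion scores
#'
#' Draws the three screening measures (mean unavailable-period presses, PR
#' breakpoint, mean presses under punishment) as count-valued scores. Each
#' criterion's latent Gaussian score is `l_j * liability + sqrt(1 - l_j^2) *
#' noise`, mapped through its negative-binomial quantile function; breakpoints
#' are additionally snapped to the progressive-ratio requirement grid.
#'
#' @param traits Tibble from [sample_latent_traits()].
#' @param config The [trait_config()] used to draw `traits`.
#' @param seed Optional integer overriding the derived per-stage seed.
#' @return A tibble with columns `rat_id`, `persistence`, `breakpoint`,
#'   `punished`.
#' @export
simulate_criterion_scores <- function(traits, config, seed = NULL) {
  stopifnot(inherits(config, "trait_config"))
  if (!all(c("rat_id", "liability") %in% names(traits))) {
    stop("`traits` must have columns rat_id and liability.", call. = FALSE)
  }
  n <- nrow(traits)
  l <- config$factor_loadings
  qfs <- criterion_quantile_funs(config$criterion_means,
                                 config$criterion_dispersions)
  seed <- seed %||% derive_seed(config$seed, "scores")
  z <- withr::with_seed(seed, {
    eps <- matrix(rnorm(3 * n), nrow = n)
    vapply(1:3, function(j) {
      l[j] * traits$liability + sqrt(1 - l[j]^2) * eps[, j]
    }, numeric(n))
  })
  tibble::tibble(
    rat_id = traits$rat_id,
    persistence = as.numeric(qfs$persistence(pnorm(z[, 1]))),
    breakpoint = as.numeric(qfs$breakpoint(pnorm(z[, 2]))),
    punished = as.numeric(qfs$punished(pnorm(z[, 3])))
  )
}
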