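# Small cohort builders used across test files.

make_scores <- function(persistence, breakpoint, punished,
                        ids = sprintf("rat%03d", seq_along(persistence))) {
  tibble::tibble(rat_id = ids, persistence = persistence,
                 breakpoint = breakpoint, punished = punished)
}

# Brute-force percentile classifier: sorts and indexes ranks directly,
# independent of stats::quantile(). The p-quantile sits at rank
# 1 + (n - 1) * p of the sorted sample, linearly interpolated.
brute_force_threshold <- function(values, percentile) {
  xs <- sort(values)
  n <- length(xs)
  h <- 1 + (n - 1) * percentile / 100
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

brute_force_classify <- function(scores, lower = 66, upper = 99,
                                 policy = "count_positive") {
  flags <- sapply(c("persistence", "breakpoint", "punished"), function(cr) {
    x <- scores[[cr]]
    f <- x >= brute_force_threshold(x, lower)
    if (policy == "exclude_flagged") {
      f[x > brute_force_threshold(x, upper)] <- FALSE
    }
    f
  })
  colnames(flags) <- c("flag_persistence", "flag_motivation",
                       "flag_punishment")
  flags
}

# A default-calibrated config; construction is memoized so repeated calls
# across test files share one calibration.
default_cfg <- function(seed = 20170825, ...) trait_config(seed = seed, ...)

# Simulated 59-rat cohort screened end to end.
simulate_screened_cohort <- function(seed) {
  cfg <- default_cfg(seed = seed)
  tr <- sample_latent_traits(cfg)
  sc <- simulate_criterion_scores(tr, cfg)
  list(cfg = cfg, traits = tr, scores = sc,
       screening = suppressWarnings(screen_cohort(sc)))
}
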