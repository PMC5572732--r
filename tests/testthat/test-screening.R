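test_that("percentile thresholds follow the linear-interpolation convention", {
  # rank 1 + (n - 1) * p: for {1,2,3} at the 66.67th percentile the rank is
  # 2.333, interpolating to 7/3
  expect_equal(percentile_threshold(c(1, 2, 3), 200 / 3), 7 / 3,
               tolerance = 1e-12)
  expect_equal(percentile_threshold(c(4, 9, 1, 7), 100), 9)
  expect_error(percentile_threshold(c(5, 5, 5), 66), "degenerate")
  expect_error(percentile_threshold(c(1, 2), 0), "\\(0, 100\\]")
})

test_that("three-rat cohort flags only the top scorer", {
  sc <- make_scores(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  flags <- suppressWarnings(classify_criteria(sc))
  expect_equal(flags$flag_persistence, c(FALSE, FALSE, TRUE))
  expect_equal(flags$flag_motivation, c(FALSE, FALSE, TRUE))
  expect_equal(flags$flag_punishment, c(FALSE, FALSE, TRUE))
})

test_that("the above-99th policy only affects scores above the upper threshold", {
  set.seed(13)
  sc <- make_scores(rnorm(30, 50, 10), rnorm(30, 30, 8), rnorm(30, 12, 4))
  keep <- suppressWarnings(
    classify_criteria(sc, screening_config(above_upper_policy =
                                             "count_positive")))
  drop <- classify_criteria(sc, screening_config(above_upper_policy =
                                                   "exclude_flagged"))
  for (cl in c("flag_persistence", "flag_motivation", "flag_punishment")) {
    crit <- c(flag_persistence = "persistence", flag_motivation = "breakpoint",
              flag_punishment = "punished")[[cl]]
    hi <- percentile_threshold(sc[[crit]], 99)
    differs <- keep[[cl]] != drop[[cl]]
    expect_true(all(sc[[crit]][differs] > hi))
    expect_true(all(keep[[cl]][differs]))
  }
  w <- testthat::capture_warnings(classify_criteria(sc))
  expect_true(any(grepl("99th percentile", w)))
})

test_that("classification matches a brute-force rank oracle on small cohorts", {
  set.seed(29)
  for (i in 1:200) {
    n <- sample(4:8, 1)
    sc <- make_scores(sample(0:40, n, TRUE), sample(1:118, n, TRUE),
                      sample(0:30, n, TRUE))
    # degenerate distributions are rejected, not classified
    degen <- any(apply(sc[-1], 2, function(x) length(unique(x)) < 2))
    if (degen) {
      expect_error(suppressWarnings(classify_criteria(sc)), "degenerate")
      next
    }
    for (policy in c("count_positive", "exclude_flagged")) {
      got <- suppressWarnings(
        classify_criteria(sc, screening_config(above_upper_policy = policy)))
      want <- brute_force_classify(sc, policy = policy)
      expect_identical(as.matrix(got[-1]), want)
    }
  }
})

test_that("with thresholds fixed, flags are monotone in score", {
  set.seed(31)
  sc <- make_scores(rpois(20, 8), audtrait:::pr_snap(rpois(20, 30)),
                    rpois(20, 12))
  flags <- suppressWarnings(classify_criteria(sc))
  # raising the already-maximal score moves no threshold and changes no flag
  sc2 <- sc
  top <- which.max(sc2$persistence)
  sc2$persistence[top] <- sc2$persistence[top] + 50
  flags2 <- suppressWarnings(classify_criteria(sc2))
  expect_identical(flags$flag_persistence, flags2$flag_persistence)
  expect_identical(flags$flag_motivation, flags2$flag_motivation)
})

test_that("two-rat addiction scores are the +/- 3/sqrt(2) pair", {
  sc <- make_scores(c(2, 6), c(20, 40), c(5, 9))
  z <- addiction_score(sc)
  expect_equal(z$addiction_score, c(-3 / sqrt(2), 3 / sqrt(2)),
               tolerance = 1e-12)
})

test_that("addiction scores sum to zero and ignore criterion translation", {
  set.seed(37)
  for (i in 1:20) {
    sc <- make_scores(rpois(12, 8), rpois(12, 30), rpois(12, 12))
    if (any(apply(sc[-1], 2, sd) == 0)) next
    z <- addiction_score(sc)
    expect_equal(sum(z$addiction_score), 0, tolerance = 1e-9)
    shifted <- sc
    shifted$persistence <- shifted$persistence + 100
    expect_equal(addiction_score(shifted)$addiction_score,
                 z$addiction_score, tolerance = 1e-12)
  }
  const <- make_scores(rep(4, 5), 1:5, 2:6)
  expect_error(addiction_score(const), "zero variance.*persistence")
})

test_that("groups split at two criteria, configurably", {
  flags <- tibble::tibble(
    rat_id = sprintf("rat%03d", 1:4),
    flag_persistence = c(FALSE, TRUE, TRUE, TRUE),
    flag_motivation = c(FALSE, FALSE, TRUE, TRUE),
    flag_punishment = c(FALSE, FALSE, FALSE, TRUE)
  )
  z <- tibble::tibble(rat_id = flags$rat_id, addiction_score = c(-2, -1, 1, 2))
  res <- assign_groups(flags, z)
  expect_equal(res$n_criteria, 0:3)
  expect_equal(as.character(res$group),
               c("resilient", "resilient", "vulnerable", "vulnerable"))
  strict <- assign_groups(flags, z,
                          screening_config(vulnerable_min_criteria = 3))
  expect_equal(as.character(strict$group),
               c("resilient", "resilient", "resilient", "vulnerable"))
  empty <- assign_groups(flags[0, ], z[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("criterion-count distribution reproduces published-style percentages", {
  res <- tibble::tibble(n_criteria = rep(0:3, c(25, 14, 13, 7)))
  d <- criterion_count_distribution(res)
  expect_equal(d$count, c(25L, 14L, 13L, 7L))
  expect_equal(d$pct, c(42.4, 23.7, 22.0, 11.9))
  all0 <- criterion_count_distribution(tibble::tibble(n_criteria = rep(0, 10)))
  expect_equal(all0$pct, c(100, 0, 0, 0))
})

test_that("independent criteria reproduce the Binomial(3, 1/3) distribution", {
  cfg <- trait_config(n_rats = 3000, factor_loadings = c(0, 0, 0), seed = 91)
  sc <- simulate_criterion_scores(sample_latent_traits(cfg), cfg)
  res <- suppressWarnings(screen_cohort(sc))
  d <- criterion_count_distribution(res)
  want <- 100 * dbinom(0:3, 3, 1 / 3)
  expect_equal(d$pct, want, tolerance = 0.12)
})

test_that("addiction score correlates positively with every criterion", {
  cohort <- simulate_screened_cohort(seed = 93)
  m <- merge(cohort$scores, cohort$screening[c("rat_id", "addiction_score")])
  expect_gt(cor(m$addiction_score, m$persistence), 0)
  expect_gt(cor(m$addiction_score, m$breakpoint), 0)
  expect_gt(cor(m$addiction_score, m$punished), 0)
})
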