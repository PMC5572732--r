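big_traits <- function(n = 4000, seed = 201, rho = 0.7) {
  cfg <- trait_config(n_rats = n, factor_loadings = c(0.7, 0.9, 0.3),
                      anxiety_liability_corr = rho, seed = seed)
  sample_latent_traits(cfg)
}

test_that("ethanol preference fades in saccharine concentration", {
  tr <- big_traits()
  ch <- simulate_choice(tr, seed = 1)
  curve <- tapply(ch$preference_pct, ch$saccharine_conc_pct_wv, mean,
                  na.rm = TRUE)
  # ordered by concentration ascending; preference must decrease
  expect_true(all(diff(curve[order(as.numeric(names(curve)))]) < 0))
})

test_that("liability coupling widens the preference gap as saccharine fades", {
  tr <- big_traits()
  ch <- simulate_choice(tr, seed = 2)
  ch$liab <- tr$liability[match(ch$rat_id, tr$rat_id)]
  gap <- function(conc) {
    d <- ch[ch$saccharine_conc_pct_wv == conc, ]
    mean(d$preference_pct[d$liab > 0], na.rm = TRUE) -
      mean(d$preference_pct[d$liab <= 0], na.rm = TRUE)
  }
  expect_gt(gap(0), gap(0.2))
  expect_gt(gap(0), 5)
})

test_that("zero group effect removes the liability-preference coupling", {
  tr <- big_traits(seed = 202)
  ch <- simulate_choice(tr, config = choice_config(group_effect = 0),
                        seed = 3)
  ch$liab <- tr$liability[match(ch$rat_id, tr$rat_id)]
  water <- ch[ch$saccharine_conc_pct_wv == 0, ]
  expect_lt(abs(cor(water$liab, water$preference_pct, use = "complete.obs")),
            0.05)
})

test_that("records without presses are flagged as undefined preference", {
  tr <- big_traits(n = 50, seed = 203)
  expect_warning(
    ch <- simulate_choice(tr, config = choice_config(total_presses_mean = 0.2),
                          seed = 4),
    "undefined"
  )
  none <- ch$ethanol_presses + ch$saccharine_presses == 0
  expect_true(all(is.na(ch$preference_pct[none])))
  expect_true(all(!is.na(ch$preference_pct[!none])))
})

test_that("open-arm time stays in range and loses the configured rats", {
  cfg <- default_cfg(seed = 205)
  tr <- sample_latent_traits(cfg)
  epm <- simulate_epm(tr, seed = 5)
  expect_equal(sum(is.na(epm$open_arm_pct)), 8)
  expect_equal(sum(!is.na(epm$open_arm_pct)), 51)
  obs <- epm$open_arm_pct[!is.na(epm$open_arm_pct)]
  expect_true(all(obs >= 0 & obs <= 100))
  expect_error(simulate_epm(tr, epm_config(n_dropout = 60)),
               "smaller than the cohort")
})

test_that("anxious rats avoid the open arms; weight 0 removes the effect", {
  tr <- big_traits(seed = 206)
  epm <- simulate_epm(tr, epm_config(n_dropout = 0), seed = 6)
  expect_lt(cor(tr$anxiety, epm$open_arm_pct), -0.5)
  flat <- simulate_epm(tr, epm_config(anxiety_weight = 0, n_dropout = 0),
                       seed = 7)
  expect_lt(abs(cor(tr$anxiety, flat$open_arm_pct)), 0.05)
})

test_that("screened cohorts reproduce an anxiety contrast near the calibrated t", {
  ts <- vapply(1:120, function(i) {
    cohort <- simulate_screened_cohort(seed = 7000 + i)
    epm <- simulate_epm(cohort$traits, root_seed = cohort$cfg$seed)
    d <- merge(epm, cohort$screening[c("rat_id", "group")])
    d <- d[!is.na(d$open_arm_pct), ]
    v <- d$open_arm_pct[d$group == "vulnerable"]
    r <- d$open_arm_pct[d$group == "resilient"]
    if (length(v) < 2 || length(r) < 2) return(NA_real_)
    unpaired_t(r, v)$t
  }, numeric(1))
  expect_equal(mean(ts, na.rm = TRUE), 2.6, tolerance = 0.25)
})

test_that("the BAL model honors its kinetic limit cases", {
  tr <- big_traits(n = 5, seed = 207)
  # no elimination, absorption essentially complete: flat at the peak
  flat_cfg <- bal_config(absorption_rate = 1, elimination_rate = 0,
                         subject_sd = 0, noise_sd = 0)
  flat <- simulate_bal(tr, flat_cfg, seed = 8)
  spread <- tapply(flat$bal_g_per_kg, flat$rat_id, function(x) diff(range(x)))
  expect_lt(max(spread), 1e-6)
  expect_equal(max(flat$bal_g_per_kg), 0.8, tolerance = 1e-6)
  # zero-order decay: equal concentration drops per unit time post-absorption
  dec_cfg <- bal_config(absorption_rate = 1, elimination_rate = 0.002,
                        subject_sd = 0, noise_sd = 0,
                        sample_times_min = c(30, 60, 180))
  dec <- simulate_bal(tr, dec_cfg, seed = 9)
  one <- dec[dec$rat_id == dec$rat_id[1], ]
  drop1 <- one$bal_g_per_kg[1] - one$bal_g_per_kg[2]
  drop2 <- one$bal_g_per_kg[2] - one$bal_g_per_kg[3]
  expect_equal(drop1 / 30, 0.002, tolerance = 1e-9)
  expect_equal(drop2 / 120, 0.002, tolerance = 1e-9)
  expect_error(bal_config(elimination_rate = -1), "non-negative")
})

test_that("without a group effect the BAL group test keeps its nominal size", {
  reject <- vapply(1:250, function(i) {
    cfg <- trait_config(n_rats = 19, factor_loadings = c(0.7, 0.9, 0.3),
                        seed = 8000 + i)
    tr <- sample_latent_traits(cfg)
    tr$grp <- rep(c("R", "V"), c(12, 7))
    bal <- simulate_bal(tr, seed = 9000 + i)
    d <- data.frame(subject = bal$rat_id,
                    group = tr$grp[match(bal$rat_id, tr$rat_id)],
                    level = factor(bal$time_min), value = bal$bal_g_per_kg)
    res <- mixed_rm_anova(d)
    res$effects$p[res$effects$effect == "group"] < 0.05
  }, logical(1))
  # alpha = 0.05 design: non-significant group effect in about 95% of
  # replicates; assert with Monte-Carlo slack
  expect_gt(mean(!reject), 0.90)
})

test_that("BAL declines over the sampling window and the time effect is detected", {
  tr <- big_traits(n = 19, seed = 208)
  tr$grp <- rep(c("R", "V"), c(12, 7))
  bal <- simulate_bal(tr, seed = 10)
  by_time <- tapply(bal$bal_g_per_kg, bal$time_min, mean)
  expect_lt(by_time[["180"]], by_time[["30"]])
  d <- data.frame(subject = bal$rat_id,
                  group = tr$grp[match(bal$rat_id, tr$rat_id)],
                  level = factor(bal$time_min), value = bal$bal_g_per_kg)
  res <- mixed_rm_anova(d)
  expect_lt(res$effects$p[res$effects$effect == "level"], 1e-4)
})
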