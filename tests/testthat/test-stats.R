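test_that("one-way ANOVA matches the hand decomposition", {
  res <- one_way_anova(list(c(1, 2, 3), c(2, 3, 4)))
  expect_equal(res$F, 1.5, tolerance = 1e-12)
  expect_equal(res$df_between, 1)
  expect_equal(res$df_within, 4)
  expect_equal(res$ss_between, 1.5, tolerance = 1e-12)
  expect_equal(res$ms_within, 1, tolerance = 1e-12)
})

test_that("degenerate ANOVA inputs resolve to the defined limits", {
  same <- one_way_anova(list(c(1, 2, 3), c(3, 2, 1)))
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)
  # a perfect separation trips lm's perfect-fit warning; the limit itself
  # is what matters here
  sep <- suppressWarnings(one_way_anova(list(c(1, 1), c(2, 2))))
  expect_equal(sep$F, Inf)
  expect_equal(sep$p, 0)
  expect_error(one_way_anova(list(1:3)), "at least 2")
  expect_error(one_way_anova(list(1:3, 4)), "at least 2 observations")
})

test_that("two-group F equals the squared pooled t", {
  set.seed(61)
  for (i in 1:10) {
    x <- rnorm(7, 1); y <- rnorm(5)
    a <- one_way_anova(list(x, y))
    t <- unpaired_t(x, y)
    expect_equal(a$F, t$t^2, tolerance = 1e-10)
    expect_equal(a$p, t$p, tolerance = 1e-10)
  }
})

test_that("summary-statistic ANOVA equals the raw-data ANOVA exactly", {
  set.seed(67)
  for (i in 1:25) {
    k <- sample(2:5, 1)
    groups <- lapply(seq_len(k), function(j) rnorm(sample(3:12, 1), j, 2))
    raw <- one_way_anova(groups)
    summ <- data.frame(
      mean = vapply(groups, mean, numeric(1)),
      se = vapply(groups, function(g) sd(g) / sqrt(length(g)), numeric(1)),
      n = lengths(groups)
    )
    rec <- anova_from_summary(summ)
    expect_equal(rec$F, raw$F, tolerance = 1e-10)
    expect_equal(rec$p, raw$p, tolerance = 1e-10)
    expect_equal(rec$ss_between, raw$ss_between, tolerance = 1e-9)
    expect_equal(rec$ss_within, raw$ss_within, tolerance = 1e-9)
  }
})

test_that("group summaries are validated", {
  expect_error(group_summary(1, 0.5, 1), ">= 2")
  expect_error(group_summary(1, 0, 5), "positive")
  expect_error(anova_from_summary(data.frame(mean = 1, se = 1, n = 5)),
               "at least 2")
})

test_that("Tukey post hocs reduce to the pooled t for two groups", {
  set.seed(71)
  for (i in 1:10) {
    x <- rnorm(6, 0.5); y <- rnorm(9)
    tk <- tukey_hsd(list(a = x, b = y))
    tt <- unpaired_t(y, x)
    expect_equal(tk$p_adj, tt$p, tolerance = 1e-7)
    expect_equal(tk$diff, tt$mean_diff, tolerance = 1e-12)
  }
})

test_that("Tukey-Kramer matches the manual studentized-range computation", {
  groups <- list(g1 = c(5, 7, 6, 8, 9), g2 = c(10, 12, 11), g3 = c(4, 5, 6, 5))
  tk <- tukey_hsd(groups)
  a <- one_way_anova(groups)
  n <- lengths(groups)
  m <- vapply(groups, mean, numeric(1))
  manual <- function(i, j) {
    se <- sqrt(a$ms_within / 2 * (1 / n[i] + 1 / n[j]))
    q <- abs(m[[i]] - m[[j]]) / se
    unname(stats::ptukey(q, length(groups), a$df_within, lower.tail = FALSE))
  }
  expect_equal(tk$p_adj[tk$contrast == "g2-g1"], manual(2, 1),
               tolerance = 1e-9)
  expect_equal(tk$p_adj[tk$contrast == "g3-g1"], manual(3, 1),
               tolerance = 1e-9)
  expect_equal(tk$p_adj[tk$contrast == "g3-g2"], manual(3, 2),
               tolerance = 1e-9)
  # identical pair of groups -> q = 0, adjusted p = 1
  same <- tukey_hsd(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$p_adj, 1, tolerance = 1e-9)
})

test_that("pooled t from summaries matches the hand case and raw data", {
  hand <- unpaired_t_from_summary(list(mean = 1, se = 1 / sqrt(2), n = 2),
                                  list(mean = 0, se = 1 / sqrt(2), n = 2))
  expect_equal(hand$t, 1, tolerance = 1e-12)
  expect_equal(hand$df, 2)
  set.seed(73)
  x <- rnorm(12, 1); y <- rnorm(9)
  raw <- unpaired_t(x, y)
  summ <- unpaired_t_from_summary(
    list(mean = mean(x), se = sd(x) / sqrt(12), n = 12),
    list(mean = mean(y), se = sd(y) / sqrt(9), n = 9)
  )
  expect_equal(raw$t, summ$t, tolerance = 1e-10)
  expect_equal(raw$p, summ$p, tolerance = 1e-10)
  expect_equal(raw$df, 19)
  # degenerate cases
  flat <- unpaired_t(c(2, 2), c(2, 2))
  expect_equal(flat$t, 0)
  expect_equal(flat$p, 1)
  expect_error(unpaired_t(c(2, 2), c(3, 3)), "zero pooled variance")
})

test_that("pearson_r follows the closed-form t transform", {
  lin <- pearson_r(1:10, 2 * (1:10) + 1)
  expect_equal(lin$r, 1, tolerance = 1e-12)
  neg <- pearson_r(1:10, -(1:10))
  expect_equal(neg$r, -1, tolerance = 1e-12)
  set.seed(79)
  x <- rnorm(10); y <- rnorm(10)
  res <- pearson_r(x, y)
  expect_equal(res$t, res$r * sqrt((res$n - 2) / (1 - res$r^2)),
               tolerance = 1e-10)
  expect_equal(res$p, 2 * pt(abs(res$t), res$n - 2, lower.tail = FALSE),
               tolerance = 1e-12)
  # r = 0.5 at n = 10 gives t = 1.633, p ~ 0.141
  expect_equal(2 * pt(0.5 * sqrt(8 / 0.75), 8, lower.tail = FALSE), 0.1411,
               tolerance = 1e-3)
  expect_error(pearson_r(1:2, 2:3), "3 complete pairs")
  expect_error(pearson_r(rep(1, 5), 1:5), "zero variance")
})

test_that("the mixed-design decomposition matches an independent implementation", {
  # fixture checked against a reference split-plot ANOVA implementation
  set.seed(5)
  d <- expand.grid(subject = sprintf("s%d", 1:8), level = c("a", "b", "c"))
  d$group <- ifelse(as.integer(sub("s", "", d$subject)) <= 4, "g1", "g2")
  d$value <- round(10 + 2 * (d$group == "g2") + 1.5 * (d$level == "b") +
                     3 * (d$level == "c") +
                     2 * (d$group == "g2") * (d$level == "c") +
                     rnorm(nrow(d)), 3)
  res <- mixed_rm_anova(d)
  expect_equal(res$effects$F, c(272.700213, 33.433129, 9.642200),
               tolerance = 1e-6)
  expect_equal(res$effects$df1, c(1, 2, 2))
  expect_equal(res$effects$df2, c(6, 12, 12))
  expect_equal(res$effects$p, c(3.143616e-06, 1.240909e-05, 3.185082e-03),
               tolerance = 1e-4)
  # matches aov() with a subject error stratum on the same data
  fit <- summary(stats::aov(value ~ group * level + Error(subject),
                            data = d))
  expect_equal(res$effects$F[1], fit[[1]][[1]]["group", "F value"],
               tolerance = 1e-10)
  expect_equal(res$effects$F[2:3],
               unname(fit[[2]][[1]][c("level", "group:level"), "F value"]),
               tolerance = 1e-10)
})

test_that("additive group shifts hit the degenerate mixed-ANOVA limits", {
  d <- expand.grid(subject = sprintf("s%d", 1:6), level = c("a", "b"))
  d$group <- ifelse(as.integer(sub("s", "", d$subject)) <= 3, "g1", "g2")
  d$value <- 1 + 2 * (d$level == "b") + 5 * (d$group == "g2")
  res <- mixed_rm_anova(d)
  expect_equal(res$effects$F[res$effects$effect == "group"], Inf)
  expect_equal(res$effects$F[res$effects$effect == "group:level"], 0)
})

test_that("unbalanced mixed designs are rejected with subject diagnostics", {
  d <- expand.grid(subject = sprintf("s%d", 1:4), level = c("a", "b"))
  d$group <- rep(c("g1", "g2"), 4)
  d$value <- rnorm(nrow(d))
  expect_error(mixed_rm_anova(d[-2, ]), "s2")
})

test_that("null mixed designs give F statistics near their null mean", {
  set.seed(83)
  Fs <- replicate(150, {
    d <- expand.grid(subject = sprintf("s%d", 1:10), level = c("a", "b", "c"))
    d$group <- ifelse(as.integer(sub("s", "", d$subject)) <= 5, "g1", "g2")
    d$value <- rnorm(nrow(d))
    mixed_rm_anova(d)$effects$F
  })
  # E[F(df1, df2)] = df2 / (df2 - 2)
  expect_equal(mean(Fs[1, ]), 8 / 6, tolerance = 0.45)
  expect_equal(mean(Fs[2, ]), 16 / 14, tolerance = 0.3)
  expect_equal(mean(Fs[3, ]), 16 / 14, tolerance = 0.3)
})
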