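new_anova_result <- function(F, df_between, df_within, p, group_means,
                             ms_between, ms_within, ss_between, ss_within) {
  structure(
    list(F = F, df_between = df_between, df_within = df_within, p = p,
         group_means = group_means, ms_between = ms_between,
         ms_within = ms_within, ss_between = ss_between,
         ss_within = ss_within),
    class = "anova_result"
  )
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, %s\n",
              x$df_between, x$df_within, x$F, format_p(x$p)))
  invisible(x)
}

# p-value formatting mirrors the reporting style: below 1e-4 print the bound.
format_p <- function(p) {
  if (is.na(p)) return("p = NA")
  if (p < 1e-4) "p < 0.0001" else sprintf("p = %.4f", p)
}

#' One-way analysis of variance
#'
#' Standard fixed-effects decomposition, computed through [stats::lm()] /
#' [stats::anova()]. Degenerate inputs are resolved explicitly: identical
#' group means give F = 0, p = 1; zero within-group variance with distinct
#' means gives F = Inf, p = 0.
#'
#' @param groups List of numeric vectors (>= 2 groups, each n >= 2).
#' @return An object of class `anova_result`.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("`groups` must be a list of at least 2 numeric vectors.",
         call. = FALSE)
  }
  if (any(lengths(groups) < 2)) {
    stop("every group needs at least 2 observations.", call. = FALSE)
  }
  d <- data.frame(
    y = unlist(groups, use.names = FALSE),
    g = factor(rep(seq_along(groups), lengths(groups)))
  )
  tab <- stats::anova(stats::lm(y ~ g, data = d))
  ssb <- tab$`Sum Sq`[1]
  ssw <- tab$`Sum Sq`[2]
  dfb <- tab$Df[1]
  dfw <- tab$Df[2]
  msb <- ssb / dfb
  msw <- ssw / dfw
  sst <- ssb + ssw
  if (sst <= 0 || ssb <= sst * 1e-14) {
    F <- 0; p <- 1
  } else if (msw <= sst * 1e-14) {
    F <- Inf; p <- 0
  } else {
    F <- tab$`F value`[1]
    p <- tab$`Pr(>F)`[1]
  }
  new_anova_result(F, dfb, dfw, p,
                   group_means = vapply(groups, mean, numeric(1)),
                   ms_between = msb, ms_within = msw,
                   ss_between = ssb, ss_within = ssw)
}

#' Group summary constructor
#'
#' @param mean Group mean.
#' @param se Standard error of the mean (> 0).
#' @param n Group size (>= 2).
#' @return A list of class `group_summary`.
#' @export
group_summary <- function(mean, se, n) {
  if (n < 2 || n %% 1 != 0) stop("`n` must be an integer >= 2.",
                                 call. = FALSE)
  if (se <= 0) stop("`se` must be positive.", call. = FALSE)
  structure(list(mean = mean, se = se, n = as.integer(n)),
            class = "group_summary")
}

as_summary_df <- function(summaries) {
  if (is.data.frame(summaries)) {
    stopifnot(all(c("mean", "se", "n") %in% names(summaries)))
    return(summaries[c("mean", "se", "n")])
  }
  if (is.list(summaries) &&
      all(vapply(summaries, inherits, logical(1), "group_summary"))) {
    return(data.frame(
      mean = vapply(summaries, `[[`, numeric(1), "mean"),
      se = vapply(summaries, `[[`, numeric(1), "se"),
      n = vapply(summaries, `[[`, numeric(1), "n")
    ))
  }
  stop("`summaries` must be a data frame with mean/se/n columns or a list ",
       "of group_summary objects.", call. = FALSE)
}

#' One-way ANOVA reconstructed from group summary statistics
#'
#' Rebuilds the full decomposition from per-group means, standard errors and
#' sizes: `SD_i = SE_i * sqrt(n_i)`, within sum of squares
#' `sum((n_i - 1) * SD_i^2)`, between sum of squares from the group means
#' about the size-weighted grand mean. When the summaries come from raw data
#' without rounding this reproduces [one_way_anova()] exactly.
#'
#' @param summaries Data frame with columns `mean`, `se`, `n`, or a list of
#'   [group_summary()] objects.
#' @return An object of class `anova_result`.
#' @export
anova_from_summary <- function(summaries) {
  s <- as_summary_df(summaries)
  if (nrow(s) < 2) stop("need at least 2 group summaries.", call. = FALSE)
  if (any(s$n < 2)) stop("every group needs n >= 2.", call. = FALSE)
  N <- sum(s$n)
  k <- nrow(s)
  grand <- sum(s$n * s$mean) / N
  ssb <- sum(s$n * (s$mean - grand)^2)
  sdv <- s$se * sqrt(s$n)
  ssw <- sum((s$n - 1) * sdv^2)
  dfb <- k - 1L
  dfw <- N - k
  msb <- ssb / dfb
  msw <- ssw / dfw
  sst <- ssb + ssw
  if (sst <= 0 || ssb <= sst * 1e-14) {
    F <- 0; p <- 1
  } else if (msw <= sst * 1e-14) {
    F <- Inf; p <- 0
  } else {
    F <- msb / msw
    p <- stats::pf(F, dfb, dfw, lower.tail = FALSE)
  }
  new_anova_result(F, dfb, as.integer(dfw), p, group_means = s$mean,
                   ms_between = msb, ms_within = msw,
                   ss_between = ssb, ss_within = ssw)
}

#' Tukey-Kramer post hoc comparisons
#'
#' Pairwise comparisons after a one-way ANOVA, using the studentized-range
#' distribution with Tukey-Kramer standard errors for unequal group sizes
#' (via [stats::TukeyHSD()]).
#'
#' @param groups List of numeric vectors; names, if present, label the
#'   contrasts.
#' @return A tibble `contrast`, `diff`, `lwr`, `upr`, `p_adj`.
#' @export
tukey_hsd <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("`groups` must be a list of at least 2 numeric vectors.",
         call. = FALSE)
  }
  nm <- names(groups) %||% paste0("g", seq_along(groups))
  nm[nm == ""] <- paste0("g", which(nm == ""))
  d <- data.frame(
    y = unlist(groups, use.names = FALSE),
    g = factor(rep(nm, lengths(groups)), levels = nm)
  )
  tk <- stats::TukeyHSD(stats::aov(y ~ g, data = d))$g
  tibble::tibble(
    contrast = rownames(tk),
    diff = unname(tk[, "diff"]),
    lwr = unname(tk[, "lwr"]),
    upr = unname(tk[, "upr"]),
    p_adj = unname(tk[, "p adj"])
  )
}

#' Pooled-variance unpaired t test
#'
#' Student's two-sample t with the pooled variance estimate and
#' `df = n1 + n2 - 2`, two-tailed.
#'
#' @param x,y Numeric vectors with `length(x) + length(y) >= 4`.
#' @return List with `t`, `df`, `p`, `mean_diff`.
#' @export
unpaired_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 + n2 < 4 || n1 < 2 || n2 < 2) {
    stop("need at least 2 observations per group and 4 in total.",
         call. = FALSE)
  }
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
    (n1 + n2 - 2)
  d <- mean(x) - mean(y)
  if (sp2 <= 0) {
    if (abs(d) < 1e-12) {
      return(list(t = 0, df = n1 + n2 - 2L, p = 1, mean_diff = d))
    }
    stop("zero pooled variance with unequal means; t is undefined.",
         call. = FALSE)
  }
  ht <- stats::t.test(x, y, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_diff = d)
}

#' Unpaired t test from group summaries
#'
#' @param s1,s2 [group_summary()] objects (or lists with `mean`, `se`, `n`).
#' @return List with `t`, `df`, `p`, `mean_diff`.
#' @export
unpaired_t_from_summary <- function(s1, s2) {
  n1 <- s1$n; n2 <- s2$n
  if (n1 + n2 < 4) stop("need n1 + n2 >= 4.", call. = FALSE)
  v1 <- (s1$se * sqrt(n1))^2
  v2 <- (s2$se * sqrt(n2))^2
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  d <- s1$mean - s2$mean
  if (sp2 <= 0) {
    if (abs(d) < 1e-12) {
      return(list(t = 0, df = n1 + n2 - 2L, p = 1, mean_diff = d))
    }
    stop("zero pooled variance with unequal means; t is undefined.",
         call. = FALSE)
  }
  t <- d / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2L
  list(t = t, df = df, p = 2 * stats::pt(abs(t), df, lower.tail = FALSE),
       mean_diff = d)
}

#' Pearson correlation with two-tailed test
#'
#' @param x,y Numeric vectors, `n >= 3`, nonzero variance.
#' @return List with `r`, `n`, `t`, `df`, `p`.
#' @export
pearson_r <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs.", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance; correlation undefined.", call. = FALSE)
  }
  ht <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ht$estimate), n = length(x),
       t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Mixed-design (split-plot) repeated-measures ANOVA
#'
#' One between-subject factor and one within-subject factor, every subject
#' observed at every within level. Standard mixed-model decomposition via
#' [stats::aov()] with a subject error stratum; no sphericity correction is
#' applied by default (`gg_correction = TRUE` applies Greenhouse-Geisser to
#' the within-stratum tests). Between-group contrasts at each within level
#' use pooled t tests with Bonferroni correction over levels (and group
#' pairs, when more than two groups).
#'
#' @param data Data frame with columns `subject`, `group`, `level`, `value`.
#' @param gg_correction Apply Greenhouse-Geisser epsilon to within-stratum
#'   degrees of freedom.
#' @return A list of class `mixed_rm_anova`: `effects` (tibble with `effect`,
#'   `df1`, `df2`, `F`, `p`) and `contrasts` (tibble of Bonferroni-adjusted
#'   per-level group contrasts).
#' @export
mixed_rm_anova <- function(data, gg_correction = FALSE) {
  needed <- c("subject", "group", "level", "value")
  if (!all(needed %in% names(data))) {
    stop("`data` must have columns subject, group, level, value.",
         call. = FALSE)
  }
  d <- data.frame(
    subject = factor(data$subject),
    group = factor(data$group),
    level = factor(data$level),
    value = as.numeric(data$value)
  )
  # balance: each subject exactly once per level, one group per subject
  tab <- table(d$subject, d$level)
  if (any(tab != 1)) {
    bad <- rownames(tab)[rowSums(tab != 1) > 0]
    stop("unbalanced design; subject(s) without exactly one observation ",
         "per level: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  gmap <- unique(d[c("subject", "group")])
  if (anyDuplicated(gmap$subject)) {
    stop("subject(s) assigned to more than one group: ",
         paste(gmap$subject[duplicated(gmap$subject)], collapse = ", "),
         call. = FALSE)
  }

  n_subj <- nlevels(d$subject)
  k <- nlevels(d$group)
  l <- nlevels(d$level)

  ss <- function(x) sum(x^2)
  grand <- mean(d$value)
  # cell/marginal means
  subj_mean <- tapply(d$value, d$subject, mean)
  grp_of_subj <- gmap$group[match(names(subj_mean), gmap$subject)]
  grp_mean <- tapply(d$value, d$group, mean)
  lev_mean <- tapply(d$value, d$level, mean)
  cell_mean <- tapply(d$value, list(d$group, d$level), mean)
  n_per_grp <- table(gmap$group)

  ss_between_subj <- l * ss(subj_mean - grand)
  ss_group <- l * sum(n_per_grp * (grp_mean - grand)^2)
  ss_subj_within <- ss_between_subj - ss_group
  ss_level <- n_subj * ss(lev_mean - grand)
  ss_inter <- sum(outer(seq_len(k), seq_len(l), Vectorize(function(i, j) {
    n_per_grp[i] * (cell_mean[i, j] - grp_mean[i] - lev_mean[j] + grand)^2
  })))
  ss_total <- ss(d$value - grand)
  ss_resid <- ss_total - ss_between_subj - ss_level - ss_inter

  df_group <- k - 1L
  df_subj <- n_subj - k
  df_level <- l - 1L
  df_inter <- (k - 1L) * (l - 1L)
  df_resid <- (n_subj - k) * (l - 1L)

  eff <- function(name, ss_eff, df_eff, ss_err, df_err) {
    ms_eff <- ss_eff / df_eff
    ms_err <- ss_err / df_err
    tot <- ss_eff + ss_err
    if (tot <= 0 || ss_eff <= max(tot, 1) * 1e-13) {
      F <- 0; p <- 1
    } else if (ms_err <= max(tot, 1) * 1e-13) {
      F <- Inf; p <- 0
    } else {
      F <- ms_eff / ms_err
      p <- stats::pf(F, df_eff, df_err, lower.tail = FALSE)
    }
    tibble::tibble(effect = name, df1 = df_eff, df2 = df_err, F = F, p = p)
  }

  eps <- 1
  if (gg_correction) eps <- gg_epsilon(d)
  effects <- dplyr::bind_rows(
    eff("group", ss_group, df_group, ss_subj_within, df_subj),
    eff("level", ss_level, df_level * eps, ss_resid, df_resid * eps),
    eff("group:level", ss_inter, df_inter * eps, ss_resid, df_resid * eps)
  )

  # Bonferroni-adjusted between-group contrasts at each within level
  pairs <- utils::combn(levels(d$group), 2, simplify = FALSE)
  m <- l * length(pairs)
  contrasts <- dplyr::bind_rows(lapply(levels(d$level), function(lv) {
    dplyr::bind_rows(lapply(pairs, function(pr) {
      x <- d$value[d$level == lv & d$group == pr[1]]
      y <- d$value[d$level == lv & d$group == pr[2]]
      tt <- tryCatch(unpaired_t(x, y), error = function(e) {
        # zero pooled variance with distinct means: the separation is exact
        list(t = sign(mean(x) - mean(y)) * Inf,
             df = length(x) + length(y) - 2L, p = 0,
             mean_diff = mean(x) - mean(y))
      })
      tibble::tibble(level = lv, contrast = paste(pr[1], "-", pr[2]),
                     mean_diff = tt$mean_diff, t = tt$t, df = tt$df,
                     p_adj = min(1, tt$p * m))
    }))
  }))

  structure(list(effects = effects, contrasts = contrasts,
                 gg_correction = gg_correction),
            class = "mixed_rm_anova")
}

# Greenhouse-Geisser epsilon from the within-subject covariance matrix.
gg_epsilon <- function(d) {
  wide <- tapply(d$value, list(d$subject, d$level), mean)
  S <- stats::cov(wide)
  l <- ncol(S)
  mbar <- mean(S)
  row_m <- rowMeans(S)
  num <- (l * (mean(diag(S)) - mbar))^2
  den <- (l - 1) * (sum(S^2) - 2 * l * sum(row_m^2) + l^2 * mbar^2)
  max(1 / (l - 1), min(1, num / den))
}

#' @export
print.mixed_rm_anova <- function(x, ...) {
  cat("Mixed repeated-measures ANOVA",
      if (x$gg_correction) "(Greenhouse-Geisser corrected)" else "", "\n")
  for (i in seq_len(nrow(x$effects))) {
    r <- x$effects[i, ]
    cat(sprintf("  %-12s F(%.3g, %.4g) = %.3f, %s\n", r$effect, r$df1,
                r$df2, r$F, format_p(r$p)))
  }
  invisible(x)
}
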