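#' Group-statistics layer for a screened cohort
#'
#' Reproduces the analysis battery on one cohort: one-way ANOVAs with
#' Tukey-Kramer post hocs for each criterion and for the addiction score
#' across the four criterion-count groups, the criterion-count distribution,
#' Pearson correlations of the addiction score with each criterion,
#' single-factor extraction of the criterion correlation matrix, the
#' resilient/vulnerable open-arm t test, the mixed repeated-measures ANOVA of
#' choice preference (group x saccharine concentration; subjects with any
#' undefined preference are dropped with a note), the correlation of
#' addiction score with ethanol-vs-water preference, and the mixed
#' repeated-measures ANOVA of blood alcohol levels (group x time).
#'
#' @param scores CriterionScores tibble.
#' @param screening ScreeningResult tibble from [screen_cohort()].
#' @param epm Optional tibble from [simulate_epm()] (or matching columns).
#' @param choice Optional tibble from [simulate_choice()].
#' @param bal Optional tibble from [simulate_bal()].
#' @return A list of class `stats_report`.
#' @export
analyze_cohort <- function(scores, screening, epm = NULL, choice = NULL,
                           bal = NULL) {
  merged <- dplyr::inner_join(scores, screening, by = "rat_id")
  by_crit <- function(col) {
    grp <- split(merged[[col]], merged$n_criteria)
    grp <- grp[lengths(grp) >= 2]
    list(anova = one_way_anova(grp), tukey = tukey_hsd(grp))
  }
  report <- list(
    n = nrow(merged),
    distribution = criterion_count_distribution(screening),
    persistence = by_crit("persistence"),
    breakpoint = by_crit("breakpoint"),
    punished = by_crit("punished"),
    addiction_score = by_crit("addiction_score"),
    score_criterion_corr = list(
      persistence = pearson_r(merged$addiction_score, merged$persistence),
      breakpoint = pearson_r(merged$addiction_score, merged$breakpoint),
      punished = pearson_r(merged$addiction_score, merged$punished)
    ),
    factor = extract_single_factor(pearson_correlation_matrix(scores))
  )

  if (!is.null(epm)) {
    d <- dplyr::inner_join(epm, screening[c("rat_id", "group")],
                           by = "rat_id")
    d <- d[!is.na(d$open_arm_pct), ]
    report$epm <- c(
      unpaired_t(d$open_arm_pct[d$group == "resilient"],
                 d$open_arm_pct[d$group == "vulnerable"]),
      list(
        n_resilient = sum(d$group == "resilient"),
        n_vulnerable = sum(d$group == "vulnerable"),
        mean_resilient = mean(d$open_arm_pct[d$group == "resilient"]),
        mean_vulnerable = mean(d$open_arm_pct[d$group == "vulnerable"])
      )
    )
  }

  if (!is.null(choice)) {
    d <- dplyr::inner_join(choice, screening[c("rat_id", "group")],
                           by = "rat_id")
    incomplete <- unique(d$rat_id[is.na(d$preference_pct)])
    if (length(incomplete) > 0) {
      message("dropping ", length(incomplete),
              " subject(s) with undefined preference from the choice ANOVA.")
      d <- d[!d$rat_id %in% incomplete, ]
    }
    rm_in <- data.frame(subject = d$rat_id, group = d$group,
                        level = factor(d$saccharine_conc_pct_wv),
                        value = d$preference_pct)
    report$choice <- mixed_rm_anova(rm_in)
    water <- d[d$saccharine_conc_pct_wv == 0, ]
    water <- dplyr::inner_join(
      water, screening[c("rat_id", "addiction_score")], by = "rat_id")
    if (nrow(water) >= 3) {
      report$score_vs_water_choice <- pearson_r(water$addiction_score,
                                                water$preference_pct)
    }
  }

  if (!is.null(bal)) {
    d <- dplyr::inner_join(bal, screening[c("rat_id", "group")],
                           by = "rat_id")
    report$bal <- mixed_rm_anova(data.frame(
      subject = d$rat_id, group = d$group, level = factor(d$time_min),
      value = d$bal_g_per_kg
    ))
  }
  structure(report, class = "stats_report")
}

#' Render a stats report as plain text
#'
#' @param report A `stats_report` from [analyze_cohort()].
#' @return Character vector of report lines (invisibly printed-friendly).
#' @export
format_stats_report <- function(report) {
  stopifnot(inherits(report, "stats_report"))
  ln <- character(0)
  add <- function(...) ln <<- c(ln, sprintf(...))
  add("Cohort of %d rats", report$n)
  d <- report$distribution
  add("Criterion counts: %s",
      paste(sprintf("%dcrit n=%d (%.1f%%)", d$n_criteria, d$count, d$pct),
            collapse = ", "))
  for (nm in c("persistence", "breakpoint", "punished", "addiction_score")) {
    a <- report[[nm]]$anova
    add("%s: F(%d, %d) = %.3f, %s", nm, a$df_between, a$df_within, a$F,
        format_p(a$p))
  }
  for (nm in names(report$score_criterion_corr)) {
    r <- report$score_criterion_corr[[nm]]
    add("addiction score vs %s: r = %.3f, %s", nm, r$r, format_p(r$p))
  }
  f <- report$factor
  add("factor analysis: %d factor(s) retained, loadings %s, %.0f%% variance",
      f$n_retained, paste(sprintf("%.3f", f$loadings), collapse = "/"),
      100 * f$variance_fraction)
  if (!is.null(report$epm)) {
    e <- report$epm
    add("open-arm %% (R n=%d: %.2f, V n=%d: %.2f): t(%d) = %.2f, %s",
        e$n_resilient, e$mean_resilient, e$n_vulnerable, e$mean_vulnerable,
        e$df, e$t, format_p(e$p))
  }
  if (!is.null(report$choice)) {
    for (i in seq_len(nrow(report$choice$effects))) {
      r <- report$choice$effects[i, ]
      add("choice %s: F(%g, %g) = %.3f, %s", r$effect, r$df1, r$df2, r$F,
          format_p(r$p))
    }
  }
  if (!is.null(report$score_vs_water_choice)) {
    r <- report$score_vs_water_choice
    add("addiction score vs ethanol/water preference: r = %.3f, %s", r$r,
        format_p(r$p))
  }
  if (!is.null(report$bal)) {
    for (i in seq_len(nrow(report$bal$effects))) {
      r <- report$bal$effects[i, ]
      add("BAL %s: F(%g, %g) = %.3f, %s", r$effect, r$df1, r$df2, r$F,
          format_p(r$p))
    }
  }
  ln
}

#' @export
print.stats_report <- function(x, ...) {
  cat(format_stats_report(x), sep = "\n")
  invisible(x)
}

#' Run the full pipeline: simulate, screen, analyze
#'
#' Generates a cohort under the run configuration, screens it, runs the
#' statistics layer, and (when `output_dir` is set) writes `traits.csv`,
#' `sessions.csv`, `criteria.csv`, `choice.csv`, `epm.csv`, `bal.csv`,
#' `screening.csv`, `stats_report.json`, a plain-text `report.txt` and a
#' `cohort_config.yaml` echo of the resolved configuration. Stage errors are
#' re-raised with the failing stage named.
#'
#' @param config A [run_config()].
#' @return An object of class `result_bundle`: `screening`, `stats`,
#'   `tables` (the simulated tables) and `provenance` (config hash, seed,
#'   package version).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  root <- config$seed
  traits <- stage("simulate", sample_latent_traits(config$cohort))
  truth <- stage("simulate",
                 simulate_criterion_scores(traits, config$cohort))
  sessions <- stage("simulate",
                    simulate_sessions(traits, truth, config$sessions,
                                      root_seed = root))
  choice <- stage("simulate",
                  simulate_choice(traits, config = config$choice,
                                  root_seed = root))
  epm <- stage("simulate",
               simulate_epm(traits, config$epm, root_seed = root))
  bal <- stage("simulate", simulate_bal(traits, config$bal,
                                        root_seed = root))

  criteria <- stage("screen", criterion_scores_from_sessions(sessions))
  screening <- stage("screen",
                     withCallingHandlers(
                       screen_cohort(criteria, config$screening),
                       warning = function(w) {
                         message("screening note: ", conditionMessage(w))
                         invokeRestart("muffleWarning")
                       }))

  # the elimination assay runs on a subset of each group, as in practice
  bal_sub <- stage("analyze", {
    r_ids <- screening$rat_id[screening$group == "resilient"]
    v_ids <- screening$rat_id[screening$group == "vulnerable"]
    keep <- c(utils::head(r_ids, 12), utils::head(v_ids, 7))
    bal[bal$rat_id %in% keep, ]
  })
  stats <- stage("analyze",
                 analyze_cohort(criteria, screening, epm = epm,
                                choice = choice, bal = bal_sub))

  provenance <- list(
    config_hash = rlang::hash(rapply(unclass(config), unclass,
                                     how = "replace")),
    seed = root,
    package_version = as.character(utils::packageVersion("audtrait"))
  )

  if (!is.null(config$output_dir)) {
    out <- config$output_dir
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    write_schema_csv(traits, file.path(out, "traits.csv"), "traits")
    write_sessions(sessions, file.path(out, "sessions.csv"))
    write_schema_csv(criteria, file.path(out, "criteria.csv"), "criteria")
    write_schema_csv(choice, file.path(out, "choice.csv"), "choice")
    write_schema_csv(epm, file.path(out, "epm.csv"), "epm")
    write_schema_csv(bal, file.path(out, "bal.csv"), "bal")
    write_schema_csv(screening, file.path(out, "screening.csv"),
                     "screening")
    write_run_config(config, file.path(out, "cohort_config.yaml"))
    jsonlite::write_json(
      serialize_report(stats, provenance),
      file.path(out, "stats_report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    writeLines(format_stats_report(stats), file.path(out, "report.txt"))
  }

  structure(
    list(screening = screening, stats = stats,
         tables = list(traits = traits, truth = truth, sessions = sessions,
                       criteria = criteria, choice = choice, epm = epm,
                       bal = bal),
         provenance = provenance),
    class = "result_bundle"
  )
}

# stats_report -> plain lists for JSON
serialize_report <- function(stats, provenance) {
  strip <- function(x) {
    if (inherits(x, "anova_result") || inherits(x, "mixed_rm_anova")) {
      x <- unclass(x)
    }
    if (inherits(x, "factor_solution")) {
      x <- list(eigenvalues = x$eigenvalues,
                loadings = as.list(x$loadings),
                variance_fraction = x$variance_fraction,
                n_retained = x$n_retained)
    }
    if (is.list(x) && !is.data.frame(x)) return(lapply(x, strip))
    x
  }
  c(list(provenance = provenance), strip(unclass(stats)))
}

#' @export
print.result_bundle <- function(x, ...) {
  cat("<result_bundle> seed", x$provenance$seed, "config",
      substr(x$provenance$config_hash, 1, 8), "\n\n")
  print(x$stats)
  invisible(x)
}
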