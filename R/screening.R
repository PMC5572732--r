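#' Screening configuration
#'
#' A rat is positive for an addiction-like criterion when its score lies in
#' the cohort's 66th-99th percentile window for that criterion; rats meeting
#' at least `vulnerable_min_criteria` criteria form the vulnerable group
#' (Group V), the rest the resilient group (Group R).
#'
#' Scores strictly above the upper percentile are governed by
#' `above_upper_policy`: `"count_positive"` (default) keeps them positive with
#' a warning — dropping the single most extreme rat of a small cohort would
#' distort group sizes — while `"exclude_flagged"` reads the window literally
#' and clears their flag.
#'
#' @param lower_percentile,upper_percentile Window bounds, `0 < lower < upper
#'   <= 100`.
#' @param above_upper_policy `"count_positive"` or `"exclude_flagged"`.
#' @param vulnerable_min_criteria Minimum criterion count for Group V.
#' @return An object of class `screening_config`.
#' @export
screening_config <- function(lower_percentile = 66,
                             upper_percentile = 99,
                             above_upper_policy = c("count_positive",
                                                    "exclude_flagged"),
                             vulnerable_min_criteria = 2) {
  if (!(lower_percentile > 0 && lower_percentile < upper_percentile &&
        upper_percentile <= 100)) {
    stop("need 0 < lower_percentile < upper_percentile <= 100.",
         call. = FALSE)
  }
  if (vulnerable_min_criteria < 0 || vulnerable_min_criteria > 3) {
    stop("`vulnerable_min_criteria` must be between 0 and 3.", call. = FALSE)
  }
  structure(
    list(lower_percentile = as.numeric(lower_percentile),
         upper_percentile = as.numeric(upper_percentile),
         above_upper_policy = match.arg(above_upper_policy),
         vulnerable_min_criteria = as.integer(vulnerable_min_criteria)),
    class = "screening_config"
  )
}

#' Per-rat criterion scores from session records
#'
#' Aggregates raw session rows into the three screening measures:
#' * persistence — mean active presses per signaled-unavailable period across
#'   the no-drug test sessions (3 sessions x 3 cycles = 9 periods);
#' * breakpoint — mean over the 3 PR sessions of the final completed
#'   requirement, recovered from each session's reward count through
#'   [pr_ratio_sequence()];
#' * punished — mean active presses over the 3 punishment sessions.
#'
#' @param records SessionRecord tibble (see [simulate_sessions()]).
#' @return A tibble `rat_id`, `persistence`, `breakpoint`, `punished`.
#' @export
criterion_scores_from_sessions <- function(records) {
  needed <- c("rat_id", "phase", "session_index", "period", "active_presses",
              "rewards")
  if (!all(needed %in% names(records))) {
    stop("`records` is missing column(s): ",
         paste(setdiff(needed, names(records)), collapse = ", "),
         call. = FALSE)
  }
  rats <- unique(records$rat_id)
  test_phases <- c("nodrug_test", "pr_test", "punishment_test")
  counts <- records |>
    dplyr::filter(.data$phase %in% test_phases) |>
    dplyr::distinct(.data$rat_id, .data$phase, .data$session_index) |>
    dplyr::count(.data$rat_id, .data$phase) |>
    tidyr::complete(rat_id = rats, phase = test_phases,
                    fill = list(n = 0L))
  bad <- dplyr::filter(counts, .data$n != 3L)
  if (nrow(bad) > 0) {
    stop("expected exactly 3 test sessions per criterion; found: ",
         paste(sprintf("%s/%s=%d", bad$rat_id, bad$phase, bad$n),
               collapse = ", "), call. = FALSE)
  }

  persistence <- records |>
    dplyr::filter(.data$phase == "nodrug_test",
                  .data$period == "unavailable") |>
    dplyr::summarise(persistence = mean(.data$active_presses),
                     .by = "rat_id")

  seq_max <- pr_ratio_sequence(
    max(records$rewards[records$phase == "pr_test"], 1))
  breakpoint <- records |>
    dplyr::filter(.data$phase == "pr_test") |>
    dplyr::mutate(final_ratio = ifelse(.data$rewards == 0, 0,
                                       seq_max[pmax(.data$rewards, 1)])) |>
    dplyr::summarise(breakpoint = mean(.data$final_ratio), .by = "rat_id")

  punished <- records |>
    dplyr::filter(.data$phase == "punishment_test") |>
    dplyr::summarise(punished = mean(.data$active_presses), .by = "rat_id")

  out <- persistence |>
    dplyr::inner_join(breakpoint, by = "rat_id") |>
    dplyr::inner_join(punished, by = "rat_id")
  out[match(rats, out$rat_id), ]
}

#' Percentile threshold of a score distribution
#'
#' Linear-interpolation quantile: the p-th percentile sits at rank
#' `1 + (n - 1) * p / 100` of the sorted sample (the common default
#' convention, pinned for reproducibility).
#'
#' @param values Numeric vector with at least 2 distinct values.
#' @param percentile Percentile in (0, 100].
#' @return Threshold value.
#' @export
percentile_threshold <- function(values, percentile) {
  if (length(percentile) != 1 || percentile <= 0 || percentile > 100) {
    stop("`percentile` must be a single value in (0, 100].", call. = FALSE)
  }
  values <- as.numeric(values)
  if (anyNA(values)) stop("`values` must not contain NA.", call. = FALSE)
  if (length(unique(values)) < 2) {
    stop("degenerate score distribution (fewer than 2 distinct values); ",
         "percentile classification is meaningless.", call. = FALSE)
  }
  unname(quantile(values, percentile / 100, type = 7, names = FALSE))
}

#' Flag criterion positivity by the percentile window
#'
#' Cohort-level call: each criterion is thresholded on its own distribution.
#' A score is positive when it is at or above the lower-percentile threshold
#' (the window is read as inclusive at the boundary); scores strictly above
#' the upper threshold follow `config$above_upper_policy`.
#'
#' @param scores CriterionScores tibble (`rat_id`, `persistence`,
#'   `breakpoint`, `punished`).
#' @param config A [screening_config()].
#' @return A tibble `rat_id`, `flag_persistence`, `flag_motivation`,
#'   `flag_punishment`.
#' @export
classify_criteria <- function(scores, config = screening_config()) {
  stopifnot(inherits(config, "screening_config"))
  cols <- c(persistence = "flag_persistence", breakpoint = "flag_motivation",
            punished = "flag_punishment")
  out <- tibble::tibble(rat_id = scores$rat_id)
  for (crit in names(cols)) {
    x <- scores[[crit]]
    lo <- percentile_threshold(x, config$lower_percentile)
    hi <- percentile_threshold(x, config$upper_percentile)
    flag <- x >= lo
    above <- x > hi
    if (any(above)) {
      if (config$above_upper_policy == "count_positive") {
        warning("score(s) above the ", config$upper_percentile,
                "th percentile on ", crit, " kept positive: ",
                paste(scores$rat_id[above], collapse = ", "), call. = FALSE)
      } else {
        flag[above] <- FALSE
      }
    }
    out[[cols[[crit]]]] <- flag
  }
  out
}

#' Composite addiction score (z-sum)
#'
#' Sum of the three criterion z-scores; each criterion is standardized
#' against the cohort mean and sample SD (n - 1 denominator). The scores sum
#' to zero over the cohort by construction.
#'
#' @param scores CriterionScores tibble.
#' @return A tibble `rat_id`, `addiction_score`.
#' @export
addiction_score <- function(scores) {
  if (nrow(scores) < 2) {
    stop("addiction scores need at least 2 rats.", call. = FALSE)
  }
  zs <- vapply(c("persistence", "breakpoint", "punished"), function(crit) {
    x <- scores[[crit]]
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) {
      stop("zero variance on criterion '", crit,
           "'; z-scores are undefined.", call. = FALSE)
    }
    (x - mean(x)) / s
  }, numeric(nrow(scores)))
  tibble::tibble(rat_id = scores$rat_id,
                 addiction_score = rowSums(zs))
}

#' Assign resilient/vulnerable groups
#'
#' @param flags Tibble from [classify_criteria()].
#' @param scores_z Tibble from [addiction_score()].
#' @param config A [screening_config()].
#' @return ScreeningResult tibble: `rat_id`, the three flags, `n_criteria`,
#'   `addiction_score`, `group` (factor resilient/vulnerable).
#' @export
assign_groups <- function(flags, scores_z, config = screening_config()) {
  stopifnot(inherits(config, "screening_config"))
  out <- dplyr::inner_join(flags, scores_z, by = "rat_id")
  out$n_criteria <- as.integer(out$flag_persistence + out$flag_motivation +
                                 out$flag_punishment)
  out$group <- factor(
    ifelse(out$n_criteria >= config$vulnerable_min_criteria,
           "vulnerable", "resilient"),
    levels = c("resilient", "vulnerable")
  )
  dplyr::relocate(out, "rat_id", "flag_persistence", "flag_motivation",
                  "flag_punishment", "n_criteria", "addiction_score",
                  "group")
}

#' Screen a cohort end to end
#'
#' Convenience wrapper: [classify_criteria()] + [addiction_score()] +
#' [assign_groups()].
#'
#' @param scores CriterionScores tibble.
#' @param config A [screening_config()].
#' @return ScreeningResult tibble (see [assign_groups()]).
#' @export
screen_cohort <- function(scores, config = screening_config()) {
  flags <- classify_criteria(scores, config)
  z <- addiction_score(scores)
  assign_groups(flags, z, config)
}

#' Distribution of criterion counts
#'
#' @param results ScreeningResult tibble.
#' @return A tibble `n_criteria` (0-3), `count`, `pct` (percent of the
#'   cohort, rounded to one decimal).
#' @export
criterion_count_distribution <- function(results) {
  n <- nrow(results)
  counts <- vapply(0:3, function(k) sum(results$n_criteria == k), integer(1))
  tibble::tibble(
    n_criteria = 0:3,
    count = counts,
    pct = round(100 * counts / n, 1)
  )
}
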