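#' Operant session parameters
#'
#' Physical schedule parameters for the self-administration sessions: 30-min
#' FR1 baseline sessions (0.1 mL of 10 percent w/v ethanol per press, 4-s
#' timeout), no-drug test sessions of three 8-min available / 4-min signaled
#' unavailable cycles (36 min total), 90-min progressive-ratio sessions that
#' stop after 20 min of inactivity, and punishment sessions pairing each
#' reward with a 0.22 mA / 0.5 s footshock. Each criterion is tested on 3
#' consecutive daily sessions.
#'
#' `session_noise` scales trial-to-trial variability of the simulated counts:
#' 0 makes every session realize the rat's criterion score exactly, 1 draws
#' Poisson-distributed counts around it (and log-normal jitter on PR session
#' targets).
#'
#' @param baseline_sessions Number of baseline sessions before screening.
#' @param saccharine_sessions How many initial baseline sessions belong to the
#'   saccharine-fading phase.
#' @param baseline_duration_min,fixed_ratio,timeout_s,reward_volume_ml,ethanol_conc_pct_wv
#'   Baseline schedule parameters.
#' @param nodrug_avail_min,nodrug_unavail_min,nodrug_cycles No-drug test
#'   structure; the total must be `cycles * (avail + unavail)` = 36 min.
#' @param pr_max_min,pr_inactivity_stop_min Progressive-ratio session limits.
#' @param shock_mA,shock_s Punishment parameters.
#' @param test_sessions_per_criterion Consecutive daily test sessions averaged
#'   per criterion.
#' @param session_noise Non-negative noise scale (see Details).
#' @return An object of class `session_config`.
#' @export
session_config <- function(baseline_sessions = 80,
                           saccharine_sessions = 14,
                           baseline_duration_min = 30,
                           fixed_ratio = 1,
                           timeout_s = 4,
                           reward_volume_ml = 0.1,
                           ethanol_conc_pct_wv = 10,
                           nodrug_avail_min = 8,
                           nodrug_unavail_min = 4,
                           nodrug_cycles = 3,
                           pr_max_min = 90,
                           pr_inactivity_stop_min = 20,
                           shock_mA = 0.22,
                           shock_s = 0.5,
                           test_sessions_per_criterion = 3,
                           session_noise = 1) {
  pos <- c(baseline_sessions, baseline_duration_min, fixed_ratio, timeout_s,
           reward_volume_ml, ethanol_conc_pct_wv, nodrug_avail_min,
           nodrug_unavail_min, nodrug_cycles, pr_max_min,
           pr_inactivity_stop_min, shock_mA, shock_s,
           test_sessions_per_criterion)
  if (any(pos <= 0)) {
    stop("all durations, ratios and intensities must be strictly positive.",
         call. = FALSE)
  }
  if (session_noise < 0) {
    stop("`session_noise` must be non-negative.", call. = FALSE)
  }
  if (saccharine_sessions < 0 || saccharine_sessions >= baseline_sessions) {
    stop("`saccharine_sessions` must be in [0, baseline_sessions).",
         call. = FALSE)
  }
  structure(
    list(
      baseline_sessions = as.integer(baseline_sessions),
      saccharine_sessions = as.integer(saccharine_sessions),
      baseline_duration_min = as.numeric(baseline_duration_min),
      fixed_ratio = as.numeric(fixed_ratio),
      timeout_s = as.numeric(timeout_s),
      reward_volume_ml = as.numeric(reward_volume_ml),
      ethanol_conc_pct_wv = as.numeric(ethanol_conc_pct_wv),
      nodrug_avail_min = as.numeric(nodrug_avail_min),
      nodrug_unavail_min = as.numeric(nodrug_unavail_min),
      nodrug_cycles = as.integer(nodrug_cycles),
      nodrug_total_min = as.numeric(nodrug_cycles * (nodrug_avail_min +
                                                       nodrug_unavail_min)),
      pr_max_min = as.numeric(pr_max_min),
      pr_inactivity_stop_min = as.numeric(pr_inactivity_stop_min),
      shock_mA = as.numeric(shock_mA),
      shock_s = as.numeric(shock_s),
      test_sessions_per_criterion = as.integer(test_sessions_per_criterion),
      session_noise = as.numeric(session_noise)
    ),
    class = "session_config"
  )
}

# Count with configurable dispersion around `mean`: noise = 0 returns the mean
# (assumed integer-valued for scores), noise = 1 is Poisson; intermediate
# values shrink Poisson deviations toward the mean.
noisy_count <- function(mean, noise) {
  if (noise == 0) return(as.integer(round(mean)))
  draw <- rpois(length(mean), lambda = mean)
  as.integer(pmax(0, round(mean + noise * (draw - mean))))
}

#' Simulate session-level records for a cohort
#'
#' Emits the raw-data atoms behind the screening: per-rat baseline training
#' sessions (saccharine fading then ethanol, one `whole`-period row each),
#' three no-drug test sessions with one row per 8-min available and 4-min
#' unavailable period, three progressive-ratio test sessions and three
#' punishment test sessions. Baseline ethanol response rates drift slowly,
#' with low-liability rats declining over training and high-liability rats
#' maintaining responding, so late-training presses carry the liability signal
#' while saccharine-phase presses do not.
#'
#' With `session_noise = 0`, 3-session averages reproduce each rat's
#' configured criterion scores exactly; PR sessions are always internally
#' consistent with [pr_ratio_sequence()] (cumulative active presses of a
#' session with k rewards are at least the sum of the first k requirements).
#'
#' @param traits Tibble from [sample_latent_traits()].
#' @param scores Tibble from [simulate_criterion_scores()]; one row per rat in
#'   `traits`.
#' @param sconfig A [session_config()].
#' @param seed Optional integer seed (defaults to a stream derived from
#'   `attr(traits, "seed")` when present, else a fixed stream).
#' @param root_seed Root seed used to derive the session stream; defaults to
#'   the `trait_config` default.
#' @return A tibble of `SessionRecord` rows: `rat_id`, `phase`,
#'   `session_index`, `period`, `active_presses`, `inactive_presses`,
#'   `rewards`, `shocks`.
#' @export
simulate_sessions <- function(traits, scores, sconfig = session_config(),
                              seed = NULL, root_seed = 20170825) {
  missing_rats <- setdiff(traits$rat_id, scores$rat_id)
  if (length(missing_rats) > 0) {
    stop("no criterion scores for rat(s): ",
         paste(missing_rats, collapse = ", "), call. = FALSE)
  }
  scores <- scores[match(traits$rat_id, scores$rat_id), ]
  n <- nrow(traits)
  noise <- sconfig$session_noise
  k_test <- sconfig$test_sessions_per_criterion
  seed <- seed %||% derive_seed(root_seed, "sessions")

  withr::with_seed(seed, {
    ## -- baseline phase ----------------------------------------------------
    n_base <- sconfig$baseline_sessions
    n_sacc <- sconfig$saccharine_sessions
    # saccharine responding: independent of liability
    sacc_base <- exp(log(50) + 0.25 * rnorm(n))
    # ethanol responding: level and slope coupled to liability
    eth_base <- exp(log(45) + 0.20 * (0.5 * traits$liability +
                                        0.87 * rnorm(n)))
    slope <- -0.20 + 0.25 * traits$liability + 0.10 * rnorm(n)

    base_grid <- expand.grid(rat = seq_len(n), session = seq_len(n_base))
    is_sacc <- base_grid$session <= n_sacc
    frac <- (base_grid$session - n_sacc) / (n_base - n_sacc)
    rate <- ifelse(
      is_sacc,
      sacc_base[base_grid$rat],
      eth_base[base_grid$rat] * exp(slope[base_grid$rat] * pmax(frac, 0))
    )
    active <- noisy_count(rate, max(noise, 0))
    baseline <- tibble::tibble(
      rat_id = traits$rat_id[base_grid$rat],
      phase = ifelse(is_sacc, "saccharine_training", "ethanol_training"),
      session_index = base_grid$session,
      period = "whole",
      active_presses = active,
      inactive_presses = noisy_count(rep(3, nrow(base_grid)), noise),
      rewards = active,
      shocks = 0L
    )

    ## -- no-drug test sessions (persistence) -------------------------------
    cyc <- sconfig$nodrug_cycles
    nd_grid <- expand.grid(rat = seq_len(n), session = seq_len(k_test),
                           cycle = seq_len(cyc))
    avail_rate <- pmax(
      eth_base[nd_grid$rat] * sconfig$nodrug_avail_min /
        sconfig$baseline_duration_min, 1)
    avail_active <- noisy_count(avail_rate, noise)
    unavail_active <- noisy_count(scores$persistence[nd_grid$rat], noise)
    nodrug <- tibble::tibble(
      rat_id = rep(traits$rat_id[nd_grid$rat], 2),
      phase = "nodrug_test",
      session_index = rep(nd_grid$session, 2),
      period = rep(c("available", "unavailable"), each = nrow(nd_grid)),
      active_presses = c(avail_active, unavail_active),
      inactive_presses = noisy_count(rep(2, 2 * nrow(nd_grid)), noise),
      rewards = c(avail_active, rep(0L, nrow(nd_grid))),
      shocks = 0L
    )

    ## -- progressive-ratio test sessions (motivation) ----------------------
    pr_grid <- expand.grid(rat = seq_len(n), session = seq_len(k_test))
    target <- scores$breakpoint[pr_grid$rat] *
      exp(noise * 0.15 * rnorm(nrow(pr_grid)))
    bp <- pr_snap(target)
    k <- pr_rewards_for_breakpoint(bp)  # completed ratios this session
    seq_all <- pr_ratio_sequence(max(k, 1) + 1L)
    cum <- cumsum(seq_all)
    completed <- ifelse(k == 0, 0L, cum[pmax(k, 1)])
    next_req <- seq_all[k + 1L]
    partial <- if (noise > 0) {
      as.integer(floor(runif(nrow(pr_grid)) * pmin(next_req - 1, 0.5 *
                                                     next_req)))
    } else {
      0L
    }
    pr <- tibble::tibble(
      rat_id = traits$rat_id[pr_grid$rat],
      phase = "pr_test",
      session_index = pr_grid$session,
      period = "whole",
      active_presses = as.integer(completed + partial),
      inactive_presses = noisy_count(rep(2, nrow(pr_grid)), noise),
      rewards = as.integer(k),
      shocks = 0L
    )

    ## -- punishment test sessions ------------------------------------------
    pu_grid <- expand.grid(rat = seq_len(n), session = seq_len(k_test))
    pu_active <- noisy_count(scores$punished[pu_grid$rat], noise)
    punishment <- tibble::tibble(
      rat_id = traits$rat_id[pu_grid$rat],
      phase = "punishment_test",
      session_index = pu_grid$session,
      period = "whole",
      active_presses = pu_active,
      inactive_presses = noisy_count(rep(2, nrow(pu_grid)), noise),
      rewards = pu_active,
      shocks = pu_active
    )
  })

  out <- dplyr::bind_rows(baseline, nodrug, pr, punishment)
  out <- dplyr::arrange(out, .data$rat_id, .data$phase, .data$session_index)
  out
}
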