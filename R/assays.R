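#' Two-lever choice test configuration
#'
#' The choice test opposes a 10 percent w/v ethanol lever to a saccharine
#' lever whose concentration fades across test blocks
#' (0.2, 0.1, 0.05, 0.025, 0.0125, 0.00625, 0 percent w/v; the final block is
#' plain water). Preference for ethanol rises as saccharine fades; the
#' coupling of preference to addiction liability grows as the alternative
#' loses value, so the vulnerable-resilient gap widens at low concentrations.
#'
#' @param concentrations Saccharine fading ladder (percent w/v, descending).
#' @param base_logits Logit of the mean ethanol preference of a liability-0
#'   rat at each concentration (must be non-decreasing as saccharine fades).
#' @param liability_slope Logit shift per liability SD at the final (water)
#'   block; the shift ramps linearly from 0 at the highest concentration.
#' @param group_effect Multiplier on the liability coupling; 0 removes any
#'   group difference.
#' @param total_presses_mean Mean total presses (both levers) per block.
#' @param noise_sd SD of per-rat-by-block logit noise.
#' @return An object of class `choice_config`.
#' @export
choice_config <- function(concentrations = c(0.2, 0.1, 0.05, 0.025, 0.0125,
                                             0.00625, 0),
                          base_logits = stats::qlogis(c(0.10, 0.13, 0.18,
                                                        0.25, 0.33, 0.42,
                                                        0.50)),
                          liability_slope = 0.9,
                          group_effect = 1,
                          total_presses_mean = 60,
                          noise_sd = 0.4) {
  if (is.unsorted(rev(concentrations))) {
    stop("`concentrations` must be in descending (fading) order.",
         call. = FALSE)
  }
  if (length(base_logits) != length(concentrations)) {
    stop("`base_logits` must match `concentrations` in length.",
         call. = FALSE)
  }
  structure(
    list(concentrations = as.numeric(unlist(concentrations)),
         base_logits = as.numeric(unlist(base_logits)),
         liability_slope = as.numeric(liability_slope),
         group_effect = as.numeric(group_effect),
         total_presses_mean = as.numeric(total_presses_mean),
         noise_sd = as.numeric(noise_sd)),
    class = "choice_config"
  )
}

#' Simulate the ethanol vs saccharine two-choice test
#'
#' @param traits Tibble from [sample_latent_traits()].
#' @param concentrations Optional override of the fading ladder (must be a
#'   subset, in order, of the configured ladder).
#' @param config A [choice_config()].
#' @param seed Optional integer seed.
#' @param root_seed Root seed for the derived stream.
#' @return A tibble with one row per rat and concentration: `rat_id`,
#'   `saccharine_conc_pct_wv`, `ethanol_presses`, `saccharine_presses`,
#'   `preference_pct` (NA, flagged degenerate, when no press was emitted).
#' @export
simulate_choice <- function(traits, concentrations = NULL,
                            config = choice_config(), seed = NULL,
                            root_seed = 20170825) {
  stopifnot(inherits(config, "choice_config"))
  keep <- if (is.null(concentrations)) {
    seq_along(config$concentrations)
  } else {
    idx <- match(concentrations, config$concentrations)
    if (anyNA(idx)) {
      stop("`concentrations` must come from the configured fading ladder.",
           call. = FALSE)
    }
    idx
  }
  n <- nrow(traits)
  k <- length(config$concentrations)
  ramp <- (seq_len(k) - 1) / (k - 1)
  seed <- seed %||% derive_seed(root_seed, "choice")
  grid <- expand.grid(rat = seq_len(n), level = keep)
  withr::with_seed(seed, {
    eta <- config$base_logits[grid$level] +
      config$group_effect * config$liability_slope * ramp[grid$level] *
        traits$liability[grid$rat] +
      config$noise_sd * rnorm(nrow(grid))
    total <- rpois(nrow(grid), config$total_presses_mean)
    eth <- rbinom(nrow(grid), total, stats::plogis(eta))
  })
  out <- tibble::tibble(
    rat_id = traits$rat_id[grid$rat],
    saccharine_conc_pct_wv = config$concentrations[grid$level],
    ethanol_presses = as.integer(eth),
    saccharine_presses = as.integer(total - eth),
    preference_pct = ifelse(total > 0, 100 * eth / total, NA_real_)
  )
  if (anyNA(out$preference_pct)) {
    warning("preference undefined (zero total presses) for ",
            sum(is.na(out$preference_pct)), " record(s); flagged as NA.",
            call. = FALSE)
  }
  dplyr::arrange(out, .data$rat_id,
                 dplyr::desc(.data$saccharine_conc_pct_wv))
}

#' Elevated plus maze configuration
#'
#' Open-arm time declines with the anxiety trait. Defaults are calibrated so
#' that a 59-rat cohort screened into resilient/vulnerable groups reproduces
#' the published group summaries (about 30 vs 12 percent open-arm time) and an
#' unpaired t near 2.6 after the loss of 8 rats.
#'
#' @param open_arm_base Mean open-arm percent for an anxiety-0 rat.
#' @param anxiety_weight Drop in open-arm percent per anxiety SD.
#' @param noise_sd Residual SD (percent points) before clamping to `[0, 100]`.
#' @param n_dropout Rats lost completely at random (technical failure).
#' @return An object of class `epm_config`.
#' @export
epm_config <- function(open_arm_base = 19, anxiety_weight = 28,
                       noise_sd = 15, n_dropout = 8) {
  if (n_dropout < 0 || n_dropout %% 1 != 0) {
    stop("`n_dropout` must be a non-negative integer.", call. = FALSE)
  }
  structure(
    list(open_arm_base = as.numeric(open_arm_base),
         anxiety_weight = as.numeric(anxiety_weight),
         noise_sd = as.numeric(noise_sd), n_dropout = as.integer(n_dropout)),
    class = "epm_config"
  )
}

#' Simulate elevated plus maze open-arm time
#'
#' @param traits Tibble from [sample_latent_traits()].
#' @param config An [epm_config()].
#' @param seed Optional integer seed.
#' @param root_seed Root seed for the derived stream.
#' @return A tibble `rat_id`, `open_arm_pct` in `[0, 100]`; dropped rats carry
#'   NA (missing completely at random).
#' @export
simulate_epm <- function(traits, config = epm_config(), seed = NULL,
                         root_seed = 20170825) {
  stopifnot(inherits(config, "epm_config"))
  n <- nrow(traits)
  if (config$n_dropout >= n) {
    stop("`n_dropout` must be smaller than the cohort size.", call. = FALSE)
  }
  seed <- seed %||% derive_seed(root_seed, "epm")
  withr::with_seed(seed, {
    raw <- config$open_arm_base - config$anxiety_weight * traits$anxiety +
      config$noise_sd * rnorm(n)
    lost <- sample.int(n, config$n_dropout)
  })
  open <- pmin(100, pmax(0, raw))
  open[lost] <- NA_real_
  tibble::tibble(rat_id = traits$rat_id, open_arm_pct = open)
}

#' Blood alcohol level model configuration
#'
#' One-compartment model with first-order absorption and zero-order
#' (capacity-limited) elimination after a single oral gavage:
#' `C(t) = F * dose * (1 - exp(-ka * t)) - k0 * t`, floored at zero. BAL is
#' expressed in g/kg to match the reporting convention of the assay this
#' emulates (g/L is the more common unit; a unit note is attached to the
#' output).
#'
#' @param dose_g_per_kg Gavage dose (default 1 g/kg).
#' @param sample_times_min Sampling times in minutes (sorted, positive).
#' @param absorption_rate First-order absorption rate constant (per min).
#' @param elimination_rate Zero-order elimination slope (g/kg per min).
#' @param bioavailability Fraction of the dose reaching blood.
#' @param subject_sd SD of the per-rat log peak level.
#' @param noise_sd Measurement noise SD (g/kg).
#' @param group_effect Relative shift of peak level per liability SD; 0
#'   reproduces the null group difference.
#' @return An object of class `bal_config`.
#' @export
bal_config <- function(dose_g_per_kg = 1.0,
                       sample_times_min = c(15, 30, 60, 180),
                       absorption_rate = 0.08,
                       elimination_rate = 0.003,
                       bioavailability = 0.8,
                       subject_sd = 0.08,
                       noise_sd = 0.05,
                       group_effect = 0) {
  if (absorption_rate < 0 || elimination_rate < 0) {
    stop("absorption and elimination rates must be non-negative.",
         call. = FALSE)
  }
  if (is.unsorted(sample_times_min) || any(sample_times_min <= 0)) {
    stop("`sample_times_min` must be sorted and strictly positive.",
         call. = FALSE)
  }
  structure(
    list(dose_g_per_kg = as.numeric(dose_g_per_kg),
         sample_times_min = as.numeric(unlist(sample_times_min)),
         absorption_rate = as.numeric(absorption_rate),
         elimination_rate = as.numeric(elimination_rate),
         bioavailability = as.numeric(bioavailability),
         subject_sd = as.numeric(subject_sd),
         noise_sd = as.numeric(noise_sd),
         group_effect = as.numeric(group_effect)),
    class = "bal_config"
  )
}

#' Simulate blood alcohol levels after oral gavage
#'
#' @param traits Tibble from [sample_latent_traits()].
#' @param bconfig A [bal_config()].
#' @param seed Optional integer seed.
#' @param root_seed Root seed for the derived stream.
#' @return A tibble `rat_id`, `time_min`, `bal_g_per_kg` (non-negative), with
#'   attribute `unit_note` recording the unit convention.
#' @export
simulate_bal <- function(traits, bconfig = bal_config(), seed = NULL,
                         root_seed = 20170825) {
  stopifnot(inherits(bconfig, "bal_config"))
  n <- nrow(traits)
  times <- bconfig$sample_times_min
  seed <- seed %||% derive_seed(root_seed, "bal")
  withr::with_seed(seed, {
    peak <- bconfig$bioavailability * bconfig$dose_g_per_kg *
      exp(bconfig$subject_sd * rnorm(n)) *
      (1 + bconfig$group_effect * traits$liability)
    grid <- expand.grid(rat = seq_len(n), t = times)
    conc <- peak[grid$rat] *
      (1 - exp(-bconfig$absorption_rate * grid$t)) -
      bconfig$elimination_rate * grid$t +
      bconfig$noise_sd * rnorm(nrow(grid))
  })
  out <- tibble::tibble(
    rat_id = traits$rat_id[grid$rat],
    time_min = grid$t,
    bal_g_per_kg = pmax(0, conc)
  )
  attr(out, "unit_note") <-
    "BAL expressed in g/kg (reporting convention); g/L is more usual."
  dplyr::arrange(out, .data$rat_id, .data$time_min)
}
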