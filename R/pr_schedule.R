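#' Progressive-ratio response requirements
#'
#' Under a progressive-ratio (PR) schedule the cost of each successive reward
#' grows exponentially: the i-th reward requires
#' `round(5 * exp(0.2 * i) - 5)` active lever presses. The largest requirement
#' an animal completes within a session is its breakpoint, the standard index
#' of motivation for the reinforcer.
#'
#' Rounding is half-away-from-zero and pinned as part of the schedule
#' definition; no element of the progression actually falls on a .5 boundary,
#' so the familiar 1, 2, 4, 6, 9, 12, 15, 20, ... values are insensitive to
#' the convention.
#'
#' @param n_rewards Single non-negative integer: how many requirements to
#'   return.
#' @return Integer vector of length `n_rewards` (empty when `n_rewards = 0`),
#'   strictly increasing from the second element on.
#' @examples
#' pr_ratio_sequence(16)
#' @export
pr_ratio_sequence <- function(n_rewards) {
  if (length(n_rewards) != 1L || is.na(n_rewards) || !is.numeric(n_rewards) ||
      n_rewards < 0 || n_rewards %% 1 != 0) {
    stop("`n_rewards` must be a single non-negative integer.", call. = FALSE)
  }
  n_rewards <- as.integer(n_rewards)
  if (n_rewards == 0L) return(integer(0))
  i <- seq_len(n_rewards)
  as.integer(round_half_away(5 * exp(0.2 * i) - 5))
}

# round-half-away-from-zero (base round() is round-half-even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Largest PR requirement <= x (0 when x < first requirement). Used both to
# realize session breakpoints and to express generated breakpoint scores as
# values the schedule can actually produce.
pr_snap <- function(x) {
  x <- pmax(as.numeric(x), 0)
  n <- ceiling(5 * log((max(x, 1) + 5) / 5)) + 2L
  s <- pr_ratio_sequence(n)
  idx <- findInterval(x, s)
  out <- rep(0L, length(x))
  out[idx > 0] <- s[idx[idx > 0]]
  out
}

# Number of rewards earned when the final completed requirement is b
# (b must be an element of the sequence, or 0).
pr_rewards_for_breakpoint <- function(b) {
  b <- as.numeric(b)
  n <- ceiling(5 * log((max(b, 1) + 5) / 5)) + 2L
  s <- pr_ratio_sequence(n)
  idx <- findInterval(b, s)
  bad <- b > 0 & (idx == 0 | s[pmax(idx, 1)] != b)
  if (any(bad)) {
    stop("breakpoint value(s) not on the progressive-ratio grid: ",
         paste(unique(b[bad]), collapse = ", "), call. = FALSE)
  }
  idx
}
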