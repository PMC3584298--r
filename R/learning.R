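#' Learning schedule
#'
#' Times of repeated learning episodes and their effectiveness. Because the
#' cascade is linear, intensities from separate episodes superpose exactly:
#' saturating learning is deliberately not modelled here. A massed block of
#' several trials within one episode is represented by its effective trial
#' count `massed_factor` (e.g. eight massed foot shocks as effective as 3.34
#' spaced ones), which scales the acquired intensity of that episode before
#' any decline.
#'
#' @param trial_times nondecreasing episode times.
#' @param trials positive integer trial counts per episode (recycled).
#' @param massed_factor effective trial count per episode, in
#'   `[1, trials]` when `trials > 1`; defaults to `trials` (no massed
#'   discount for single trials).
#' @return An object of class `"learning_schedule"`.
#' @examples
#' learning_schedule(trial_times = c(0, 1, 2))             # daily trials
#' learning_schedule(0, trials = 8, massed_factor = 3.34)  # one massed block
#' @export
learning_schedule <- function(trial_times, trials = 1L, massed_factor = NULL) {
  trial_times <- .check_times(trial_times)
  if (is.unsorted(trial_times))
    stop("'trial_times' must be nondecreasing", call. = FALSE)
  k <- length(trial_times)
  trials <- rep_len(as.integer(trials), k)
  if (any(trials < 1L)) stop("'trials' must be positive", call. = FALSE)
  if (is.null(massed_factor)) massed_factor <- as.numeric(trials)
  massed_factor <- rep_len(as.numeric(massed_factor), k)
  if (any(massed_factor <= 0) || any(massed_factor > trials))
    stop("'massed_factor' must lie in (0, trials] per episode",
         call. = FALSE)
  if (any(trials > 1L & massed_factor < 1))
    stop("'massed_factor' must be at least 1 for multi-trial episodes",
         call. = FALSE)
  structure(
    list(trial_times = trial_times, trials = trials,
         massed_factor = massed_factor),
    class = "learning_schedule"
  )
}

#' @export
print.learning_schedule <- function(x, ...) {
  cat("Learning schedule:", length(x$trial_times), "episode(s)\n")
  print(data.frame(time = x$trial_times, trials = x$trials,
                   effective = x$massed_factor))
  invisible(x)
}

#' Accumulated intensity over repeated learning
#'
#' Total chain intensity at test after a schedule of learning episodes: the
#' sum over episodes of the effective trial count times the full-chain
#' intensity at that episode's lag. With `mu2 = 0` this reduces to the
#' familiar sum `r1(lag1) + r1(lag2) + ...` of store-1 intensities.
#'
#' @inheritParams total_intensity
#' @param schedule a [learning_schedule()].
#' @param t_test test time(s), each at or after the last episode.
#' @param lesion optional [lesion_profile()] applied to each episode's chain.
#' @return Accumulated intensities at `t_test`.
#' @examples
#' # daily single trials at days 0, 1, 2, tested on day 2
#' cp <- chain_params(mu = c(0.372, 0), a = c(0.326, 0))
#' acc <- accumulated_intensity(cp, learning_schedule(0:2), t_test = 2)
#' recall_from_intensity(acc)
#' @export
accumulated_intensity <- function(params, schedule, t_test, lesion = NULL) {
  .check_chain(params)
  if (!inherits(schedule, "learning_schedule"))
    stop("'schedule' must be a learning_schedule object", call. = FALSE)
  t_test <- .check_times(t_test)
  if (any(t_test < max(schedule$trial_times)))
    stop("'t_test' must not precede the last learning episode",
         call. = FALSE)
  out <- numeric(length(t_test))
  for (e in seq_along(schedule$trial_times)) {
    lag <- t_test - schedule$trial_times[e]
    out <- out + schedule$massed_factor[e] *
      total_intensity(params, lag, lesion)
  }
  out
}
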