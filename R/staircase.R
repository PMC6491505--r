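#' Configure an adaptive staircase track
#'
#' Transformed up-down rule used for titration: the frequency difference
#' between the base and comparison vibration starts at `initial_delta`,
#' steps up by `step_fraction` of its current value after every incorrect
#' response, and steps down by the same fraction once a tally of
#' `down_count` correct responses has accumulated. The tally persists
#' through incorrect responses ("non-consecutive" rule) and resets only on
#' a step-down.
#'
#' @param initial_delta starting frequency difference in Hz (default 5).
#' @param step_fraction multiplicative step size (default 0.10).
#' @param down_count correct-response tally triggering a step-down
#'   (6 = easy track, 2 = hard track).
#' @param base_frequency base flutter frequency in Hz (default 34).
#' @return a `staircase_config`.
#' @export
staircase_config <- function(initial_delta = 5, step_fraction = 0.10,
                             down_count = 6L, base_frequency = 34) {
  assert_scalar_pos(initial_delta, "initial_delta")
  assert_scalar_pos(base_frequency, "base_frequency")
  if (!is.numeric(step_fraction) || step_fraction <= 0 || step_fraction >= 1)
    stop_invalid("'step_fraction' must lie in (0, 1)")
  if (!is.numeric(down_count) || down_count < 1)
    stop_invalid("'down_count' must be >= 1")
  structure(list(initial_delta = initial_delta,
                 step_fraction = step_fraction,
                 down_count = as.integer(down_count),
                 base_frequency = base_frequency),
            class = "staircase_config")
}

#' Initialise a staircase state
#'
#' @param config a [staircase_config()].
#' @return a `staircase_state` with `delta = initial_delta`, zero tally,
#'   zero trials, and an empty history.
#' @export
staircase_init <- function(config) {
  stopifnot(inherits(config, "staircase_config"))
  structure(list(delta = config$initial_delta, tally = 0L,
                 trial_index = 0L,
                 history = list(delta = numeric(0), correct = logical(0))),
            class = "staircase_state")
}

#' Advance a staircase by one response
#'
#' Incorrect: delta is multiplied by `1 + step_fraction`, tally unchanged.
#' Correct: the tally increments; when it reaches `down_count` the delta is
#' multiplied by `1 - step_fraction` and the tally resets to zero. Steps
#' are multiplicative, so delta stays strictly positive forever.
#'
#' @param state a `staircase_state`.
#' @param correct logical, whether the response was correct.
#' @param config the track's [staircase_config()].
#' @return the updated `staircase_state`.
#' @export
staircase_update <- function(state, correct, config) {
  stopifnot(inherits(state, "staircase_state"),
            inherits(config, "staircase_config"),
            is.logical(correct), length(correct) == 1L, !is.na(correct))
  state$history$delta <- c(state$history$delta, state$delta)
  state$history$correct <- c(state$history$correct, correct)
  state$trial_index <- state$trial_index + 1L
  if (!correct) {
    state$delta <- state$delta * (1 + config$step_fraction)
  } else {
    state$tally <- state$tally + 1L
    if (state$tally >= config$down_count) {
      state$delta <- state$delta * (1 - config$step_fraction)
      state$tally <- 0L
    }
  }
  state
}

#' Drift-balance equilibrium accuracy of a staircase rule
#'
#' For a rule that steps up on every error and down after `m` accumulated
#' correct responses, the delta stops drifting when the expected per-trial
#' rates of up- and down-steps balance: `1 - p = p / m`, giving the
#' asymptotic proportion correct `p = m / (m + 1)`. The hard track (m = 2)
#' therefore converges near 2/3 and the easy track (m = 6) near 6/7.
#'
#' @param down_count the tally size `m`.
#' @return the equilibrium proportion correct.
#' @export
equilibrium_accuracy <- function(down_count) {
  if (!is.numeric(down_count) || any(down_count < 1))
    stop_invalid("'down_count' must be >= 1")
  down_count / (down_count + 1)
}

#' Geometric-mean medium difficulty
#'
#' The medium frequency difference is the geometric mean of the converged
#' easy and hard differences.
#'
#' @param easy_delta,hard_delta converged frequency differences in Hz.
#' @return `sqrt(easy_delta * hard_delta)` in Hz.
#' @export
medium_difference <- function(easy_delta, hard_delta) {
  if (!is.numeric(easy_delta) || !is.numeric(hard_delta) ||
      any(easy_delta <= 0) || any(hard_delta <= 0))
    stop_invalid("deltas must be positive")
  sqrt(easy_delta * hard_delta)
}

#' A cumulative-Gaussian simulated observer for titration
#'
#' Two-interval frequency comparison with independent Gaussian encoding
#' noise of SD `sd` on each percept: the probability of a correct
#' faster-slower judgment at frequency difference `delta` is
#' `pnorm(delta / (sqrt(2) * sd))`. The returned function draws a
#' correct/incorrect response from the ambient RNG stream.
#'
#' @param sd perceptual encoding SD in Hz.
#' @return a function `respond(delta) -> logical`.
#' @export
make_gaussian_observer <- function(sd) {
  assert_scalar_pos(sd, "sd")
  function(delta) runif(1) < pnorm(delta / (sqrt(2) * sd))
}

track_summary <- function(state) {
  n <- state$trial_index
  tail_idx <- seq.int(floor(2 * n / 3) + 1L, n)
  list(converged_delta = exp(mean(log(state$history$delta[tail_idx]))),
       asymptotic_accuracy = mean(state$history$correct[tail_idx]))
}

#' Run the interleaved easy/hard titration procedure
#'
#' Each trial selects the easy or hard track uniformly at random (and
#' randomizes base/comparison presentation order), queries the observer at
#' the track's current delta, and applies [staircase_update()]. Converged
#' deltas are the geometric mean of each track's delta over its final
#' third; the medium difficulty is the geometric mean of the two.
#'
#' @param observer a function `respond(delta) -> logical`, e.g. from
#'   [make_gaussian_observer()].
#' @param config_easy,config_hard the two track configurations.
#' @param n_trials total number of titration trials (>= 50).
#' @param seed integer RNG seed.
#' @return a `titration_result` with `easy_delta`, `hard_delta`,
#'   `medium_delta`, per-track histories and asymptotic accuracies, and a
#'   `short_run` flag set when either track has fewer than 30 trials in
#'   its convergence window.
#' @export
run_titration <- function(observer,
                          config_easy = staircase_config(down_count = 6L),
                          config_hard = staircase_config(down_count = 2L),
                          n_trials = 400L, seed = 1L) {
  stopifnot(is.function(observer))
  if (n_trials < 50) stop_invalid("'n_trials' must be at least 50")
  set.seed(seed)
  tracks <- list(easy = staircase_init(config_easy),
                 hard = staircase_init(config_hard))
  configs <- list(easy = config_easy, hard = config_hard)
  log <- data.frame(trial = seq_len(n_trials), staircase = NA_character_,
                    delta_hz = NA_real_, comparison_first = NA,
                    correct = NA)
  for (i in seq_len(n_trials)) {
    which_track <- if (runif(1) < 0.5) "easy" else "hard"
    comparison_first <- runif(1) < 0.5
    st <- tracks[[which_track]]
    correct <- isTRUE(observer(st$delta))
    log$staircase[i] <- which_track
    log$delta_hz[i] <- st$delta
    log$comparison_first[i] <- comparison_first
    log$correct[i] <- correct
    tracks[[which_track]] <- staircase_update(st, correct,
                                              configs[[which_track]])
  }
  easy <- track_summary(tracks$easy)
  hard <- track_summary(tracks$hard)
  structure(list(
    easy_delta = easy$converged_delta,
    hard_delta = hard$converged_delta,
    medium_delta = medium_difference(easy$converged_delta,
                                     hard$converged_delta),
    easy_accuracy = easy$asymptotic_accuracy,
    hard_accuracy = hard$asymptotic_accuracy,
    easy_track = tracks$easy, hard_track = tracks$hard,
    log = log,
    short_run = min(tracks$easy$trial_index,
                    tracks$hard$trial_index) < 90,
    seed = seed), class = "titration_result")
}

#' @export
print.titration_result <- function(x, ...) {
  cat(sprintf(paste0("<titration> easy %.3f Hz (acc %.3f), hard %.3f Hz ",
                     "(acc %.3f), medium %.3f Hz%s\n"),
              x$easy_delta, x$easy_accuracy, x$hard_delta, x$hard_accuracy,
              x$medium_delta,
              if (x$short_run) " [short run: convergence unreliable]" else ""))
  invisible(x)
}

#' Export titration tracks as CSV
#'
#' One row per trial: trial index, staircase, delta in Hz, correctness.
#'
#' @param result a `titration_result`.
#' @param path output file path.
#' @export
write_titration_csv <- function(result, path) {
  stopifnot(inherits(result, "titration_result"))
  write.csv(result$log[c("trial", "staircase", "delta_hz", "correct")],
            path, row.names = FALSE)
  invisible(path)
}
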