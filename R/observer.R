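#' Parameters of the simulated perceptual observer
#'
#' The observer encodes each vibration as a Gaussian percept whose mean is
#' the true frequency (plus a constant bias) and whose SD combines internal
#' encoding noise with an external component contributed by stimulus
#' roughness. Decisions are made either by precision weighting (the
#' perceived difference is divided by the summed percept SD before being
#' compared to a criterion) or on the raw difference in Hz.
#'
#' @param perceptual_sd internal encoding noise SD in Hz.
#' @param bias constant shift of the first percept in Hz (default 0).
#' @param stim_noise_coupling dimensionless coupling `kappa` mapping
#'   stimulus roughness (in Hz, see [stimulus_noise_hz()]) to added percept
#'   SD (default 1).
#' @param criterion same-different decision criterion `c`: a z-score bound
#'   under the precision-weighted rule, a bound in Hz under the
#'   raw-difference rule.
#' @param rule `"precision_weighted"` (default) or `"raw_difference"`.
#' @return an `observer_params` object.
#' @export
observer_params <- function(perceptual_sd = 1, bias = 0,
                            stim_noise_coupling = 1, criterion = 1.5,
                            rule = c("precision_weighted", "raw_difference")) {
  rule <- match.arg(rule)
  if (perceptual_sd < 0 || stim_noise_coupling < 0 || criterion < 0)
    stop_invalid("perceptual_sd, stim_noise_coupling and criterion must be >= 0")
  structure(list(perceptual_sd = perceptual_sd, bias = bias,
                 stim_noise_coupling = stim_noise_coupling,
                 criterion = criterion, rule = rule),
            class = "observer_params")
}

#' Effective frequency-estimate SD contributed by stimulus roughness
#'
#' A jittered stimulus conveys its frequency through the mean of its
#' roughly `frequency x duration/1000` cycle periods, so the SD of the
#' frequency estimate scales as `noise_fraction x frequency / sqrt(n_cycles)`
#' (the SD of the mean period, propagated to Hz).
#'
#' @param frequency flutter frequency in Hz.
#' @param noise_fraction per-cycle jitter fraction (0 for regular stimuli).
#' @param duration_ms stimulus duration in ms (default 512).
#' @return roughness-induced frequency SD in Hz.
#' @export
stimulus_noise_hz <- function(frequency, noise_fraction, duration_ms = 512) {
  if (noise_fraction == 0) return(0)
  n_cycles <- frequency * duration_ms / 1000
  noise_fraction * frequency / sqrt(n_cycles)
}

#' Encode one stimulus as a Gaussian percept
#'
#' The percept value is drawn from
#' `N(frequency + bias, sqrt(sd_p^2 + kappa^2 s^2))` where `s` is the
#' stimulus-roughness SD in Hz; `known_sd` records the observer's own
#' belief about that SD (the observer knows the stimulus feels rough, not
#' its exact jitter sequence).
#'
#' @param frequency true stimulus frequency in Hz.
#' @param stimulus_noise_sd roughness SD `s` in Hz (0 for regular stimuli).
#' @param params an [observer_params()].
#' @return a `percept`: list with `value` and `known_sd` (both Hz).
#' @export
encode_percept <- function(frequency, stimulus_noise_sd, params) {
  stopifnot(inherits(params, "observer_params"))
  assert_scalar_pos(frequency, "frequency")
  if (stimulus_noise_sd < 0) stop_invalid("stimulus_noise_sd must be >= 0")
  known_sd <- sqrt(params$perceptual_sd^2 +
                     (params$stim_noise_coupling * stimulus_noise_sd)^2)
  value <- frequency + params$bias +
    if (known_sd > 0) rnorm(1, 0, known_sd) else 0
  structure(list(value = value, known_sd = known_sd), class = "percept")
}

#' Faster-slower decision
#'
#' Answers "Is the 2nd vibration faster?" by the sign of the difference of
#' the two percept values; an exact tie is broken by a fair coin. No
#' criterion and no precision enter this decision.
#'
#' @param p1,p2 `percept` objects for the first and second vibration.
#' @return `"yes"` or `"no"`.
#' @export
decide_faster <- function(p1, p2) {
  d <- p2$value - p1$value
  if (d == 0) return(if (runif(1) < 0.5) "yes" else "no")
  if (d > 0) "yes" else "no"
}

#' Same-different decision
#'
#' Answers "Are the vibrations different?". Under the precision-weighted
#' rule the perceived difference is standardized by the combined known SD,
#' `z = |v2 - v1| / sqrt(sd1^2 + sd2^2)`, and "different" is reported when
#' `z` strictly exceeds the criterion; under the raw-difference rule the
#' absolute difference in Hz is compared to the criterion directly.
#' Boundary equality (and the degenerate zero-SD, zero-difference case)
#' resolves conservatively to "no" (same).
#'
#' @param p1,p2 `percept` objects.
#' @param params an [observer_params()] carrying `rule` and `criterion`.
#' @return `"yes"` (different) or `"no"` (same).
#' @export
decide_different <- function(p1, p2, params) {
  stopifnot(inherits(params, "observer_params"))
  adiff <- abs(p2$value - p1$value)
  if (params$rule == "raw_difference")
    return(if (adiff > params$criterion) "yes" else "no")
  denom <- sqrt(p1$known_sd^2 + p2$known_sd^2)
  if (denom == 0) return(if (adiff > 0) "yes" else "no")
  if (adiff / denom > params$criterion) "yes" else "no"
}

#' Simulate an observer over a trial schedule
#'
#' One row per schedule trial. Percepts are drawn independently except on
#' same-noisy trials, where the two stimuli reuse the exact same jitter
#' sequence, so the stimulus-noise component of both percepts is a single
#' common draw (internal noise stays independent). Faster-slower trials
#' are scored against which frequency is truly higher; same-different
#' trials against the truth label.
#'
#' @param schedule a data frame with columns `context`
#'   (`"fast-slow"`/`"same-different"`), `noise` (`"regular"`/`"noisy"`),
#'   `f1`, `f2` (Hz), `truth`, and optionally `noise_fraction`
#'   (default 0.08 on noisy trials).
#' @param params an [observer_params()].
#' @param seed integer RNG seed.
#' @return a `trial_table` data frame with percepts, choices, correctness,
#'   and an `rt` placeholder column (reaction times are not modeled).
#' @export
simulate_session <- function(schedule, params, seed = 1L) {
  stopifnot(inherits(params, "observer_params"), is.data.frame(schedule))
  needed <- c("context", "noise", "f1", "f2", "truth")
  missing_cols <- setdiff(needed, names(schedule))
  if (length(missing_cols))
    stop_invalid("schedule lacks column(s): %s",
                 paste(missing_cols, collapse = ", "))
  n <- nrow(schedule)
  if (n == 0L) stop_invalid("schedule has no trials")
  bad <- which(!schedule$context %in% c("fast-slow", "same-different") |
                 !schedule$noise %in% c("regular", "noisy") |
                 !is.finite(schedule$f1) | !is.finite(schedule$f2) |
                 schedule$f1 <= 0 | schedule$f2 <= 0)
  if (length(bad))
    stop_invalid("malformed schedule row(s): %s",
                 paste(utils::head(bad, 5L), collapse = ", "))
  nf <- schedule$noise_fraction %||% ifelse(schedule$noise == "noisy", 0.08, 0)
  nf[schedule$noise == "regular"] <- 0
  set.seed(seed)
  kap <- params$stim_noise_coupling
  out <- schedule[needed]
  out$percept1 <- out$percept2 <- out$known_sd1 <- out$known_sd2 <- NA_real_
  out$choice <- NA_character_
  out$correct <- NA
  for (i in seq_len(n)) {
    s1 <- stimulus_noise_hz(schedule$f1[i], nf[i])
    s2 <- stimulus_noise_hz(schedule$f2[i], nf[i])
    sd1 <- sqrt(params$perceptual_sd^2 + (kap * s1)^2)
    sd2 <- sqrt(params$perceptual_sd^2 + (kap * s2)^2)
    same_noisy <- schedule$noise[i] == "noisy" &&
      schedule$f1[i] == schedule$f2[i] &&
      identical(schedule$truth[i], "same")
    if (same_noisy) {
      eta <- rnorm(1, 0, kap * s1)  # verbatim stimulus reuse: shared draw
      v1 <- schedule$f1[i] + params$bias + rnorm(1, 0, params$perceptual_sd) + eta
      v2 <- schedule$f2[i] + rnorm(1, 0, params$perceptual_sd) + eta
    } else {
      v1 <- schedule$f1[i] + params$bias + rnorm(1, 0, sd1)
      v2 <- schedule$f2[i] + rnorm(1, 0, sd2)
    }
    p1 <- structure(list(value = v1, known_sd = sd1), class = "percept")
    p2 <- structure(list(value = v2, known_sd = sd2), class = "percept")
    if (schedule$context[i] == "fast-slow") {
      ch <- decide_faster(p1, p2)
      correct <- (ch == "yes") == (schedule$f2[i] > schedule$f1[i])
    } else {
      ch <- decide_different(p1, p2, params)
      correct <- (ch == "yes") == (schedule$truth[i] == "different")
    }
    out$percept1[i] <- v1; out$percept2[i] <- v2
    out$known_sd1[i] <- sd1; out$known_sd2[i] <- sd2
    out$choice[i] <- ch
    out$correct[i] <- correct
  }
  out$rt <- NA_real_
  out$seed <- seed
  out$trial <- seq_len(n)
  class(out) <- c("trial_table", "data.frame")
  out
}

#' Signal-detection sensitivity d'
#'
#' `d' = qnorm(hit_rate) - qnorm(false_alarm_rate)`. Rates of exactly 0 or
#' 1 are corrected to `1/(2N)` and `1 - 1/(2N)`, which requires the trial
#' counts underlying each rate.
#'
#' @param hit_rate,false_alarm_rate proportions in \[0, 1\].
#' @param n_signal,n_noise trial counts behind each rate; required only
#'   when the corresponding rate is exactly 0 or 1.
#' @return the sensitivity d' (dimensionless).
#' @export
dprime <- function(hit_rate, false_alarm_rate, n_signal = NULL,
                   n_noise = n_signal) {
  fix_rate <- function(r, n, label) {
    if (r < 0 || r > 1) stop_invalid("%s must lie in [0, 1]", label)
    if (r == 0 || r == 1) {
      if (is.null(n))
        stop_invalid("%s is %g: trial count needed for edge correction",
                     label, r)
      r <- max(1 / (2 * n), min(1 - 1 / (2 * n), r))
    }
    r
  }
  h <- fix_rate(hit_rate, n_signal, "hit_rate")
  f <- fix_rate(false_alarm_rate, n_noise, "false_alarm_rate")
  qnorm(h) - qnorm(f)
}

#' Accuracy table and noise-by-difference interaction
#'
#' Summarizes a simulated trial table: proportion correct in each
#' noise-by-difference cell of the same-different context, the interaction
#' contrast `(same_noisy - same_regular) - (diff_noisy - diff_regular)`,
#' hit/false-alarm rates, and d' per context (for fast-slow, a hit is a
#' "yes" when f2 is truly faster and a false alarm a "yes" when it is not).
#'
#' @param trials a `trial_table` from [simulate_session()] containing
#'   same-different trials in all four noise-by-difference cells.
#' @return an `accuracy_table` list.
#' @export
cell_accuracies <- function(trials) {
  stopifnot(is.data.frame(trials))
  sd_ctx <- trials[trials$context == "same-different", ]
  cells <- expand.grid(truth = c("same", "different"),
                       noise = c("regular", "noisy"),
                       stringsAsFactors = FALSE)
  acc <- setNames(numeric(4L),
                  paste(cells$truth, cells$noise, sep = "_"))
  for (k in seq_len(nrow(cells))) {
    sel <- sd_ctx$truth == cells$truth[k] & sd_ctx$noise == cells$noise[k]
    if (!any(sel))
      stop_invalid("empty cell: %s x %s", cells$truth[k], cells$noise[k])
    acc[k] <- mean(sd_ctx$correct[sel])
  }
  interaction <- (acc[["same_noisy"]] - acc[["same_regular"]]) -
    (acc[["different_noisy"]] - acc[["different_regular"]])
  n_diff <- sum(sd_ctx$truth == "different")
  n_same <- sum(sd_ctx$truth == "same")
  hit <- mean(sd_ctx$choice[sd_ctx$truth == "different"] == "yes")
  fa <- mean(sd_ctx$choice[sd_ctx$truth == "same"] == "yes")
  d_sd <- dprime(hit, fa, n_signal = n_diff, n_noise = n_same)
  d_fs <- NA_real_
  fs <- trials[trials$context == "fast-slow", ]
  if (nrow(fs) > 0) {
    sig <- fs$f2 > fs$f1
    if (any(sig) && any(!sig))
      d_fs <- dprime(mean(fs$choice[sig] == "yes"),
                     mean(fs$choice[!sig] == "yes"),
                     n_signal = sum(sig), n_noise = sum(!sig))
  }
  structure(list(cell_accuracy = acc, interaction = interaction,
                 hit_rate = hit, false_alarm_rate = fa,
                 dprime_same_different = d_sd, dprime_fast_slow = d_fs,
                 accuracy_fast_slow = if (nrow(fs)) mean(fs$correct) else NA_real_,
                 accuracy_same_different = mean(sd_ctx$correct)),
            class = "accuracy_table")
}

#' @export
print.accuracy_table <- function(x, ...) {
  cat("<accuracy_table> same-different cells (proportion correct):\n")
  print(round(x$cell_accuracy, 3))
  cat(sprintf("interaction contrast: %.3f\n", x$interaction))
  cat(sprintf("hit %.3f, false alarm %.3f, d' same-different %.3f",
              x$hit_rate, x$false_alarm_rate, x$dprime_same_different))
  if (is.finite(x$dprime_fast_slow))
    cat(sprintf(", d' fast-slow %.3f", x$dprime_fast_slow))
  cat("\n")
  invisible(x)
}

#' Export an accuracy table as CSV
#'
#' @param x an `accuracy_table`.
#' @param path output file path.
#' @export
write_accuracy_csv <- function(x, path) {
  stopifnot(inherits(x, "accuracy_table"))
  df <- data.frame(measure = c(names(x$cell_accuracy), "interaction",
                               "hit_rate", "false_alarm_rate",
                               "dprime_same_different", "dprime_fast_slow",
                               "accuracy_fast_slow", "accuracy_same_different"),
                   value = c(unname(x$cell_accuracy), x$interaction,
                             x$hit_rate, x$false_alarm_rate,
                             x$dprime_same_different, x$dprime_fast_slow,
                             x$accuracy_fast_slow, x$accuracy_same_different))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
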