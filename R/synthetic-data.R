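#' Configuration for trial-schedule generation
#'
#' Encodes the trial timing of the task: paired 512 ms stimuli separated
#' by a 600 ms ISI, a 2 s response window after the second stimulus onset,
#' and inter-trial intervals jittered uniformly between 6 and 12 s. The
#' comparison stimulus differs from the 34 Hz base by `delta` Hz and the
#' presentation order is pseudorandomized. In same-different sessions
#' exactly half of the pairs are the same, and same-noisy trials carry
#' identical jitter seeds for both stimuli (verbatim reuse).
#'
#' @param base_frequency base flutter frequency in Hz.
#' @param delta comparison frequency difference in Hz.
#' @param context `"same-different"` or `"fast-slow"`.
#' @param noise_fraction jitter level of noisy stimuli.
#' @param stim_duration,isi,response_window,iti_range timing in s.
#' @param start_time onset of the first trial in s.
#' @return a `schedule_config`.
#' @export
schedule_config <- function(base_frequency = 34, delta = 2,
                            context = c("same-different", "fast-slow"),
                            noise_fraction = 0.08, stim_duration = 0.512,
                            isi = 0.6, response_window = 2,
                            iti_range = c(6, 12), start_time = 10) {
  context <- match.arg(context)
  assert_scalar_pos(base_frequency, "base_frequency")
  assert_scalar_pos(delta, "delta")
  stopifnot(length(iti_range) == 2L, iti_range[1] <= iti_range[2],
            iti_range[1] >= 0, response_window <= 2 + 1e-9)
  structure(list(base_frequency = base_frequency, delta = delta,
                 context = context, noise_fraction = noise_fraction,
                 stim_duration = stim_duration, isi = isi,
                 response_window = response_window, iti_range = iti_range,
                 start_time = start_time),
            class = "schedule_config")
}

#' Generate a trial schedule
#'
#' Produces `n_trials` rows with onsets, per-stimulus onsets/durations,
#' frequencies, condition labels, truth labels, and per-stimulus jitter
#' seeds. Noise (regular/noisy) is balanced exactly; in same-different
#' sessions the same/different split is exactly 50/50 (trial order
#' shuffled); in fast-slow sessions every pair differs and the faster
#' stimulus is equally often first or second.
#'
#' @param n_trials number of trials (>= 1).
#' @param config a [schedule_config()].
#' @param seed integer RNG seed.
#' @return an `event_schedule` data frame.
#' @export
generate_schedule <- function(n_trials, config = schedule_config(),
                              seed = 1L) {
  stopifnot(inherits(config, "schedule_config"))
  if (!is.numeric(n_trials) || n_trials < 1)
    stop_invalid("'n_trials' must be at least 1")
  n_trials <- as.integer(n_trials)
  set.seed(seed)
  half <- floor(n_trials / 2)
  noise <- sample(rep(c("regular", "noisy"), c(n_trials - half, half)))
  if (config$context == "same-different") {
    # exactly half same within each noise condition where possible
    truth <- character(n_trials)
    for (cond in c("regular", "noisy")) {
      idx <- which(noise == cond)
      ns <- floor(length(idx) / 2)
      truth[idx] <- sample(rep(c("different", "same"),
                               c(length(idx) - ns, ns)))
    }
    n_same <- floor(n_trials / 2)
    # rebalance to an exact global 50/50 same/different split
    while (sum(truth == "same") > n_same)
      truth[sample(which(truth == "same"), 1)] <- "different"
    while (sum(truth == "same") < n_same)
      truth[sample(which(truth == "different"), 1)] <- "same"
  } else {
    truth <- sample(rep(c("faster", "slower"),
                        c(ceiling(n_trials / 2), floor(n_trials / 2))))
  }
  base <- config$base_frequency
  comp <- base + config$delta
  f1 <- rep(base, n_trials)
  f2 <- rep(base, n_trials)
  if (config$context == "same-different") {
    diff_idx <- truth == "different"
    comp_first <- runif(sum(diff_idx)) < 0.5
    f1[diff_idx][comp_first] <- comp
    f2[diff_idx][!comp_first] <- comp
  } else {
    f2[truth == "faster"] <- comp
    f1[truth == "slower"] <- comp
  }
  iti <- runif(n_trials, config$iti_range[1], config$iti_range[2])
  trial_span <- 2 * config$stim_duration + config$isi
  onset <- config$start_time +
    c(0, cumsum(trial_span + config$response_window + iti)[-n_trials])
  f1_seed <- vapply(seq_len(n_trials), function(i)
    derive_seed(seed, i, salt = 1L), 0L)
  f2_seed <- vapply(seq_len(n_trials), function(i)
    derive_seed(seed, i, salt = 2L), 0L)
  same_noisy <- noise == "noisy" & truth == "same"
  f2_seed[same_noisy] <- f1_seed[same_noisy]  # verbatim stimulus reuse
  out <- data.frame(
    trial = seq_len(n_trials), onset = onset,
    duration = trial_span,
    f1_onset = onset, f1_duration_ms = config$stim_duration * 1000,
    f2_onset = onset + config$stim_duration + config$isi,
    f2_duration_ms = config$stim_duration * 1000,
    f1 = f1, f2 = f2,
    context = config$context, noise = noise, truth = truth,
    noise_fraction = ifelse(noise == "noisy", config$noise_fraction, 0),
    f1_seed = f1_seed, f2_seed = f2_seed,
    response_deadline = onset + config$stim_duration + config$isi +
      config$response_window,
    stringsAsFactors = FALSE)
  class(out) <- c("event_schedule", "data.frame")
  attr(out, "config") <- config
  attr(out, "seed") <- seed
  out
}

#' Number of trials that fit in a session
#'
#' Uses the expected trial footprint (stimuli + ISI + response window +
#' mean ITI) to size a schedule for a session of given length.
#'
#' @param session_length session duration in s.
#' @param config a [schedule_config()].
#' @return an integer trial count (even, >= 2).
#' @export
trials_for_session <- function(session_length, config = schedule_config()) {
  span <- 2 * config$stim_duration + config$isi + config$response_window +
    mean(config$iti_range)
  n <- floor((session_length - config$start_time - 10) / span)
  max(2L, as.integer(n - n %% 2))
}

#' Write a BIDS-style events TSV
#'
#' Columns `onset`, `duration`, `trial_type` (noise x truth), plus the
#' schedule's extra columns.
#'
#' @param schedule an `event_schedule`.
#' @param path output file path.
#' @export
write_events_tsv <- function(schedule, path) {
  stopifnot(inherits(schedule, "event_schedule"))
  df <- data.frame(onset = schedule$onset, duration = schedule$duration,
                   trial_type = paste(schedule$noise, schedule$truth,
                                      sep = "_"),
                   schedule[setdiff(names(schedule),
                                    c("onset", "duration"))],
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Build DCM input streams from a schedule
#'
#' Three binary streams on a regular `dt` grid: `stim` is on during both
#' stimulus epochs of every trial; `regular` and `different` are
#' trial-spanning boxcars (first stimulus onset to second stimulus offset)
#' on qualifying trials.
#'
#' @param schedule an `event_schedule`.
#' @param dt grid step in s (<= 0.05).
#' @param duration total stream duration in s; defaults to the last trial
#'   end plus 20 s of washout.
#' @return a `dcm_inputs`: list with `dt` and binary matrix `U`
#'   (steps x 3, columns stim/regular/different).
#' @export
build_dcm_inputs <- function(schedule, dt = 0.01, duration = NULL) {
  stopifnot(inherits(schedule, "event_schedule"))
  if (nrow(schedule) == 0L) stop_invalid("schedule has no trials")
  if (dt > 0.05) stop_invalid("dt must be at most 0.05 s")
  stim_dur <- schedule$f1_duration_ms[1] / 1000
  duration <- duration %||% (max(schedule$f2_onset) + stim_dur + 20)
  n_steps <- ceiling(duration / dt)
  U <- matrix(0, n_steps, 3,
              dimnames = list(NULL, c("stim", "regular", "different")))
  mark <- function(col, t0, t1) {
    i0 <- pmax(1L, floor(t0 / dt) + 1L)
    i1 <- pmin(n_steps, ceiling(t1 / dt))
    for (k in seq_along(i0))
      if (i1[k] >= i0[k]) U[i0[k]:i1[k], col] <<- 1
  }
  mark("stim", schedule$f1_onset, schedule$f1_onset + stim_dur)
  mark("stim", schedule$f2_onset, schedule$f2_onset + stim_dur)
  trial_end <- schedule$f2_onset + stim_dur
  reg <- schedule$noise == "regular"
  if (any(reg)) mark("regular", schedule$f1_onset[reg], trial_end[reg])
  dif <- schedule$truth == "different"
  if (any(dif)) mark("different", schedule$f1_onset[dif], trial_end[dif])
  structure(list(dt = dt, U = U, duration = n_steps * dt),
            class = "dcm_inputs")
}

#' Canonical double-gamma HRF kernel
#'
#' Difference of two gamma densities (peak 6 s, undershoot 16 s, ratio
#' 1/6), normalized so the kernel integrates to exactly 1 (`sum(h) * dt
#' = 1`); convolving a boxcar of area a therefore yields a response of
#' integral a.
#'
#' @param dt sampling step in s.
#' @param duration kernel length in s (default 32).
#' @return numeric vector of kernel values.
#' @export
hrf_kernel <- function(dt, duration = 32) {
  t <- seq(0, duration, by = dt)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / (sum(h) * dt)
}

#' Convolve event boxcars with the canonical HRF
#'
#' Builds a boxcar stream from onsets/durations on a `dt` grid and
#' convolves it with [hrf_kernel()]. Used for decision-locked evoked
#' regressors (e.g. a 200 ms boxcar immediately before the response) and
#' for sanity-checking simulated evoked responses.
#'
#' @param onsets,durations event onsets and durations in s.
#' @param dt grid step in s.
#' @param total total stream duration in s.
#' @return numeric vector of length `ceiling(total/dt)`.
#' @export
convolve_hrf <- function(onsets, durations, dt, total) {
  n <- ceiling(total / dt)
  box <- numeric(n)
  durations <- rep(durations, length.out = length(onsets))
  for (k in seq_along(onsets)) {
    i0 <- max(1L, floor(onsets[k] / dt) + 1L)
    i1 <- min(n, ceiling((onsets[k] + durations[k]) / dt))
    if (i1 >= i0) box[i0:i1] <- 1
  }
  h <- hrf_kernel(dt)
  out <- stats::convolve(box, rev(h), type = "open")[seq_len(n)] * dt
  out
}

#' Configuration for synthetic group datasets
#'
#' @param n_subjects number of subjects (default 16).
#' @param session_length session duration in s.
#' @param TR repetition time in s.
#' @param SNR per-region ratio of BOLD signal SD to observation-noise SD.
#' @param between_sd SD of between-subject Gaussian deviations applied to
#'   the group-mean A/B/C/D connection strengths.
#' @param model generating motif name.
#' @param master_seed master seed for hierarchical seeding.
#' @param dt integration/input grid step in s.
#' @param schedule a [schedule_config()] for the per-subject schedules.
#' @return a `group_config`.
#' @export
group_config <- function(n_subjects = 16L, session_length = 360, TR = 2,
                         SNR = 1, between_sd = 0.1, model = "Stork3",
                         master_seed = 1L, dt = 0.02,
                         schedule = schedule_config()) {
  stopifnot(n_subjects >= 2, session_length > 0, TR > 0, SNR > 0,
            between_sd >= 0)
  structure(list(n_subjects = as.integer(n_subjects),
                 session_length = session_length, TR = TR, SNR = SNR,
                 between_sd = between_sd, model = model,
                 master_seed = master_seed, dt = dt, schedule = schedule),
            class = "group_config")
}

sample_subject_params <- function(group_params, model, between_sd) {
  n <- length(model$nodes)
  off <- model$A_mask & !diag(n)
  A <- group_params$A
  A[off] <- A[off] + rnorm(sum(off), 0, between_sd)
  B <- group_params$B
  for (u in seq_along(B)) {
    mk <- model$B_masks[[u]]
    B[[u]][mk] <- B[[u]][mk] + rnorm(sum(mk), 0, between_sd)
  }
  C <- group_params$C
  C[model$C_mask] <- C[model$C_mask] + rnorm(sum(model$C_mask), 0,
                                             between_sd)
  D <- group_params$D
  for (k in seq_along(D)) {
    mk <- model$D_masks[[k]]
    if (any(mk)) D[[k]][mk] <- D[[k]][mk] + rnorm(sum(mk), 0, between_sd)
  }
  make_dcm_params(model, A = A, B = B, C = C, D = D,
                  theta_self = group_params$theta_self)
}

#' Generate a synthetic group dataset with known ground truth
#'
#' For each subject: draws connection strengths as group means plus
#' Gaussian between-subject deviations (resampling unstable draws),
#' generates an event schedule, builds DCM input streams, simulates BOLD
#' through the generating motif with observation noise set per region by
#' the target SNR, and simulates the behavioral trial table with the
#' observer model on the same schedule. Everything is hierarchically
#' seeded: the same master seed reproduces the dataset bit for bit, and
#' each subject is reproducible from its recorded seed alone.
#'
#' @param config a [group_config()].
#' @param model_space result of [build_model_space()].
#' @param model generating motif name (default `config$model`).
#' @param group_params group-mean parameters (default
#'   [default_group_params()] of the motif).
#' @param observer an [observer_params()] for the behavioral simulation.
#' @param hemo a [hemo_params()].
#' @return a `group_dataset`: per-subject list (`schedule`, `inputs`,
#'   `trials`, `bold`, `params`, `seed`) plus group metadata.
#' @export
generate_group <- function(config, model_space, model = config$model,
                           group_params = NULL,
                           observer = observer_params(),
                           hemo = hemo_params()) {
  stopifnot(inherits(config, "group_config"))
  if (!model %in% names(model_space))
    stop_invalid("generating model '%s' is not in the model space", model)
  mod <- model_space[[model]]
  group_params <- group_params %||% default_group_params(mod)
  n_trials <- trials_for_session(config$session_length, config$schedule)
  subjects <- vector("list", config$n_subjects)
  resampled <- 0L
  for (s in seq_len(config$n_subjects)) {
    seed_s <- derive_seed(config$master_seed, s, salt = 7L)
    set.seed(seed_s)
    params <- sample_subject_params(group_params, mod, config$between_sd)
    tries <- 0L
    while (!stability_check(params)$pass) {
      tries <- tries + 1L
      resampled <- resampled + 1L
      if (tries > 50L)
        stop_invalid("could not sample stable parameters for subject %d", s)
      params <- sample_subject_params(group_params, mod, config$between_sd)
    }
    schedule <- generate_schedule(n_trials, config$schedule,
                                  seed = derive_seed(seed_s, 1L, salt = 11L))
    inputs <- build_dcm_inputs(schedule, dt = config$dt,
                               duration = config$session_length)
    clean <- simulate_bold(mod, params, hemo, inputs, TR = config$TR,
                           noise_sd = 0)
    sig_sd <- apply(clean$Y, 2, sd)
    noise_sd <- sig_sd / config$SNR
    noise_seed <- derive_seed(seed_s, 2L, salt = 13L)
    set.seed(noise_seed)
    Y <- clean$Y + matrix(rnorm(length(clean$Y)), nrow(clean$Y),
                          ncol(clean$Y)) %*% diag(noise_sd)
    bold <- structure(list(Y = Y, TR = config$TR, model = mod$name,
                           seed = noise_seed,
                           noise_sd = noise_sd, dt = config$dt),
                      class = "bold_series")
    trials <- simulate_session(schedule, observer,
                               seed = derive_seed(seed_s, 3L, salt = 17L))
    subjects[[s]] <- list(schedule = schedule, inputs = inputs,
                          trials = trials, bold = bold, params = params,
                          noise_sd = noise_sd, seed = seed_s)
  }
  structure(list(subjects = subjects, model = model, config = config,
                 group_params = group_params, resampled = resampled),
            class = "group_dataset")
}

#' @export
print.group_dataset <- function(x, ...) {
  cat(sprintf("<group_dataset> %d subjects from %s, %g s sessions, TR %g s, SNR %g\n",
              length(x$subjects), x$model, x$config$session_length,
              x$config$TR, x$config$SNR))
  invisible(x)
}

#' Write a group dataset to disk
#'
#' One directory per subject with `events.tsv`, `trials.csv`, `bold.csv`
#' and `truth.json` (generating parameters and seeds).
#'
#' @param dataset a `group_dataset`.
#' @param dir output directory (created if needed).
#' @export
write_group_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "group_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in seq_along(dataset$subjects)) {
    sub <- dataset$subjects[[s]]
    sdir <- file.path(dir, sprintf("sub-%02d", s))
    dir.create(sdir, showWarnings = FALSE)
    write_events_tsv(sub$schedule, file.path(sdir, "events.tsv"))
    write.csv(sub$trials, file.path(sdir, "trials.csv"),
              row.names = FALSE)
    write_bold_csv(sub$bold, file.path(sdir, "bold.csv"))
    jsonlite::write_json(
      list(model = dataset$model, seed = sub$seed,
           noise_sd = sub$noise_sd,
           A = sub$params$A, theta_self = sub$params$theta_self,
           B = sub$params$B, C = sub$params$C, D = sub$params$D),
      file.path(sdir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
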