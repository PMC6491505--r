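#' Specify a vibrotactile flutter stimulus
#'
#' Describes one 512 ms flutter stimulus in the 10-50 Hz range. With
#' `noise_fraction = 0` the stimulus is a pure sinusoid ("regular"); with a
#' positive fraction the wavelength of every cycle is independently
#' perturbed by zero-mean Gaussian jitter whose standard deviation is that
#' fraction of the base cycle length ("noisy").
#'
#' @param frequency flutter frequency in Hz (nominally 10-50).
#' @param duration stimulus duration in ms (default 512).
#' @param noise_fraction SD of the per-cycle period jitter as a fraction of
#'   the base period (0 = regular, 0.08 = the standard noisy level).
#' @param sample_rate samples per second; must be at least 20x `frequency`.
#' @param seed optional integer seed for the jitter sequence; storing it is
#'   what allows verbatim stimulus reuse on same-noisy trials.
#' @return an object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(frequency, duration = 512, noise_fraction = 0,
                          sample_rate = 8000, seed = NULL) {
  assert_scalar_pos(frequency, "frequency")
  assert_scalar_pos(duration, "duration")
  assert_scalar_pos(sample_rate, "sample_rate")
  if (!is.numeric(noise_fraction) || length(noise_fraction) != 1L ||
      !is.finite(noise_fraction) || noise_fraction < 0)
    stop_invalid("'noise_fraction' must be a non-negative scalar")
  if (sample_rate < 20 * frequency)
    stop_invalid("sample_rate (%g) must be at least 20 x frequency (%g Hz)",
                 sample_rate, frequency)
  structure(list(frequency = frequency, duration = duration,
                 noise_fraction = noise_fraction, sample_rate = sample_rate,
                 seed = seed),
            class = "stimulus_spec")
}

# Draw per-cycle periods (ms) until their cumulative length covers `duration`.
# Non-positive draws are rejected and redrawn so the generator is total even
# at extreme jitter levels (at 8% jitter a non-positive period has
# probability ~1e-36).
draw_cycle_periods <- function(base_period, noise_fraction, duration) {
  sd_ms <- noise_fraction * base_period
  periods <- numeric(0)
  total <- 0
  while (total < duration) {
    n_need <- max(8L, ceiling((duration - total) / base_period * 1.1) + 4L)
    draw <- base_period + rnorm(n_need, 0, sd_ms)
    bad <- draw <= 0
    while (any(bad)) {
      draw[bad] <- base_period + rnorm(sum(bad), 0, sd_ms)
      bad <- draw <= 0
    }
    periods <- c(periods, draw)
    total <- sum(periods)
  }
  periods
}

synthesize_impl <- function(spec, final_cycle) {
  base_period <- 1000 / spec$frequency
  if (spec$noise_fraction == 0) {
    n_full <- floor(spec$duration / base_period + 1e-9)
    periods <- rep(base_period, n_full + 1L)
  } else {
    if (!is.null(spec$seed)) set.seed(spec$seed)
    periods <- draw_cycle_periods(base_period, spec$noise_fraction,
                                  spec$duration)
  }
  bounds <- cumsum(periods)
  n_full <- sum(bounds <= spec$duration + 1e-9)
  if (final_cycle == "complete") {
    n_keep <- min(n_full + 1L, length(periods))
    duration_out <- cumsum(periods)[n_keep]
    cycle_periods <- periods[seq_len(n_keep)]
  } else {
    duration_out <- spec$duration
    cycle_periods <- periods[seq_len(n_full)]
  }
  n_samples <- round(duration_out * spec$sample_rate / 1000)
  t_ms <- (seq_len(n_samples) - 1) / spec$sample_rate * 1000
  starts <- c(0, cumsum(periods))
  idx <- findInterval(t_ms, starts, rightmost.closed = FALSE)
  idx[idx < 1L] <- 1L
  phase <- (t_ms - starts[idx]) / periods[idx]
  samples <- sin(2 * pi * phase)
  structure(list(samples = samples, sample_rate = spec$sample_rate,
                 cycle_periods = cycle_periods, duration = duration_out,
                 frequency = spec$frequency,
                 noise_fraction = spec$noise_fraction),
            class = "waveform")
}

#' Synthesize a regular (noise-free) flutter stimulus
#'
#' A pure sinusoid at the specified frequency. Each stored cycle period is
#' exactly `1000/frequency` ms; the final partial cycle is truncated at the
#' stimulus duration and excluded from the stored periods.
#'
#' @param spec a [stimulus_spec()] with `noise_fraction = 0`.
#' @param final_cycle `"truncate"` (default) cuts the waveform at exactly
#'   `duration`; `"complete"` extends it so the last cycle finishes, in
#'   which case that cycle's period is also stored.
#' @return a `waveform`: unit-amplitude `samples`, the `sample_rate`, and
#'   `cycle_periods` (ms) of every full cycle.
#' @export
synthesize_regular <- function(spec, final_cycle = c("truncate", "complete")) {
  stopifnot(inherits(spec, "stimulus_spec"))
  final_cycle <- match.arg(final_cycle)
  if (spec$noise_fraction != 0)
    stop_invalid("synthesize_regular() requires noise_fraction = 0")
  synthesize_impl(spec, final_cycle)
}

#' Synthesize a noisy (temporally jittered) flutter stimulus
#'
#' The waveform is a concatenation of full sine cycles. Cycle k has period
#' `T_k = T_base + e_k` with `e_k ~ N(0, noise_fraction * T_base)`,
#' independent across cycles; non-positive draws are rejected and redrawn.
#' Jitter is applied in the period (wavelength) domain, so the expected
#' cycle period equals the base period while the mean instantaneous
#' frequency slightly exceeds the nominal frequency (Jensen's inequality);
#' this is a property of wavelength jitter, not an artifact.
#'
#' @inheritParams synthesize_regular
#' @param spec a [stimulus_spec()] with `noise_fraction > 0`; set its
#'   `seed` for a reproducible jitter sequence.
#' @return a `waveform`; `cycle_periods` holds the generated `T_k`.
#' @export
synthesize_noisy <- function(spec, final_cycle = c("truncate", "complete")) {
  stopifnot(inherits(spec, "stimulus_spec"))
  final_cycle <- match.arg(final_cycle)
  if (spec$noise_fraction <= 0)
    stop_invalid("synthesize_noisy() requires noise_fraction > 0")
  synthesize_impl(spec, final_cycle)
}

#' Cycle statistics of a synthesized waveform
#'
#' Mean and standard deviation of the stored generated cycle periods (not
#' re-estimated from the samples), with the ratio of that SD to the base
#' period. The SD uses the population (divide-by-N) convention, matching
#' the within-stimulus definition of cycle-length variability.
#'
#' @param w a `waveform`.
#' @param base_frequency base frequency in Hz used for `sd_ratio`; defaults
#'   to the waveform's own nominal frequency.
#' @return a list with `mean_period` (ms), `sd_period` (ms), `n_cycles`,
#'   and dimensionless `sd_ratio = sd_period / base period`.
#' @export
cycle_stats <- function(w, base_frequency = w$frequency) {
  stopifnot(inherits(w, "waveform"))
  p <- w$cycle_periods
  if (length(p) == 0L) stop_invalid("waveform has no stored cycle periods")
  assert_scalar_pos(base_frequency, "base_frequency")
  m <- mean(p)
  s <- sqrt(mean((p - m)^2))
  list(mean_period = m, sd_period = s, n_cycles = length(p),
       sd_ratio = s * base_frequency / 1000)
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %g Hz, %.1f ms, %d full cycles, jitter %.3f, %d samples @ %g Hz\n",
              x$frequency, x$duration, length(x$cycle_periods),
              x$noise_fraction, length(x$samples), x$sample_rate))
  invisible(x)
}

#' Export a waveform as CSV (time_s, amplitude)
#'
#' @param w a `waveform`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(w, path) {
  stopifnot(inherits(w, "waveform"))
  df <- data.frame(time_s = (seq_along(w$samples) - 1) / w$sample_rate,
                   amplitude = w$samples)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export the generated cycle periods as CSV
#'
#' @inheritParams write_waveform_csv
#' @export
write_cycle_periods_csv <- function(w, path) {
  stopifnot(inherits(w, "waveform"))
  write.csv(data.frame(cycle = seq_along(w$cycle_periods),
                       period_ms = w$cycle_periods),
            path, row.names = FALSE)
  invisible(path)
}

#' Export a waveform as a single-channel 16-bit PCM WAV file
#'
#' Minimal RIFF/WAVE writer; samples are clipped to \[-1, 1\] and scaled to
#' the 16-bit integer range.
#'
#' @inheritParams write_waveform_csv
#' @export
write_wav <- function(w, path) {
  stopifnot(inherits(w, "waveform"))
  pcm <- as.integer(round(pmin(1, pmax(-1, w$samples)) * 32767))
  n <- length(pcm)
  sr <- as.integer(w$sample_rate)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(sr, con, size = 4, endian = "little")
  writeBin(2L * sr, con, size = 4, endian = "little")  # byte rate
  writeBin(2L, con, size = 2, endian = "little")   # block align
  writeBin(16L, con, size = 2, endian = "little")  # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
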