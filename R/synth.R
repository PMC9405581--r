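#' Sinusoidal noise specification
#'
#' A bank of sinusoids added to a record, each defined by frequency (Hz),
#' amplitude as a fraction of the record's pulsatile (AC) amplitude, and
#' phase (radians). The default reproduces typical measured PPG
#' interference: 20/40/60 Hz tones at 38/59/59% of AC. At the common 120 Hz
#' sampling rate the 60 Hz tone sits exactly at Nyquist, so its default
#' phase is pi/2 (a zero phase would sample only zero crossings).
#'
#' @param frequency Frequencies, Hz.
#' @param fraction Amplitudes as fractions of AC.
#' @param phase Phases, radians.
#' @return An object of class `noise_spec` (a data frame).
#' @export
noise_spec <- function(frequency = c(20, 40, 60),
                       fraction = c(0.38, 0.59, 0.59),
                       phase = c(0, 0, pi / 2)) {
  stopifnot(length(frequency) == length(fraction),
            length(fraction) == length(phase))
  structure(data.frame(frequency = frequency, fraction = fraction,
                       phase = phase),
            class = c("noise_spec", "data.frame"))
}

#' Construct a PPG record
#'
#' @param samples Signal samples.
#' @param fs Sampling frequency, Hz.
#' @param meta Named list of provenance metadata (age, vfm, wavelength, ac,
#'   dc, hr, noise, filter, adc, ...).
#' @return An object of class `ppg_record`.
#' @export
ppg_record <- function(samples, fs, meta = list()) {
  stopifnot(fs > 0)
  structure(list(samples = as.numeric(samples), fs = fs,
                 duration = length(samples) / fs, meta = meta),
            class = "ppg_record")
}

#' @export
print.ppg_record <- function(x, ...) {
  m <- x$meta
  extra <- if (!is.null(m$age))
    sprintf(" (age %.1f, VFM %.2f, %g nm)", m$age, m$vfm, m$wavelength) else ""
  cat(sprintf("PPG record: %d samples @ %g Hz (%.3g s)%s\n",
              length(x$samples), x$fs, x$duration, extra))
  invisible(x)
}

#' @export
plot.ppg_record <- function(x, max_s = 5, ...) {
  n <- min(length(x$samples), ceiling(max_s * x$fs))
  tt <- (seq_len(n) - 1) / x$fs
  graphics::plot(tt, x$samples[seq_len(n)], type = "l",
                 xlab = "time [s]", ylab = "amplitude", ...)
  invisible(x)
}

#' Time axis of a record (0-based: time = index / fs)
#' @param record A [ppg_record()].
#' @export
record_time <- function(record) (seq_along(record$samples) - 1) / record$fs

#' Synthesize a continuous PPG record from a pulse template
#'
#' The template is time-scaled from its native period to the beat period
#' `60/hr`, tiled by concatenation (each sample takes the template value at
#' its phase within the beat; no cross-beat additive overlap) and linearly
#' rescaled so that the record minimum equals `dc` and its peak-to-foot span
#' equals `ac`.
#'
#' @param params A [gaussian_params()] template.
#' @param hr Heart rate, beats per minute.
#' @param fs Sampling frequency, Hz.
#' @param duration Record length, seconds.
#' @param ac,dc Pulsatile span and baseline of the output record (e.g. from
#'   a converged Monte Carlo amplitude grid).
#' @param meta Additional metadata merged into the record.
#' @return A [ppg_record()] whose `meta` records all generation parameters.
#' @export
synthesize_ppg <- function(params, hr = 75, fs = 120, duration = 30,
                           ac = 1, dc = 0, meta = list()) {
  if (hr <= 0 || fs <= 0) stop("hr and fs must be positive")
  if (duration <= 0) stop("duration must be positive")
  period <- 60 / hr
  n <- round(fs * duration)
  n_beat <- fs * period
  if (abs(n_beat - round(n_beat)) < 1e-9) {
    # integral samples per beat: build one beat and tile it exactly
    n_beat <- round(n_beat)
    beat <- gaussian_sum(params,
                         (seq_len(n_beat) - 1) / fs *
                           (params$period / period))
    y <- rep_len(beat, n)
  } else {
    tt <- (seq_len(n) - 1) / fs
    phase <- tt %% period
    y <- gaussian_sum(params, phase * (params$period / period))
  }
  rng <- range(y)
  if (diff(rng) <= 0) stop("template is constant; cannot scale to AC span")
  y <- dc + (y - rng[1]) * (ac / diff(rng))
  ppg_record(y, fs, modifyList(list(hr = hr, duration = duration, ac = ac,
                                    dc = dc, template_period = params$period,
                                    noise = NULL, filter = "none"),
                               meta))
}

#' Add sinusoidal noise to a record
#'
#' Adds `sum_i fraction_i * AC * sin(2 pi f_i t + phase_i)` to the samples.
#' The AC amplitude is taken from the record metadata. Tones at or above the
#' Nyquist frequency are permitted but warned about.
#'
#' @param record A [ppg_record()] with `ac` in its metadata.
#' @param spec A [noise_spec()].
#' @return The noisy record (noise spec recorded in metadata).
#' @export
add_ppg_noise <- function(record, spec = noise_spec()) {
  ac <- record$meta$ac
  if (is.null(ac)) stop("record metadata lacks the AC amplitude")
  if (any(spec$frequency >= record$fs / 2))
    warning("noise tone(s) at or above Nyquist (",
            record$fs / 2, " Hz) will alias")
  tt <- record_time(record)
  y <- record$samples
  for (i in seq_len(nrow(spec)))
    y <- y + spec$fraction[i] * ac *
      sin(2 * pi * spec$frequency[i] * tt + spec$phase[i])
  out <- record
  out$samples <- y
  out$meta$noise <- spec
  out
}
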