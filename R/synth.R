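#' Parameters for a synthetic borer pulse train
#'
#' Feeding larvae produce sparse, impulsive substrate-borne pulses. Recordings
#' of emerald ash borer larvae concentrate spectral energy slightly below
#' 2 kHz and around 17 kHz, so the generator synthesizes each pulse as a sum
#' of exponentially damped sinusoids at the configured carrier frequencies.
#' Pulse rate and duration are not quantified in the literature for these
#' larvae; the defaults are engineering placeholders, not biological claims.
#'
#' @param sample_rate Sampling rate in Hz.
#' @param duration Clip duration in seconds (> 0).
#' @param pulse_rate Mean pulses per second (>= 0).
#' @param pulse_duration_ms Length of each synthesized pulse in milliseconds.
#' @param carrier_bands Carrier center frequencies in Hz; each must be below
#'   the Nyquist frequency.
#' @param band_weights Relative amplitude of each carrier.
#' @param amplitude_jitter Per-pulse amplitude jitter fraction in \[0, 1).
#' @param decay_ms Exponential decay time constant in milliseconds.
#' @param onsets `"poisson"` for a Poisson event process (larval gnawing is
#'   aperiodic) or `"regular"` for a jittered regular grid.
#' @param seed Integer seed; identical parameters and seed give bit-identical
#'   output.
#' @return A `pulse_train_params` object.
#' @export
pulse_train_params <- function(sample_rate = 44100, duration = 5,
                               pulse_rate = 6, pulse_duration_ms = 20,
                               carrier_bands = c(1800, 17000),
                               band_weights = NULL,
                               amplitude_jitter = 0.3, decay_ms = 4,
                               onsets = c("poisson", "regular"), seed = 1L) {
  check_number(sample_rate, "sample_rate", lower = 0, strict_lower = TRUE)
  check_number(duration, "duration", lower = 0, strict_lower = TRUE)
  check_number(pulse_rate, "pulse_rate", lower = 0)
  check_number(pulse_duration_ms, "pulse_duration_ms", lower = 0, strict_lower = TRUE)
  check_number(amplitude_jitter, "amplitude_jitter", lower = 0, upper = 1,
               strict_upper = TRUE)
  check_number(decay_ms, "decay_ms", lower = 0, strict_lower = TRUE)
  if (!is.numeric(carrier_bands) || length(carrier_bands) < 1L) {
    vib_abort("`carrier_bands` must hold at least one frequency",
              "vib_invalid_parameter")
  }
  if (any(carrier_bands >= sample_rate / 2)) {
    vib_abort("carrier frequencies must lie below the Nyquist frequency",
              "vib_invalid_parameter")
  }
  if (is.null(band_weights)) band_weights <- rep(1, length(carrier_bands))
  if (length(band_weights) != length(carrier_bands) || any(band_weights < 0)) {
    vib_abort("`band_weights` must be non-negative, one per carrier",
              "vib_invalid_parameter")
  }
  onsets <- match.arg(onsets)
  structure(list(sample_rate = sample_rate, duration = duration,
                 pulse_rate = pulse_rate,
                 pulse_duration_ms = pulse_duration_ms,
                 carrier_bands = carrier_bands, band_weights = band_weights,
                 amplitude_jitter = amplitude_jitter, decay_ms = decay_ms,
                 onsets = onsets, seed = as.integer(seed)),
            class = "pulse_train_params")
}

#' Generate a synthetic borer pulse train
#'
#' Pulses are exponentially damped multi-carrier bursts placed at Poisson (or
#' jittered-regular) onset times; the result is scaled, if necessary, so no
#' sample exceeds full scale.
#'
#' @param params A [pulse_train_params()] object.
#' @return A [wave_clip()] of the requested duration.
#' @examples
#' clip <- gen_pulse_train(pulse_train_params(duration = 1, seed = 7))
#' @export
gen_pulse_train <- function(params) {
  if (!inherits(params, "pulse_train_params")) {
    vib_abort("`params` must come from pulse_train_params()",
              "vib_invalid_parameter")
  }
  fs <- params$sample_rate
  n <- as.integer(round(params$duration * fs))
  out <- numeric(n)
  pulse_len <- max(1L, as.integer(round(params$pulse_duration_ms / 1000 * fs)))
  tau <- params$decay_ms / 1000
  t_pulse <- (0:(pulse_len - 1L)) / fs
  env <- exp(-t_pulse / tau)
  with_seed(params$seed, {
    onsets <- if (params$onsets == "poisson") {
      k <- stats::rpois(1, params$pulse_rate * params$duration)
      sort(stats::runif(k, 0, params$duration))
    } else {
      if (params$pulse_rate <= 0) numeric(0) else {
        grid <- seq(0, params$duration, by = 1 / params$pulse_rate)
        grid + stats::runif(length(grid), 0, 0.2 / max(params$pulse_rate, 1e-9))
      }
    }
    onsets <- onsets[onsets * fs < n]
    for (t0 in onsets) {
      amp <- 1 + params$amplitude_jitter * stats::runif(1, -1, 1)
      pulse <- numeric(pulse_len)
      for (b in seq_along(params$carrier_bands)) {
        phase <- stats::runif(1, 0, 2 * pi)
        pulse <- pulse + params$band_weights[b] *
          sin(2 * pi * params$carrier_bands[b] * t_pulse + phase)
      }
      pulse <- amp * env * pulse
      i0 <- as.integer(floor(t0 * fs)) + 1L
      i1 <- min(n, i0 + pulse_len - 1L)
      out[i0:i1] <- out[i0:i1] + pulse[seq_len(i1 - i0 + 1L)]
    }
  })
  peak <- if (n) max(abs(out)) else 0
  if (peak > 1) out <- out / peak * 0.99
  wave_clip(out, fs)
}

#' Parameters for a synthetic environmental noise scene
#'
#' Emulates the vibroscape picked up by a trunk-mounted probe: wind (broadband
#' rumble up to ~5 kHz with slow, unpredictable amplitude modulation), bird
#' chirps (frequency-modulated tone bursts between 1.5 and 4 kHz), babble
#' (band-limited chatter below ~1.4 kHz), and a white instrumentation noise
#' floor.
#'
#' @param sample_rate Sampling rate in Hz.
#' @param duration Scene duration in seconds (> 0).
#' @param components Named list; names drawn from `wind`, `bird`, `babble`,
#'   `floor`, each a list with at least `level_db` (RMS level in dB relative
#'   to full scale). At least one component is required.
#' @param seed Integer seed.
#' @return A `noise_scene_params` object.
#' @export
noise_scene_params <- function(sample_rate = 44100, duration = 5,
                               components = list(wind = list(level_db = -20),
                                                 bird = list(level_db = -18),
                                                 babble = list(level_db = -22),
                                                 floor = list(level_db = -40)),
                               seed = 1L) {
  check_number(sample_rate, "sample_rate", lower = 0, strict_lower = TRUE)
  check_number(duration, "duration", lower = 0, strict_lower = TRUE)
  if (!is.list(components) || length(components) == 0L) {
    vib_abort("at least one noise component is required", "vib_invalid_parameter")
  }
  known <- c("wind", "bird", "babble", "floor")
  if (is.null(names(components)) || !all(names(components) %in% known)) {
    vib_abort(sprintf("component names must be among: %s",
                      paste(known, collapse = ", ")), "vib_invalid_parameter")
  }
  structure(list(sample_rate = sample_rate, duration = duration,
                 components = components, seed = as.integer(seed)),
            class = "noise_scene_params")
}

# Component generators; each returns a unit-RMS signal of length n.
synth_floor_component <- function(n, fs) {
  x <- stats::rnorm(n)
  x / sqrt(mean(x^2))
}

synth_wind_component <- function(n, fs, f_hi = 5000) {
  f_hi <- min(f_hi, 0.95 * fs / 2)
  x <- fft_bandpass(stats::rnorm(n), fs, 0, f_hi)
  # slow random amplitude modulation (gusts): low-pass modulator below 2 Hz
  mod <- fft_bandpass(stats::rnorm(n), fs, 0, 2)
  mod <- mod / max(stats::sd(mod), 1e-12)
  gain <- pmax(0.1, 1 + 0.6 * mod)
  x <- x * gain
  x / sqrt(mean(x^2))
}

synth_babble_component <- function(n, fs, f_lo = 80, f_hi = 1400) {
  f_hi <- min(f_hi, 0.95 * fs / 2)
  x <- fft_bandpass(stats::rnorm(n), fs, f_lo, f_hi)
  # syllabic-rate modulation around 4 Hz
  mod <- fft_bandpass(stats::rnorm(n), fs, 0, 6)
  mod <- mod / max(stats::sd(mod), 1e-12)
  x <- x * pmax(0.2, 1 + 0.5 * mod)
  x / sqrt(mean(x^2))
}

synth_bird_component <- function(n, fs, f_lo = 1500, f_hi = 4000) {
  f_hi <- min(f_hi, 0.95 * fs / 2)
  # keep sweep endpoints slightly inside the band so windowing leakage stays in
  lo <- f_lo + 0.03 * (f_hi - f_lo)
  hi <- f_hi - 0.03 * (f_hi - f_lo)
  x <- numeric(n)
  t_cursor <- stats::rexp(1, 8)
  while (TRUE) {
    dur <- stats::runif(1, 0.05, 0.3)           # 50-300 ms chirps
    i0 <- as.integer(floor(t_cursor * fs)) + 1L
    if (i0 > n) break
    len <- min(as.integer(round(dur * fs)), n - i0 + 1L)
    if (len >= 8L) {
      tt <- (0:(len - 1L)) / fs
      f0 <- stats::runif(1, lo, hi)
      f1 <- stats::runif(1, lo, hi)
      sweep <- f0 + (f1 - f0) * tt / max(tt[len], 1e-9)
      phase <- 2 * pi * cumsum(sweep) / fs
      chirp <- sin(phase + stats::runif(1, 0, 2 * pi)) * hann_window(len)
      x[i0:(i0 + len - 1L)] <- x[i0:(i0 + len - 1L)] + chirp
    }
    t_cursor <- t_cursor + dur + stats::rexp(1, 4)
  }
  if (all(x == 0)) {
    # degenerate short scene: place one chirp at the start
    len <- max(8L, min(n, as.integer(round(0.05 * fs))))
    tt <- (0:(len - 1L)) / fs
    sweep <- lo + (hi - lo) * tt / max(tt[len], 1e-9)
    x[1:len] <- sin(2 * pi * cumsum(sweep) / fs) * hann_window(len)
  }
  x / sqrt(mean(x^2))
}

#' Generate a synthetic environmental noise scene
#'
#' Sums the requested components, each scaled to its configured RMS level in
#' dB relative to full scale, then rescales (if needed) so no sample exceeds
#' full scale.
#'
#' @param params A [noise_scene_params()] object.
#' @return A [wave_clip()].
#' @examples
#' scene <- gen_noise_scene(noise_scene_params(
#'   duration = 1, components = list(floor = list(level_db = -30)), seed = 3))
#' @export
gen_noise_scene <- function(params) {
  if (!inherits(params, "noise_scene_params")) {
    vib_abort("`params` must come from noise_scene_params()",
              "vib_invalid_parameter")
  }
  fs <- params$sample_rate
  n <- as.integer(round(params$duration * fs))
  if (n < 1L) vib_abort("duration too short", "vib_invalid_parameter")
  out <- numeric(n)
  with_seed(params$seed, {
    for (name in names(params$components)) {
      comp <- params$components[[name]]
      level_db <- if (!is.null(comp$level_db)) comp$level_db else -20
      target_rms <- 10^(level_db / 20)
      sig <- switch(name,
        floor = synth_floor_component(n, fs),
        wind = synth_wind_component(n, fs,
                 f_hi = if (!is.null(comp$f_hi)) comp$f_hi else 5000),
        babble = synth_babble_component(n, fs,
                 f_lo = if (!is.null(comp$f_lo)) comp$f_lo else 80,
                 f_hi = if (!is.null(comp$f_hi)) comp$f_hi else 1400),
        bird = synth_bird_component(n, fs,
                 f_lo = if (!is.null(comp$f_lo)) comp$f_lo else 1500,
                 f_hi = if (!is.null(comp$f_hi)) comp$f_hi else 4000))
      out <- out + target_rms * sig
    }
  })
  peak <- max(abs(out))
  if (peak > 1) out <- out / peak * 0.99
  wave_clip(out, fs)
}
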