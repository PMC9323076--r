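# Short-time Fourier analysis/resynthesis used by spectral subtraction and the
# multi-resolution STFT loss. A periodic Hann analysis window with hop =
# win_length / 2 gives constant overlap-add weight, which the weighted
# overlap-add resynthesis normalizes explicitly anyway.

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)

# Frame a signal into a win_length x n_frames matrix (no padding; frames that
# would run past the end are not taken).
frame_signal <- function(x, win_length, hop) {
  n <- length(x)
  if (n < win_length) return(NULL)
  starts <- seq(1L, n - win_length + 1L, by = hop)
  idx <- outer(0:(win_length - 1L), starts, "+")
  matrix(x[idx], nrow = win_length)
}

# Complex STFT: returns n_fft x n_frames matrix (all bins).
stft <- function(x, n_fft = 1024L, hop = n_fft %/% 2L, win_length = n_fft) {
  if (win_length > n_fft) {
    vib_abort("win_length must be <= n_fft", "vib_invalid_parameter")
  }
  frames <- frame_signal(x, win_length, hop)
  if (is.null(frames)) {
    vib_abort("signal shorter than one analysis window", "vib_invalid_parameter")
  }
  w <- hann_window(win_length)
  frames <- frames * w
  if (win_length < n_fft) {
    frames <- rbind(frames, matrix(0, n_fft - win_length, ncol(frames)))
  }
  stats::mvfft(frames)
}

# Inverse STFT by plain overlap-add. The analysis frames already carry the
# periodic Hann window, which at hop = win/2 satisfies constant overlap-add
# (w[k] + w[k + win/2] = 1), so interior samples reconstruct exactly without
# a normalization division (which would amplify modified frames where the
# window vanishes).
istft <- function(X, hop, win_length, length_out) {
  n_fft <- nrow(X)
  frames <- Re(stats::mvfft(X, inverse = TRUE)) / n_fft
  frames <- frames[seq_len(win_length), , drop = FALSE]
  n_frames <- ncol(frames)
  total <- (n_frames - 1L) * hop + win_length
  y <- numeric(total)
  for (j in seq_len(n_frames)) {
    seg <- ((j - 1L) * hop + 1L):((j - 1L) * hop + win_length)
    y[seg] <- y[seg] + frames[, j]
  }
  if (length_out <= total) y[seq_len(length_out)] else c(y, numeric(length_out - total))
}

# Brick-wall FFT filter keeping the band [f_lo, f_hi] (Hz). Used by the
# synthetic noise generators, where exact band localization matters more than
# a realizable filter response.
fft_bandpass <- function(x, sample_rate, f_lo, f_hi) {
  n <- length(x)
  X <- stats::fft(x)
  k <- 0:(n - 1)
  freq <- pmin(k, n - k) * sample_rate / n
  X[freq < f_lo | freq > f_hi] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

# Fraction of total spectral energy inside the union of [lo_i, hi_i] bands.
band_energy_fraction <- function(x, sample_rate, bands_lo, bands_hi) {
  n <- length(x)
  X <- abs(stats::fft(x))^2
  k <- 0:(n - 1)
  freq <- pmin(k, n - k) * sample_rate / n
  inside <- rep(FALSE, n)
  for (i in seq_along(bands_lo)) {
    inside <- inside | (freq >= bands_lo[i] & freq <= bands_hi[i])
  }
  sum(X[inside]) / sum(X)
}
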