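#' Signal-to-noise ratio in dB
#'
#' `10 * log10(sum(s^2) / sum((s - s_hat)^2))`, capped at `+/- cap_db`. The
#' denominator is the energy of the squared difference between the clean and
#' enhanced signals; a literal difference-of-squares denominator would not be
#' a valid error energy (it can be negative), so it is never used here.
#'
#' @param s Clean reference waveform (numeric vector or [wave_clip()]).
#' @param s_hat Enhanced/estimated waveform of the same length.
#' @param cap_db Cap applied symmetrically, default 60 dB.
#' @return SNR in dB.
#' @examples
#' snr(c(2, -2, 2, -2), c(1, -1, 1, -1))  # 10*log10(16/4) = 6.0206
#' @export
snr <- function(s, s_hat, cap_db = 60) {
  s <- as_samples(s)
  s_hat <- as_samples(s_hat)
  if (length(s) != length(s_hat) || length(s) == 0L) {
    vib_abort("signals must be non-empty and equal length", "vib_invalid_parameter")
  }
  es <- sum(s^2)
  if (es == 0) vib_abort("clean signal has zero energy", "vib_invalid_parameter")
  ee <- sum((s - s_hat)^2)
  val <- if (ee == 0) Inf else 10 * log10(es / ee)
  min(max(val, -cap_db), cap_db)
}

as_samples <- function(x) {
  if (inherits(x, "wave_clip")) x$samples else as.numeric(x)
}

#' Segmental signal-to-noise ratio in dB
#'
#' The mean over whole non-overlapping frames of the per-frame SNR, with each
#' frame value clamped to `clamp` (default \[-10, 35\] dB, standard practice
#' for segmental measures) before averaging. The trailing partial frame is
#' ignored.
#'
#' @inheritParams snr
#' @param frame_len Frame length in samples (default 1024).
#' @param clamp Length-2 vector of per-frame clamp bounds in dB.
#' @return Segmental SNR in dB.
#' @export
segsnr <- function(s, s_hat, frame_len = 1024L, clamp = c(-10, 35)) {
  s <- as_samples(s)
  s_hat <- as_samples(s_hat)
  if (length(s) != length(s_hat)) {
    vib_abort("signals must be equal length", "vib_invalid_parameter")
  }
  m <- length(s) %/% frame_len
  if (m < 1L) vib_abort("signal shorter than one frame", "vib_invalid_parameter")
  vals <- numeric(m)
  for (j in seq_len(m)) {
    idx <- ((j - 1L) * frame_len + 1L):(j * frame_len)
    es <- sum(s[idx]^2)
    ee <- sum((s[idx] - s_hat[idx])^2)
    v <- if (ee == 0) Inf else if (es == 0) -Inf else 10 * log10(es / ee)
    vals[j] <- min(max(v, clamp[1]), clamp[2])
  }
  mean(vals)
}

# Biased autocorrelation at lags 0..max_lag.
autocorr <- function(x, max_lag) {
  n <- length(x)
  vapply(0:max_lag, function(k) sum(x[1:(n - k)] * x[(1 + k):n]), numeric(1))
}

#' Linear-prediction coefficients by Levinson-Durbin
#'
#' Autocorrelation-method LPC: solves the Toeplitz normal equations by the
#' Levinson-Durbin recursion. The returned vector is monic, `c(1, -a_1, ...,
#' -a_p)`, such that the prediction residual is `x[n] - sum(a_k x[n-k])`.
#' The zero-lag autocorrelation is inflated by 1e-9 to regularize
#' ill-conditioned frames.
#'
#' @param frame Numeric vector, longer than `order`, not all zero.
#' @param order LPC order (default 16, suited to 44.1 kHz frames).
#' @return Numeric vector of length `order + 1` with leading coefficient 1.
#' @export
lpc_coefficients <- function(frame, order = 16L) {
  frame <- as_samples(frame)
  if (length(frame) <= order) {
    vib_abort("frame must be longer than the LPC order", "vib_invalid_parameter")
  }
  if (all(frame == 0)) {
    vib_abort("all-zero frame has no LPC model", "vib_invalid_parameter")
  }
  r <- autocorr(frame, order)
  r[1] <- r[1] * (1 + 1e-9)
  a <- numeric(order)
  e <- r[1]
  for (i in seq_len(order)) {
    acc <- r[i + 1]
    if (i > 1L) acc <- acc - sum(a[1:(i - 1L)] * r[i:2])
    k <- acc / e
    a_new <- a
    a_new[i] <- k
    if (i > 1L) a_new[1:(i - 1L)] <- a[1:(i - 1L)] - k * a[(i - 1L):1]
    a <- a_new
    e <- e * (1 - k^2)
    if (e <= 0) break  # numerically degenerate; coefficients so far stand
  }
  c(1, -a)
}

#' Log-likelihood ratio spectral distance
#'
#' For each whole frame, fits LPC models to the clean and enhanced signals
#' and evaluates `log((a_hat %*% Rx %*% a_hat) / (a %*% Rx %*% a))`, where
#' `Rx` is the clean frame's autocorrelation (Toeplitz) matrix and `a`,
#' `a_hat` the monic LPC coefficient vectors. The clean-frame coefficients
#' minimize this quadratic form over monic vectors, so each frame value is
#' nonnegative and zero only when the all-pole spectra agree. Frames whose
#' clean or enhanced part is all zero are skipped with a warning; the
#' aggregate is the mean over retained frames.
#'
#' @inheritParams segsnr
#' @param order LPC order (default 16).
#' @return Mean LLR (unitless, >= 0 up to rounding).
#' @export
llr <- function(s, s_hat, frame_len = 1024L, order = 16L) {
  s <- as_samples(s)
  s_hat <- as_samples(s_hat)
  if (length(s) != length(s_hat)) {
    vib_abort("signals must be equal length", "vib_invalid_parameter")
  }
  m <- length(s) %/% frame_len
  if (m < 1L) vib_abort("signal shorter than one frame", "vib_invalid_parameter")
  vals <- numeric(0)
  skipped <- 0L
  for (j in seq_len(m)) {
    idx <- ((j - 1L) * frame_len + 1L):(j * frame_len)
    x <- s[idx]
    y <- s_hat[idx]
    if (all(x == 0) || all(y == 0)) {
      skipped <- skipped + 1L
      next
    }
    vals <- c(vals, llr_frame(x, y, order))
  }
  if (skipped > 0L) {
    warning(sprintf("llr: skipped %d degenerate frame(s)", skipped),
            call. = FALSE)
  }
  if (!length(vals)) vib_abort("all frames degenerate", "vib_invalid_parameter")
  mean(vals)
}

llr_frame <- function(x, y, order) {
  a <- lpc_coefficients(x, order)
  a_hat <- lpc_coefficients(y, order)
  r <- autocorr(x, order)
  rx <- stats::toeplitz(r)
  num <- drop(a_hat %*% rx %*% a_hat)
  den <- drop(a %*% rx %*% a)
  log(pmax(num, 1e-300) / pmax(den, 1e-300))
}

#' Evaluate an enhancer over a manifest's test split
#'
#' Enhances every noisy test clip and reports the unweighted mean SNR,
#' segmental SNR, and LLR against the clean references, along with the mean
#' input (unenhanced) SNR so that the improvement `delta_snr_db = snr_db -
#' input_snr_db` is available directly.
#'
#' @param manifest A `dataset_manifest` with a non-empty test split.
#' @param model An enhancer model (see [init_enhancer()]), or a function
#'   `wave_clip -> wave_clip` (e.g. `identity` for a pass-through baseline).
#' @param frame_len Frame length for segmental SNR and LLR.
#' @param lpc_order LPC order for LLR.
#' @return A `metric_report` list with `snr_db`, `segsnr_db`, `llr`,
#'   `input_snr_db`, `delta_snr_db`, `n_clips`.
#' @export
evaluate_testset <- function(manifest, model, frame_len = 1024L,
                             lpc_order = 16L) {
  ids <- manifest_split_ids(manifest, "test")
  if (!length(ids)) vib_abort("manifest has no test split", "vib_invalid_parameter")
  apply_model <- if (is.function(model)) {
    model
  } else {
    function(clip) enhance(clip, model)
  }
  acc <- list(snr = 0, seg = 0, llr = 0, input = 0)
  for (id in ids) {
    pair <- manifest_load_pair(manifest, id)
    est <- apply_model(pair$noisy)
    acc$snr <- acc$snr + snr(pair$clean, est)
    acc$seg <- acc$seg + segsnr(pair$clean, est, frame_len)
    acc$llr <- acc$llr + llr(pair$clean, est, frame_len, lpc_order)
    acc$input <- acc$input + snr(pair$clean, pair$noisy)
  }
  n <- length(ids)
  structure(list(snr_db = acc$snr / n, segsnr_db = acc$seg / n,
                 llr = acc$llr / n, input_snr_db = acc$input / n,
                 delta_snr_db = (acc$snr - acc$input) / n, n_clips = n),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "<metric_report: %d clip(s)>\n  SNR     %8.3f dB (input %.3f dB, delta %+.3f dB)\n  SegSNR  %8.3f dB\n  LLR     %8.4f\n",
    x$n_clips, x$snr_db, x$input_snr_db, x$delta_snr_db, x$segsnr_db, x$llr))
  invisible(x)
}
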