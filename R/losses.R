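#' Specify a training objective
#'
#' Six waveform-enhancement objectives are supported: pointwise L1, L2,
#' Huber, and log-cosh losses in the time domain, L1 augmented with an SNR
#' term, and L1 augmented with a multi-resolution STFT loss. Log-cosh behaves
#' like L2 for small errors and L1 for large ones and is the recommended
#' default for this task.
#'
#' @param name One of `"l1"`, `"l2"`, `"huber"`, `"l1_snr"`, `"l1_stft"`,
#'   `"logcosh"`.
#' @param reduction `"mean"` (default; loss magnitude independent of clip
#'   length) or `"sum"` (the literal summed form).
#' @param stft_resolutions For `"l1_stft"`: list of `c(n_fft, hop,
#'   win_length)` triples, one per resolution.
#' @param huber_delta Huber threshold (default 1).
#' @return A `loss_spec` object.
#' @export
loss_spec <- function(name = c("logcosh", "l1", "l2", "huber", "l1_snr", "l1_stft"),
                      reduction = c("mean", "sum"),
                      stft_resolutions = list(c(512, 50, 240),
                                              c(1024, 120, 600),
                                              c(2048, 240, 1200)),
                      huber_delta = 1) {
  name <- match.arg(name)
  reduction <- match.arg(reduction)
  if (name == "l1_stft" && length(stft_resolutions) < 1L) {
    vib_abort("l1_stft needs at least one STFT resolution", "vib_invalid_parameter")
  }
  check_number(huber_delta, "huber_delta", lower = 0, strict_lower = TRUE)
  structure(list(name = name, reduction = reduction,
                 stft_resolutions = stft_resolutions,
                 huber_delta = huber_delta),
            class = "loss_spec")
}

# Numerically stable log(cosh(x)) = |x| - log 2 + log1p(exp(-2|x|)); the
# naive form overflows for |x| beyond ~350.
log_cosh <- function(x) abs(x) - log(2) + log1p(exp(-2 * abs(x)))

#' Compute a training loss (and optionally its gradient)
#'
#' @param y Clean reference waveform.
#' @param y_hat Enhanced waveform, same length.
#' @param spec A [loss_spec()].
#' @param gradient If `TRUE`, also return the gradient with respect to
#'   `y_hat`.
#' @return The scalar loss, or (with `gradient = TRUE`) a list with `value`
#'   and `grad`.
#' @examples
#' compute_loss(c(0, 1), c(0, 1), loss_spec("l1"))  # 0
#' @export
compute_loss <- function(y, y_hat, spec, gradient = FALSE) {
  y <- as_samples(y)
  y_hat <- as_samples(y_hat)
  if (length(y) != length(y_hat) || length(y) == 0L) {
    vib_abort("waveforms must be non-empty and equal length",
              "vib_invalid_parameter")
  }
  n <- length(y)
  e <- y_hat - y
  red <- if (spec$reduction == "mean") n else 1
  base <- switch(spec$name,
    l1 = list(value = sum(abs(e)) / red, grad = sign(e) / red),
    l2 = list(value = sum(e^2) / red, grad = 2 * e / red),
    huber = {
      d <- spec$huber_delta
      small <- abs(e) < d
      v <- ifelse(small, 0.5 * e^2, d * (abs(e) - 0.5 * d))
      g <- ifelse(small, e, d * sign(e))
      list(value = sum(v) / red, grad = g / red)
    },
    logcosh = list(value = sum(log_cosh(e)) / red, grad = tanh(e) / red),
    l1_snr = {
      l1v <- sum(abs(e)) / red
      if (l1v == 0) {
        vib_abort("l1_snr loss undefined for identical signals (log of zero L1)",
                  "vib_invalid_parameter")
      }
      cap <- 60
      snr_raw <- 10 * log10(sum(y^2) / sum(e^2))
      snr_val <- min(max(snr_raw, -cap), cap)
      v <- log(l1v) - snr_val
      g <- (sign(e) / red) / l1v
      if (abs(snr_raw) < cap) {
        g <- g + (10 / log(10)) * 2 * e / sum(e^2)
      }
      list(value = v, grad = g)
    },
    l1_stft = {
      l1v <- sum(abs(e)) / red
      v <- l1v
      g <- sign(e) / red
      for (res in spec$stft_resolutions) {
        term <- stft_loss(y, y_hat, res, gradient = gradient)
        if (gradient) {
          v <- v + term$value
          g <- g + term$grad
        } else {
          v <- v + as.numeric(term)
        }
      }
      list(value = v, grad = g)
    })
  if (gradient) base else base$value
}

#' Single-resolution STFT loss
#'
#' One resolution's term of the multi-resolution STFT objective: the spectral
#' convergence norm `||  |Y| - |Y_hat| ||_F / || |Y| ||_F` plus the mean L1
#' distance between log magnitude spectra.
#'
#' @inheritParams compute_loss
#' @param resolution `c(n_fft, hop, win_length)`.
#' @return The scalar term, or (with `gradient = TRUE`) a list with `value`
#'   and `grad` with respect to `y_hat`.
#' @export
stft_loss <- function(y, y_hat, resolution, gradient = FALSE) {
  y <- as_samples(y)
  y_hat <- as_samples(y_hat)
  n_fft <- as.integer(resolution[1])
  hop <- as.integer(resolution[2])
  win <- as.integer(resolution[3])
  if (win > n_fft) vib_abort("window longer than FFT size", "vib_invalid_parameter")
  if (length(y) < win) {
    vib_abort("clip shorter than one STFT window", "vib_invalid_parameter")
  }
  eps <- 1e-7
  Yc <- stft(y, n_fft, hop, win)
  Hc <- stft(y_hat, n_fft, hop, win)
  Y <- abs(Yc)
  H <- abs(Hc)
  diff_norm <- sqrt(sum((Y - H)^2))
  ref_norm <- sqrt(sum(Y^2))
  sc <- diff_norm / max(ref_norm, 1e-300)
  lm <- mean(abs(log(Y + eps) - log(H + eps)))
  value <- sc + lm
  attr(value, "spectral_convergence") <- sc
  attr(value, "log_magnitude") <- lm
  if (!gradient) return(value)
  # gradient w.r.t. |H|
  g_mag <- (H - Y) / max(diff_norm * ref_norm, 1e-300) +
    (-sign(log(Y + eps) - log(H + eps))) / (length(H) * (H + eps))
  # magnitude -> complex frame -> windowed samples (forward DFT identity)
  hmat <- g_mag * Conj(Hc) / pmax(H, 1e-12)
  gframes <- Re(stats::mvfft(hmat))[seq_len(win), , drop = FALSE]
  w <- hann_window(win)
  grad <- numeric(length(y_hat))
  starts <- seq(1L, length(y_hat) - win + 1L, by = hop)
  for (j in seq_along(starts)) {
    seg <- starts[j]:(starts[j] + win - 1L)
    grad[seg] <- grad[seg] + gframes[, j] * w
  }
  list(value = value, grad = grad)
}
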