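#' Enhancer architecture configuration
#'
#' The denoiser is a U-Net-style waveform mapper: `L` strided convolutional
#' encoder layers (each: strided conv, ReLU, 1x1 channel-doubling conv, GLU),
#' a recurrent sequence-modeling bottleneck over the latent time series, and
#' `L` mirrored decoder layers (skip addition, 1x1 conv, GLU, transposed
#' conv, ReLU except on the last layer, which emits a single channel with no
#' activation). Encoder layer `i` outputs `2^(i-1) * channels` channels, so
#' the latent has `2^(L-1) * channels` channels.
#'
#' @param L Number of encoder/decoder layers (default 5).
#' @param kernel Convolution kernel size K (default 8; must exceed the stride).
#' @param stride Convolution stride S (default 4).
#' @param channels Base channel count Ch (default 48).
#' @param seq_module Sequence bottleneck: `"srupp"` (default), `"sru"`, or
#'   `"lstm"`.
#' @param seq_layers Number of recurrent layers (default 2).
#' @param attention_dim Attention dimension d' for SRU++ (default: a quarter
#'   of the latent channel count; must stay below it).
#' @param normalize Divide each input clip by its standard deviation before
#'   the network and multiply back after (default `TRUE`).
#' @param floor_eps Floor added to the standard deviation so silent clips do
#'   not blow up (default 1e-3).
#' @return An `enhancer_config` object.
#' @export
enhancer_config <- function(L = 5L, kernel = 8L, stride = 4L, channels = 48L,
                            seq_module = c("srupp", "sru", "lstm"),
                            seq_layers = 2L, attention_dim = NULL,
                            normalize = TRUE, floor_eps = 1e-3) {
  check_number(L, "L", lower = 1)
  check_number(kernel, "kernel", lower = 1)
  check_number(stride, "stride", lower = 1)
  check_number(channels, "channels", lower = 1)
  check_number(seq_layers, "seq_layers", lower = 1)
  check_number(floor_eps, "floor_eps", lower = 0, strict_lower = TRUE)
  if (kernel <= stride) {
    vib_abort("kernel must exceed stride", "vib_invalid_parameter")
  }
  seq_module <- match.arg(seq_module)
  latent <- 2L^(as.integer(L) - 1L) * as.integer(channels)
  if (is.null(attention_dim)) attention_dim <- max(1L, latent %/% 4L)
  if (seq_module == "srupp" && attention_dim >= latent) {
    vib_abort("attention_dim must be smaller than the latent channel count",
              "vib_configuration_error")
  }
  structure(list(L = as.integer(L), kernel = as.integer(kernel),
                 stride = as.integer(stride), channels = as.integer(channels),
                 seq_module = seq_module, seq_layers = as.integer(seq_layers),
                 attention_dim = as.integer(attention_dim),
                 normalize = isTRUE(normalize), floor_eps = floor_eps),
            class = "enhancer_config")
}

enc_channels <- function(config, i) 2L^(i - 1L) * config$channels

#' Initialize an enhancer model
#'
#' All convolution weights use Kaiming-style fan-in initialization; gate
#' biases start at zero and every SRU++ attention scalar alpha starts at
#' zero.
#'
#' @param config An [enhancer_config()].
#' @param seed Integer seed for the weight draw.
#' @return An `enhancer_model` with fields `config` and `params`.
#' @export
init_enhancer <- function(config, seed = 1L) {
  if (!inherits(config, "enhancer_config")) {
    vib_abort("`config` must be an enhancer_config", "vib_invalid_parameter")
  }
  K <- config$kernel
  with_seed(seed, {
    enc <- lapply(seq_len(config$L), function(i) {
      c_in <- if (i == 1L) 1L else enc_channels(config, i - 1L)
      c_out <- enc_channels(config, i)
      list(w1 = init_weight(c_out, c_in * K, fan_in = c_in * K),
           b1 = numeric(c_out),
           w2 = init_weight(2L * c_out, c_out, fan_in = c_out),
           b2 = numeric(2L * c_out))
    })
    dec <- lapply(seq_len(config$L), function(i) {
      c_mid <- 2L^(config$L - i) * config$channels
      c_out <- if (i == config$L) 1L else 2L^(config$L - i - 1L) * config$channels
      list(w1 = init_weight(2L * c_mid, c_mid, fan_in = c_mid),
           b1 = numeric(2L * c_mid),
           wt = init_weight(c_out, c_mid * K, fan_in = c_mid * K),
           bt = numeric(c_out))
    })
    latent <- enc_channels(config, config$L)
    seq_params <- lapply(seq_len(config$seq_layers), function(j) {
      switch(config$seq_module,
             srupp = unclass(init_srupp_layer(latent, latent,
                                              config$attention_dim)),
             sru = unclass(init_sru_cell(latent, latent)),
             lstm = init_lstm_layer(latent, latent))
    })
    structure(list(config = config,
                   params = list(enc = enc, seq = seq_params, dec = dec)),
              class = "enhancer_model")
  })
}

#' @export
print.enhancer_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<enhancer_model: L=%d K=%d S=%d Ch=%d, %d-layer %s bottleneck, %d parameters>\n",
    cfg$L, cfg$kernel, cfg$stride, cfg$channels, cfg$seq_layers,
    cfg$seq_module, count_parameters(x)))
  invisible(x)
}

#' Count learnable scalars in a model
#' @param model An `enhancer_model`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(model) {
  as.integer(tree_n_leaves(model$params))
}

#' Smallest admissible padded length
#'
#' The smallest `n' >= n` such that every encoder stage (length map
#' `floor((len - K) / S) + 1`) stays at least one step long and the mirrored
#' decoder (`(len - 1) * S + K` per stage) returns at least `n` samples.
#'
#' @param n Input sample count (>= 1).
#' @param config An [enhancer_config()].
#' @return The padded length `n'`.
#' @export
valid_length <- function(n, config) {
  check_number(n, "n", lower = 1)
  K <- config$kernel
  S <- config$stride
  # minimal input length that keeps every encoder stage >= 1 step
  min_len <- 1
  for (i in seq_len(config$L)) min_len <- (min_len - 1) * S + K
  np <- max(n, min_len)
  repeat {
    len <- np
    ok <- TRUE
    for (i in seq_len(config$L)) {
      len <- (len - K) %/% S + 1L
      if (len < 1L) { ok <- FALSE; break }
    }
    if (ok) {
      for (i in seq_len(config$L)) len <- (len - 1L) * S + K
      if (len >= n) return(as.integer(np))
    }
    np <- np + 1L
  }
}

# ---- forward / backward -----------------------------------------------------

encoder_forward <- function(x, model) {
  cfg <- model$config
  skips <- vector("list", cfg$L)
  caches <- vector("list", cfg$L)
  for (i in seq_len(cfg$L)) {
    p <- model$params$enc[[i]]
    x_dim <- dim(x)
    cv <- conv1d_forward(x, p$w1, p$b1, cfg$kernel, cfg$stride)
    rl <- relu_forward(cv$out)
    pre_glu <- p$w2 %*% rl$out + p$b2
    gl <- glu_forward(pre_glu)
    caches[[i]] <- list(x_dim = x_dim, col = cv$col, relu_mask = rl$mask,
                        relu_out = rl$out, glu = gl)
    x <- gl$out
    skips[[i]] <- x
  }
  list(latent = x, skips = skips, caches = caches)
}

# Encoder backward; `douts` holds the externally arriving gradient for each
# layer's output (skip paths, plus the sequence-module path for layer L).
encoder_backward <- function(douts, caches, model) {
  cfg <- model$config
  grads <- vector("list", cfg$L)
  dx <- NULL
  for (i in rev(seq_len(cfg$L))) {
    dout <- douts[[i]]
    if (!is.null(dx)) dout <- dout + dx
    p <- model$params$enc[[i]]
    cc <- caches[[i]]
    dpre <- glu_backward(dout, cc$glu)
    dw2 <- dpre %*% t(cc$relu_out)
    db2 <- rowSums(dpre)
    drelu <- crossprod(p$w2, dpre)
    dconv <- relu_backward(drelu, cc$relu_mask)
    cb <- conv1d_backward(dconv, cc$col, cc$x_dim, p$w1, cfg$kernel, cfg$stride)
    grads[[i]] <- list(w1 = cb$dweight, b1 = cb$dbias, w2 = dw2, b2 = db2)
    dx <- cb$dx
  }
  list(dx = dx, grads = grads)
}

decoder_forward <- function(x, skips, model) {
  cfg <- model$config
  caches <- vector("list", cfg$L)
  for (i in seq_len(cfg$L)) {
    p <- model$params$dec[[i]]
    skip <- skips[[cfg$L - i + 1L]]
    if (nrow(x) != nrow(skip)) {
      vib_abort("skip connection channel mismatch", "vib_invalid_parameter")
    }
    # floor division in the encoder can leave the decoder stream a little
    # shorter than its skip; add over the common prefix
    t_min <- min(ncol(x), ncol(skip))
    x_sum <- x[, seq_len(t_min), drop = FALSE] +
      skip[, seq_len(t_min), drop = FALSE]
    pre_glu <- p$w1 %*% x_sum + p$b1
    gl <- glu_forward(pre_glu)
    tc <- tconv1d_forward(gl$out, p$wt, p$bt, cfg$kernel, cfg$stride)
    last <- i == cfg$L
    rl <- if (last) NULL else relu_forward(tc)
    caches[[i]] <- list(x_sum = x_sum, glu = gl, t_x = ncol(x),
                        t_skip = ncol(skip), t_min = t_min,
                        relu_mask = if (last) NULL else rl$mask)
    x <- if (last) tc else rl$out
  }
  list(out = x, caches = caches)
}

decoder_backward <- function(dx, caches, model) {
  cfg <- model$config
  grads <- vector("list", cfg$L)
  dskips <- vector("list", cfg$L)
  for (i in rev(seq_len(cfg$L))) {
    p <- model$params$dec[[i]]
    cc <- caches[[i]]
    if (i != cfg$L) dx <- relu_backward(dx, cc$relu_mask)
    tb <- tconv1d_backward(dx, cc$glu$out, p$wt, cfg$kernel, cfg$stride)
    dpre <- glu_backward(tb$dx, cc$glu)
    dw1 <- dpre %*% t(cc$x_sum)
    db1 <- rowSums(dpre)
    dsum <- crossprod(p$w1, dpre)
    grads[[i]] <- list(w1 = dw1, b1 = db1, wt = tb$dweight, bt = tb$dbias)
    dskips[[cfg$L - i + 1L]] <-
      cbind(dsum, matrix(0, nrow(dsum), cc$t_skip - cc$t_min))
    dx <- cbind(dsum, matrix(0, nrow(dsum), cc$t_x - cc$t_min))
  }
  list(dx = dx, grads = grads, dskips = dskips)
}

seq_forward <- function(z, model) {
  cfg <- model$config
  caches <- vector("list", cfg$seq_layers)
  for (j in seq_len(cfg$seq_layers)) {
    p <- model$params$seq[[j]]
    fwd <- switch(cfg$seq_module,
                  srupp = srupp_layer_forward_cached(z, p),
                  sru = sru_layer_forward_cached(z, p),
                  lstm = lstm_layer_forward_cached(z, p))
    caches[[j]] <- fwd$cache
    z <- fwd$H
  }
  list(out = z, caches = caches)
}

seq_backward <- function(dz, caches, model) {
  cfg <- model$config
  grads <- vector("list", cfg$seq_layers)
  for (j in rev(seq_len(cfg$seq_layers))) {
    p <- model$params$seq[[j]]
    bwd <- switch(cfg$seq_module,
                  srupp = srupp_layer_backward(dz, caches[[j]], p),
                  sru = sru_layer_backward(dz, caches[[j]], p),
                  lstm = lstm_layer_backward(dz, caches[[j]], p))
    grads[[j]] <- bwd$dparams
    dz <- bwd$dX
  }
  list(dz = dz, grads = grads)
}

# Full pipeline with cache: normalize -> pad -> encode -> sequence ->
# decode -> trim -> denormalize.
enhancer_forward <- function(samples, model) {
  cfg <- model$config
  n <- length(samples)
  if (n == 0L) vib_abort("empty clip", "vib_invalid_parameter")
  factor <- if (cfg$normalize) stats::sd(samples) + cfg$floor_eps else 1
  vl <- valid_length(n, cfg)
  x <- matrix(c(samples / factor, numeric(vl - n)), nrow = 1L)
  enc <- encoder_forward(x, model)
  sq <- seq_forward(enc$latent, model)
  dec_in <- sq$out
  dec <- decoder_forward(dec_in, enc$skips, model)
  y_full <- dec$out
  y <- y_full[1L, seq_len(n)] * factor
  list(y = y,
       cache = list(n = n, factor = factor, t_full = ncol(y_full),
                    enc = enc$caches, seq = sq$caches, dec = dec$caches))
}

enhancer_backward <- function(dy, cache, model) {
  cfg <- model$config
  dfull <- matrix(0, 1L, cache$t_full)
  dfull[1L, seq_len(cache$n)] <- dy * cache$factor
  dec_b <- decoder_backward(dfull, cache$dec, model)
  # decoder_backward's dx is the gradient into the decoder input, i.e. the
  # sequence-module output; the latent additionally receives the skip-L path.
  sq_b <- seq_backward(dec_b$dx, cache$seq, model)
  douts <- dec_b$dskips
  douts[[cfg$L]] <- douts[[cfg$L]] + sq_b$dz
  enc_b <- encoder_backward(douts, cache$enc, model)
  list(grads = list(enc = enc_b$grads, seq = sq_b$grads, dec = dec_b$grads))
}

#' Encode a padded waveform
#'
#' Runs the convolutional encoder and returns the latent sequence plus every
#' per-layer output (the skip tensors). The input must already be padded to
#' [valid_length()].
#'
#' @param wave Numeric vector (or `1 x T` matrix) of padded samples.
#' @param model An `enhancer_model`.
#' @return A list with `latent` (channels x time) and `skips` (list of L
#'   per-layer outputs; the last one is the latent itself).
#' @export
enhancer_encode <- function(wave, model) {
  x <- if (is.matrix(wave)) wave else matrix(as_samples(wave), nrow = 1L)
  out <- encoder_forward(x, model)
  list(latent = out$latent, skips = out$skips)
}

#' Decode a latent sequence back to a waveform
#'
#' @param latent Channels x time latent (typically the sequence module's
#'   output).
#' @param skips Skip tensors from the matching [enhancer_encode()] call.
#' @param model An `enhancer_model`.
#' @return Numeric vector of decoded samples (single channel, no final
#'   activation, so values may be negative).
#' @export
enhancer_decode <- function(latent, skips, model) {
  drop(decoder_forward(latent, skips, model)$out)
}

#' Enhance a noisy clip
#'
#' @param noisy A [wave_clip()].
#' @param model An `enhancer_model` from [init_enhancer()] or [train()].
#' @return A [wave_clip()] of identical length and sample rate.
#' @export
enhance <- function(noisy, model) {
  check_wave_clip(noisy, "noisy")
  if (!inherits(model, "enhancer_model")) {
    vib_abort("`model` must be an enhancer_model", "vib_invalid_parameter")
  }
  wave_clip(enhancer_forward(noisy$samples, model)$y, noisy$sample_rate)
}
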