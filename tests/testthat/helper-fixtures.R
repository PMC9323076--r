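# Shared fixtures and oracles, all generated in code.

# deterministic white-noise clip
white_clip <- function(n, fs = 8000, sd = 0.1, seed = 1) {
  vibdenoise:::with_seed(seed, wave_clip(stats::rnorm(n, sd = sd), fs))
}

tone_clip <- function(freq, n, fs = 8000, amp = 0.5) {
  wave_clip(amp * sin(2 * pi * freq * (0:(n - 1)) / fs), fs)
}

# central finite-difference gradient of a scalar function
num_grad <- function(f, x, h = 1e-6) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

# tiny configuration used for end-to-end gradient checks
gradcheck_config <- function(seq_module = "srupp") {
  enhancer_config(L = 2, kernel = 5, stride = 2, channels = 2,
                  seq_module = seq_module, seq_layers = 1, attention_dim = 2)
}

# relative error between analytic and numeric parameter gradients of the
# full enhancer pipeline under a given loss
enhancer_gradcheck <- function(config, seed, spec, n = 60) {
  model <- init_enhancer(config, seed = seed)
  if (config$seq_module == "srupp") {
    for (j in seq_along(model$params$seq)) model$params$seq[[j]]$alpha <- 0.3
  }
  vibdenoise:::with_seed(seed + 100, {
    x <- stats::rnorm(n)
    yref <- stats::rnorm(n)
  })
  fwd <- vibdenoise:::enhancer_forward(x, model)
  lg <- compute_loss(yref, fwd$y, spec, gradient = TRUE)
  an <- vibdenoise:::tree_flatten(
    vibdenoise:::enhancer_backward(lg$grad, fwd$cache, model)$grads)
  flat <- vibdenoise:::tree_flatten(model$params)
  loss_at <- function(v) {
    m <- model
    m$params <- vibdenoise:::tree_unflatten(model$params, v)
    compute_loss(yref, vibdenoise:::enhancer_forward(x, m)$y, spec)
  }
  num <- num_grad(loss_at, flat, h = 1e-5)
  max(abs(an - num)) / max(max(abs(num)), 1e-12)
}

# build a small synthetic benchmark dataset in a fresh temp dir
make_micro_dataset <- function(n_pairs = 6, clip_seconds = 0.25, seed = 1,
                               train_fraction = 0.7) {
  dir <- file.path(tempfile("ds"), "data")
  build_synthetic_dataset(n_pairs, dir, clip_seconds = clip_seconds,
                          seed = seed, train_fraction = train_fraction)
}
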