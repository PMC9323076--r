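test_that("valid_length matches a brute-force search and is monotone", {
  cfg <- enhancer_config(L = 3, channels = 8)
  brute <- function(n) {
    np <- n
    repeat {
      len <- np
      ok <- TRUE
      for (i in 1:cfg$L) {
        len <- (len - cfg$kernel) %/% cfg$stride + 1
        if (len < 1) { ok <- FALSE; break }
      }
      if (ok) {
        for (i in 1:cfg$L) len <- (len - 1) * cfg$stride + cfg$kernel
        if (len >= n) return(np)
      }
      np <- np + 1
    }
  }
  for (n in c(1, 5, 100, 1000, 4001)) {
    expect_equal(valid_length(n, cfg), brute(n))
  }
  # fixed point: an admissible length maps to itself
  n_adm <- valid_length(1000, cfg)
  expect_equal(valid_length(n_adm, cfg), n_adm)
  # monotonicity
  vals <- vapply(seq(1, 5000, by = 117), function(n) valid_length(n, cfg), 1L)
  expect_true(all(diff(vals) >= 0))
})

test_that("encoder channel progression follows the doubling rule up to the latent", {
  cfg <- enhancer_config(L = 5, channels = 48)
  model <- init_enhancer(cfg, seed = 1)
  n <- valid_length(9000, cfg)
  x <- vibdenoise:::with_seed(2, stats::rnorm(n))
  enc <- enhancer_encode(x, model)
  chans <- vapply(enc$skips, nrow, 1L)
  expect_equal(chans, 48 * 2^(0:4))       # 48 96 192 384 768
  expect_equal(nrow(enc$latent), 768)     # 2^(L-1) * Ch
  # zero input with zero-initialized biases gives a zero latent
  enc0 <- enhancer_encode(numeric(n), model)
  expect_equal(max(abs(enc0$latent)), 0)
})

test_that("decoder mirrors the encoder and its skips are live paths", {
  cfg <- enhancer_config(L = 3, channels = 4)
  model <- init_enhancer(cfg, seed = 3)
  n <- valid_length(600, cfg)
  x <- vibdenoise:::with_seed(4, stats::rnorm(n))
  enc <- enhancer_encode(x, model)
  y <- enhancer_decode(enc$latent, enc$skips, model)
  expect_length(y, n)
  zeroed <- lapply(enc$skips, function(s) s * 0)
  y0 <- enhancer_decode(enc$latent, zeroed, model)
  expect_gt(max(abs(y - y0)), 0)
  # the last decoder layer has no ReLU: outputs take both signs
  expect_true(any(y < 0) && any(y > 0))
  expect_error(enhancer_decode(enc$latent, rev(enc$skips), model),
               class = "vib_invalid_parameter")
})

test_that("enhance preserves length, is deterministic, and respects scaling", {
  cfg <- enhancer_config(L = 3, channels = 8)
  model <- init_enhancer(cfg, seed = 5)
  for (n in c(1000, 4413, 8000)) {
    clip <- white_clip(n, fs = 8000, seed = n)
    out <- enhance(clip, model)
    expect_length(out$samples, n)
    expect_identical(out$samples, enhance(clip, model)$samples)
  }
  # normalization round trip: scaling the input scales the output
  cfg2 <- enhancer_config(L = 3, channels = 8, floor_eps = 1e-9)
  m2 <- init_enhancer(cfg2, seed = 6)
  clip <- white_clip(2000, seed = 7)
  y1 <- enhance(clip, m2)$samples
  y5 <- enhance(wave_clip(clip$samples * 5, 8000), m2)$samples
  expect_equal(y5, 5 * y1, tolerance = 1e-6)
  expect_error(enhance(wave_clip(numeric(0), 8000), model),
               class = "vib_invalid_parameter")
})

test_that("parameter counting matches closed-form layer arithmetic", {
  cfg <- enhancer_config(L = 1, kernel = 8, stride = 4, channels = 48,
                         seq_module = "lstm", seq_layers = 1)
  model <- init_enhancer(cfg, seed = 8)
  # first conv: in=1, out=48, K=8 plus bias = 432 parameters
  expect_equal(length(model$params$enc[[1]]$w1) + length(model$params$enc[[1]]$b1),
               1 * 48 * 8 + 48)
  # conservation: total equals the sum over named submodules
  total <- count_parameters(model)
  parts <- vapply(model$params, vibdenoise:::tree_n_leaves, numeric(1))
  expect_equal(total, sum(parts))
  # doubling Ch roughly quadruples the strided-conv parameter count
  n_conv <- function(ch) {
    m <- init_enhancer(enhancer_config(L = 2, channels = ch,
                                       seq_module = "lstm", seq_layers = 1),
                       seed = 1)
    length(m$params$enc[[2]]$w1)
  }
  expect_equal(n_conv(16) / n_conv(8), 4)
})

test_that("full backward pass matches finite differences for every bottleneck", {
  expect_lt(enhancer_gradcheck(gradcheck_config("srupp"), 31,
                               loss_spec("logcosh")), 1e-5)
  expect_lt(enhancer_gradcheck(gradcheck_config("sru"), 32,
                               loss_spec("l2")), 1e-5)
  expect_lt(enhancer_gradcheck(gradcheck_config("lstm"), 33,
                               loss_spec("l1_stft",
                                         stft_resolutions = list(c(32, 8, 16)))),
            1e-4)
})
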