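test_that("SNR matches hand arithmetic and honors its cap", {
  expect_equal(snr(c(2, -2, 2, -2), c(1, -1, 1, -1)), 10 * log10(4),
               tolerance = 1e-10)
  s <- white_clip(1000)$samples
  expect_equal(snr(s, s), 60)
  expect_equal(snr(s, s, cap_db = 40), 40)
  expect_error(snr(numeric(10), stats::rnorm(10)),
               class = "vib_invalid_parameter")
  expect_error(snr(1:3, 1:4), class = "vib_invalid_parameter")
})

test_that("the error term is the squared difference, not a difference of squares", {
  # with s = (2,...) and s_hat = -s the printed difference-of-squares
  # denominator would be 0 (log10 undefined); the squared difference gives
  # error energy 4 * sum(s^2)
  s <- c(2, -2, 2, -2)
  expect_equal(snr(s, -s), 10 * log10(sum(s^2) / (4 * sum(s^2))))
})

test_that("segmental SNR reduces to SNR for one frame and clamps correctly", {
  vibdenoise:::with_seed(5, {
    s <- stats::rnorm(1024)
    sh <- s + stats::rnorm(1024, sd = 0.3)
  })
  expect_equal(segsnr(s, sh, frame_len = 1024), snr(s, sh), tolerance = 1e-10)
  expect_equal(segsnr(s, s, frame_len = 256), 35)
  expect_error(segsnr(s[1:100], sh[1:100], frame_len = 1024),
               class = "vib_invalid_parameter")
})

test_that("segmental SNR concentrates around a constant per-frame power ratio", {
  vibdenoise:::with_seed(6, {
    s <- stats::rnorm(64 * 1024)
    e <- stats::rnorm(64 * 1024, sd = sqrt(1 / 10))  # power ratio 10
  })
  expect_equal(segsnr(s, s + e, frame_len = 1024), 10, tolerance = 0.5)
})

test_that("LPC recovers an AR(1) generator and matches a direct Toeplitz solve", {
  vibdenoise:::with_seed(7, {
    n <- 16384
    w <- stats::rnorm(n)
    x <- stats::filter(w, 0.9, method = "recursive")
  })
  a <- lpc_coefficients(as.numeric(x), order = 1)
  expect_equal(a[1], 1)
  expect_equal(a[2], -0.9, tolerance = 0.02)
  # white frame: higher-order coefficients near zero
  wn <- vibdenoise:::with_seed(8, stats::rnorm(4096))
  aw <- lpc_coefficients(wn, order = 8)
  expect_lt(max(abs(aw[-1])), 3 / sqrt(4096))
  # Levinson-Durbin vs generic linear solver on the same normal equations
  frame <- vibdenoise:::with_seed(9, as.numeric(
    stats::filter(stats::rnorm(2048), c(0.5, -0.3), method = "recursive")))
  ord <- 6
  lev <- lpc_coefficients(frame, ord)
  r <- vibdenoise:::autocorr(frame, ord)
  r[1] <- r[1] * (1 + 1e-9)
  direct <- solve(stats::toeplitz(r[1:ord]), r[2:(ord + 1)])
  expect_equal(lev, c(1, -direct), tolerance = 1e-8)
  expect_error(lpc_coefficients(numeric(100), 4),
               class = "vib_invalid_parameter")
  expect_error(lpc_coefficients(stats::rnorm(4), 8),
               class = "vib_invalid_parameter")
})

test_that("LLR is zero at identity, matches the quadratic-form oracle, and is nonnegative", {
  vibdenoise:::with_seed(10, {
    s <- as.numeric(stats::filter(stats::rnorm(4096), 0.8, method = "recursive"))
    sh <- s + stats::rnorm(4096, sd = 0.5)
  })
  expect_equal(llr(s, s, frame_len = 1024, order = 10), 0, tolerance = 1e-9)
  # frame-level oracle: build the full Toeplitz matrix and evaluate both
  # quadratic forms explicitly
  frame_s <- s[1:1024]
  frame_h <- sh[1:1024]
  ord <- 10
  a <- lpc_coefficients(frame_s, ord)
  ah <- lpc_coefficients(frame_h, ord)
  rx <- stats::toeplitz(vibdenoise:::autocorr(frame_s, ord))
  oracle <- log(drop(t(ah) %*% rx %*% ah) / drop(t(a) %*% rx %*% a))
  expect_equal(llr(frame_s, frame_h, frame_len = 1024, order = ord), oracle,
               tolerance = 1e-8)
  # nonnegativity: the clean LPC vector minimizes the form over monic vectors
  vibdenoise:::with_seed(11, {
    for (rep in 1:10) {
      f1 <- as.numeric(stats::filter(stats::rnorm(1024),
                                     stats::runif(1, -0.8, 0.8),
                                     method = "recursive"))
      f2 <- stats::rnorm(1024)
      expect_gte(llr(f1, f2, frame_len = 1024, order = 8), -1e-9)
    }
  })
})

test_that("metrics never leak NaN or infinity", {
  vibdenoise:::with_seed(12, {
    for (rep in 1:5) {
      s <- stats::rnorm(2048) * 10^stats::runif(1, -6, 2)
      sh <- s * stats::runif(1, -2, 2) + stats::rnorm(2048, sd = 1e-8)
      expect_true(is.finite(snr(s, sh)))
      expect_true(is.finite(segsnr(s, sh)))
      expect_true(is.finite(suppressWarnings(llr(s, sh))))
    }
  })
})

test_that("test-set evaluation reports pass-through and oracle baselines", {
  man <- make_micro_dataset(n_pairs = 5, clip_seconds = 0.5, seed = 21,
                            train_fraction = 0.4)
  passthrough <- suppressWarnings(
    evaluate_testset(man, identity, frame_len = 512, lpc_order = 8))
  expect_equal(passthrough$snr_db, -10, tolerance = 0.05)
  expect_equal(passthrough$delta_snr_db, 0, tolerance = 1e-9)
  oracle <- function(noisy) noisy  # replaced below per pair
  # an oracle returning the clean clip achieves the cap and zero LLR
  ids <- vibdenoise:::manifest_split_ids(man, "test")
  cleans <- lapply(ids, function(id) vibdenoise:::manifest_load_pair(man, id)$clean)
  i <- 0
  oracle <- function(noisy) { i <<- i + 1; cleans[[i]] }
  rep2 <- suppressWarnings(
    evaluate_testset(man, oracle, frame_len = 512, lpc_order = 8))
  expect_equal(rep2$snr_db, 60)
  expect_equal(rep2$llr, 0, tolerance = 1e-9)
  expect_error(evaluate_testset(make_micro_dataset(2, seed = 3,
                                                   train_fraction = 0.9),
                                identity),
               class = "vib_invalid_parameter")
})
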