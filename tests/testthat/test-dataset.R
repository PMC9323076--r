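test_that("spectral subtraction attenuates stationary noise by >= 6 dB", {
  fs <- 44100
  clip <- white_clip(fs, fs = fs, sd = 0.1, seed = 10)
  profile <- white_clip(fs, fs = fs, sd = 0.1, seed = 11)
  out <- spectral_subtract(clip, profile)
  expect_length(out$samples, length(clip$samples))
  reduction_db <- 10 * log10(sum(clip$samples^2) / sum(out$samples^2))
  expect_gte(reduction_db, 6)
})

test_that("spectral subtraction passes silence through and preserves tones", {
  fs <- 44100
  profile <- white_clip(fs, fs = fs, sd = 0.1, seed = 11)
  silent <- spectral_subtract(wave_clip(numeric(8000), fs), profile)
  expect_lt(max(abs(silent$samples)), 1e-10)
  tone <- tone_clip(1000, fs, fs = fs, amp = 0.3)
  noisy <- wave_clip(tone$samples + white_clip(fs, fs = fs, sd = 0.1,
                                               seed = 10)$samples, fs)
  out <- spectral_subtract(noisy, profile)
  sp_in <- abs(stats::fft(noisy$samples))
  sp_out <- abs(stats::fft(out$samples))
  bin <- which.max(sp_in[1:(fs %/% 2)])
  expect_lt(abs(20 * log10(sp_out[bin] / sp_in[bin])), 3)
})

test_that("spectral subtraction rejects mismatched or too-short profiles", {
  clip <- white_clip(8000, fs = 8000)
  expect_error(spectral_subtract(clip, white_clip(8000, fs = 44100)),
               class = "vib_invalid_parameter")
  expect_error(spectral_subtract(clip, wave_clip(numeric(100), 8000)),
               class = "vib_invalid_parameter")
})

test_that("top-energy selection keeps the right clips in stable order", {
  mk <- function(amp) wave_clip(rep(amp, 10), 100)
  clips <- list(mk(1), mk(2), mk(sqrt(2)), mk(sqrt(3)))  # energies 10,40,20,30
  kept <- select_top_energy(clips, 0.5)
  expect_equal(vapply(kept, function(c) sum(c$samples^2), 1), c(40, 30),
               tolerance = 1e-12)
  expect_identical(select_top_energy(clips, 1), clips)
  # tie at the cut: earlier-indexed clip wins
  ties <- list(mk(1), mk(2), mk(1), mk(1))
  kept2 <- select_top_energy(ties, 0.5)
  expect_identical(kept2, ties[c(1, 2)])
  expect_error(select_top_energy(list(), 0.5), class = "vib_invalid_parameter")
})

test_that("mixing gain follows the closed form", {
  fs <- 8000
  clean <- tone_clip(500, 4000, fs = fs, amp = 0.1)
  noise <- tone_clip(1250, 4000, fs = fs, amp = 0.1)  # equal power
  pair0 <- vibdenoise:::with_seed(1, mix_at_snr(clean, noise, 0))
  expect_equal(max(abs(pair0$noise$samples)) / max(abs(noise$samples)), 1,
               tolerance = 1e-9)
  pair10 <- vibdenoise:::with_seed(1, mix_at_snr(clean, noise, -10))
  expect_equal(max(abs(pair10$noise$samples)) / max(abs(noise$samples)),
               sqrt(10), tolerance = 1e-9)
  expect_equal(pair10$noisy$samples,
               pair10$clean$samples + pair10$noise$samples)
})

test_that("measured SNR of mixed pairs equals the request within 0.01 dB", {
  vibdenoise:::with_seed(77, {
    for (target in stats::runif(8, -20, 20)) {
      clean <- wave_clip(stats::rnorm(3000) * 0.05, 8000)
      noise <- wave_clip(stats::rnorm(5000) * 0.2, 8000)   # longer: crop path
      pair <- mix_at_snr(clean, noise, target)
      expect_equal(snr(pair$clean, pair$noisy), target, tolerance = 0.01)
      short <- wave_clip(stats::rnorm(1000) * 0.2, 8000)   # shorter: tile path
      pair2 <- mix_at_snr(clean, short, target)
      expect_equal(snr(pair2$clean, pair2$noisy), target, tolerance = 0.01)
    }
  })
})

test_that("mixing rejects degenerate inputs", {
  clean <- white_clip(1000)
  expect_error(mix_at_snr(clean, wave_clip(numeric(1000), 8000), 0),
               class = "vib_invalid_parameter")
  expect_error(mix_at_snr(wave_clip(numeric(1000), 8000), clean, 0),
               class = "vib_invalid_parameter")
  expect_error(mix_at_snr(clean, white_clip(1000, fs = 44100), 0),
               class = "vib_invalid_parameter")
})

test_that("build_dataset splits 94/6, is seeded, and mixes at the target SNR", {
  vibdenoise:::with_seed(5, {
    clean <- lapply(1:25, function(i) wave_clip(stats::rnorm(800) * 0.05, 8000))
    noise <- lapply(1:10, function(i) wave_clip(stats::rnorm(800) * 0.2, 8000))
  })
  dir1 <- tempfile("ds1")
  man <- build_dataset(clean, noise, dir1, snr_db = -10,
                       train_fraction = 0.94, seed = 9)
  train_ids <- vibdenoise:::manifest_split_ids(man, "train")
  test_ids <- vibdenoise:::manifest_split_ids(man, "test")
  expect_length(train_ids, round(0.94 * 25))
  expect_length(test_ids, 25 - round(0.94 * 25))
  expect_length(intersect(train_ids, test_ids), 0)
  # determinism: same inputs + seed -> identical manifest records
  dir2 <- tempfile("ds2")
  man2 <- build_dataset(clean, noise, dir2, snr_db = -10,
                        train_fraction = 0.94, seed = 9)
  expect_identical(man$records, man2$records)
  # re-measure each written pair's SNR from its files
  for (id in c(train_ids[1:3], test_ids[1])) {
    pair <- vibdenoise:::manifest_load_pair(man, id)
    expect_equal(snr(pair$clean, pair$noisy), -10, tolerance = 0.01)
  }
})

test_that("manifests survive a write/read round trip", {
  man <- make_micro_dataset(n_pairs = 4, seed = 3)
  back <- read_manifest(file.path(man$dir, "manifest.tsv"))
  expect_equal(back$records, man$records)
  expect_equal(back$train_fraction, man$train_fraction)
  expect_equal(back$snr_db, man$snr_db)
  pair <- vibdenoise:::manifest_load_pair(back, back$records$id[1])
  expect_s3_class(pair$clean, "wave_clip")
})
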