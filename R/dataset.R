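#' Build a fully synthetic borer-vibration benchmark dataset
#'
#' Convenience wrapper tying the synthetic vibroscape generator to the mixing
#' pipeline: generates `n_pairs` borer pulse-train clips and independent noise
#' scenes, then mixes and writes them with [build_dataset()]. The defaults
#' define the package's desk-scale benchmark condition: 1-second clips at
#' 8 kHz, pulse carriers at 1.8 kHz and (scaled below Nyquist) the high
#' band, babble-plus-floor noise spectrally disjoint from the carriers, and
#' mixing at -10 dB SNR.
#'
#' @param n_pairs Number of clean/noise pairs to synthesize.
#' @param out_dir Output directory for WAVs and `manifest.tsv`.
#' @param sample_rate Sampling rate in Hz (default 8000).
#' @param clip_seconds Clip length in seconds (default 1).
#' @param snr_db Mixing SNR in dB (default -10).
#' @param train_fraction Train split fraction (default 0.94).
#' @param noise_components Component spec passed to [noise_scene_params()];
#'   the default (babble at -12 dB, floor at -34 dB) keeps the noise support
#'   disjoint from the pulse carriers so the denoising task is solvable.
#' @param seed Integer seed governing every clip and the split.
#' @return The `dataset_manifest`.
#' @export
build_synthetic_dataset <- function(n_pairs, out_dir, sample_rate = 8000,
                                    clip_seconds = 1, snr_db = -10,
                                    train_fraction = 0.94,
                                    noise_components = list(
                                      babble = list(level_db = -12),
                                      floor = list(level_db = -34)),
                                    seed = 1L) {
  check_number(n_pairs, "n_pairs", lower = 1)
  carriers <- c(1800, min(17000, 0.425 * sample_rate))
  clean <- lapply(seq_len(n_pairs), function(i) {
    s <- seed * 20000L + i
    repeat {
      clip <- gen_pulse_train(pulse_train_params(
        sample_rate = sample_rate, duration = clip_seconds, pulse_rate = 8,
        carrier_bands = carriers, seed = s))
      # a Poisson draw can yield zero events; silent clips cannot be mixed at
      # a target SNR and are re-drawn (as inactive recordings are discarded)
      if (sum(clip$samples^2) > 0) return(clip)
      s <- s + 7919L
    }
  })
  noise <- lapply(seq_len(n_pairs), function(i) {
    gen_noise_scene(noise_scene_params(
      sample_rate = sample_rate, duration = clip_seconds,
      components = noise_components, seed = seed * 20000L + 10000L + i))
  })
  build_dataset(clean, noise, out_dir, snr_db = snr_db,
                train_fraction = train_fraction, seed = seed)
}

#' Spectral subtraction against a noise-floor profile
#'
#' Classical magnitude-domain denoising used to remove the instrumentation
#' noise floor from recordings before mixing. The clip is analyzed by STFT
#' (Hann window, 50% overlap), the mean magnitude spectrum of `noise_profile`
#' is subtracted (scaled by `oversubtraction`), residual magnitudes are
#' floored at `spectral_floor` times the noise magnitude, and the signal is
#' resynthesized with the noisy phase. Output length equals input length.
#'
#' @param clip A [wave_clip()] to denoise.
#' @param noise_profile A [wave_clip()] holding noise only, at the same
#'   sample rate, at least one analysis frame long.
#' @param oversubtraction Multiplier on the subtracted noise magnitude.
#' @param spectral_floor Floor as a fraction of the noise magnitude.
#' @param n_fft Analysis frame length in samples (Hann window, 50% overlap).
#' @return A [wave_clip()] of the same length and rate.
#' @export
spectral_subtract <- function(clip, noise_profile, oversubtraction = 1.0,
                              spectral_floor = 0.01, n_fft = 1024L) {
  check_wave_clip(clip)
  check_wave_clip(noise_profile, "noise_profile")
  if (clip$sample_rate != noise_profile$sample_rate) {
    vib_abort("clip and noise profile must share a sample rate",
              "vib_invalid_parameter")
  }
  if (length(noise_profile$samples) < n_fft) {
    vib_abort("noise profile shorter than one analysis frame",
              "vib_invalid_parameter")
  }
  hop <- n_fft %/% 2L
  n <- length(clip$samples)
  noise_mag <- rowMeans(abs(stft(noise_profile$samples, n_fft, hop)))
  # pad both sides so every input sample gets full overlap-add weight
  x <- c(numeric(hop), clip$samples, numeric(n_fft))
  X <- stft(x, n_fft, hop)
  mag <- abs(X)
  sub <- pmax(mag - oversubtraction * noise_mag, spectral_floor * noise_mag)
  scale <- sub / pmax(mag, 1e-12)
  Y <- X * scale
  y <- istft(Y, hop, n_fft, n + hop)
  wave_clip(y[(hop + 1L):(hop + n)], clip$sample_rate)
}

#' Keep the highest-energy clips
#'
#' Returns the `ceil(fraction * n)` clips with largest sum-of-squares energy,
#' preserving their original order. Ties at the cut are broken stably in
#' favor of the earlier-indexed clip.
#'
#' @param clips Non-empty list of [wave_clip()] objects.
#' @param fraction Fraction in (0, 1\] of clips to keep.
#' @return The selected subset, in original order.
#' @export
select_top_energy <- function(clips, fraction = 0.5) {
  if (!is.list(clips) || length(clips) == 0L) {
    vib_abort("`clips` must be a non-empty list", "vib_invalid_parameter")
  }
  check_number(fraction, "fraction", lower = 0, upper = 1, strict_lower = TRUE)
  energies <- vapply(clips, function(c) sum(c$samples^2), numeric(1))
  k <- ceiling(fraction * length(clips))
  keep <- sort(order(-energies)[seq_len(k)])  # order() is stable on ties
  clips[keep]
}

#' Mix clean signal and noise at an exact SNR
#'
#' Noise is cropped (if longer) or tiled (if shorter) to the clean clip's
#' length, then scaled by `g = sqrt((sum(clean^2) / sum(noise^2)) *
#' 10^(-snr_db / 10))` so that the measured SNR of the returned pair — by the
#' squared-difference convention of [snr()] — equals `snr_db` exactly. Crop
#' and tile offsets are drawn from the caller's RNG state.
#'
#' @param clean,noise [wave_clip()] objects at the same rate, both with
#'   nonzero energy.
#' @param snr_db Target signal-to-noise ratio in dB.
#' @return A `clip_pair` with fields `clean`, `noise` (the scaled additive
#'   component), `noisy`, and `snr_db`, all equal length.
#' @export
mix_at_snr <- function(clean, noise, snr_db) {
  check_wave_clip(clean, "clean")
  check_wave_clip(noise, "noise")
  check_number(snr_db, "snr_db")
  if (clean$sample_rate != noise$sample_rate) {
    vib_abort("sample-rate mismatch between clean and noise",
              "vib_invalid_parameter")
  }
  n <- length(clean$samples)
  if (n == 0L || sum(clean$samples^2) == 0) {
    vib_abort("clean clip has zero energy", "vib_invalid_parameter")
  }
  m <- length(noise$samples)
  if (m == 0L || sum(noise$samples^2) == 0) {
    vib_abort("noise clip has zero energy", "vib_invalid_parameter")
  }
  v <- noise$samples
  if (m > n) {
    start <- sample.int(m - n + 1L, 1L)
    v <- v[start:(start + n - 1L)]
  } else if (m < n) {
    reps <- ceiling((n + m) / m)
    tiled <- rep(v, reps)
    start <- sample.int(m, 1L)
    v <- tiled[start:(start + n - 1L)]
  }
  if (sum(v^2) == 0) {
    vib_abort("cropped noise has zero energy", "vib_invalid_parameter")
  }
  g <- sqrt(sum(clean$samples^2) / sum(v^2) * 10^(-snr_db / 10))
  scaled <- g * v
  structure(list(clean = clean,
                 noise = wave_clip(scaled, clean$sample_rate),
                 noisy = wave_clip(clean$samples + scaled, clean$sample_rate),
                 snr_db = snr_db),
            class = "clip_pair")
}

#' @export
print.clip_pair <- function(x, ...) {
  cat(sprintf("<clip_pair: %d samples @ %g Hz, mixed at %g dB SNR>\n",
              length(x$clean$samples), x$clean$sample_rate, x$snr_db))
  invisible(x)
}

# ---- manifests --------------------------------------------------------------

new_manifest <- function(records, train_fraction, seed, snr_db, dir) {
  stopifnot(is.data.frame(records))
  if (anyDuplicated(paste(records$id, records$role))) {
    vib_abort("duplicate (id, role) in manifest", "vib_invalid_parameter")
  }
  structure(list(records = records, train_fraction = train_fraction,
                 seed = seed, snr_db = snr_db, dir = dir),
            class = "dataset_manifest")
}

#' Write a dataset manifest as tab-separated text
#'
#' The manifest lists every written clip with its id, path (relative to the
#' manifest's directory), role (`clean`, `noise`, `noisy`) and split
#' (`train`, `test`); mixing settings are kept in `#`-prefixed header lines.
#'
#' @param manifest A `dataset_manifest`.
#' @param path Output path for the TSV file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# train_fraction: %.17g", manifest$train_fraction), con)
  writeLines(sprintf("# seed: %d", manifest$seed), con)
  writeLines(sprintf("# snr_db: %.17g", manifest$snr_db), con)
  writeLines("id\tpath\trole\tsplit", con)
  utils::write.table(manifest$records, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a dataset manifest
#'
#' @param path Path to a manifest TSV written by [write_manifest()].
#' @return A `dataset_manifest`; clip paths resolve relative to the
#'   manifest's directory.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    vib_abort(sprintf("manifest not found: %s", path), "vib_io_error")
  }
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  get_meta <- function(key, default) {
    hit <- grep(sprintf("^# %s:", key), meta, value = TRUE)
    if (length(hit)) as.numeric(sub(".*: *", "", hit[1])) else default
  }
  body <- lines[!startsWith(lines, "#")]
  records <- utils::read.table(text = body, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
  new_manifest(records,
               train_fraction = get_meta("train_fraction", NA_real_),
               seed = as.integer(get_meta("seed", 0)),
               snr_db = get_meta("snr_db", NA_real_),
               dir = dirname(normalizePath(path)))
}

manifest_split_ids <- function(manifest, split) {
  unique(manifest$records$id[manifest$records$split == split])
}

# Load the (clean, noisy) clip pair for one manifest id.
manifest_load_pair <- function(manifest, id) {
  rec <- manifest$records[manifest$records$id == id, ]
  pick <- function(role) {
    row <- rec[rec$role == role, ]
    if (nrow(row) != 1L) {
      vib_abort(sprintf("manifest id %s lacks a %s clip", id, role),
                "vib_io_error")
    }
    read_wav(file.path(manifest$dir, row$path))
  }
  list(clean = pick("clean"), noisy = pick("noisy"))
}

#' Build an SNR-mixed train/test dataset on disk
#'
#' Pairs each clean clip with a randomly drawn noise clip (with replacement
#' when noise clips are fewer), mixes each pair at `snr_db`, assigns
#' train/test splits by clean-clip identity so no clean clip leaks across
#' splits, writes all clips as WAV files under `out_dir`, and writes a
#' `manifest.tsv` describing them.
#'
#' @param clean_clips,noise_clips Non-empty lists of [wave_clip()] objects.
#' @param out_dir Output directory (created if missing).
#' @param snr_db Mixing SNR in dB (default -10, the low-SNR regime typical of
#'   field recordings).
#' @param train_fraction Fraction of pairs assigned to the training split.
#' @param seed Integer seed controlling pairing, crops, and the split.
#' @return The `dataset_manifest`, invisibly readable back with
#'   [read_manifest()].
#' @export
build_dataset <- function(clean_clips, noise_clips, out_dir, snr_db = -10,
                          train_fraction = 0.94, seed = 1L) {
  if (!is.list(clean_clips) || length(clean_clips) == 0L) {
    vib_abort("`clean_clips` must be a non-empty list", "vib_invalid_parameter")
  }
  if (!is.list(noise_clips) || length(noise_clips) == 0L) {
    vib_abort("`noise_clips` must be a non-empty list", "vib_invalid_parameter")
  }
  check_number(train_fraction, "train_fraction", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(clean_clips)
  with_seed(seed, {
    n_train <- max(0L, min(n, as.integer(round(train_fraction * n))))
    split <- rep("test", n)
    split[sample.int(n, n_train)] <- "train"
    noise_idx <- sample.int(length(noise_clips), n, replace = TRUE)
    records <- vector("list", 3L * n)
    for (i in seq_len(n)) {
      pair <- mix_at_snr(clean_clips[[i]], noise_clips[[noise_idx[i]]], snr_db)
      # joint rescale (SNR-preserving) so 16-bit writing never clips
      peak <- max(abs(pair$noisy$samples), abs(pair$clean$samples),
                  abs(pair$noise$samples))
      if (peak > 0.99) {
        for (role in c("clean", "noise", "noisy")) {
          pair[[role]] <- wave_clip(pair[[role]]$samples * 0.99 / peak,
                                    pair[[role]]$sample_rate)
        }
      }
      id <- sprintf("pair%04d", i)
      for (role in c("clean", "noise", "noisy")) {
        fname <- sprintf("%s_%s.wav", id, role)
        write_wav(pair[[role]], file.path(out_dir, fname))
        records[[3L * (i - 1L) + match(role, c("clean", "noise", "noisy"))]] <-
          data.frame(id = id, path = fname, role = role, split = split[i],
                     stringsAsFactors = FALSE)
      }
    }
    records <- do.call(rbind, records)
    manifest <- new_manifest(records, train_fraction, as.integer(seed), snr_db,
                             normalizePath(out_dir))
    write_manifest(manifest, file.path(out_dir, "manifest.tsv"))
    manifest
  })
}
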