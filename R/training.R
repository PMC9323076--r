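#' Training configuration
#'
#' Mirrors the study protocol at configurable scale: Adam with learning rate
#' 3e-4, periodic test-split evaluation, per-evaluation checkpoints, and a
#' fully seeded loop.
#'
#' @param learning_rate Adam step size (default 3e-4).
#' @param epochs Total training epochs (default 150).
#' @param eval_every_epochs Evaluate on the test split every this many epochs
#'   (default 5).
#' @param batch_size Clips per optimizer step (default 8, a desk-scale
#'   choice).
#' @param loss A [loss_spec()] (default log-cosh, the best-performing
#'   objective for this task).
#' @param seed Integer seed for shuffling and any stochastic component.
#' @param checkpoint_dir Directory for per-evaluation checkpoints; `NULL`
#'   disables writing.
#' @param beta1,beta2,adam_eps Adam moment decay rates and stabilizer.
#' @param grad_clip Optional global gradient-norm clip; `NULL` (default)
#'   disables clipping.
#' @param metric_frame_len,metric_lpc_order Passed to [evaluate_testset()].
#' @return A `train_config` object.
#' @export
train_config <- function(learning_rate = 3e-4, epochs = 150L,
                         eval_every_epochs = 5L, batch_size = 8L,
                         loss = loss_spec("logcosh"), seed = 1L,
                         checkpoint_dir = NULL, beta1 = 0.9, beta2 = 0.999,
                         adam_eps = 1e-8, grad_clip = NULL,
                         metric_frame_len = 1024L, metric_lpc_order = 16L) {
  check_number(learning_rate, "learning_rate", lower = 0, strict_lower = TRUE)
  check_number(epochs, "epochs", lower = 1)
  check_number(eval_every_epochs, "eval_every_epochs", lower = 1)
  check_number(batch_size, "batch_size", lower = 1)
  if (!inherits(loss, "loss_spec")) {
    vib_abort("`loss` must be a loss_spec", "vib_invalid_parameter")
  }
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 eval_every_epochs = as.integer(eval_every_epochs),
                 batch_size = as.integer(batch_size), loss = loss,
                 seed = as.integer(seed), checkpoint_dir = checkpoint_dir,
                 beta1 = beta1, beta2 = beta2, adam_eps = adam_eps,
                 grad_clip = grad_clip,
                 metric_frame_len = as.integer(metric_frame_len),
                 metric_lpc_order = as.integer(metric_lpc_order)),
            class = "train_config")
}

adam_init <- function(params) {
  list(m = tree_zeros_like(params), v = tree_zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1, beta2, eps) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2,
                       state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  mhat <- tree_map(function(m) m / bc1, state$m)
  step <- tree_map2(function(m, v) lr * m / (sqrt(v / bc2) + eps), mhat, state$v)
  params <- tree_map2(`-`, params, step)
  list(params = params, state = state)
}

# Loss + parameter gradients for one (noisy, clean) pair.
pair_loss_grad <- function(model, noisy, clean, spec) {
  fwd <- enhancer_forward(noisy, model)
  lg <- compute_loss(clean, fwd$y, spec, gradient = TRUE)
  bwd <- enhancer_backward(lg$grad, fwd$cache, model)
  list(value = lg$value, grads = bwd$grads)
}

#' Train an enhancer on a dataset manifest
#'
#' Runs shuffled mini-batch Adam over the manifest's train split, evaluating
#' on the test split every `eval_every_epochs` epochs, checkpointing at each
#' evaluation, and tracking the best checkpoint by test SNR. Test clips are
#' never used in an optimizer step. Identical seeds and configuration give
#' identical loss curves.
#'
#' @param model An `enhancer_model` from [init_enhancer()].
#' @param manifest A `dataset_manifest` with a non-empty train split.
#' @param config A [train_config()].
#' @return A list with the trained `model` and `history` (per-epoch mean
#'   training loss, evaluation reports, and `best_epoch` by test SNR).
#' @export
train <- function(model, manifest, config) {
  if (!inherits(config, "train_config")) {
    vib_abort("`config` must be a train_config", "vib_invalid_parameter")
  }
  train_ids <- manifest_split_ids(manifest, "train")
  if (!length(train_ids)) {
    vib_abort("manifest has no train split", "vib_invalid_parameter")
  }
  test_ids <- manifest_split_ids(manifest, "test")
  stopifnot(length(intersect(train_ids, test_ids)) == 0L)
  pairs <- lapply(train_ids, function(id) {
    p <- manifest_load_pair(manifest, id)
    list(noisy = p$noisy$samples, clean = p$clean$samples)
  })
  params <- model$params
  state <- adam_init(params)
  epoch_loss <- numeric(config$epochs)
  evals <- list()
  if (!is.null(config$checkpoint_dir)) {
    dir.create(config$checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
  }
  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      order_idx <- sample.int(length(pairs))
      losses <- numeric(0)
      batch_starts <- seq(1L, length(pairs), by = config$batch_size)
      for (bs in batch_starts) {
        idx <- order_idx[bs:min(bs + config$batch_size - 1L, length(pairs))]
        acc <- NULL
        batch_loss <- 0
        for (k in idx) {
          pg <- pair_loss_grad(model, pairs[[k]]$noisy, pairs[[k]]$clean,
                               config$loss)
          batch_loss <- batch_loss + pg$value
          acc <- if (is.null(acc)) pg$grads else tree_map2(`+`, acc, pg$grads)
        }
        nb <- length(idx)
        acc <- tree_map(function(g) g / nb, acc)
        batch_loss <- batch_loss / nb
        if (!is.finite(batch_loss)) {
          vib_abort(sprintf(
            "NaN/Inf loss at epoch %d; try a lower learning rate", epoch),
            "vib_training_diverged")
        }
        if (!is.null(config$grad_clip)) {
          gn <- sqrt(sum(tree_flatten(acc)^2))
          if (gn > config$grad_clip) {
            acc <- tree_map(function(g) g * config$grad_clip / gn, acc)
          }
        }
        upd <- adam_step(params, acc, state, config$learning_rate,
                         config$beta1, config$beta2, config$adam_eps)
        params <- upd$params
        state <- upd$state
        model$params <- params
        losses <- c(losses, batch_loss)
      }
      epoch_loss[epoch] <- mean(losses)
      if (epoch %% config$eval_every_epochs == 0L && length(test_ids)) {
        report <- evaluate_testset(manifest, model, config$metric_frame_len,
                                   config$metric_lpc_order)
        evals[[length(evals) + 1L]] <- list(epoch = epoch, report = report)
        if (!is.null(config$checkpoint_dir)) {
          save_checkpoint(model, file.path(
            config$checkpoint_dir, sprintf("epoch%04d.rds", epoch)),
            epoch = epoch)
        }
      }
    }
  })
  history <- structure(list(epoch_loss = epoch_loss, evals = evals,
                            best_epoch = if (length(evals))
                              select_best_checkpoint(list(evals = evals))
                            else NA_integer_),
                       class = "train_history")
  list(model = model, history = history)
}

#' Pick the best evaluation epoch by test SNR
#'
#' @param history A `train_history` (or any list with an `evals` field of
#'   `(epoch, report)` records).
#' @return The epoch with the highest test SNR; ties go to the earliest.
#' @export
select_best_checkpoint <- function(history) {
  evals <- history$evals
  if (is.null(evals) || !length(evals)) {
    vib_abort("no evaluation records", "vib_invalid_parameter")
  }
  snrs <- vapply(evals, function(e) e$report$snr_db, numeric(1))
  epochs <- vapply(evals, function(e) e$epoch, numeric(1))
  as.integer(epochs[which.max(snrs)])  # which.max: earliest on ties
}

#' Save / load a model checkpoint
#'
#' Checkpoints bundle the architecture configuration, all parameters, and
#' the training step into one serialized file.
#'
#' @param model An `enhancer_model`.
#' @param path Checkpoint file path.
#' @param epoch Optional epoch tag stored alongside the parameters.
#' @return `path` (save) or the restored `enhancer_model` (load).
#' @export
save_checkpoint <- function(model, path, epoch = NA_integer_) {
  saveRDS(list(config = model$config, params = model$params, epoch = epoch),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) {
    vib_abort(sprintf("checkpoint not found: %s", path), "vib_io_error")
  }
  obj <- readRDS(path)
  structure(list(config = obj$config, params = obj$params),
            class = "enhancer_model")
}

#' Desk-scale preset
#'
#' A configuration small enough to train in minutes on one CPU while keeping
#' every architectural ingredient: 3 encoder/decoder layers, 8 base channels,
#' a 2-layer SRU++ bottleneck, and 1-second clips at 8 kHz.
#'
#' @param seed Integer seed shared by model init and training.
#' @return A list with `enh` ([enhancer_config()]), `train`
#'   ([train_config()]), `sample_rate`, and `clip_seconds`.
#' @export
tiny_preset <- function(seed = 1L) {
  list(enh = enhancer_config(L = 3L, channels = 8L, seq_module = "srupp",
                             seq_layers = 2L),
       train = train_config(epochs = 10L, eval_every_epochs = 5L,
                            batch_size = 8L, seed = seed),
       sample_rate = 8000,
       clip_seconds = 1)
}

#' Paper-scale preset
#'
#' The full-size architecture (5 layers, 48 base channels, 2-layer SRU++,
#' 5-second clips at 44.1 kHz). Training this preset is GPU-scale work;
#' it is provided for completeness and for forward-pass use on CPU.
#'
#' @inheritParams tiny_preset
#' @return As [tiny_preset()].
#' @export
full_preset <- function(seed = 1L) {
  list(enh = enhancer_config(L = 5L, channels = 48L, seq_module = "srupp",
                             seq_layers = 2L),
       train = train_config(epochs = 150L, eval_every_epochs = 5L,
                            batch_size = 8L, seed = seed),
       sample_rate = 44100,
       clip_seconds = 5)
}
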