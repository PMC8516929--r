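# Two-phase weakly supervised training.
#
# Phase 1: random balanced sampling of tiles over the per-slide pools,
# binary cross-entropy on the slide label, Adam, stepped learning-rate
# decay; switches to phase 2 when the validation loss has not improved for
# switch_patience consecutive epochs. Phase 2 (hard mining): alternates
# sliding-window inference and training - per slide, the k tiles the model
# scores worst relative to the slide label join a subset; once the subset
# holds N tiles it is trained on (batched, arrival order) and cleared.
# Training stops after stop_patience non-improving epochs and the weights
# snapshot with the lowest validation loss is returned.

#' Optimiser configuration
#'
#' Paper-default Adam schedule: beta1 = 0.9, beta2 = 0.999, batch size 32,
#' initial learning rate 0.001 when training from scratch (0.0001 when
#' fine-tuning pretrained weights), decayed by 0.95 every 2 epochs.
#'
#' @param initial_lr starting learning rate.
#' @param lr_decay multiplicative decay factor.
#' @param decay_every epochs between decay steps.
#' @param beta1,beta2 Adam moment decay rates (< 1).
#' @param batch_size tiles per training batch.
#' @return object of class `optimizer_config`.
#' @export
optimizer_config <- function(initial_lr = 0.001, lr_decay = 0.95,
                             decay_every = 2L, beta1 = 0.9, beta2 = 0.999,
                             batch_size = 32L) {
  stopifnot(initial_lr > 0, lr_decay > 0, decay_every >= 1,
            beta1 > 0, beta1 < 1, beta2 > 0, beta2 < 1, batch_size >= 1)
  structure(list(initial_lr = initial_lr, lr_decay = lr_decay,
                 decay_every = as.integer(decay_every), beta1 = beta1,
                 beta2 = beta2, batch_size = as.integer(batch_size)),
            class = "optimizer_config")
}

#' Hard-mining configuration
#'
#' Paper defaults: k = 16 tiles mined per WSI, subset size N = 256, phase
#' switch after 2 non-improving validation epochs, stop after 10.
#'
#' @param k tiles mined per WSI pass.
#' @param N subset size that triggers a training flush (>= k).
#' @param switch_patience phase-1 patience in epochs.
#' @param stop_patience phase-2 early-stopping patience in epochs.
#' @return object of class `hard_mining_config`.
#' @export
hard_mining_config <- function(k = 16L, N = 256L, switch_patience = 2L,
                               stop_patience = 10L) {
  stopifnot(k >= 1, N >= k, switch_patience >= 1, stop_patience >= 1)
  structure(list(k = as.integer(k), N = as.integer(N),
                 switch_patience = as.integer(switch_patience),
                 stop_patience = as.integer(stop_patience)),
            class = "hard_mining_config")
}

#' Learning rate at a given epoch
#'
#' `lr(e) = initial_lr * lr_decay^(e %/% decay_every)`: with the defaults
#' the rate decays at the start of epochs 2, 4, 6, ... and epoch 4 runs at
#' `0.001 * 0.95^2`.
#'
#' @param opt an `optimizer_config`.
#' @param epoch 1-based epoch number.
#' @return learning rate.
#' @export
lr_at_epoch <- function(opt, epoch) {
  opt$initial_lr * opt$lr_decay^(epoch %/% opt$decay_every)
}

#' Select the hard tiles of one slide
#'
#' For a negative slide: the k tiles with the highest positive probability
#' (most offending false positives). For a positive slide: the k tiles with
#' the lowest positive probability. Ties keep the input (row-major) order;
#' if fewer than k tiles exist, all are returned.
#'
#' @param tiles list of `tile_ref` (or any list parallel to `probs`).
#' @param probs probabilities in `[0, 1]`, one per tile.
#' @param slide_label "positive" or "negative".
#' @param k number of tiles to select.
#' @return the selected sub-list of `tiles` (attribute `index` gives their
#'   positions in the input).
#' @export
select_hard_tiles <- function(tiles, probs, slide_label, k) {
  if (length(tiles) != length(probs) || length(tiles) == 0)
    stopf("tiles and probs must be nonempty and parallel")
  if (any(probs < 0 | probs > 1)) stopf("probs must lie in [0, 1]")
  idx <- select_hard_index(probs, slide_label, k)
  out <- tiles[idx]
  attr(out, "index") <- idx
  out
}

# Stable radix order: ascending for positive slides, descending (on -p) for
# negative slides, ties by original position either way.
select_hard_index <- function(probs, slide_label, k) {
  ord <- if (identical(slide_label, "positive"))
    order(probs, method = "radix")
  else order(-probs, method = "radix")
  ord[seq_len(min(k, length(probs)))]
}

new_history <- function() {
  data.frame(phase = character(0), epoch = integer(0), lr = numeric(0),
              train_loss = numeric(0), val_loss = numeric(0))
}

#' Phase-1 training: random balanced sampling
#'
#' Streams balanced batches, one Adam step per batch at the epoch's
#' learning rate, until the validation loss fails to improve for
#' `cfg$switch_patience` consecutive epochs (the improvement baseline is
#' initialised from a pre-training validation evaluation). Returns the
#' current model plus a hard-mining state; the phase transition happens
#' exactly once.
#'
#' @param model a scorer (or stub).
#' @param stream a [balanced_batch_stream()].
#' @param fetch function mapping a list of `tile_ref` to a feature matrix.
#' @param val list with `features` and `y` - the fixed validation tile
#'   sample.
#' @param opt an `optimizer_config`.
#' @param cfg a `hard_mining_config`.
#' @param max_epochs safety cap.
#' @param log_file optional structured-log destination.
#' @return list: `model`, `state` (phase, best_val_loss,
#'   epochs_since_improvement), `history` (per-epoch data frame).
#' @export
train_phase1 <- function(model, stream, fetch, val, opt, cfg,
                         max_epochs = 100L, log_file = NULL) {
  if (nrow(val$features) == 0) stopf("validation set must be nonempty")
  opt_env <- new.env(parent = emptyenv())
  opt_env$adam <- adam_new(length(head_theta_safe(model)))
  best <- model_loss(model, val$features, val$y)
  since <- 0L
  history <- new_history()
  for (epoch in seq_len(max_epochs)) {
    lr <- lr_at_epoch(opt, epoch)
    losses <- c()
    repeat {
      b <- next_batch(stream)
      step <- train_step(model, fetch(b$tiles), b$y, lr, opt_env, opt)
      model <- step$model
      losses <- c(losses, step$loss)
      if (b$epoch_end) break
    }
    vl <- model_loss(model, val$features, val$y)
    history[nrow(history) + 1L, ] <-
      list("random_balanced", epoch, lr, mean(losses), vl)
    if (!is.null(log_file))
      wsi_log("phase=random_balanced epoch=%d lr=%.6g loss=%.4f val_loss=%.4f",
              epoch, lr, mean(losses), vl, file = log_file)
    if (vl < best) { best <- vl; since <- 0L } else since <- since + 1L
    if (since >= cfg$switch_patience) break
  }
  list(model = model,
       state = list(phase = "hard_mining", best_val_loss = best,
                    epochs_since_improvement = since),
       history = history)
}

head_theta_safe <- function(model) {
  if (inherits(model, "wsi_scorer")) head_theta(model) else numeric(1)
}

#' Phase-2 training: hard mining
#'
#' Per epoch, loops over the slides in a freshly shuffled order; for each
#' slide runs sliding-window inference over all its tissue tiles, appends
#' the [select_hard_tiles()] output to the accumulating subset, and - once
#' the subset holds at least `cfg$N` tiles - trains on it in arrival order
#' (batches of `opt$batch_size`, final partial batch allowed) and clears
#' it. Early-stops after `cfg$stop_patience` non-improving validation
#' epochs and returns the snapshot with the lowest validation loss.
#'
#' @param model scorer (continuing from phase 1).
#' @param slide_sets list, one entry per training slide: `slide_id`,
#'   `label`, `tiles` (whole-tissue tile list).
#' @param fetch feature fetcher as in [train_phase1()].
#' @param val fixed validation tile sample (`features`, `y`).
#' @param opt an `optimizer_config`.
#' @param cfg a `hard_mining_config`.
#' @param seed shuffling seed.
#' @param max_epochs safety cap.
#' @param log_file optional log destination.
#' @return list: `model` (best snapshot), `history`, `flushes` (data frame
#'   of flush events: epoch, slides since previous flush, subset size).
#' @export
train_phase2 <- function(model, slide_sets, fetch, val, opt, cfg,
                         seed = 1L, max_epochs = 200L, log_file = NULL) {
  if (length(slide_sets) == 0) stopf("slide list must be nonempty")
  rng <- rng_env(seed)
  opt_env <- new.env(parent = emptyenv())
  opt_env$adam <- adam_new(length(head_theta_safe(model)))
  best <- model_loss(model, val$features, val$y)
  best_model <- model
  since <- 0L
  history <- new_history()
  flushes <- data.frame(epoch = integer(0), slides_since_flush = integer(0),
                        subset_size = integer(0))
  sub_feat <- NULL; sub_y <- integer(0)
  slides_since_flush <- 0L
  # features of each slide's tissue grid are fetched once and reused
  feat_cache <- lapply(slide_sets, function(s) fetch(s$tiles))
  for (epoch in seq_len(max_epochs)) {
    lr <- lr_at_epoch(opt, epoch)
    losses <- c()
    ord <- rng_eval(rng, function() sample(length(slide_sets)))
    for (si in ord) {
      s <- slide_sets[[si]]
      X <- feat_cache[[si]]
      probs <- score_features(model, X)
      idx <- select_hard_index(probs, s$label, cfg$k)
      sub_feat <- rbind(sub_feat, X[idx, , drop = FALSE])
      sub_y <- c(sub_y, rep(as.integer(s$label == "positive"), length(idx)))
      slides_since_flush <- slides_since_flush + 1L
      if (length(sub_y) >= cfg$N) {
        starts <- seq(1L, length(sub_y), by = opt$batch_size)
        for (st in starts) {
          en <- min(st + opt$batch_size - 1L, length(sub_y))
          step <- train_step(model, sub_feat[st:en, , drop = FALSE],
                             sub_y[st:en], lr, opt_env, opt)
          model <- step$model
          losses <- c(losses, step$loss)
        }
        flushes[nrow(flushes) + 1L, ] <-
          list(epoch, slides_since_flush, length(sub_y))
        sub_feat <- NULL; sub_y <- integer(0)
        slides_since_flush <- 0L
      }
    }
    vl <- model_loss(model, val$features, val$y)
    history[nrow(history) + 1L, ] <-
      list("hard_mining", epoch, lr,
           if (length(losses)) mean(losses) else NA_real_, vl)
    if (!is.null(log_file))
      wsi_log("phase=hard_mining epoch=%d lr=%.6g loss=%.4f val_loss=%.4f",
              epoch, lr, if (length(losses)) mean(losses) else NA_real_, vl,
              file = log_file)
    if (vl < best) { best <- vl; best_model <- model; since <- 0L }
    else since <- since + 1L
    if (since >= cfg$stop_patience) break
  }
  list(model = best_model, history = history, flushes = flushes,
       best_val_loss = best)
}

# ---- data preparation ---------------------------------------------------

# Per-slide feature store: opens each slide once, detects tissue, builds the
# whole-tissue grid and the training pool, and extracts frozen features for
# the union of both tile sets.
prepare_slide_data <- function(entry, scorer, config) {
  slide <- if (inherits(entry$slide, "wsi_slide")) entry$slide
  else open_slide(entry$slide)
  tissue <- detect_tissue(slide, config$thumbnail_downsample)
  grid <- enumerate_tiles(tissue, config$magnification, config$tile_size,
                          stride_px = config$stride,
                          min_tissue_fraction = config$min_tissue_fraction,
                          slide_id = entry$slide_id)
  attributes(grid) <- NULL
  pool <- build_pool(slide, entry$annotations, entry$label,
                     config$tile_size, config$magnification,
                     slide_id = entry$slide_id, tissue = tissue,
                     min_tissue_fraction = config$min_tissue_fraction)
  key <- function(t) paste(t$x, t$y, sep = "_")
  all_tiles <- grid
  keys <- vapply(all_tiles, key, "")
  for (t in pool$tiles) {
    if (!key(t) %in% keys) {
      all_tiles[[length(all_tiles) + 1]] <- t
      keys <- c(keys, key(t))
    }
  }
  if (length(all_tiles) == 0)
    stopf("slide %s has no tissue tiles", entry$slide_id)
  rasters <- lapply(all_tiles, function(t) read_tile(slide, t))
  X <- scorer_features(scorer, rasters)
  rownames(X) <- keys
  list(slide_id = entry$slide_id, label = entry$label, pool = pool,
       grid_tiles = grid, X = X, keys = keys)
}

make_fetcher <- function(store) {
  index <- new.env(parent = emptyenv())
  for (s in store) assign(s$slide_id, s, envir = index)
  function(tiles) {
    rows <- lapply(tiles, function(t) {
      s <- get(t$slide_id, envir = index)
      s$X[paste(t$x, t$y, sep = "_"), , drop = FALSE]
    })
    do.call(rbind, rows)
  }
}

sample_validation_tiles <- function(store, fetch, per_label = 256L, seed = 1L) {
  tiles <- list(); y <- integer(0)
  with_seed(seed, {
    for (lab in c("negative", "positive")) {
      cand <- list()
      for (s in store) if (s$label == lab) cand <- c(cand, s$pool$tiles)
      if (length(cand) == 0) stopf("validation slides lack label %s", lab)
      pick <- if (length(cand) > per_label) sample(length(cand), per_label)
      else seq_along(cand)
      tiles <- c(tiles, cand[pick])
      y <- c(y, rep(as.integer(lab == "positive"), length(pick)))
    }
  })
  list(features = fetch(tiles), y = y, tiles = tiles)
}

#' Train a weakly supervised WSI classifier end-to-end
#'
#' Prepares per-slide tile pools and frozen features, calibrates the
#' scorer's BN statistics on the training pool, then runs phase 1 (random
#' balanced sampling) followed by phase 2 (hard mining), both controlled by
#' the validation tile loss.
#'
#' @param train,val lists of labelled slide entries: each has `slide`
#'   (a `wsi_slide` or a path), `annotations` (`wsi_annotations` or NULL),
#'   `label`, `slide_id`.
#' @param config a [pipeline_config()].
#' @param scorer optional pre-built `wsi_scorer`.
#' @param log_file optional structured-log destination.
#' @return list: `model`, `history` (both phases), `flushes`, `config`.
#' @export
train_wsi_classifier <- function(train, val, config = pipeline_config(),
                                 scorer = NULL, log_file = NULL) {
  if (length(train) == 0 || length(val) == 0)
    stopf("training and validation slide lists must be nonempty")
  scorer <- scorer %||% build_scorer(toy_backbone(), seed = config$seed)
  opt <- optimizer_config(initial_lr = config$initial_lr,
                          lr_decay = config$lr_decay,
                          decay_every = config$decay_every,
                          beta1 = config$beta1, beta2 = config$beta2,
                          batch_size = config$batch_size)
  cfg <- hard_mining_config(k = config$k, N = config$N,
                            switch_patience = config$switch_patience,
                            stop_patience = config$stop_patience)
  if (!is.null(log_file)) wsi_log("preparing %d train + %d val slides",
                                  length(train), length(val), file = log_file)
  train_store <- lapply(train, prepare_slide_data, scorer = scorer,
                        config = config)
  pool_feat <- do.call(rbind, lapply(train_store, function(s) {
    ks <- vapply(s$pool$tiles, function(t) paste(t$x, t$y, sep = "_"), "")
    s$X[ks, , drop = FALSE]
  }))
  scorer <- calibrate_scorer(scorer, pool_feat)
  val_store <- lapply(val, prepare_slide_data, scorer = scorer,
                      config = config)
  fetch_train <- make_fetcher(train_store)
  fetch_val <- make_fetcher(val_store)
  val_sample <- sample_validation_tiles(val_store, fetch_val,
                                        seed = derive_seed(config$seed, 9001))
  pools <- lapply(train_store, `[[`, "pool")
  stream <- balanced_batch_stream(pools, opt$batch_size,
                                  seed = derive_seed(config$seed, 9002),
                                  labels = c("negative", "positive"))
  p1 <- train_phase1(scorer, stream, fetch_train, val_sample, opt, cfg,
                     log_file = log_file)
  if (!is.null(log_file))
    wsi_log("phase switch after %d epochs (best val loss %.4f)",
            nrow(p1$history), p1$state$best_val_loss, file = log_file)
  slide_sets <- lapply(train_store, function(s)
    list(slide_id = s$slide_id, label = s$label, tiles = s$grid_tiles))
  p2 <- train_phase2(p1$model, slide_sets, fetch_train, val_sample, opt, cfg,
                     seed = derive_seed(config$seed, 9003),
                     log_file = log_file)
  list(model = p2$model, phase1_model = p1$model,
       history = rbind(p1$history, p2$history),
       flushes = p2$flushes, config = config,
       best_val_loss = p2$best_val_loss)
}
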