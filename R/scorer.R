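# The tile scorer: a small convolutional network instantiated from a
# backbone spec, trained by partial fine-tuning. The convolutional stack is
# frozen (seeded He-normal filters); only the batch-normalisation affine
# parameters and the final classification layer receive gradient updates, so
# the trainable part of the model is an exact closed-form head over frozen
# features. BN runs in inference mode: its normalisation statistics are
# fixed once by calibrate_scorer() and only the affine pair trains, which is
# how partial fine-tuning treats a frozen pretrained backbone.

#' Instantiate a tile scorer from a backbone spec
#'
#' Supports backbones whose trainable layers (batch norm, dense head) all
#' sit after the global pooling step, e.g. [toy_backbone()]. Convolution
#' weights are drawn once from a seeded He-normal distribution and frozen.
#'
#' @param spec a `backbone_spec` (default [toy_backbone()]).
#' @param seed integer seed for the frozen filters and head initialisation.
#' @return object of class `wsi_scorer`.
#' @export
build_scorer <- function(spec = toy_backbone(), seed = 1L) {
  stopifnot(inherits(spec, "backbone_spec"))
  hi <- head_layer_index(spec)
  kinds <- vapply(spec$layers, `[[`, "", "kind")
  gpool <- which(kinds == "pool" &
                   vapply(spec$layers, function(l) isTRUE(l$global), FALSE))
  if (length(gpool) != 1)
    stopf("scorer backbones need exactly one global pooling layer")
  trainable_layers <- which(kinds %in% c("batch_norm", "dense"))
  if (any(trainable_layers < gpool))
    stopf(paste("this scorer trains only head-side parameters: batch-norm and",
                "dense layers must come after global pooling"))
  mask <- trainable_mask(spec)
  weights <- list()
  with_seed(seed, {
    for (ly in spec$layers[seq_len(gpool - 1)]) {
      if (ly$kind == "conv") {
        sh <- ly$params$weights  # kh, kw, in, out
        fan_in <- prod(sh[1:3])
        weights[[paste0(ly$name, "/weights")]] <-
          matrix(stats::rnorm(prod(sh), 0, sqrt(2 / fan_in)),
                 nrow = fan_in, ncol = sh[4])
      }
    }
  })
  nf <- spec$layers[[hi]]$in_units
  bn_idx <- which(kinds == "batch_norm")
  head_bn <- if (length(bn_idx) > 0) spec$layers[[bn_idx[length(bn_idx)]]]$name
  else NULL
  structure(list(
    spec = spec, seed = seed, mask = mask,
    frozen = weights,
    head = list(gamma = rep(1, nf), beta = rep(0, nf),
                w = rep(0, nf), b = 0),
    head_bn = head_bn,
    bn_mu = rep(0, nf), bn_sd = rep(1, nf),
    input_px = spec$input[1]
  ), class = "wsi_scorer")
}

#' @export
print.wsi_scorer <- function(x, ...) {
  cat(sprintf("<wsi_scorer> %d frozen filters sets, %d trainable parameters (%s)\n",
              length(x$frozen), count_trainable(x$spec, x$mask),
              paste(x$mask, collapse = ", ")))
  invisible(x)
}

# im2col for valid convolution: H x W x C array -> (oh*ow) x (kh*kw*C)
# matrix, column order (ki fastest, then kj, then channel) matching the
# frozen weight layout.
im2col <- function(a, kh, kw) {
  d <- dim(a); H <- d[1]; W <- d[2]; C <- d[3]
  oh <- H - kh + 1; ow <- W - kw + 1
  cols <- matrix(0, oh * ow, kh * kw * C)
  cc <- 0L
  for (ch in seq_len(C)) for (kj in seq_len(kw)) for (ki in seq_len(kh)) {
    cc <- cc + 1L
    cols[, cc] <- as.vector(a[ki:(ki + oh - 1), kj:(kj + ow - 1), ch])
  }
  cols
}

pool_channels <- function(a, f) {
  d <- dim(a)
  oh <- d[1] %/% f; ow <- d[2] %/% f
  out <- array(0, c(oh, ow, d[3]))
  for (ch in seq_len(d[3])) out[, , ch] <- block_mean(a[, , ch], f)
  out
}

# Tile raster -> preprocessed single-channel input in [0, 1].
preprocess_tile <- function(scorer, raster) {
  g <- as_gray(raster)
  resample_to(g, scorer$input_px, scorer$input_px) / 255
}

# Frozen forward pass: preprocessed input -> pooled feature vector.
forward_features <- function(scorer, x) {
  a <- array(x, c(nrow(x), ncol(x), 1L))
  for (ly in scorer$spec$layers) {
    if (ly$kind == "conv") {
      wmat <- scorer$frozen[[paste0(ly$name, "/weights")]]
      sh <- ly$params$weights
      cols <- im2col(a, sh[1], sh[2])
      oh <- dim(a)[1] - sh[1] + 1; ow <- dim(a)[2] - sh[2] + 1
      a <- array(cols %*% wmat, c(oh, ow, sh[4]))
    } else if (ly$kind == "activation") {
      a <- pmax(a, 0)
    } else if (ly$kind == "pool") {
      if (isTRUE(ly$global)) {
        return(if (identical(ly$pool_type, "max")) apply(a, 3, max)
               else apply(a, 3, mean))
      }
      a <- pool_channels(a, ly$size)
    } else break  # batch_norm / dense belong to the head
  }
  stopf("backbone has no global pooling layer")
}

#' Extract frozen features for a batch of tile rasters
#'
#' @param scorer a `wsi_scorer`.
#' @param rasters list of tile rasters (matrices or RGB arrays, 0-255).
#' @return numeric matrix, one row per tile.
#' @export
scorer_features <- function(scorer, rasters) {
  t(vapply(rasters, function(r) forward_features(scorer, preprocess_tile(scorer, r)),
           numeric(length(scorer$head$gamma))))
}

#' Fix the scorer's batch-normalisation statistics
#'
#' One-time calibration: the head BN normalises features with the mean and
#' standard deviation of the supplied (training-pool) feature matrix; the
#' statistics stay frozen afterwards, as in inference-mode BN.
#'
#' @param scorer a `wsi_scorer`.
#' @param features numeric feature matrix from [scorer_features()].
#' @return the calibrated scorer.
#' @export
calibrate_scorer <- function(scorer, features) {
  scorer$bn_mu <- colMeans(features)
  scorer$bn_sd <- pmax(apply(features, 2, stats::sd), 1e-6)
  scorer
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Score tiles from their frozen features
#'
#' `sigmoid(w . (gamma * xhat + beta) + b)` with `xhat` the BN-normalised
#' feature row.
#'
#' @param model a scorer (or scorer-like stub).
#' @param features numeric feature matrix.
#' @return vector of probabilities in `[0, 1]`.
#' @export
score_features <- function(model, features) UseMethod("score_features")

#' @export
score_features.wsi_scorer <- function(model, features) {
  xhat <- sweep(sweep(features, 2, model$bn_mu), 2, model$bn_sd, "/")
  z <- sweep(sweep(xhat, 2, model$head$gamma, "*"), 2, model$head$beta, "+")
  as.vector(sigmoid(z %*% model$head$w + model$head$b))
}

#' Score raw tile rasters
#'
#' @param model a scorer (or stub).
#' @param rasters list of tile rasters.
#' @return vector of probabilities.
#' @export
score_tile_rasters <- function(model, rasters) UseMethod("score_tile_rasters")

#' @export
score_tile_rasters.wsi_scorer <- function(model, rasters) {
  score_features(model, scorer_features(model, rasters))
}

# Binary cross-entropy with probability clipping.
bce_loss <- function(p, y, eps = 1e-12) {
  p <- clamp(p, eps, 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Loss of a model on a labelled feature set
#'
#' @param model a scorer or stub.
#' @param features feature matrix.
#' @param y 0/1 labels.
#' @return binary cross-entropy.
#' @export
model_loss <- function(model, features, y) UseMethod("model_loss")

#' @export
model_loss.default <- function(model, features, y) {
  bce_loss(score_features(model, features), y)
}

# --- head parameter vector <-> list -------------------------------------

head_theta <- function(scorer) {
  with(scorer$head, c(gamma, beta, w, b))
}

set_head_theta <- function(scorer, theta) {
  nf <- length(scorer$head$gamma)
  scorer$head$gamma <- theta[seq_len(nf)]
  scorer$head$beta <- theta[nf + seq_len(nf)]
  scorer$head$w <- theta[2 * nf + seq_len(nf)]
  scorer$head$b <- theta[3 * nf + 1]
  scorer
}

# Exact gradient of the BCE loss w.r.t. (gamma, beta, w, b).
head_grad <- function(scorer, features, y) {
  xhat <- sweep(sweep(features, 2, scorer$bn_mu), 2, scorer$bn_sd, "/")
  z <- sweep(sweep(xhat, 2, scorer$head$gamma, "*"), 2, scorer$head$beta, "+")
  p <- as.vector(sigmoid(z %*% scorer$head$w + scorer$head$b))
  ds <- (p - y) / length(y)
  dz <- outer(ds, scorer$head$w)
  c(colSums(dz * xhat),        # d gamma
    colSums(dz),               # d beta
    as.vector(crossprod(z, ds)),  # d w
    sum(ds))                   # d b
}

# --- Adam ----------------------------------------------------------------

adam_new <- function(n) list(m = rep(0, n), v = rep(0, n), t = 0L)

adam_update <- function(theta, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = state)
}

#' One optimisation step on a labelled tile batch
#'
#' Updates only the parameters in the partial fine-tuning mask (BN affine +
#' head); frozen parameters are untouched. `opt_env` is an environment
#' carrying the Adam state (`opt_env$adam`), created by the training loop.
#'
#' @param model a scorer or stub.
#' @param features batch feature matrix.
#' @param y 0/1 batch labels.
#' @param lr learning rate for this step.
#' @param opt_env optimiser state environment.
#' @param opt an `optimizer_config` (betas).
#' @return list with the updated `model` and the batch `loss` (pre-update).
#' @export
train_step <- function(model, features, y, lr, opt_env, opt) UseMethod("train_step")

#' @export
train_step.wsi_scorer <- function(model, features, y, lr, opt_env, opt) {
  loss <- model_loss(model, features, y)
  if (!is.finite(loss)) stopf("non-finite training loss; aborting")
  g <- head_grad(model, features, y)
  upd <- adam_update(head_theta(model), g, opt_env$adam, lr,
                     beta1 = opt$beta1, beta2 = opt$beta2)
  opt_env$adam <- upd$state
  list(model = set_head_theta(model, upd$theta), loss = loss)
}

# --- constant stub (testing aid) ----------------------------------------

#' Constant-output stub scorer
#'
#' Emits a fixed probability for every tile and ignores training; used to
#' exercise patience/stopping contracts.
#'
#' @param p constant probability.
#' @return object of classes `constant_scorer`.
#' @export
constant_scorer <- function(p = 0.5) {
  structure(list(p = p), class = "constant_scorer")
}

#' @export
score_features.constant_scorer <- function(model, features) {
  rep(model$p, if (is.matrix(features)) nrow(features) else length(features))
}

#' @export
score_tile_rasters.constant_scorer <- function(model, rasters) {
  rep(model$p, length(rasters))
}

#' @export
train_step.constant_scorer <- function(model, features, y, lr, opt_env, opt) {
  list(model = model, loss = model_loss(model, features, y))
}
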