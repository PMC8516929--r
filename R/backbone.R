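# Backbone structural descriptors and the partial fine-tuning mask.
#
# A backbone spec is an ordered list of layers, each describing its kind and
# the shapes of its parameters. Partial fine-tuning trains only the affine
# parameters (scale/offset) of every batch-normalisation layer plus the
# final classification layer; everything else is frozen.

layer_spec <- function(kind, name, params = list(), ...) {
  structure(c(list(kind = kind, name = name, params = params), list(...)),
            class = "wsi_layer")
}

#' Convolution layer descriptor
#'
#' @param name unique layer name.
#' @param kernel kernel side (or c(kh, kw)).
#' @param in_ch,out_ch channel counts.
#' @param depthwise depthwise convolution (one filter per channel)?
#' @param bias include a bias vector?
#' @return a layer descriptor.
#' @export
layer_conv <- function(name, kernel, in_ch, out_ch, depthwise = FALSE,
                       bias = FALSE) {
  k <- if (length(kernel) == 1) c(kernel, kernel) else kernel
  params <- list(weights = if (depthwise) c(k, in_ch, 1L) else c(k, in_ch, out_ch))
  if (bias) params$bias <- out_ch
  layer_spec("conv", name, params, in_ch = in_ch, out_ch = out_ch,
             depthwise = depthwise)
}

#' Batch-normalisation layer descriptor
#'
#' Exposes exactly two trainable vectors (scale `gamma`, offset `beta`) of
#' length equal to the channel count; the running statistics are not
#' trainable parameters.
#'
#' @param name unique layer name.
#' @param channels channel count.
#' @return a layer descriptor.
#' @export
layer_bn <- function(name, channels) {
  layer_spec("batch_norm", name, list(gamma = channels, beta = channels),
             channels = channels)
}

#' Dense (fully connected) layer descriptor
#'
#' @param name unique layer name.
#' @param in_units,out_units unit counts.
#' @param bias include a bias vector?
#' @return a layer descriptor.
#' @export
layer_dense <- function(name, in_units, out_units, bias = TRUE) {
  params <- list(weights = c(in_units, out_units))
  if (bias) params$bias <- out_units
  layer_spec("dense", name, params, in_units = in_units, out_units = out_units)
}

#' Activation / pooling / global-pooling layer descriptors
#'
#' Parameter-free layers: `layer_act` (activation), `layer_pool`
#' (2x2-style average pooling with integer factor), `layer_gpool` (global
#' average pooling over the spatial grid).
#'
#' @param name unique layer name.
#' @param fun activation name (only "relu" is executed by the toy scorer).
#' @param size pooling factor.
#' @return a layer descriptor.
#' @export
layer_act <- function(name, fun = "relu") layer_spec("activation", name, fun = fun)

#' @rdname layer_act
#' @export
layer_pool <- function(name, size = 2L) layer_spec("pool", name, size = size)

#' @rdname layer_act
#' @param type global pooling statistic, "avg" or "max".
#' @export
layer_gpool <- function(name, type = c("avg", "max")) {
  layer_spec("pool", name, size = NA_integer_, global = TRUE,
             pool_type = match.arg(type))
}

#' Assemble a backbone spec
#'
#' The final dense layer is treated as the classification head; specs
#' without a dense layer are rejected where a head is required.
#'
#' @param layers list of layer descriptors.
#' @param input input geometry `c(height, width, channels)` consumed by the
#'   first layer (after tile preprocessing).
#' @return object of class `backbone_spec`.
#' @export
backbone_spec <- function(layers, input = c(28L, 28L, 1L)) {
  nms <- vapply(layers, `[[`, "", "name")
  if (anyDuplicated(nms)) stopf("layer names must be unique")
  structure(list(layers = layers, input = input), class = "backbone_spec")
}

#' @export
print.backbone_spec <- function(x, ...) {
  kinds <- table(vapply(x$layers, `[[`, "", "kind"))
  cat(sprintf("<backbone_spec> %d layers (%s); %s total parameters\n",
              length(x$layers),
              paste(sprintf("%s:%d", names(kinds), kinds), collapse = ", "),
              format(sum(param_sizes(x)), big.mark = ",")))
  invisible(x)
}

# Named vector of parameter element counts, ids "layer/param".
param_sizes <- function(spec) {
  out <- integer(0)
  for (ly in spec$layers) {
    for (pn in names(ly$params)) {
      out[paste0(ly$name, "/", pn)] <- prod(ly$params[[pn]])
    }
  }
  out
}

head_layer_index <- function(spec) {
  dense <- which(vapply(spec$layers, `[[`, "", "kind") == "dense")
  if (length(dense) == 0)
    stopf("backbone has no dense layer to act as the classification head")
  dense[length(dense)]
}

#' Partial fine-tuning parameter mask
#'
#' Returns the identifiers (`"layer/param"`) of every trainable parameter
#' under partial fine-tuning: the scale and offset vectors of all
#' batch-normalisation layers plus the weights and bias of the final
#' classification (dense) layer. All other parameters are frozen.
#'
#' @param backbone a `backbone_spec` with a dense head.
#' @return character vector of parameter ids.
#' @export
trainable_mask <- function(backbone) {
  stopifnot(inherits(backbone, "backbone_spec"))
  hi <- head_layer_index(backbone)
  ids <- character(0)
  for (i in seq_along(backbone$layers)) {
    ly <- backbone$layers[[i]]
    if (ly$kind == "batch_norm" || i == hi)
      ids <- c(ids, paste0(ly$name, "/", names(ly$params)))
  }
  ids
}

#' Count parameters selected by a mask
#'
#' @param backbone a `backbone_spec`.
#' @param mask character vector of parameter ids (default: the partial
#'   fine-tuning mask).
#' @return exact integer element count.
#' @export
count_trainable <- function(backbone, mask = trainable_mask(backbone)) {
  sizes <- param_sizes(backbone)
  unknown <- setdiff(mask, names(sizes))
  if (length(unknown) > 0)
    stopf("unknown parameter id(s): %s", paste(unknown, collapse = ", "))
  sum(sizes[unique(mask)])
}

#' Toy convolutional backbone
#'
#' Default tile scorer architecture for synthetic studies: three frozen
#' valid-convolution blocks (3x3 kernels, average pooling) over a
#' single-channel `input_px` x `input_px` input, a global pooling layer, one
#' batch-normalisation layer on the pooled feature vector, and a 1-unit
#' classification head. Under partial fine-tuning only the BN affine pair
#' and the head train (2 * channels[3] + channels[3] + 1 parameters).
#'
#' Global pooling averages each channel over the spatial grid; a "max"
#' variant is available for experimentation but pooled random-filter maxima
#' proved noise-dominated on speckle textures.
#'
#' @param input_px input side length after tile preprocessing (default 32).
#' @param channels per-block output channels.
#' @param gpool global pooling statistic ("avg" default, or "max").
#' @return a `backbone_spec`.
#' @export
toy_backbone <- function(input_px = 32L, channels = c(16L, 16L, 32L),
                         gpool = "avg") {
  nf <- channels[3]
  backbone_spec(list(
    layer_conv("conv1", 3L, 1L, channels[1]),
    layer_act("act1"),
    layer_pool("pool1"),
    layer_conv("conv2", 3L, channels[1], channels[2]),
    layer_act("act2"),
    layer_pool("pool2"),
    layer_conv("conv3", 3L, channels[2], nf),
    layer_act("act3"),
    layer_gpool("gpool", gpool),
    layer_bn("head_bn", nf),
    layer_dense("head", nf, 1L)
  ), input = c(as.integer(input_px), as.integer(input_px), 1L))
}

# EfficientNet compound-scaling helpers (width divisor 8).
round_filters <- function(filters, width_coefficient, divisor = 8) {
  f <- filters * width_coefficient
  new_f <- max(divisor, (floor(f + divisor / 2) %/% divisor) * divisor)
  if (new_f < 0.9 * f) new_f <- new_f + divisor
  as.integer(new_f)
}

round_repeats <- function(repeats, depth_coefficient) {
  as.integer(ceiling(depth_coefficient * repeats))
}

#' EfficientNetB1 structural descriptor
#'
#' Builds the EfficientNet-B1 layer structure (width coefficient 1.0, depth
#' coefficient 1.1) as a shape-level descriptor: stem, 23 mobile
#' inverted-bottleneck blocks with squeeze-excitation, top convolution, and
#' a classification head with `num_classes` output units. Weights are not
#' instantiated; the descriptor exists so the partial fine-tuning mask can
#' be counted exactly (with a 1-unit head: 63,329 trainable parameters).
#'
#' @param num_classes head output units (default 1: binary task with a
#'   sigmoid unit).
#' @return a `backbone_spec`.
#' @export
efficientnet_b1_spec <- function(num_classes = 1L) {
  width <- 1.0; depth <- 1.1
  blocks <- list(  # expand_ratio, out_filters (B0), repeats (B0), kernel, stride
    list(e = 1, f = 16,  r = 1, k = 3, s = 1),
    list(e = 6, f = 24,  r = 2, k = 3, s = 2),
    list(e = 6, f = 40,  r = 2, k = 5, s = 2),
    list(e = 6, f = 80,  r = 3, k = 3, s = 2),
    list(e = 6, f = 112, r = 3, k = 5, s = 1),
    list(e = 6, f = 192, r = 4, k = 5, s = 2),
    list(e = 6, f = 320, r = 1, k = 3, s = 1))
  layers <- list()
  add <- function(ly) layers[[length(layers) + 1]] <<- ly
  stem <- round_filters(32, width)
  add(layer_conv("stem_conv", 3L, 3L, stem))
  add(layer_bn("stem_bn", stem))
  add(layer_act("stem_act", "swish"))
  in_ch <- stem
  for (bi in seq_along(blocks)) {
    b <- blocks[[bi]]
    out_ch <- round_filters(b$f, width)
    reps <- round_repeats(b$r, depth)
    for (ri in seq_len(reps)) {
      nm <- sprintf("block%d%s", bi, letters[ri])
      exp_ch <- in_ch * b$e
      if (b$e != 1) {
        add(layer_conv(paste0(nm, "_expand"), 1L, in_ch, exp_ch))
        add(layer_bn(paste0(nm, "_expand_bn"), exp_ch))
        add(layer_act(paste0(nm, "_expand_act"), "swish"))
      }
      add(layer_conv(paste0(nm, "_dw"), b$k, exp_ch, exp_ch, depthwise = TRUE))
      add(layer_bn(paste0(nm, "_dw_bn"), exp_ch))
      add(layer_act(paste0(nm, "_dw_act"), "swish"))
      se_ch <- max(1L, as.integer(in_ch * 0.25))  # squeeze-excitation (no BN)
      add(layer_conv(paste0(nm, "_se_reduce"), 1L, exp_ch, se_ch, bias = TRUE))
      add(layer_conv(paste0(nm, "_se_expand"), 1L, se_ch, exp_ch, bias = TRUE))
      add(layer_conv(paste0(nm, "_project"), 1L, exp_ch, out_ch))
      add(layer_bn(paste0(nm, "_project_bn"), out_ch))
      in_ch <- out_ch
    }
  }
  top <- round_filters(1280, width)
  add(layer_conv("top_conv", 1L, in_ch, top))
  add(layer_bn("top_bn", top))
  add(layer_act("top_act", "swish"))
  add(layer_gpool("avg_pool"))
  add(layer_dense("predictions", top, as.integer(num_classes)))
  backbone_spec(layers, input = c(240L, 240L, 3L))
}
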