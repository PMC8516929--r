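# Tile-pool construction and label-balanced batch streaming.
#
# Positive slides with lesion annotations contribute only annotation tiles
# (centre rule for small annotations, overlapping grid for large ones);
# unannotated slides contribute their whole tissue grid. Batches are built
# by alternating label categories over per-label shuffled WSI queues, with
# oversampling so every WSI is seen each epoch.

#' Tiles covering one annotation polygon
#'
#' If the polygon's bounding box fits inside a `size_px` square, exactly one
#' tile is placed with its centre on the bounding-box centre (clamped inside
#' the slide). Otherwise tiles are laid on an overlapping grid over the
#' bounding box (stride `size_px / 2`, with a final row/column flushed to
#' the far edge) and tiles intersecting the polygon are kept.
#'
#' @param polygon list with `ring` (base-level vertices) or a bare ring
#'   matrix.
#' @param slide the `wsi_slide` (for bounds and magnification mapping).
#' @param size_px tile side.
#' @param magnification tile magnification.
#' @param stride_px grid stride for large annotations (default
#'   `size_px / 2`).
#' @param slide_id id stamped on the tiles.
#' @return list of `tile_ref`.
#' @export
tiles_from_annotation <- function(polygon, slide, size_px, magnification,
                                  stride_px = max(1L, size_px %/% 2L),
                                  slide_id = "slide") {
  ring_base <- if (is.list(polygon)) polygon$ring else polygon
  dims <- slide_dims_at(slide, magnification)
  W <- dims[["width"]]; H <- dims[["height"]]
  scale <- slide$base_magnification / magnification
  ring <- ring_base / scale
  bb <- ring_bbox(ring)
  if (bb["x0"] < 0 || bb["y0"] < 0 || bb["x1"] > W || bb["y1"] > H)
    stopf("annotation polygon lies outside the slide bounds")
  if (W < size_px || H < size_px)
    stopf("slide smaller than the tile size at x%g", magnification)
  clamp_xy <- function(v, lim) as.integer(clamp(round(v), 0, lim - size_px))
  if (bb["x1"] - bb["x0"] <= size_px && bb["y1"] - bb["y0"] <= size_px) {
    cx <- (bb["x0"] + bb["x1"]) / 2
    cy <- (bb["y0"] + bb["y1"]) / 2
    return(list(tile_ref(slide_id, magnification,
                         clamp_xy(cx - size_px / 2, W),
                         clamp_xy(cy - size_px / 2, H), size_px)))
  }
  grid_positions <- function(lo, hi, lim) {
    lo <- max(0, floor(lo)); hi <- min(lim, ceiling(hi))
    if (hi - lo <= size_px) return(clamp_xy(lo, lim))
    xs <- seq(lo, hi - size_px, by = stride_px)
    if (xs[length(xs)] < hi - size_px) xs <- c(xs, hi - size_px)
    unique(vapply(xs, clamp_xy, 0L, lim))
  }
  xs <- grid_positions(bb["x0"], bb["x1"], W)
  ys <- grid_positions(bb["y0"], bb["y1"], H)
  tiles <- list()
  for (y in ys) for (x in xs) {
    if (rect_intersects_ring(x, y, x + size_px, y + size_px, ring))
      tiles[[length(tiles) + 1]] <-
        tile_ref(slide_id, magnification, x, y, size_px)
  }
  tiles
}

#' Build the training tile pool of one slide
#'
#' Slides with lesion annotations get an annotation-restricted pool (union
#' of [tiles_from_annotation()] over all polygons, deduplicated by
#' position); unannotated slides get the whole-tissue sliding grid.
#'
#' @param slide a `wsi_slide`.
#' @param annotations a `wsi_annotations` (possibly empty).
#' @param label slide label string ("positive"/"negative").
#' @param size_px,magnification tile geometry.
#' @param slide_id identifier.
#' @param tissue optional precomputed `tissue_mask`.
#' @param min_tissue_fraction,working_downsample tissue-grid settings.
#' @return object of class `tile_pool`: `slide_id`, `label`, `tiles`,
#'   `source` ("annotation_restricted" or "whole_tissue").
#' @export
build_pool <- function(slide, annotations, label, size_px, magnification,
                       slide_id = "slide", tissue = NULL,
                       min_tissue_fraction = 0.25, working_downsample = 32) {
  annotated <- inherits(annotations, "wsi_annotations") && length(annotations) > 0
  if (annotated) {
    tiles <- list()
    seen <- character(0)
    for (p in annotations$polygons) {
      for (t in tiles_from_annotation(p, slide, size_px, magnification,
                                      slide_id = slide_id)) {
        key <- paste(t$x, t$y)
        if (!key %in% seen) {
          seen <- c(seen, key)
          tiles[[length(tiles) + 1]] <- t
        }
      }
    }
    if (length(tiles) == 0)
      stopf("slide %s: annotations yielded no tiles (inconsistent ground truth)",
            slide_id)
    source <- "annotation_restricted"
  } else {
    tissue <- tissue %||% detect_tissue(slide, working_downsample)
    tiles <- enumerate_tiles(tissue, magnification, size_px,
                             min_tissue_fraction = min_tissue_fraction,
                             slide_id = slide_id)
    attributes(tiles) <- NULL
    source <- "whole_tissue"
  }
  structure(list(slide_id = slide_id, label = label, tiles = tiles,
                 source = source), class = "tile_pool")
}

#' @export
print.tile_pool <- function(x, ...) {
  cat(sprintf("<tile_pool> %s (%s): %d tiles, %s\n", x$slide_id, x$label,
              length(x$tiles), x$source))
  invisible(x)
}

#' Export / import a tile pool as CSV
#'
#' Columns: slide_id, label, source, magnification, x, y, size.
#'
#' @param pool a `tile_pool`.
#' @param path CSV path.
#' @return `path` (write) / the `tile_pool` (read).
#' @export
write_pool_csv <- function(pool, path) {
  df <- data.frame(
    slide_id = pool$slide_id, label = pool$label, source = pool$source,
    magnification = vapply(pool$tiles, `[[`, 0, "magnification"),
    x = vapply(pool$tiles, `[[`, 0L, "x"),
    y = vapply(pool$tiles, `[[`, 0L, "y"),
    size = vapply(pool$tiles, `[[`, 0L, "size_px"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pool_csv
#' @export
read_pool_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tiles <- lapply(seq_len(nrow(df)), function(i)
    tile_ref(df$slide_id[i], df$magnification[i], df$x[i], df$y[i],
             df$size[i]))
  structure(list(slide_id = df$slide_id[1], label = df$label[1],
                 tiles = tiles, source = df$source[1]),
            class = "tile_pool")
}

#' Label-balanced batch stream over a shuffled WSI queue
#'
#' Keeps one shuffled queue of slides per label and alternates labels in a
#' fixed (sorted) rotation. Each draw pops the next WSI of that label and
#' samples `batch_size / num_labels` tiles from its pool - without
#' replacement when the pool is large enough, with replacement otherwise.
#' A queue that empties is reshuffled and recycled (oversampling of the
#' smaller label); an epoch ends once every WSI has been drawn at least
#' once. Deterministic for a fixed seed.
#'
#' @param pools list of `tile_pool` (>= 1 per label).
#' @param batch_size batch size, divisible by the number of labels.
#' @param seed stream seed.
#' @param labels the label universe; defaults to the labels present in
#'   `pools`, and every listed label must have at least one pool.
#' @return a stream object; advance it with [next_batch()].
#' @export
balanced_batch_stream <- function(pools, batch_size, seed = 1L,
                                  labels = NULL) {
  labels <- sort(labels %||% unique(vapply(pools, `[[`, "", "label")))
  if (batch_size %% length(labels) != 0)
    stopf("batch_size %d not divisible by %d labels", batch_size, length(labels))
  by_label <- lapply(labels, function(l)
    which(vapply(pools, `[[`, "", "label") == l))
  names(by_label) <- labels
  if (any(vapply(by_label, length, 0L) == 0))
    stopf("every label needs at least one pool")
  e <- rng_env(seed)
  e$pools <- pools
  e$labels <- labels
  e$by_label <- by_label
  e$per_label <- batch_size %/% length(labels)
  resample <- function(x) x[sample.int(length(x))]  # safe for length 1
  e$resample <- resample
  e$queues <- rng_eval(e, function() lapply(by_label, resample))
  e$drawn <- logical(length(pools))
  e$epoch <- 1L
  class(e) <- c("balanced_batch_stream", "environment")
  e
}

#' Draw the next balanced batch from a stream
#'
#' @param stream a [balanced_batch_stream()].
#' @return list with `tiles` (list of `tile_ref`), `labels` (character),
#'   `y` (0/1, positive = 1), `slide_ids`, `epoch`, and `epoch_end` (TRUE
#'   when this batch completed coverage of all WSIs).
#' @export
next_batch <- function(stream) {
  rng_eval(stream, function() {
    tiles <- list(); labs <- character(0); sids <- character(0)
    for (l in stream$labels) {
      q <- stream$queues[[l]]
      if (length(q) == 0) q <- stream$resample(stream$by_label[[l]])
      pool_idx <- q[1]
      stream$queues[[l]] <- q[-1]
      stream$drawn[pool_idx] <- TRUE
      pool <- stream$pools[[pool_idx]]
      n <- stream$per_label
      pick <- if (length(pool$tiles) >= n) sample(length(pool$tiles), n)
      else sample(length(pool$tiles), n, replace = TRUE)
      tiles <- c(tiles, pool$tiles[pick])
      labs <- c(labs, rep(pool$label, n))
      sids <- c(sids, rep(pool$slide_id, n))
    }
    epoch <- stream$epoch
    epoch_end <- all(stream$drawn)
    if (epoch_end) {
      stream$drawn <- logical(length(stream$pools))
      stream$epoch <- stream$epoch + 1L
    }
    list(tiles = tiles, labels = labs, y = as.integer(labs == "positive"),
         slide_ids = sids, epoch = epoch, epoch_end = epoch_end)
  })
}
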