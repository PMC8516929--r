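# Sliding-window inference: per-tile probability heatmaps, max aggregation
# to one slide-level probability, two-stage probability combination, and
# overlay rendering.

#' Sliding-window probability heatmap
#'
#' Applies the tile scorer to every tissue tile of the sliding grid (see
#' [enumerate_tiles()]); non-tissue grid cells are invalid (NA). A slide
#' with no tissue tiles yields an empty heatmap with a warning.
#'
#' @param slide a `wsi_slide`.
#' @param model scorer or stub.
#' @param magnification,tile_size,stride grid geometry (stride defaults to
#'   the tile size: non-overlapping cells).
#' @param min_tissue_fraction tissue criterion per tile.
#' @param tissue optional precomputed `tissue_mask`.
#' @param working_downsample thumbnail downsample for tissue detection.
#' @param slide_id identifier stamped on the result.
#' @return object of class `wsi_heatmap`: probability `grid` (rows = y,
#'   cols = x; NA outside tissue), `valid` mask, grid geometry and
#'   magnification.
#' @export
predict_heatmap <- function(slide, model, magnification, tile_size,
                            stride = tile_size, min_tissue_fraction = 0.25,
                            tissue = NULL, working_downsample = 32,
                            slide_id = "slide") {
  tissue <- tissue %||% detect_tissue(slide, working_downsample)
  tiles <- enumerate_tiles(tissue, magnification, tile_size, stride,
                           min_tissue_fraction, slide_id = slide_id)
  xs <- attr(tiles, "xs"); ys <- attr(tiles, "ys")
  gidx <- attr(tiles, "grid_index")
  grid <- matrix(NA_real_, length(ys), length(xs))
  if (length(tiles) == 0) {
    warnf("slide %s: no tissue tiles; empty heatmap", slide_id)
  } else {
    rasters <- lapply(tiles, function(t) read_tile(slide, t))
    probs <- score_tile_rasters(model, rasters)
    grid[gidx] <- probs
  }
  structure(list(slide_id = slide_id, magnification = magnification,
                 tile_size_px = tile_size, stride_px = stride,
                 grid = grid, valid = !is.na(grid),
                 xs = xs, ys = ys, origin = c(0L, 0L)),
            class = "wsi_heatmap")
}

#' @export
print.wsi_heatmap <- function(x, ...) {
  cat(sprintf("<wsi_heatmap> %s: %dx%d grid (%d valid), tile %dpx at x%g\n",
              x$slide_id, ncol(x$grid), nrow(x$grid), sum(x$valid),
              x$tile_size_px, x$magnification))
  invisible(x)
}

#' Slide-level probability by max aggregation
#'
#' The WSI probability is the maximum probability over the valid heatmap
#' cells.
#'
#' @param h a `wsi_heatmap` with at least one valid cell.
#' @return probability in `[0, 1]`.
#' @export
slide_probability <- function(h) {
  stopifnot(inherits(h, "wsi_heatmap"))
  if (!any(h$valid)) stopf("heatmap %s has no valid cells", h$slide_id)
  max(h$grid[h$valid])
}

#' Two-stage probability combination
#'
#' `P(diffuse-type) = P1(ADC) * P2(diffuse-type | ADC)`: the product of the
#' first-stage slide probability and the second-stage (this package's)
#' slide probability.
#'
#' @param p1 first-stage probability in `[0, 1]` (pluggable source).
#' @param p2 second-stage probability in `[0, 1]`.
#' @return combined probability (vectorised).
#' @export
two_stage_probability <- function(p1, p2) {
  if (any(!is.finite(p1)) || any(p1 < 0 | p1 > 1))
    stopf("p1 must lie in [0, 1]")
  if (any(!is.finite(p2)) || any(p2 < 0 | p2 > 1))
    stopf("p2 must lie in [0, 1]")
  p1 * p2
}

#' Render a heatmap overlay PNG
#'
#' Draws the slide thumbnail with one colour-mapped square per valid cell
#' (square side = tile size at the heatmap magnification): probability 0 is
#' fully transparent, probability 1 fully saturated red.
#'
#' @param slide the `wsi_slide`.
#' @param h its `wsi_heatmap`.
#' @param path output PNG path.
#' @param max_dim largest thumbnail side in pixels.
#' @return `path` invisibly, with attribute `squares` = number of cells
#'   drawn.
#' @export
render_overlay <- function(slide, h, path, max_dim = 1024) {
  ds <- vapply(slide$levels, `[[`, 0L, "downsample")
  fits <- which(vapply(slide$levels, function(lv)
    max(lv$width, lv$height) <= max_dim, FALSE))
  li <- if (length(fits)) fits[1] else length(slide$levels)
  lv <- slide$levels[[li]]
  g <- lv$data / 255
  thumb <- array(rep(g, 3), c(nrow(g), ncol(g), 3))
  scale <- slide$base_magnification / h$magnification  # base px per heatmap px
  to_thumb <- function(v) v * scale / lv$downsample
  n <- 0L
  for (iy in seq_along(h$ys)) for (ix in seq_along(h$xs)) {
    if (!h$valid[iy, ix]) next
    p <- h$grid[iy, ix]
    r0 <- clamp(floor(to_thumb(h$ys[iy])) + 1, 1, nrow(g))
    r1 <- clamp(ceiling(to_thumb(h$ys[iy] + h$tile_size_px)), 1, nrow(g))
    c0 <- clamp(floor(to_thumb(h$xs[ix])) + 1, 1, ncol(g))
    c1 <- clamp(ceiling(to_thumb(h$xs[ix] + h$tile_size_px)), 1, ncol(g))
    thumb[r0:r1, c0:c1, 1] <- (1 - p) * thumb[r0:r1, c0:c1, 1] + p
    thumb[r0:r1, c0:c1, 2] <- (1 - p) * thumb[r0:r1, c0:c1, 2]
    thumb[r0:r1, c0:c1, 3] <- (1 - p) * thumb[r0:r1, c0:c1, 3]
    n <- n + 1L
  }
  png::writePNG(thumb, path)
  out <- invisible(path)
  attr(out, "squares") <- n
  out
}
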