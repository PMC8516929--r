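# Tissue detection: Otsu thresholding on a grayscale thumbnail, and
# enumeration of candidate tiles over the tissue mask.

#' Otsu threshold of a 256-bin gray histogram
#'
#' Scans every split point t in 0..254 (class 0 = gray <= t, class 1 =
#' gray > t) and maximises the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2`; ties resolve to the lowest qualifying level.
#' The returned threshold is `t + 1`, so tissue pixels are those with
#' `gray < threshold`.
#'
#' @param histogram integer vector of 256 counts for gray levels 0..255.
#' @return threshold gray level in 1..255.
#' @export
otsu_threshold <- function(histogram) {
  if (length(histogram) != 256 || any(histogram < 0))
    stopf("histogram must be 256 non-negative counts")
  if (sum(histogram > 0) < 2)
    stopf("degenerate histogram: fewer than two occupied gray levels")
  g <- 0:255
  n <- sum(histogram)
  w0 <- cumsum(histogram)[1:255]
  s0 <- cumsum(histogram * g)[1:255]
  total <- sum(histogram * g)
  w1 <- n - w0
  mu0 <- ifelse(w0 > 0, s0 / w0, 0)
  mu1 <- ifelse(w1 > 0, (total - s0) / w1, 0)
  bcv <- (w0 / n) * (w1 / n) * (mu0 - mu1)^2
  bcv[w0 == 0 | w1 == 0] <- -Inf
  t_split <- which.max(bcv) - 1L  # which.max returns the first (lowest) max
  t_split + 1L
}

#' Detect tissue regions on a thumbnail
#'
#' Converts a working thumbnail (coarsest pyramid level, further
#' area-averaged to `working_downsample` relative to the base level) to
#' grayscale by luminance, computes the Otsu threshold of its histogram and
#' marks pixels darker than the threshold as tissue. A slide whose thumbnail
#' is single-valued has no separable classes: it yields an all-background
#' (bright) or all-tissue (dark) mask with a warning instead of an error.
#'
#' @param slide a `wsi_slide`.
#' @param working_downsample thumbnail downsample relative to base (default
#'   32).
#' @return object of class `tissue_mask`: logical `mask` (TRUE = tissue),
#'   `downsample`, `threshold`, plus base geometry and magnification.
#' @export
detect_tissue <- function(slide, working_downsample = 32) {
  stopifnot(inherits(slide, "wsi_slide"))
  ds <- vapply(slide$levels, `[[`, 0L, "downsample")
  li <- max(which(ds <= working_downsample))
  g <- as_gray(slide$levels[[li]]$data)
  f <- working_downsample / ds[li]
  if (f > 1) {
    if (abs(f - round(f)) > 1e-9)
      stopf("working_downsample %s is not a multiple of level downsample %d",
            working_downsample, ds[li])
    g <- quantize8(block_mean(g, as.integer(round(f)), partial = "average"))
  }
  h <- tabulate(as.integer(g) + 1L, nbins = 256L)
  if (sum(h > 0) < 2) {
    lone <- which(h > 0) - 1L
    warnf("slide thumbnail is single-valued (gray %d); %s mask returned",
          lone, if (lone >= 128) "empty" else "full")
    mask <- matrix(lone < 128, nrow(g), ncol(g))
    thr <- NA_integer_
  } else {
    thr <- otsu_threshold(h)
    mask <- g < thr
  }
  structure(list(mask = mask, downsample = working_downsample,
                 threshold = thr,
                 base_width = slide$levels[[1]]$width,
                 base_height = slide$levels[[1]]$height,
                 base_magnification = slide$base_magnification),
            class = "tissue_mask")
}

#' @export
print.tissue_mask <- function(x, ...) {
  cat(sprintf("<tissue_mask> %dx%d at /%g, threshold %s, tissue %.1f%%\n",
              ncol(x$mask), nrow(x$mask), x$downsample,
              ifelse(is.na(x$threshold), "NA", x$threshold),
              100 * mean(x$mask)))
  invisible(x)
}

# Mask-cell row/column ranges covered by a tile (half-open pixel intervals,
# outer cell bounds: floor start, ceiling end).
tile_mask_span <- function(px0, px1, cell, n) {
  i0 <- floor(px0 / cell)
  i1 <- ceiling(px1 / cell)
  c(max(i0, 0), min(i1, n))
}

#' Enumerate candidate tiles over tissue
#'
#' Lays a sliding-window grid (positions `0, stride, 2*stride, ...` with
#' `x + size <= width` at the target magnification) and keeps tiles whose
#' tissue fraction, measured on the thumbnail mask over the covered cells,
#' reaches `min_tissue_fraction`. Tiles are returned in row-major order
#' (y outer, x inner). Edge positions that would exceed the slide bounds are
#' discarded, not padded.
#'
#' @param mask a `tissue_mask`.
#' @param magnification target magnification of the tiles.
#' @param size_px tile side in pixels.
#' @param stride_px grid stride in pixels (default: `size_px`,
#'   non-overlapping).
#' @param min_tissue_fraction minimum tissue fraction in `[0, 1]` (default
#'   0.25).
#' @param slide_id id recorded on the returned `tile_ref`s.
#' @return list of `tile_ref`, with attributes `xs`, `ys` (grid positions)
#'   and `grid_index` (two-column matrix of row/col grid indices per tile).
#' @export
enumerate_tiles <- function(mask, magnification, size_px,
                            stride_px = size_px, min_tissue_fraction = 0.25,
                            slide_id = "slide") {
  stopifnot(inherits(mask, "tissue_mask"))
  if (!is_count(stride_px, 1)) stopf("stride_px must be >= 1")
  if (min_tissue_fraction < 0 || min_tissue_fraction > 1)
    stopf("min_tissue_fraction must be in [0, 1]")
  scale <- mask$base_magnification / magnification
  W <- floor(mask$base_width / scale)
  H <- floor(mask$base_height / scale)
  if (W < size_px || H < size_px) {
    out <- list()
    attr(out, "xs") <- integer(0); attr(out, "ys") <- integer(0)
    attr(out, "grid_index") <- matrix(0L, 0, 2)
    return(out)
  }
  xs <- seq(0L, W - size_px, by = stride_px)
  ys <- seq(0L, H - size_px, by = stride_px)
  cell <- mask$downsample / scale  # mask cells per magnification pixel^-1
  sat <- sat_table(mask$mask * 1)
  nr <- nrow(mask$mask); nc <- ncol(mask$mask)
  tiles <- vector("list", length(xs) * length(ys))
  gidx <- matrix(0L, length(xs) * length(ys), 2)
  k <- 0L
  for (iy in seq_along(ys)) {
    rs <- tile_mask_span(ys[iy] / cell, (ys[iy] + size_px) / cell, 1, nr)
    for (ix in seq_along(xs)) {
      cs <- tile_mask_span(xs[ix] / cell, (xs[ix] + size_px) / cell, 1, nc)
      area <- (rs[2] - rs[1]) * (cs[2] - cs[1])
      frac <- if (area <= 0) 0 else
        (sat[rs[2] + 1, cs[2] + 1] - sat[rs[1] + 1, cs[2] + 1] -
           sat[rs[2] + 1, cs[1] + 1] + sat[rs[1] + 1, cs[1] + 1]) / area
      if (frac >= min_tissue_fraction) {
        k <- k + 1L
        tiles[[k]] <- tile_ref(slide_id, magnification, xs[ix], ys[iy], size_px)
        gidx[k, ] <- c(iy, ix)
      }
    }
  }
  out <- tiles[seq_len(k)]
  attr(out, "xs") <- xs
  attr(out, "ys") <- ys
  attr(out, "grid_index") <- gidx[seq_len(k), , drop = FALSE]
  out
}

#' Export a tissue mask as a PNG for QC
#'
#' @param mask a `tissue_mask`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask$mask * 1, path)
  invisible(path)
}

#' Write a tile list as CSV
#'
#' Columns: slide_id, magnification, x, y, size.
#'
#' @param tiles list of `tile_ref`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tiles_csv <- function(tiles, path) {
  df <- data.frame(
    slide_id = vapply(tiles, `[[`, "", "slide_id"),
    magnification = vapply(tiles, `[[`, 0, "magnification"),
    x = vapply(tiles, `[[`, 0L, "x"),
    y = vapply(tiles, `[[`, 0L, "y"),
    size = vapply(tiles, `[[`, 0L, "size_px"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
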