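# Slide data model and raster I/O.
#
# Coordinate conventions: 0-based, top-left origin, half-open intervals
# [x, x + size). A nominal magnification m corresponds to m/2 px per micron,
# i.e. mpp(m) = 10 / m (so x20 = 0.5 um/px, x10 = 1.0 um/px). Conversions
# between magnifications scale by the magnification ratio and round toward
# zero.

#' Microns per pixel at a nominal magnification
#'
#' Calibration: x20 objective = 0.5 um/px, x10 = 1.0 um/px, i.e.
#' `mpp = 10 / magnification`.
#'
#' @param magnification nominal objective power (e.g. 20).
#' @return microns per pixel.
#' @export
mag_mpp <- function(magnification) 10 / magnification

#' Physical side length of a tile
#'
#' @param size_px tile side in pixels.
#' @param magnification nominal power at which the tile is read.
#' @return side length in microns (224 px at x20 gives 112 um).
#' @export
tile_physical_extent <- function(size_px, magnification) {
  size_px * mag_mpp(magnification)
}

#' Convert a pixel coordinate between magnifications
#'
#' Multiplies by the magnification ratio and truncates toward zero.
#'
#' @param x integer coordinate(s) at `from_mag`.
#' @param from_mag,to_mag nominal magnifications.
#' @return integer coordinate(s) at `to_mag`.
#' @export
convert_coord <- function(x, from_mag, to_mag) trunc(x * to_mag / from_mag)

#' Construct an in-memory slide from a base-level raster
#'
#' Builds the multi-level pyramid by repeated 2x area-average downsampling
#' (round half up to 8 bits per level) while both dimensions stay at or above
#' `min_level_px`.
#'
#' @param base numeric matrix (grayscale, 0-255) or H x W x 3 array.
#' @param mpp_base microns per pixel of the base level (> 0).
#' @param uri optional source locator.
#' @param max_downsample largest pyramid factor to build.
#' @param min_level_px stop once a level side would drop below this.
#' @return an object of class `wsi_slide` with fields `levels` (each
#'   `width`, `height`, `downsample`, `data`), `mpp_base`,
#'   `base_magnification`, `uri`.
#' @export
slide_from_raster <- function(base, mpp_base, uri = NA_character_,
                              max_downsample = 8, min_level_px = 128) {
  if (!is.numeric(mpp_base) || length(mpp_base) != 1 || mpp_base <= 0)
    stopf("mpp_base must be a positive number")
  base <- as_gray(base)
  levels <- list(list(width = ncol(base), height = nrow(base),
                      downsample = 1L, data = base))
  f <- 2L
  while (f <= max_downsample &&
         min(nrow(base), ncol(base)) %/% f >= min_level_px) {
    prev <- levels[[length(levels)]]$data
    levels[[length(levels) + 1L]] <-
      list(data = quantize8(block_mean(prev, 2L)))
    lv <- levels[[length(levels)]]
    levels[[length(levels)]]$width <- ncol(lv$data)
    levels[[length(levels)]]$height <- nrow(lv$data)
    levels[[length(levels)]]$downsample <- f
    f <- f * 2L
  }
  structure(list(levels = levels, mpp_base = mpp_base,
                 base_magnification = 10 / mpp_base, uri = uri),
            class = "wsi_slide")
}

#' @export
print.wsi_slide <- function(x, ...) {
  cat(sprintf("<wsi_slide> %dx%d px, %.3g um/px (x%g), %d level(s)\n",
              x$levels[[1]]$width, x$levels[[1]]$height, x$mpp_base,
              x$base_magnification, length(x$levels)))
  for (lv in x$levels)
    cat(sprintf("  level /%d: %dx%d\n", lv$downsample, lv$width, lv$height))
  invisible(x)
}

slide_sidecar_path <- function(uri) {
  paste0(tools::file_path_sans_ext(uri), ".json")
}

#' Write a slide to disk
#'
#' Pyramid levels go to a multi-page 8-bit TIFF (page i = level i), physical
#' calibration to a JSON sidecar next to it. Single-level slides may instead
#' be written as PNG (extension-driven), in which case no pyramid pages are
#' stored.
#'
#' @param slide a `wsi_slide`.
#' @param path output path ending in `.tif`, `.tiff` or `.png`.
#' @return `path`, invisibly.
#' @export
write_slide <- function(slide, path) {
  ext <- tolower(tools::file_ext(path))
  pages <- lapply(slide$levels, function(lv) lv$data / 255)
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  } else if (ext == "png") {
    png::writePNG(pages[[1]], path)
  } else stopf("unsupported slide extension '.%s'", ext)
  meta <- list(mpp_base = slide$mpp_base,
               base_magnification = slide$base_magnification,
               levels = lapply(slide$levels, function(lv)
                 list(width = lv$width, height = lv$height,
                      downsample = lv$downsample)))
  jsonlite::write_json(meta, slide_sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Open a slide from disk
#'
#' Reads a multi-page TIFF pyramid (or a plain single-level PNG/TIFF) plus
#' its JSON calibration sidecar. Without a sidecar the microns-per-pixel
#' must be supplied via `mpp`, otherwise opening fails.
#'
#' @param uri path to the raster file.
#' @param mpp optional microns-per-pixel override.
#' @return a `wsi_slide`.
#' @export
open_slide <- function(uri, mpp = NULL) {
  if (!file.exists(uri)) stopf("slide file not found: %s", uri)
  side <- slide_sidecar_path(uri)
  meta <- if (file.exists(side)) jsonlite::read_json(side) else NULL
  mpp_base <- mpp %||% meta$mpp_base
  if (is.null(mpp_base))
    stopf("slide %s has no calibration sidecar and no mpp override", uri)
  ext <- tolower(tools::file_ext(uri))
  pages <- if (ext %in% c("tif", "tiff")) {
    p <- tiff::readTIFF(uri, all = TRUE)
    if (!is.list(p)) list(p) else p
  } else if (ext == "png") {
    list(png::readPNG(uri))
  } else stopf("unsupported slide extension '.%s'", ext)
  pages <- lapply(pages, function(p) as_gray(quantize8(p * 255)))
  base_w <- ncol(pages[[1]])
  levels <- lapply(seq_along(pages), function(i) {
    list(width = ncol(pages[[i]]), height = nrow(pages[[i]]),
         downsample = as.integer(round(base_w / ncol(pages[[i]]))),
         data = pages[[i]])
  })
  ds <- vapply(levels, `[[`, 0L, "downsample")
  if (ds[1] != 1L || any(diff(ds) <= 0))
    stopf("slide %s: pyramid downsample factors must start at 1 and increase",
          uri)
  structure(list(levels = levels, mpp_base = as.numeric(mpp_base),
                 base_magnification = 10 / as.numeric(mpp_base), uri = uri),
            class = "wsi_slide")
}

#' Map categorical slide diagnoses to the binary task label
#'
#' The detection target is diffuse-type adenocarcinoma: `diffuse_ADC`
#' maps to "positive"; `other_ADC` and `non_neoplastic` map to "negative".
#' Labels already in binary form pass through.
#'
#' @param category character vector of diagnosis categories.
#' @return character vector of "positive"/"negative".
#' @export
binary_label <- function(category) {
  map <- c(diffuse_ADC = "positive", other_ADC = "negative",
           non_neoplastic = "negative", positive = "positive",
           negative = "negative")
  out <- unname(map[category])
  if (anyNA(out))
    stopf("unknown label categor%s: %s",
          if (sum(is.na(out)) > 1) "ies" else "y",
          paste(unique(category[is.na(out)]), collapse = ", "))
  out
}

#' Reference a square tile of a slide
#'
#' @param slide_id identifier of the slide.
#' @param magnification nominal power of the tile's pixel grid.
#' @param x,y 0-based top-left corner at that magnification.
#' @param size_px square side in pixels.
#' @return an object of class `tile_ref`.
#' @export
tile_ref <- function(slide_id, magnification, x, y, size_px) {
  if (!is_count(x) || !is_count(y) || !is_count(size_px, 1))
    stopf("tile coordinates must be non-negative integers, size >= 1")
  structure(list(slide_id = slide_id, magnification = magnification,
                 x = as.integer(x), y = as.integer(y),
                 size_px = as.integer(size_px)),
            class = "tile_ref")
}

#' @export
print.tile_ref <- function(x, ...) {
  cat(sprintf("<tile_ref> %s x%g (%d, %d) %dpx\n", x$slide_id,
              x$magnification, x$x, x$y, x$size_px))
  invisible(x)
}

# Slide dimensions on the pixel grid of a requested magnification.
slide_dims_at <- function(slide, magnification) {
  scale <- slide$base_magnification / magnification
  c(width = floor(slide$levels[[1]]$width / scale),
    height = floor(slide$levels[[1]]$height / scale))
}

# Pick the pyramid level to serve a requested magnification: the coarsest
# level still at or above the requested resolution (then area-average down);
# upscales are served from the base level.
level_for_scale <- function(slide, scale) {
  ds <- vapply(slide$levels, `[[`, 0L, "downsample")
  ok <- which(ds <= max(scale, 1))
  ok[which.max(ds[ok])]
}

#' Read a tile raster
#'
#' Pixels come from the pyramid level nearest the requested magnification
#' and are area-averaged (downscale) or bilinearly interpolated (upscale) to
#' the exact target grid, then quantised to 8 bits (round half up).
#'
#' @param slide a `wsi_slide`.
#' @param tile a `tile_ref` within bounds at its magnification.
#' @return integer array `size_px` x `size_px` x 3 (RGB, 0-255).
#' @export
read_tile <- function(slide, tile) {
  stopifnot(inherits(slide, "wsi_slide"), inherits(tile, "tile_ref"))
  mag <- tile$magnification
  dims <- slide_dims_at(slide, mag)
  if (tile$x + tile$size_px > dims["width"] ||
      tile$y + tile$size_px > dims["height"])
    stopf("tile (%d, %d, %dpx) out of bounds at x%g (%d x %d)",
          tile$x, tile$y, tile$size_px, mag, dims["width"], dims["height"])
  scale <- slide$base_magnification / mag
  li <- level_for_scale(slide, scale)
  lv <- slide$levels[[li]]
  f <- scale / lv$downsample
  if (f >= 1 && abs(f - round(f)) < 1e-9) {
    f <- as.integer(round(f))
    rows <- (tile$y * f + 1):((tile$y + tile$size_px) * f)
    cols <- (tile$x * f + 1):((tile$x + tile$size_px) * f)
    crop <- lv$data[rows, cols, drop = FALSE]
    out <- if (f == 1L) crop else quantize8(block_mean(crop, f))
  } else {
    # fractional or upscale path: crop the covering region, then bilinear
    r0 <- floor(tile$y * f); r1 <- ceiling((tile$y + tile$size_px) * f)
    c0 <- floor(tile$x * f); c1 <- ceiling((tile$x + tile$size_px) * f)
    r1 <- min(r1, lv$height); c1 <- min(c1, lv$width)
    crop <- lv$data[(r0 + 1):r1, (c0 + 1):c1, drop = FALSE]
    out <- quantize8(resize_bilinear(crop, tile$size_px, tile$size_px))
  }
  array(out, dim = c(tile$size_px, tile$size_px, 3L))
}
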