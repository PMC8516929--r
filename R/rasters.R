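# Raster primitives: grayscale conversion and resampling.
#
# Pixel values are integers on [0, 255] throughout the package; fractional
# intermediates are quantised with round-half-up (see quantize8). Downscaling
# uses exact area (block) averaging, upscaling uses bilinear interpolation.

#' Convert a raster to grayscale
#'
#' Standard luminance conversion `0.299 R + 0.587 G + 0.114 B` for 3-channel
#' arrays; single-channel matrices pass through unchanged.
#'
#' @param raster numeric matrix (H x W) or array (H x W x 3) of 0-255 values.
#' @return numeric matrix of 0-255 gray values (quantised).
#' @export
as_gray <- function(raster) {
  if (is.matrix(raster)) return(raster)
  d <- dim(raster)
  if (length(d) == 3 && d[3] >= 3) {
    return(quantize8(0.299 * raster[, , 1] + 0.587 * raster[, , 2] +
                       0.114 * raster[, , 3]))
  }
  if (length(d) == 3 && d[3] == 1) return(raster[, , 1])
  stopf("cannot convert raster with dims [%s] to grayscale",
        paste(d, collapse = ", "))
}

# Summed-area table with a zero border row/column.
sat_table <- function(m) {
  sat <- matrix(0, nrow(m) + 1, ncol(m) + 1)
  sat[-1, -1] <- t(apply(apply(m, 2, cumsum), 1, cumsum))
  sat
}

#' Area-average block downsampling
#'
#' Reduces a matrix by averaging `f` x `f` blocks. `partial = "drop"` crops a
#' trailing remainder (pyramid levels); `partial = "average"` averages the
#' smaller edge blocks so the output has `ceiling(dim / f)` cells
#' (thumbnails/masks).
#'
#' @param m numeric matrix.
#' @param f integer block factor >= 1.
#' @param partial "drop" or "average".
#' @return numeric matrix of block means (not quantised).
#' @export
block_mean <- function(m, f, partial = c("drop", "average")) {
  partial <- match.arg(partial)
  if (f == 1) return(m)
  H <- nrow(m); W <- ncol(m)
  oh <- H %/% f; ow <- W %/% f
  if ((partial == "drop" || (H %% f == 0 && W %% f == 0)) &&
      oh >= 1 && ow >= 1) {
    # exact f x f blocks: fold rows then columns via array reshaping
    m <- m[seq_len(oh * f), seq_len(ow * f), drop = FALSE]
    a <- colMeans(array(m, c(f, oh, ow * f)), dims = 1)        # oh x (ow*f)
    return(t(colMeans(array(t(a), c(f, ow, oh)), dims = 1)))   # oh x ow
  }
  # ragged edge blocks: summed-area table over block boundaries
  rb <- seq(0, oh * f, by = f)
  cb <- seq(0, ow * f, by = f)
  if (partial == "average") {
    if (rb[length(rb)] < H) rb <- c(rb, H)
    if (cb[length(cb)] < W) cb <- c(cb, W)
  }
  if (length(rb) < 2 || length(cb) < 2)
    stopf("matrix %dx%d too small for block factor %d", H, W, f)
  A <- sat_table(m)[rb + 1, cb + 1, drop = FALSE]
  nr <- length(rb); nc <- length(cb)
  sums <- A[-1, -1, drop = FALSE] - A[-nr, -1, drop = FALSE] -
    A[-1, -nc, drop = FALSE] + A[-nr, -nc, drop = FALSE]
  sums / outer(diff(rb), diff(cb))
}

#' Bilinear resampling
#'
#' Pixel-centre convention: output pixel j samples source coordinate
#' `(j - 0.5) * W / ow + 0.5` on the 1-based source grid, clamped at the
#' borders.
#'
#' @param m numeric matrix.
#' @param oh,ow output dimensions.
#' @return numeric matrix `oh` x `ow` (not quantised).
#' @export
resize_bilinear <- function(m, oh, ow) {
  H <- nrow(m); W <- ncol(m)
  sy <- clamp((seq_len(oh) - 0.5) * H / oh + 0.5, 1, H)
  sx <- clamp((seq_len(ow) - 0.5) * W / ow + 0.5, 1, W)
  y0 <- pmin(floor(sy), H - 1L); x0 <- pmin(floor(sx), W - 1L)
  if (H == 1) y0 <- rep(1, oh)
  if (W == 1) x0 <- rep(1, ow)
  wy <- sy - y0; wx <- sx - x0
  y1 <- pmin(y0 + 1, H); x1 <- pmin(x0 + 1, W)
  top <- m[y0, x0, drop = FALSE] * (1 - wx)[col(matrix(0, oh, ow))] +
    m[y0, x1, drop = FALSE] * wx[col(matrix(0, oh, ow))]
  bot <- m[y1, x0, drop = FALSE] * (1 - wx)[col(matrix(0, oh, ow))] +
    m[y1, x1, drop = FALSE] * wx[col(matrix(0, oh, ow))]
  top * (1 - wy) + bot * wy
}

# Resample to a target size: exact block averaging when the factor is a
# common integer, bilinear otherwise (including all upscales).
resample_to <- function(m, oh, ow) {
  H <- nrow(m); W <- ncol(m)
  if (H == oh && W == ow) return(m)
  if (H %% oh == 0 && W %% ow == 0 && H %/% oh == W %/% ow)
    return(block_mean(m, H %/% oh))
  resize_bilinear(m, oh, ow)
}
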