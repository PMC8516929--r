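# Brute-force Otsu oracle: exhaustive scan over all split points.
otsu_oracle <- function(h) {
  g <- 0:255
  n <- sum(h)
  best <- -Inf; best_t <- NA
  for (t in 0:254) {
    w0 <- sum(h[1:(t + 1)]); w1 <- n - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(h[1:(t + 1)] * g[1:(t + 1)]) / w0
    mu1 <- sum(h[(t + 2):256] * g[(t + 2):256]) / w1
    v <- (w0 / n) * (w1 / n) * (mu0 - mu1)^2
    if (v > best + 1e-12) { best <- v; best_t <- t }
  }
  best_t + 1L
}

test_that("otsu splits a bimodal histogram between the modes", {
  h <- integer(256); h[61] <- 50; h[201] <- 50  # gray 60 and 200
  thr <- otsu_threshold(h)
  expect_gt(thr, 60)
  expect_lt(thr, 200)
})

test_that("otsu equals the exhaustive-scan oracle on random histograms", {
  withr::local_seed(42)
  for (i in 1:120) {
    h <- integer(256)
    modes <- sample(0:255, sample(2:4, 1))
    for (m in modes) {
      lo <- max(0, m - 12); hi <- min(255, m + 12)
      h[(lo:hi) + 1] <- h[(lo:hi) + 1] +
        rpois(hi - lo + 1, 30 * exp(-((lo:hi) - m)^2 / 50))
    }
    if (sum(h > 0) < 2) next
    expect_identical(otsu_threshold(h), otsu_oracle(h))
  }
})

test_that("otsu tie-break returns the lowest qualifying level", {
  # two spikes only: every split between them has identical variance
  h <- integer(256); h[11] <- 10; h[241] <- 10
  expect_identical(otsu_threshold(h), 11L)  # lowest split t = 10 -> threshold 11
  expect_error(otsu_threshold(integer(256) + c(5, rep(0, 255))), "degenerate")
})

test_that("detect_tissue recovers the generator's tissue ground truth", {
  r <- generate_slide(small_spec(seed = 9))
  tm <- detect_tissue(r$slide, working_downsample = 8)
  gt <- block_mean(r$tissue_mask * 1, 8, partial = "average") >= 0.5
  jacc <- sum(tm$mask & gt) / sum(tm$mask | gt)
  expect_gte(jacc, 0.9)
})

test_that("blank and all-dark slides degrade gracefully", {
  expect_warning(tm <- detect_tissue(constant_slide(255, 128), 4), "single-valued")
  expect_false(any(tm$mask))
  expect_warning(tm2 <- detect_tissue(constant_slide(20, 128), 4), "single-valued")
  expect_true(all(tm2$mask))
})

full_mask <- function(n, value = TRUE, downsample = 1, mag = 20) {
  structure(list(mask = matrix(value, n, n), downsample = downsample,
                 threshold = 128L, base_width = n * downsample,
                 base_height = n * downsample, base_magnification = mag),
            class = "tissue_mask")
}

test_that("enumerate_tiles lays the expected sliding grid", {
  tiles <- enumerate_tiles(full_mask(1000), 20, 224, 224, 0)
  expect_length(tiles, 16)  # floor((1000-224)/224)+1 = 4 per axis
  # row-major order
  xy <- t(vapply(tiles, function(t) c(t$x, t$y), c(0, 0)))
  expect_equal(xy[1:4, 2], rep(0, 4))
  expect_equal(xy[1:4, 1], c(0, 224, 448, 672))
  expect_length(enumerate_tiles(full_mask(1000, FALSE), 20, 224, 224, 0.01), 0)
  # min_tissue_fraction = 0 accepts everything even over an empty mask
  expect_length(enumerate_tiles(full_mask(1000, FALSE), 20, 224, 224, 0), 16)
})

# Independent brute-force oracle: double loop with direct per-tile counting.
enumerate_oracle <- function(mask, mag, size, stride, minfrac) {
  scale <- mask$base_magnification / mag
  W <- floor(mask$base_width / scale); H <- floor(mask$base_height / scale)
  cell <- mask$downsample / scale
  out <- list()
  if (W < size || H < size) return(out)
  for (y in seq(0, H - size, by = stride)) {
    for (x in seq(0, W - size, by = stride)) {
      r0 <- max(floor(y / cell), 0); r1 <- min(ceiling((y + size) / cell), nrow(mask$mask))
      c0 <- max(floor(x / cell), 0); c1 <- min(ceiling((x + size) / cell), ncol(mask$mask))
      frac <- mean(mask$mask[(r0 + 1):r1, (c0 + 1):c1])
      if (frac >= minfrac) out[[length(out) + 1]] <- c(x, y)
    }
  }
  out
}

test_that("enumerate_tiles matches the brute-force oracle on random masks", {
  withr::local_seed(7)
  for (i in 1:110) {
    n <- sample(20:60, 1)
    ds <- sample(c(4, 8), 1)
    mag <- sample(c(10, 20), 1)
    mask <- full_mask(n, downsample = ds, mag = mag)
    mask$mask <- matrix(runif(n * n) < runif(1, 0.2, 0.8), n, n)
    size <- sample(c(16, 24, 32), 1)
    stride <- sample(c(size %/% 2, size), 1)
    minfrac <- runif(1, 0, 0.8)
    got <- enumerate_tiles(mask, mag, size, stride, minfrac)
    want <- enumerate_oracle(mask, mag, size, stride, minfrac)
    expect_equal(length(got), length(want))
    if (length(got) > 0) {
      expect_equal(t(vapply(got, function(t) c(t$x, t$y), c(0, 0))),
                   do.call(rbind, want), ignore_attr = TRUE)
    }
  }
})

test_that("QC exports write the expected artefacts", {
  r <- generate_slide(small_spec(seed = 15))
  tm <- detect_tissue(r$slide, 8)
  dir <- withr::local_tempdir()
  write_mask_png(tm, file.path(dir, "m.png"))
  img <- png::readPNG(file.path(dir, "m.png"))
  expect_equal(dim(img)[1:2], dim(tm$mask))
  expect_equal(img > 0.5, unname(tm$mask))
  tiles <- enumerate_tiles(tm, 20, 128, slide_id = "s")
  write_tiles_csv(tiles, file.path(dir, "t.csv"))
  df <- utils::read.csv(file.path(dir, "t.csv"))
  expect_equal(nrow(df), length(tiles))
  expect_named(df, c("slide_id", "magnification", "x", "y", "size"))
})

test_that("raising min_tissue_fraction never adds tiles; stride-size tiles are disjoint", {
  withr::local_seed(11)
  mask <- full_mask(40, downsample = 8)
  mask$mask <- matrix(runif(1600) < 0.5, 40, 40)
  fracs <- seq(0, 1, by = 0.1)
  counts <- vapply(fracs, function(f)
    length(enumerate_tiles(mask, 20, 32, 32, f)), 0L)
  expect_true(all(diff(counts) <= 0))
  tiles <- enumerate_tiles(mask, 20, 32, 32, 0)
  xy <- t(vapply(tiles, function(t) c(t$x, t$y), c(0, 0)))
  expect_false(anyDuplicated(xy) > 0)
  expect_true(all(diff(sort(unique(xy[, 1]))) >= 32))
})
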