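test_that("heatmap geometry matches the tile grid and stubs fill it", {
  r <- generate_slide(small_spec(seed = 41))
  tm <- detect_tissue(r$slide)
  tiles <- enumerate_tiles(tm, 20, 128, slide_id = r$slide_id)
  h <- predict_heatmap(r$slide, constant_scorer(0.3), 20, 128,
                       slide_id = r$slide_id)
  expect_equal(dim(h$grid), c(length(attr(tiles, "ys")), length(attr(tiles, "xs"))))
  expect_equal(sum(h$valid), length(tiles))
  expect_true(all(h$grid[h$valid] == 0.3))
  expect_true(all(is.na(h$grid[!h$valid])))
})

test_that("an all-background slide yields an empty heatmap with a warning", {
  s <- constant_slide(255, 256)
  tm <- suppressWarnings(detect_tissue(s))
  expect_warning(h <- predict_heatmap(s, constant_scorer(0.9), 20, 64,
                                      tissue = tm),
                 "no tissue")
  expect_false(any(h$valid))
  expect_error(slide_probability(h), "no valid cells")
})

test_that("slide probability is the max over valid cells and is monotone", {
  mk <- function(vals) {
    g <- matrix(NA_real_, 2, 2)
    g[seq_along(vals)] <- vals
    structure(list(slide_id = "s", magnification = 20, tile_size_px = 64,
                   stride_px = 64, grid = g, valid = !is.na(g),
                   xs = c(0, 64), ys = c(0, 64), origin = c(0, 0)),
              class = "wsi_heatmap")
  }
  expect_equal(slide_probability(mk(c(0.1, 0.8, 0.3))), 0.8)
  expect_equal(slide_probability(mk(0.42)), 0.42)
  withr::local_seed(3)
  for (i in 1:100) {
    vals <- runif(sample(1:3, 1))
    p0 <- slide_probability(mk(vals))
    expect_gte(slide_probability(mk(c(vals, runif(1)))), p0)
  }
})

test_that("a trained scorer scores lesion cells above plain tissue", {
  entries <- memory_entries(4, 4, seed = 77, width_px = 768L, height_px = 768L,
                            lesion_region_diameter_px = 140L)
  cfg <- pipeline_config(tile_size = 128L, seed = 77, switch_patience = 1L,
                         stop_patience = 2L)
  fit <- train_wsi_classifier(entries[c(1:3, 5:7)], entries[c(4, 8)], cfg)
  r <- generate_slide(synthetic_slide_spec(width_px = 768L, height_px = 768L,
                                           n_tissue_blobs = 2L, lesion = TRUE,
                                           n_lesion_regions = 1L,
                                           lesion_region_diameter_px = 140L,
                                           seed = 1234L))
  h <- predict_heatmap(r$slide, fit$model, cfg$magnification, cfg$tile_size,
                       slide_id = r$slide_id)
  les <- matrix(FALSE, nrow(h$grid), ncol(h$grid))
  for (iy in seq_along(h$ys)) for (ix in seq_along(h$xs)) {
    if (!h$valid[iy, ix]) next
    les[iy, ix] <- any(vapply(r$annotations$polygons, function(p)
      rect_intersects_ring(h$xs[ix], h$ys[iy], h$xs[ix] + 128, h$ys[iy] + 128,
                           p$ring), FALSE))
  }
  expect_gt(sum(les & h$valid), 0)
  expect_gt(sum(!les & h$valid), 0)
  expect_gt(mean(h$grid[les & h$valid]),
            mean(h$grid[!les & h$valid]))
})

test_that("two-stage combination is the probability product", {
  expect_equal(two_stage_probability(1.0, 0.37), 0.37)
  expect_equal(two_stage_probability(0.0, 0.99), 0.0)
  expect_equal(two_stage_probability(0.8, 0.5), 0.4)
  expect_error(two_stage_probability(1.2, 0.5), "p1")
  expect_error(two_stage_probability(0.5, -0.1), "p2")
  # product bound: combined never exceeds either stage
  withr::local_seed(5)
  p1 <- runif(100); p2 <- runif(100)
  pc <- two_stage_probability(p1, p2)
  expect_true(all(pc <= p1 & pc <= p2))
})

test_that("heatmap cells cover the stated physical extent", {
  expect_equal(tile_physical_extent(224, 20), 112)
  r <- generate_slide(small_spec(seed = 51))
  h <- predict_heatmap(r$slide, constant_scorer(0.5), 20, 128)
  expect_equal(h$tile_size_px * mag_mpp(h$magnification), 64)
  # stride = size -> pixel-disjoint cells
  expect_true(all(diff(h$xs) == h$stride_px))
})

test_that("overlay rendering draws one square per valid cell with endpoint colours", {
  r <- generate_slide(small_spec(seed = 61))
  h <- predict_heatmap(r$slide, constant_scorer(1.0), 20, 128)
  dir <- withr::local_tempdir()
  out <- render_overlay(r$slide, h, file.path(dir, "o.png"))
  expect_equal(attr(out, "squares"), sum(h$valid))
  img <- png::readPNG(file.path(dir, "o.png"))
  lv <- r$slide$levels[[1]]  # finest level fitting max_dim serves as thumbnail
  expect_equal(dim(img)[1:2], c(lv$height, lv$width))
  # p = 1 cells are maximal red
  expect_true(any(img[, , 1] == 1 & img[, , 2] == 0))

  h0 <- predict_heatmap(r$slide, constant_scorer(0.0), 20, 128)
  render_overlay(r$slide, h0, file.path(dir, "o0.png"))
  img0 <- png::readPNG(file.path(dir, "o0.png"))
  # p = 0 cells are fully transparent: thumbnail unchanged
  expect_equal(img0[, , 1], lv$data / 255, tolerance = 1 / 255)
})
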