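# Shared fixtures, all generated in code at test time.

small_spec <- function(seed = 1L, lesion = FALSE, ...) {
  synthetic_slide_spec(width_px = 512L, height_px = 512L, n_tissue_blobs = 2L,
                       lesion = lesion,
                       n_lesion_regions = if (lesion) 1L else 0L,
                       lesion_region_diameter_px = 100L, seed = seed, ...)
}

# In-memory labelled slide entries (no disk round trip) for training tests.
# The lesion flag is assigned per slide by generate_cohort, so extra args
# only tune geometry/texture.
memory_entries <- function(n_pos, n_neg, seed = 1L, spec = small_spec(), ...) {
  extra <- list(...)
  extra$lesion <- NULL; extra$n_lesion_regions <- NULL
  spec <- do.call(synthetic_slide_spec,
                  utils::modifyList(unclass(spec), extra))
  cohort <- generate_cohort(n_pos, n_neg, spec, seed)
  lapply(cohort, function(r)
    list(slide = r$slide, annotations = r$annotations, label = r$label,
         slide_id = r$slide_id))
}

# Uniform in-memory slide of a constant gray value.
constant_slide <- function(value, size = 256L, mpp = 0.5) {
  slide_from_raster(matrix(value, size, size), mpp, min_level_px = 64)
}

# Random simple (star-shaped) ring around a centre.
random_ring <- function(cx, cy, r0, n = 24) {
  theta <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  r <- r0 * runif(n, 0.7, 1.3)
  cbind(cx + r * cos(theta), cy + r * sin(theta))
}

# Independent rasterisation-based tile/polygon intersection oracle: sample
# the tile square on an integer lattice and test membership per point.
raster_intersects_ring <- function(x, y, size, ring) {
  g <- expand.grid(px = seq(x, x + size, by = max(1, size / 64)),
                   py = seq(y, y + size, by = max(1, size / 64)))
  any(points_in_ring(g$px, g$py, ring))
}

# A linearly separable 2-feature stand-in dataset.
separable_features <- function(n_per_class, gap = 2, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(2 * n_per_class, -gap / 2, 0.5), ncol = 2),
             matrix(rnorm(2 * n_per_class, gap / 2, 0.5), ncol = 2))
  list(features = X, y = rep(c(0L, 1L), each = n_per_class))
}

# Minimal scorer-like model over raw features: logistic head, trained by
# gradient steps; used to exercise the phase loops with arbitrary features.
feature_head <- function(nfeat, seed = 1) {
  s <- build_scorer(backbone_spec(list(
    layer_conv("c1", 3L, 1L, nfeat), layer_act("a1"), layer_gpool("g"),
    layer_bn("bn", nfeat), layer_dense("head", nfeat, 1L)
  ), input = c(8L, 8L, 1L)), seed = seed)
  s
}

# Tile pool built directly from synthetic tiles (no slide needed) for
# stream tests: n dummy tiles at distinct positions.
dummy_pool <- function(slide_id, label, n_tiles, size = 32L) {
  tiles <- lapply(seq_len(n_tiles) - 1L, function(i)
    tile_ref(slide_id, 20, i * size, 0L, size))
  structure(list(slide_id = slide_id, label = label, tiles = tiles,
                 source = "whole_tissue"), class = "tile_pool")
}
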