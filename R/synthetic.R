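# Deterministic synthetic slides: near-white background, darker tissue
# blobs (perturbed circles), and an optional high-frequency dark-speckle
# lesion texture embedded only in positive slides, with matching polygon
# annotations. Stands in for clinical WSIs in every test.

#' Specification of a synthetic slide
#'
#' Gray-level defaults: background 240 +/- 5, tissue 180 +/- 15, lesion
#' speckle dots 60 +/- 20 (Bernoulli density `speckle_density` inside lesion
#' polygons), chosen so Otsu cleanly separates background from tissue.
#' Negative slides may carry `n_distractor_regions` regions of sparser
#' speckle (density `distractor_density`) that mimic borderline textures
#' without being annotated or changing the label.
#'
#' @param width_px,height_px slide dimensions in pixels (> 0).
#' @param mpp_base microns per pixel at the base level (> 0; 0.5 = x20).
#' @param n_tissue_blobs number of tissue blobs (>= 1).
#' @param lesion logical; does the slide carry lesion regions?
#' @param n_lesion_regions number of lesion regions (>= 1 iff `lesion`).
#' @param lesion_region_diameter_px nominal lesion diameter in base pixels.
#' @param n_distractor_regions sparser speckle regions without annotations.
#' @param speckle_density per-pixel probability of a dark dot inside lesions.
#' @param distractor_density same, for distractor regions.
#' @param background_gray,background_sd,tissue_gray,tissue_sd,speckle_gray,speckle_sd
#'   gray-level parameters.
#' @param seed integer RNG seed.
#' @return object of class `synthetic_slide_spec`.
#' @export
synthetic_slide_spec <- function(width_px = 2048, height_px = 2048,
                                 mpp_base = 0.5, n_tissue_blobs = 3,
                                 lesion = FALSE,
                                 n_lesion_regions = if (lesion) 2L else 0L,
                                 lesion_region_diameter_px = 200,
                                 n_distractor_regions = 0L,
                                 speckle_density = 0.06,
                                 distractor_density = 0.015,
                                 background_gray = 240, background_sd = 5,
                                 tissue_gray = 180, tissue_sd = 15,
                                 speckle_gray = 60, speckle_sd = 20,
                                 seed = 1L) {
  spec <- structure(as.list(environment()), class = "synthetic_slide_spec")
  if (!is_count(spec$width_px, 1) || !is_count(spec$height_px, 1))
    stopf("slide dimensions must be positive integers")
  if (spec$mpp_base <= 0) stopf("mpp_base must be > 0")
  if (!is_count(spec$n_tissue_blobs, 1)) stopf("n_tissue_blobs must be >= 1")
  if (spec$lesion && spec$n_lesion_regions < 1)
    stopf("lesion slides need n_lesion_regions >= 1")
  if (!spec$lesion && spec$n_lesion_regions != 0)
    stopf("non-lesion slides must have n_lesion_regions = 0")
  if (spec$lesion_region_diameter_px >= min(spec$width_px, spec$height_px))
    stopf("lesion diameter must be smaller than the slide")
  spec
}

# A randomised blob: a circle of nominal radius r0 whose radius is modulated
# by a few low-frequency harmonics, r(theta) = r0 * s(theta), clipped to
# [min_scale, max_scale]. Star-shaped by construction, so the boundary
# polygon (64 vertices) is simple and its interior matches the pixel mask.
blob_shape <- function(r0, n_harmonics = 3, amp_sd = 0.08,
                       min_scale = 0.55, max_scale = 1.3) {
  amps <- stats::rnorm(n_harmonics, 0, amp_sd)
  phases <- stats::runif(n_harmonics, 0, 2 * pi)
  scale_fun <- function(theta) {
    s <- rep(1, length(theta))
    for (k in seq_len(n_harmonics)) s <- s + amps[k] * cos(k * theta + phases[k])
    clamp(s, min_scale, max_scale)
  }
  list(scale_fun = scale_fun, max_scale = max_scale)
}

blob_mask <- function(W, H, cx, cy, shape, r0) {
  # evaluate only over the blob's bounding box; the mask is FALSE elsewhere
  R <- r0 * shape$max_scale + 1
  rows <- max(1, floor(cy - R)):min(H, ceiling(cy + R))
  cols <- max(1, floor(cx - R)):min(W, ceiling(cx + R))
  dx <- matrix(rep(cols - cx, each = length(rows)), length(rows))
  dy <- matrix(rep(rows - cy, times = length(cols)), length(rows))
  theta <- atan2(dy, dx)
  r <- r0 * shape$scale_fun(theta)
  mask <- matrix(FALSE, H, W)
  mask[rows, cols] <- dx * dx + dy * dy < r * r
  mask
}

blob_polygon <- function(cx, cy, shape, r0, n_vertices = 64) {
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  r <- r0 * shape$scale_fun(theta)
  cbind(cx + r * cos(theta), cy + r * sin(theta))
}

#' Generate a synthetic slide
#'
#' Deterministic for a fixed spec seed. The base raster is built at full
#' resolution and the pyramid is synthesised by repeated 2x area-average
#' downsampling. Lesion regions are placed inside tissue blobs; their
#' boundary polygons become the ground-truth annotations. The returned
#' object also carries the generator's own tissue and lesion pixel masks as
#' ground truth for tests.
#'
#' @param spec a `synthetic_slide_spec`.
#' @param slide_id identifier stamped on the result.
#' @return object of class `synthetic_slide_result`: `slide` (`wsi_slide`),
#'   `annotations` (`wsi_annotations`), `label` ("positive"/"negative"),
#'   `tissue_mask`, `lesion_mask` (base-level logical matrices), `slide_id`.
#' @export
generate_slide <- function(spec, slide_id = sprintf("slide_seed%d", spec$seed)) {
  stopifnot(inherits(spec, "synthetic_slide_spec"))
  W <- spec$width_px; H <- spec$height_px
  with_seed(spec$seed, {
    img <- matrix(stats::rnorm(H * W, spec$background_gray, spec$background_sd),
                  H, W)
    tissue <- matrix(FALSE, H, W)
    blob_centers <- matrix(0, spec$n_tissue_blobs, 3)  # cx, cy, r0
    for (b in seq_len(spec$n_tissue_blobs)) {
      r0 <- stats::runif(1, 0.12, 0.22) * min(W, H)
      shape <- blob_shape(r0)
      margin <- r0 * shape$max_scale + 2
      cx <- if (2 * margin >= W) W / 2 else stats::runif(1, margin, W - margin)
      cy <- if (2 * margin >= H) H / 2 else stats::runif(1, margin, H - margin)
      tissue <- tissue | blob_mask(W, H, cx, cy, shape, r0)
      blob_centers[b, ] <- c(cx, cy, r0)
    }
    img[tissue] <- stats::rnorm(sum(tissue), spec$tissue_gray, spec$tissue_sd)

    paint_speckle <- function(region_mask, density) {
      idx <- which(region_mask)
      dots <- idx[stats::runif(length(idx)) < density]
      img[dots] <<- stats::rnorm(length(dots), spec$speckle_gray, spec$speckle_sd)
    }
    place_region <- function(diameter, host) {
      r_les <- diameter / 2
      shape <- blob_shape(r_les, amp_sd = 0.05, min_scale = 0.75,
                          max_scale = 1.2)
      # keep the region well inside its host blob (and the slide)
      off_max <- max(0, 0.45 * host[3] - r_les * shape$max_scale)
      ang <- stats::runif(1, 0, 2 * pi)
      off <- stats::runif(1, 0, off_max)
      cx <- clamp(host[1] + off * cos(ang), r_les * 1.25 + 1, W - r_les * 1.25 - 1)
      cy <- clamp(host[2] + off * sin(ang), r_les * 1.25 + 1, H - r_les * 1.25 - 1)
      list(mask = blob_mask(W, H, cx, cy, shape, r_les),
           polygon = blob_polygon(cx, cy, shape, r_les))
    }

    hosts <- order(blob_centers[, 3], decreasing = TRUE)  # largest blobs first
    lesion <- matrix(FALSE, H, W)
    polygons <- list()
    if (spec$lesion) {
      for (j in seq_len(spec$n_lesion_regions)) {
        host <- blob_centers[hosts[(j - 1) %% length(hosts) + 1], ]
        reg <- place_region(spec$lesion_region_diameter_px, host)
        fresh <- reg$mask & !tissue
        if (any(fresh)) {  # absorb any overhang into tissue
          img[fresh] <- stats::rnorm(sum(fresh), spec$tissue_gray, spec$tissue_sd)
          tissue <- tissue | reg$mask
        }
        paint_speckle(reg$mask, spec$speckle_density)
        lesion <- lesion | reg$mask
        polygons[[length(polygons) + 1]] <-
          list(ring = reg$polygon, label = "lesion")
      }
    }
    if (spec$n_distractor_regions > 0) {
      for (j in seq_len(spec$n_distractor_regions)) {
        host <- blob_centers[hosts[(j - 1) %% length(hosts) + 1], ]
        reg <- place_region(spec$lesion_region_diameter_px, host)
        fresh <- reg$mask & !tissue
        if (any(fresh)) {
          img[fresh] <- stats::rnorm(sum(fresh), spec$tissue_gray, spec$tissue_sd)
          tissue <- tissue | reg$mask
        }
        paint_speckle(reg$mask, spec$distractor_density)
      }
    }
    base <- quantize8(img)
    slide <- slide_from_raster(base, spec$mpp_base)
    structure(list(slide = slide,
                   annotations = annotation_set(polygons),
                   label = if (spec$lesion) "positive" else "negative",
                   tissue_mask = tissue, lesion_mask = lesion,
                   slide_id = slide_id, spec = spec),
              class = "synthetic_slide_result")
  })
}

#' @export
print.synthetic_slide_result <- function(x, ...) {
  cat(sprintf("<synthetic_slide_result> %s (%s), %d annotation(s), tissue %.1f%%\n",
              x$slide_id, x$label, length(x$annotations),
              100 * mean(x$tissue_mask)))
  invisible(x)
}

#' Generate a labelled cohort of synthetic slides
#'
#' Produces `n_positive` positive slides (lesion texture + annotations)
#' followed by `n_negative` negative slides, each generated with a per-slide
#' seed derived from the cohort seed via [derive_seed()] so cohorts are
#' stable under reordering.
#'
#' @param n_positive,n_negative slide counts (>= 0).
#' @param base_spec template `synthetic_slide_spec`; the lesion fields and
#'   seed are overridden per slide.
#' @param seed cohort seed.
#' @return list of `synthetic_slide_result`.
#' @export
cohort_member_spec <- function(base_spec, i, n_positive, seed) {
  pos <- i <= n_positive
  spec_i <- unclass(base_spec)
  spec_i$lesion <- pos
  spec_i$n_lesion_regions <- if (pos) max(1L, base_spec$n_lesion_regions) else 0L
  spec_i$seed <- derive_seed(seed, i)
  list(spec = do.call(synthetic_slide_spec, spec_i),
       slide_id = sprintf("slide_%03d_%s", i, if (pos) "pos" else "neg"),
       label = if (pos) "positive" else "negative")
}

generate_cohort <- function(n_positive, n_negative,
                            base_spec = synthetic_slide_spec(), seed = 1L) {
  if (!is_count(n_positive) || !is_count(n_negative))
    stopf("slide counts must be non-negative integers")
  lapply(seq_len(n_positive + n_negative), function(i) {
    m <- cohort_member_spec(base_spec, i, n_positive, seed)
    generate_slide(m$spec, slide_id = m$slide_id)
  })
}

#' Write a cohort to disk
#'
#' Lays out `slides/<id>.tif` (+ JSON calibration sidecars),
#' `annotations/<id>.geojson` for annotated slides, and a `manifest.csv`
#' with columns slide_path, annotation_path, label (and split, when
#' `split` is given). Paths in the manifest are relative to `out_dir`.
#'
#' @param cohort list of `synthetic_slide_result`.
#' @param out_dir output directory (must be empty unless `force`).
#' @param split optional character vector (one entry per slide, e.g.
#'   "train"/"val"/"test") recorded in the manifest.
#' @param force overwrite a non-empty directory.
#' @return path of the manifest, invisibly.
#' @export
write_cohort <- function(cohort, out_dir, split = NULL, force = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force)
    stopf("output directory %s is not empty (use force = TRUE)", out_dir)
  if (!is.null(split) && length(split) != length(cohort))
    stopf("split must have one entry per slide")
  dir.create(file.path(out_dir, "slides"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "annotations"), showWarnings = FALSE)
  rows <- lapply(seq_along(cohort), function(i) {
    r <- cohort[[i]]
    sp <- file.path("slides", paste0(r$slide_id, ".tif"))
    write_slide(r$slide, file.path(out_dir, sp))
    ap <- ""
    if (length(r$annotations) > 0) {
      ap <- file.path("annotations", paste0(r$slide_id, ".geojson"))
      write_annotations(r$annotations, file.path(out_dir, ap))
    }
    data.frame(slide_id = r$slide_id, slide_path = sp, annotation_path = ap,
               label = r$label,
               split = if (is.null(split)) NA_character_ else split[i])
  })
  manifest <- do.call(rbind, rows)
  if (is.null(split)) manifest$split <- NULL
  path <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
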