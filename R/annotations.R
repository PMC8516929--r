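# Polygon annotations: labelled closed rings in base-level pixel
# coordinates, carried as GeoJSON FeatureCollections on disk.

# Proper segment intersection test (shared endpoints of adjacent ring edges
# are excluded by the caller). Collinear overlap counts as intersecting.
segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  on_seg <- function(a, b, c) {
    d(a, b, c) == 0 &&
      min(a[1], b[1]) <= c[1] && c[1] <= max(a[1], b[1]) &&
      min(a[2], b[2]) <= c[2] && c[2] <= max(a[2], b[2])
  }
  on_seg(p3, p4, p1) || on_seg(p3, p4, p2) ||
    on_seg(p1, p2, p3) || on_seg(p1, p2, p4)
}

ring_self_intersects <- function(ring) {
  n <- nrow(ring)
  if (n < 4) return(FALSE)
  seg <- function(i) list(ring[i, ], ring[i %% n + 1, ])
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    j <- i + 2
    while (j <= jmax) {
      a <- seg(i); b <- seg(j)
      if (segments_intersect(a[[1]], a[[2]], b[[1]], b[[2]])) return(TRUE)
      j <- j + 1
    }
  }
  FALSE
}

validate_ring <- function(ring, what = "polygon") {
  ring <- as.matrix(ring)
  if (ncol(ring) != 2 || nrow(ring) < 3)
    stopf("%s ring needs an n x 2 matrix with n >= 3 vertices", what)
  # drop an explicit closing vertex; rings are implicitly closed
  if (all(ring[1, ] == ring[nrow(ring), ]) && nrow(ring) > 3)
    ring <- ring[-nrow(ring), , drop = FALSE]
  if (ring_self_intersects(ring))
    stopf("%s ring is self-intersecting", what)
  unname(ring)
}

#' Build an annotation set
#'
#' @param polygons list of polygons, each a list with `ring` (n x 2 matrix of
#'   base-level pixel vertices, implicitly closed, non-self-intersecting) and
#'   a `label` string.
#' @return object of class `wsi_annotations`.
#' @export
annotation_set <- function(polygons = list()) {
  polygons <- lapply(polygons, function(p) {
    list(ring = validate_ring(p$ring), label = p$label %||% "lesion")
  })
  structure(list(polygons = polygons), class = "wsi_annotations")
}

#' @export
length.wsi_annotations <- function(x) length(x$polygons)

#' @export
print.wsi_annotations <- function(x, ...) {
  cat(sprintf("<wsi_annotations> %d polygon(s)\n", length(x)))
  invisible(x)
}

#' Point-in-polygon test (boundary inclusive)
#'
#' @param x,y coordinate vectors.
#' @param ring n x 2 vertex matrix.
#' @return logical vector.
#' @export
points_in_ring <- function(x, y, ring) {
  pracma::inpolygon(x, y, ring[, 1], ring[, 2], boundary = TRUE)
}

ring_bbox <- function(ring) {
  c(x0 = min(ring[, 1]), y0 = min(ring[, 2]),
    x1 = max(ring[, 1]), y1 = max(ring[, 2]))
}

# Does the half-open pixel rectangle [x0, x1) x [y0, y1) intersect the
# polygon? True if a vertex lies in the rectangle, a rectangle corner lies
# in the polygon, or any edges cross.
rect_intersects_ring <- function(x0, y0, x1, y1, ring) {
  if (any(ring[, 1] >= x0 & ring[, 1] <= x1 &
          ring[, 2] >= y0 & ring[, 2] <= y1)) return(TRUE)
  cx <- c(x0, x1, x1, x0, (x0 + x1) / 2)
  cy <- c(y0, y0, y1, y1, (y0 + y1) / 2)
  if (any(points_in_ring(cx, cy, ring))) return(TRUE)
  rect <- rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1))
  n <- nrow(ring)
  for (i in seq_len(n)) {
    a1 <- ring[i, ]; a2 <- ring[i %% n + 1, ]
    for (j in 1:4) {
      b1 <- rect[j, ]; b2 <- rect[j %% 4 + 1, ]
      if (segments_intersect(a1, a2, b1, b2)) return(TRUE)
    }
  }
  FALSE
}

#' Write annotations as GeoJSON
#'
#' One Feature per polygon (geometry type Polygon, ring closed explicitly),
#' with the label in `properties$label`. Coordinates are written at full
#' double precision so a write/read round trip is lossless.
#'
#' @param set a `wsi_annotations`.
#' @param uri output path.
#' @return `uri`, invisibly.
#' @export
write_annotations <- function(set, uri) {
  stopifnot(inherits(set, "wsi_annotations"))
  features <- lapply(set$polygons, function(p) {
    ring <- rbind(p$ring, p$ring[1, ])
    coords <- lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1], ring[i, 2]))
    list(type = "Feature",
         properties = list(label = p$label),
         geometry = list(type = "Polygon", coordinates = list(coords)))
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, uri, auto_unbox = TRUE, digits = NA)
  invisible(uri)
}

#' Read annotations from GeoJSON
#'
#' Accepts a FeatureCollection of Polygons; malformed geometry or
#' self-intersecting rings are rejected with a validation error.
#'
#' @param uri path to a GeoJSON file.
#' @return a `wsi_annotations`.
#' @export
read_annotations <- function(uri) {
  if (!file.exists(uri)) stopf("annotation file not found: %s", uri)
  fc <- jsonlite::read_json(uri)
  if (!identical(fc$type, "FeatureCollection"))
    stopf("%s: expected a GeoJSON FeatureCollection", uri)
  polys <- lapply(fc$features, function(f) {
    g <- f$geometry
    if (!identical(g$type, "Polygon"))
      stopf("unsupported geometry type '%s'", g$type %||% "<missing>")
    ring <- do.call(rbind, lapply(g$coordinates[[1]], function(v)
      c(as.numeric(v[[1]]), as.numeric(v[[2]]))))
    list(ring = ring, label = f$properties$label %||% "lesion")
  })
  annotation_set(polys)
}
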