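## Spherical geometry for degree-block cells and reporting-region polygons.
## Cells are latitude-longitude rectangles, so all areas use the spherical
## area element R^2 cos(phi) dphi dlambda; polygons are taken to have
## straight edges in lon/lat space (consistent with the cell geometry).

#' Spherical area of a latitude-longitude rectangle
#'
#' Area of the cell with upper-left corner `(long1, lat1)` and lower-right
#' corner `(long2, lat2)`, in km^2, on a sphere of radius `radius`:
#' `A = R^2 (long2 - long1) (sin lat1 - sin lat2)` with longitudes in
#' radians. The result is exact for this geometry, symmetric about the
#' equator, and shrinks toward the poles at fixed longitude span.
#'
#' @param bbox numeric vector `c(long1, lat1, long2, lat2)` in decimal
#'   degrees, upper-left / lower-right convention (`long1 <= long2`,
#'   `lat1 >= lat2`), or a 4-column matrix of such rows.
#' @param radius sphere radius in km (default mean Earth radius, 6371).
#' @return area(s) in km^2.
#' @examples
#' cell_area(c(0, 1, 1, 0))   # 1-degree cell touching the equator
#' @export
cell_area <- function(bbox, radius = EARTH_RADIUS_KM) {
  if (is.null(dim(bbox))) bbox <- matrix(bbox, ncol = 4L, byrow = TRUE)
  if (ncol(bbox) != 4L) stop("'bbox' must have 4 columns: long1, lat1, long2, lat2")
  long1 <- bbox[, 1L]; lat1 <- bbox[, 2L]; long2 <- bbox[, 3L]; lat2 <- bbox[, 4L]
  if (any(!is.finite(bbox))) stop("bbox coordinates must be finite")
  if (any(long1 > long2)) stop("inverted bbox: long1 > long2")
  if (any(lat2 > lat1)) stop("inverted bbox: lat2 > lat1 (upper-left/lower-right convention)")
  if (any(lat1 > 90) || any(lat2 < -90)) stop("latitudes must lie in [-90, 90]")
  d2r <- pi / 180
  a <- radius^2 * (long2 - long1) * d2r * (sin(lat1 * d2r) - sin(lat2 * d2r))
  if (nrow(bbox) == 1L) as.numeric(a) else a
}

#' Signed spherical area of a lon/lat polygon ring
#'
#' Green's-theorem integral of the spherical area element over a polygon
#' whose edges are straight lines in (longitude, latitude) space:
#' `A = R^2 * integral of sin(phi) dlambda` around the ring. Positive for
#' counter-clockwise rings; callers usually take `abs()`.
#'
#' @param lon,lat ring vertex coordinates in decimal degrees; the ring is
#'   closed implicitly (last vertex joined to the first).
#' @param radius sphere radius in km.
#' @return signed area in km^2.
#' @keywords internal
ring_area_sphere <- function(lon, lat, radius = EARTH_RADIUS_KM) {
  n <- length(lon)
  if (n != length(lat)) stop("lon and lat lengths differ")
  if (n < 3L) return(0)
  d2r <- pi / 180
  l1 <- lon * d2r
  p1 <- lat * d2r
  l2 <- c(l1[-1L], l1[1L])
  p2 <- c(p1[-1L], p1[1L])
  dl <- l2 - l1
  dp <- p2 - p1
  ## integral of sin(phi(lambda)) dlambda along each edge, phi linear in lambda
  seg <- numeric(n)
  flat <- abs(dp) < 1e-14 | abs(dl) < 1e-14
  ## vertical edges (dl == 0) contribute 0; horizontal use sin(phi)*dl
  seg[flat] <- sin(p1[flat]) * dl[flat]
  sl <- !flat
  m <- dp[sl] / dl[sl]
  seg[sl] <- (cos(p1[sl]) - cos(p2[sl])) / m
  radius^2 * sum(seg)
}

## Sutherland-Hodgman clip of a single ring against an axis-aligned
## rectangle rect = c(xmin, ymin, xmax, ymax). Returns a list(lon, lat)
## (possibly with 0 vertices). Correct-area output for simple rings.
clip_ring_rect <- function(lon, lat, rect) {
  stopifnot(length(rect) == 4L)
  pts <- cbind(lon, lat)
  inside <- list(
    function(p) p[, 1L] >= rect[1L],
    function(p) p[, 2L] >= rect[2L],
    function(p) p[, 1L] <= rect[3L],
    function(p) p[, 2L] <= rect[4L]
  )
  ## intersection of segment with the boundary line of each half-plane
  cross <- list(
    function(a, b) { t <- (rect[1L] - a[1L]) / (b[1L] - a[1L]); c(rect[1L], a[2L] + t * (b[2L] - a[2L])) },
    function(a, b) { t <- (rect[2L] - a[2L]) / (b[2L] - a[2L]); c(a[1L] + t * (b[1L] - a[1L]), rect[2L]) },
    function(a, b) { t <- (rect[3L] - a[1L]) / (b[1L] - a[1L]); c(rect[3L], a[2L] + t * (b[2L] - a[2L])) },
    function(a, b) { t <- (rect[4L] - a[2L]) / (b[2L] - a[2L]); c(a[1L] + t * (b[1L] - a[1L]), rect[4L]) }
  )
  for (s in seq_len(4L)) {
    n <- nrow(pts)
    if (n == 0L) break
    keep <- inside[[s]](pts)
    out <- matrix(numeric(0), ncol = 2L)
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      a <- pts[i, ]; b <- pts[j, ]
      if (keep[i]) {
        out <- rbind(out, a)
        if (!keep[j]) out <- rbind(out, cross[[s]](a, b))
      } else if (keep[j]) {
        out <- rbind(out, cross[[s]](a, b))
      }
    }
    pts <- out
    keep <- NULL
  }
  list(lon = pts[, 1L], lat = pts[, 2L])
}

## Spherical area (km^2) of the part of a polygon (list of rings; first
## ring outer, remaining rings holes) inside an axis-aligned lon/lat
## rectangle. Ring orientation is ignored; holes are subtracted.
polygon_rect_overlap_area <- function(rings, rect, radius = EARTH_RADIUS_KM) {
  if (!length(rings)) return(0)
  areas <- vapply(rings, function(r) {
    cl <- clip_ring_rect(r[, 1L], r[, 2L], rect)
    abs(ring_area_sphere(cl$lon, cl$lat, radius))
  }, numeric(1))
  max(areas[1L] - sum(areas[-1L]), 0)
}

#' Read reporting-region polygons from GeoJSON
#'
#' Accepts a GeoJSON file or literal string containing a Polygon,
#' MultiPolygon, Feature, or FeatureCollection (WGS84 lon/lat). Each
#' feature becomes one region; a region is a list of polygons, each
#' polygon a list of rings (first outer, rest holes), each ring a
#' 2-column matrix of lon/lat vertices. Polygons crossing the
#' antimeridian should be pre-split at +/-180 (as GeoJSON requires).
#'
#' @param x path to a `.geojson`/`.json` file, or a GeoJSON string.
#' @return named list of regions; names come from a feature `id` or a
#'   `name`/`region_id` property when present, else `region_1`, ...
#' @export
read_region_geojson <- function(x) {
  g <- if (is.character(x) && length(x) == 1L && !grepl("[{]", x)) {
    jsonlite::fromJSON(x, simplifyVector = FALSE)
  } else {
    jsonlite::fromJSON(paste(x, collapse = "\n"), simplifyVector = FALSE)
  }
  as_ring <- function(coords) {
    m <- do.call(rbind, lapply(coords, function(p) c(p[[1L]], p[[2L]])))
    storage.mode(m) <- "double"
    m
  }
  geom_to_region <- function(geom) {
    switch(geom$type,
      Polygon = list(lapply(geom$coordinates, as_ring)),
      MultiPolygon = lapply(geom$coordinates, function(pg) lapply(pg, as_ring)),
      stop("unsupported geometry type: ", geom$type)
    )
  }
  feats <- switch(g$type,
    FeatureCollection = g$features,
    Feature = list(g),
    Polygon = ,
    MultiPolygon = list(list(geometry = g, properties = NULL)),
    stop("unsupported GeoJSON type: ", g$type)
  )
  out <- lapply(feats, function(f) geom_to_region(f$geometry))
  nm <- vapply(seq_along(feats), function(i) {
    f <- feats[[i]]
    cand <- c(f$id, f$properties$region_id, f$properties$name)
    cand <- cand[!vapply(cand, is.null, logical(1))]
    if (length(cand)) as.character(cand[[1L]]) else paste0("region_", i)
  }, character(1))
  names(out) <- nm
  out
}
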