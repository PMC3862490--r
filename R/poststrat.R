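## Post-stratification: aggregate cell trends to arbitrary reporting
## regions. Each overlapped cell gets weight w'' = w' * A_c / Abar, where
## w' is the proportion of the cell's area inside the region, A_c the
## spherical cell area, and Abar the mean area of overlapped cells (the
## area correction for degree blocks shrinking toward the poles).

#' Proportion of a cell's area inside a region polygon
#'
#' Clips the region polygon(s) to the cell rectangle in lon/lat space and
#' measures both pieces with the spherical area element, so a region that
#' covers the western half of a cell (a meridian split) gets exactly 0.5.
#'
#' @param bbox cell bounding box `c(long1, lat1, long2, lat2)` in the
#'   upper-left / lower-right convention of [cell_area()].
#' @param region a polygon: a 2-column lon/lat matrix (single ring), a
#'   list of such matrices (outer ring + holes), or a list of polygons
#'   (multi-polygon) — the shapes returned by [read_region_geojson()].
#' @param radius sphere radius in km.
#' @return fraction in `[0, 1]`.
#' @export
cell_region_proportion <- function(bbox, region, radius = EARTH_RADIUS_KM) {
  region <- as_region_polygons(region)
  rect <- c(bbox[1L], bbox[4L], bbox[3L], bbox[2L])  # xmin, ymin, xmax, ymax
  a_cell <- cell_area(bbox, radius)
  if (a_cell <= 0) stop("degenerate cell bbox")
  ov <- sum(vapply(region, polygon_rect_overlap_area, numeric(1),
                   rect = rect, radius = radius))
  min(max(ov / a_cell, 0), 1)
}

## normalize region input to list-of-polygons, each a list of ring
## matrices (first outer, rest holes); validates ring closure/validity
as_region_polygons <- function(region) {
  if (is.matrix(region)) region <- list(list(region))
  else if (is.list(region) && is.matrix(region[[1L]])) region <- list(region)
  for (pg in region) for (r in pg) {
    if (!is.matrix(r) || ncol(r) != 2L || nrow(r) < 3L)
      stop("invalid polygon ring: need a 2-column lon/lat matrix with >= 3 vertices")
    if (any(!is.finite(r))) stop("invalid polygon: non-finite coordinates")
  }
  region
}

#' Region specification: overlap proportions and area-corrected weights
#'
#' For every lattice cell overlapped by the region, computes the overlap
#' proportion `w'` and the normalized weight `w'' = w' * A_c / Abar`
#' where `Abar` is the mean area of the overlapped cells. Cells with
#' `w' = 0` are excluded.
#'
#' @param region a polygon (see [cell_region_proportion()]) or a
#'   data.frame with columns `cell` (or `cell_lon` + `cell_lat`) and
#'   `w_prime` for precomputed overlap proportions.
#' @param lattice a `car_lattice`.
#' @param region_id identifier carried into outputs.
#' @return object of class `region_spec`: data.frame with columns `cell`,
#'   `w_prime`, `area_km2`, `w_norm`, plus attribute `region_id`.
#' @export
region_weights <- function(region, lattice, region_id = "region") {
  cl <- lattice$cells
  res <- lattice$resolution
  if (is.data.frame(region)) {
    if (!"w_prime" %in% names(region)) stop("precomputed table needs a 'w_prime' column")
    key <- if ("cell" %in% names(region)) region$cell
           else cell_key(region$cell_lon, region$cell_lat)
    j <- match(key, cl$cell)
    if (anyNA(j)) stop("unknown cell(s) in weight table: ",
                       paste(utils::head(key[is.na(j)], 5L), collapse = ", "))
    wp <- region$w_prime
  } else {
    region <- as_region_polygons(region)
    j <- seq_len(nrow(cl))
    wp <- vapply(j, function(i) {
      bbox <- c(cl$lon[i], cl$lat[i] + res, cl$lon[i] + res, cl$lat[i])
      cell_region_proportion(bbox, region, lattice$radius)
    }, numeric(1))
  }
  if (any(wp < 0 | wp > 1)) stop("overlap proportions must lie in [0, 1]")
  keep <- wp > 0
  if (!any(keep)) stop("region does not overlap any lattice cell")
  cells <- cl$cell[j][keep]
  areas <- cl$area_km2[j][keep]
  spec <- data.frame(cell = cells, w_prime = wp[keep], area_km2 = areas,
                     w_norm = wp[keep] * areas / mean(areas),
                     stringsAsFactors = FALSE)
  structure(spec, region_id = region_id, class = c("region_spec", "data.frame"))
}

#' Posterior trend for a reporting region
#'
#' Default (`mode = "draws"`): for each retained draw, every member
#' cell's trend is computed and the `w''`-weighted average taken, then
#' the per-draw region trends are summarized — a convex combination, so
#' each draw's region trend lies between the member-cell extremes and
#' posterior uncertainty propagates coherently. `mode =
#' "point-estimate"` instead averages the cells' posterior point
#' estimates (no interval).
#'
#' @param fit a `car_fit`.
#' @param spec a `region_spec` from [region_weights()].
#' @param year_a,year_b interval endpoints, `year_a < year_b`.
#' @param level,point as in [cell_trend()].
#' @param mode `"draws"` (default) or `"point-estimate"`.
#' @param keep_draws retain per-draw region trends.
#' @return a `trend_estimate` (with `lo`/`hi` `NA` in point-estimate
#'   mode).
#' @export
region_trend <- function(fit, spec, year_a, year_b, level = 0.95,
                         point = "median", mode = c("draws", "point-estimate"),
                         keep_draws = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(fit, "car_fit"), inherits(spec, "region_spec"))
  if (nrow(spec) == 0L) stop("empty region specification")
  if (year_a >= year_b) stop("'year_a' must be before 'year_b'")
  miss <- setdiff(spec$cell, fit$cells)
  if (length(miss)) stop("region cell(s) absent from the fit: ",
                         paste(utils::head(miss, 5L), collapse = ", "))
  w <- spec$w_norm / sum(spec$w_norm)
  if (mode == "draws") {
    tr_mat <- vapply(spec$cell, function(cc) {
      trend_from_abundance(expected_abundance(fit, cc, year_a),
                           expected_abundance(fit, cc, year_b),
                           year_b - year_a)
    }, numeric(fit$n_total))
    reg <- drop(tr_mat %*% w)
    s <- summarize_draws(reg, level, point)
    est <- s[["estimate"]]; lo <- s[["lo"]]; hi <- s[["hi"]]
  } else {
    cell_est <- vapply(spec$cell, function(cc)
      cell_trend(fit, cc, year_a, year_b, level, point)$estimate, numeric(1))
    est <- sum(w * cell_est); lo <- NA_real_; hi <- NA_real_
    reg <- NULL
  }
  structure(list(target = attr(spec, "region_id"),
                 year_a = year_a, year_b = year_b,
                 estimate = est, lo = lo, hi = hi, level = level,
                 draws = if (keep_draws && mode == "draws") reg),
            class = "trend_estimate")
}
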