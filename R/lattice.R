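## Degree-block lattice: cell assignment, adjacency, neighbor counts,
## spherical areas. Cells are half-open blocks [lon, lon + res) x
## [lat, lat + res) identified by their lower-left corner.

cell_key <- function(lon, lat) paste(format(lon, trim = TRUE), format(lat, trim = TRUE), sep = ",")

#' Assign route start points to degree-block cells
#'
#' A route belongs to the block its starting point falls in. Blocks are
#' half-open: `[lon, lon + resolution) x [lat, lat + resolution)`, so a
#' point on the lower/left boundary belongs to the block it starts.
#'
#' @param start_lon,start_lat route start coordinates in decimal degrees;
#'   longitude in `[-180, 180)`, latitude in `(-90, 90)`. Vectorized.
#' @param resolution block size in degrees (default 1, the BBS sample
#'   allocation unit).
#' @return data.frame with columns `cell_lon`, `cell_lat` (the lower-left
#'   corner of each block, a multiple of `resolution`) and `cell` (a
#'   `"lon,lat"` id string).
#' @examples
#' assign_route(-77.3, 39.6)  # block (-78, 39)
#' @export
assign_route <- function(start_lon, start_lat, resolution = 1) {
  if (length(start_lon) != length(start_lat)) stop("coordinate vectors differ in length")
  if (any(!is.finite(start_lon)) || any(!is.finite(start_lat)))
    stop("route coordinates must be finite")
  if (any(start_lon < -180 | start_lon >= 180))
    stop("longitude out of range [-180, 180)")
  if (any(start_lat <= -90 | start_lat >= 90))
    stop("latitude out of range (-90, 90)")
  if (!is.numeric(resolution) || length(resolution) != 1L || resolution <= 0)
    stop("'resolution' must be a positive scalar")
  lon <- floor(start_lon / resolution) * resolution
  lat <- floor(start_lat / resolution) * resolution
  data.frame(cell_lon = lon, cell_lat = lat, cell = cell_key(lon, lat),
             stringsAsFactors = FALSE)
}

#' Build the degree-block lattice for a survey dataset
#'
#' Creates one cell per occupied degree block (optionally plus a one-cell
#' buffer ring), the binary adjacency `W`, neighbor counts `n_c`, the ICAR
#' scaling `M_c = 1/n_c`, and spherical cell areas. The intrinsic CAR
#' model is only defined on a connected graph with no isolated cells, so a
#' connectivity policy is applied:
#' \describe{
#'   \item{`"largest-component"`}{keep the largest connected component and
#'     drop the rest with a warning (default).}
#'   \item{`"strict"`}{error, naming the components.}
#'   \item{`"bridge"`}{connect each secondary component to the main one by
#'     an edge between the centroid-nearest (great-circle) cell pair.}
#' }
#'
#' @param data a data.frame of survey records with `start_lon`,
#'   `start_lat` columns (see [read_counts()], [simulate_survey()]).
#' @param resolution block size in degrees.
#' @param scheme `"rook"` (edge-sharing neighbors, the default: cells that
#'   share a common boundary) or `"queen"` (also corner-sharing).
#' @param connectivity connectivity policy, see above.
#' @param buffer logical; add a ring of unoccupied cells around the
#'   occupied blocks (helps edge smoothing).
#' @param radius sphere radius in km for cell areas.
#' @return an object of class `car_lattice`: list with `cells` (data.frame
#'   `cell`, `lon`, `lat`, `area_km2`, `n_nbr`), `W` (binary adjacency
#'   matrix), `nb` (neighbor index list), `M` (vector `1/n_c`),
#'   `resolution`, `scheme`.
#' @export
build_lattice <- function(data, resolution = 1,
                          scheme = c("rook", "queen"),
                          connectivity = c("largest-component", "strict", "bridge"),
                          buffer = FALSE, radius = EARTH_RADIUS_KM) {
  scheme <- match.arg(scheme)
  connectivity <- match.arg(connectivity)
  if (is.null(data) || nrow(data) == 0L) stop("empty dataset: no routes to build a lattice from")
  asg <- assign_route(data$start_lon, data$start_lat, resolution)
  occ <- unique(asg[c("cell_lon", "cell_lat")])
  gx <- as.integer(round(occ$cell_lon / resolution))
  gy <- as.integer(round(occ$cell_lat / resolution))
  if (buffer) {
    ring <- expand.grid(dx = -1:1, dy = -1:1)
    all_g <- unique(data.frame(
      gx = rep(gx, each = 9L) + rep(ring$dx, length(gx)),
      gy = rep(gy, each = 9L) + rep(ring$dy, length(gy))
    ))
    gx <- all_g$gx; gy <- all_g$gy
  }
  ord <- order(gx, gy)
  gx <- gx[ord]; gy <- gy[ord]
  C <- length(gx)
  key <- paste(gx, gy)
  idx <- setNames(seq_len(C), key)

  offsets <- if (scheme == "rook") {
    cbind(c(1L, -1L, 0L, 0L), c(0L, 0L, 1L, -1L))
  } else {
    as.matrix(expand.grid(dx = -1:1, dy = -1:1)[-5L, ])
  }
  W <- matrix(0L, C, C)
  for (o in seq_len(nrow(offsets))) {
    nk <- paste(gx + offsets[o, 1L], gy + offsets[o, 2L])
    hit <- idx[nk]
    ok <- !is.na(hit)
    W[cbind(which(ok), hit[ok])] <- 1L
  }

  comp <- graph_components(W)
  if (max(comp) > 1L) {
    tab <- tabulate(comp)
    if (connectivity == "strict") {
      desc <- vapply(seq_along(tab), function(k)
        paste0("{", paste(cell_key(gx[comp == k] * resolution, gy[comp == k] * resolution),
                          collapse = "; "), "}"), character(1))
      stop("lattice is disconnected (", length(tab), " components): ",
           paste(desc, collapse = " "))
    } else if (connectivity == "largest-component") {
      main <- which.max(tab)
      drop <- which(comp != main)
      warning("dropping ", length(drop), " cell(s) outside the largest connected component")
      keep <- comp == main
      gx <- gx[keep]; gy <- gy[keep]
      W <- W[keep, keep, drop = FALSE]
      C <- length(gx)
    } else { # bridge
      cen_lon <- (gx + 0.5) * resolution
      cen_lat <- (gy + 0.5) * resolution
      repeat {
        comp <- graph_components(W)
        if (max(comp) == 1L) break
        main <- which.max(tabulate(comp))
        a <- which(comp == main); b <- which(comp != main)
        d <- outer(a, b, function(i, j)
          gc_dist(cen_lon[i], cen_lat[i], cen_lon[j], cen_lat[j]))
        hit <- which(d == min(d), arr.ind = TRUE)[1L, ]
        i <- a[hit[1L]]; j <- b[hit[2L]]
        W[i, j] <- W[j, i] <- 1L
      }
    }
  }

  n_nbr <- rowSums(W)
  lon <- gx * resolution
  lat <- gy * resolution
  cells <- data.frame(
    cell = cell_key(lon, lat), lon = lon, lat = lat,
    area_km2 = cell_area(cbind(lon, lat + resolution, lon + resolution, lat), radius),
    n_nbr = as.integer(n_nbr), stringsAsFactors = FALSE
  )
  nb <- lapply(seq_len(C), function(i) which(W[i, ] == 1L))
  structure(list(cells = cells, W = W, nb = nb, M = 1 / n_nbr,
                 resolution = resolution, scheme = scheme, radius = radius),
            class = "car_lattice")
}

## connected components of an undirected 0/1 adjacency matrix (BFS)
graph_components <- function(W) {
  C <- nrow(W)
  comp <- integer(C)
  k <- 0L
  for (s in seq_len(C)) {
    if (comp[s] > 0L) next
    k <- k + 1L
    queue <- s
    comp[s] <- k
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nbr <- which(W[v, ] == 1L & comp == 0L)
      comp[nbr] <- k
      queue <- c(queue, nbr)
    }
  }
  comp
}

gc_dist <- function(lon1, lat1, lon2, lat2, radius = EARTH_RADIUS_KM) {
  d2r <- pi / 180
  h <- sin((lat2 - lat1) * d2r / 2)^2 +
    cos(lat1 * d2r) * cos(lat2 * d2r) * sin((lon2 - lon1) * d2r / 2)^2
  2 * radius * asin(pmin(1, sqrt(h)))
}

#' @export
print.car_lattice <- function(x, ...) {
  cat("Degree-block lattice:", nrow(x$cells), "cells at", x$resolution,
      "deg resolution (", x$scheme, "adjacency )\n")
  cat("  neighbor counts:", paste(range(x$cells$n_nbr), collapse = "-"),
      " | total area", format(round(sum(x$cells$area_km2))), "km^2\n")
  invisible(x)
}

#' Export a lattice to CSV
#'
#' Writes two files: `<stem>_cells.csv` (cell id, bbox, area, neighbor
#' count) and `<stem>_edges.csv` (one row per undirected adjacency edge).
#'
#' @param lattice a `car_lattice`.
#' @param stem output path stem.
#' @return invisibly, the two file paths.
#' @export
write_lattice <- function(lattice, stem) {
  cl <- lattice$cells
  res <- lattice$resolution
  cells_path <- paste0(stem, "_cells.csv")
  edges_path <- paste0(stem, "_edges.csv")
  write.csv(data.frame(cell = cl$cell,
                       long1 = cl$lon, lat1 = cl$lat + res,
                       long2 = cl$lon + res, lat2 = cl$lat,
                       area_km2 = cl$area_km2, n_nbr = cl$n_nbr),
            cells_path, row.names = FALSE)
  e <- which(upper.tri(lattice$W) & lattice$W == 1L, arr.ind = TRUE)
  write.csv(data.frame(cell_a = cl$cell[e[, 1L]], cell_b = cl$cell[e[, 2L]]),
            edges_path, row.names = FALSE)
  invisible(c(cells_path, edges_path))
}
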