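## Synthetic BBS-like data with known truth, generated from the same
## hierarchical model the sampler fits: Y ~ Poisson(exp(alpha_t +
## omega_{K(i,t)} + b_{c(i),t})), with per-year ICAR spatial fields.

#' Imbalanced route allocation along a spatial gradient
#'
#' Route density in real roadside surveys varies severalfold between
#' regions. This draws per-cell route counts whose expected density
#' follows a linear west-to-east gradient with a chosen max/min ratio.
#' Counts are `1 + Poisson(mu - 1)` so every cell keeps at least one
#' route (the lattice stays the full grid) while the expectation is
#' exactly `mu`.
#'
#' @param nx,ny grid dimensions (cells).
#' @param ratio max/min expected routes-per-cell ratio (>= 1) across grid
#'   columns.
#' @param mean_routes overall expected routes per cell (>= 1; the low end
#'   of the gradient, `2*mean_routes/(1+ratio)`, must also be >= 1).
#' @param seed optional RNG seed.
#' @return integer matrix `ny x nx` of route counts (column j of the grid
#'   = longitude column j).
#' @export
make_imbalanced_allocation <- function(nx, ny, ratio = 1, mean_routes = 2.5,
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (ratio < 1) stop("'ratio' must be >= 1")
  lo <- 2 * mean_routes / (1 + ratio)
  if (lo < 1) stop("gradient low end below 1 route/cell; raise 'mean_routes'")
  mu_col <- if (nx == 1L) mean_routes else seq(lo, lo * ratio, length.out = nx)
  mu <- matrix(rep(mu_col, each = ny), ny, nx)
  matrix(1L + rpois(nx * ny, mu - 1), ny, nx)
}

#' Simulate a route-count survey with known truth
#'
#' Generates a rectangular degree-block grid, places routes uniformly at
#' random within their block, assigns observers with geometric turnover
#' (each route's observer is replaced with probability `turnover` each
#' year), draws one centered ICAR spatial field per year, and samples
#' Poisson counts from the model's log-linear mean.
#'
#' @param nx,ny grid dimensions in cells.
#' @param n_years number of survey years (>= 2).
#' @param alpha year intercepts on the log scale; scalar (recycled) or
#'   length-`n_years` vector. Default: abundance of about 10 birds/route
#'   declining about 2 percent per year, a typical songbird-scale series.
#' @param sigma2 observer(-route) effect variance (log scale).
#' @param tau2 ICAR conditional variance parameter.
#' @param routes_per_cell integer matrix `ny x nx` (e.g. from
#'   [make_imbalanced_allocation()]) or a scalar; `NULL` uses
#'   `make_imbalanced_allocation(nx, ny, density_ratio, mean_routes)`.
#' @param density_ratio,mean_routes passed to
#'   [make_imbalanced_allocation()] when `routes_per_cell` is `NULL`.
#' @param turnover per-year probability that a route's observer is
#'   replaced (default 0.15, a multi-year median tenure as in volunteer
#'   surveys).
#' @param origin lower-left corner (lon, lat) of the grid in degrees.
#' @param resolution cell size in degrees.
#' @param first_year calendar year of the first survey season.
#' @param seed RNG seed; the same arguments and seed reproduce the
#'   dataset bit-for-bit.
#' @return list with `data` (a `car_survey` data.frame), `lattice` (the
#'   full-grid `car_lattice`), and `truth`: `alpha` (length `n_years`),
#'   `omega` (named by observer-route pair), `b` (cells x years matrix,
#'   centered per year), `sigma2`, `tau2`, `routes_per_cell`, `seed`.
#' @export
simulate_survey <- function(nx, ny, n_years,
                            alpha = seq(log(10), log(10) + n_years * log(0.98),
                                        length.out = n_years),
                            sigma2 = 0.1, tau2 = 0.5,
                            routes_per_cell = NULL,
                            density_ratio = 3, mean_routes = 2.5,
                            turnover = 0.15,
                            origin = c(-100, 32), resolution = 1,
                            first_year = 1999, seed = NULL) {
  if (n_years < 2L) stop("need at least 2 years")
  if (sigma2 < 0 || tau2 <= 0) stop("variances must be positive (sigma2 >= 0)")
  if (turnover < 0 || turnover > 1) stop("'turnover' must be a probability")
  alpha <- rep_len(alpha, n_years)
  if (!is.null(seed)) set.seed(seed)

  if (is.null(routes_per_cell)) {
    routes_per_cell <- make_imbalanced_allocation(nx, ny, density_ratio, mean_routes)
  } else if (length(routes_per_cell) == 1L) {
    routes_per_cell <- matrix(as.integer(routes_per_cell), ny, nx)
  }
  stopifnot(nrow(routes_per_cell) == ny, ncol(routes_per_cell) == nx,
            all(routes_per_cell >= 0))

  ## full-grid lattice (all cells occupied since allocation floors at >= 1
  ## when built by make_imbalanced_allocation)
  grid <- expand.grid(lon = origin[1L] + (seq_len(nx) - 1L) * resolution,
                      lat = origin[2L] + (seq_len(ny) - 1L) * resolution)
  anchor <- data.frame(start_lon = grid$lon + resolution / 2,
                       start_lat = grid$lat + resolution / 2)
  lattice <- build_lattice(anchor, resolution, scheme = "rook",
                           connectivity = "strict")
  C <- nrow(lattice$cells)

  ## route placement: uniform within block
  route <- list(); rid <- 0L
  for (j in seq_len(nx)) for (i in seq_len(ny)) {
    nr <- routes_per_cell[i, j]
    if (nr == 0L) next
    lon0 <- origin[1L] + (j - 1L) * resolution
    lat0 <- origin[2L] + (i - 1L) * resolution
    for (r in seq_len(nr)) {
      rid <- rid + 1L
      route[[rid]] <- c(lon0 + runif(1) * resolution, lat0 + runif(1) * resolution)
    }
  }
  n_routes <- rid
  if (n_routes == 0L) stop("no routes allocated")
  route <- do.call(rbind, route)

  ## observer schedule: new observer id on turnover; effects attach to
  ## observer-route pairs
  obs_id <- matrix("", n_routes, n_years)
  next_obs <- 1L
  for (r in seq_len(n_routes)) {
    cur <- sprintf("obs%04d", next_obs); next_obs <- next_obs + 1L
    for (t in seq_len(n_years)) {
      if (t > 1L && runif(1) < turnover) {
        cur <- sprintf("obs%04d", next_obs); next_obs <- next_obs + 1L
      }
      obs_id[r, t] <- cur
    }
  }

  ## per-year ICAR fields and observer-route effects
  b <- sample_icar_field(lattice, tau2, n = n_years)
  pair_keys <- unique(as.vector(vapply(seq_len(n_years), function(t)
    paste(obs_id[, t], sprintf("route%04d", seq_len(n_routes)), sep = "\r"),
    character(n_routes))))
  omega <- setNames(rnorm(length(pair_keys), 0, sqrt(sigma2)), pair_keys)

  asg <- assign_route(route[, 1L], route[, 2L], resolution)
  ci <- match(asg$cell, lattice$cells$cell)
  rec <- expand.grid(r = seq_len(n_routes), t = seq_len(n_years))
  key <- paste(obs_id[cbind(rec$r, rec$t)],
               sprintf("route%04d", rec$r), sep = "\r")
  eta <- alpha[rec$t] + omega[key] + b[cbind(ci[rec$r], rec$t)]
  y <- rpois(nrow(rec), exp(eta))

  data <- survey_data(data.frame(
    route_id = sprintf("route%04d", rec$r),
    observer_id = obs_id[cbind(rec$r, rec$t)],
    year = first_year + rec$t - 1L,
    count = y,
    start_lon = route[rec$r, 1L],
    start_lat = route[rec$r, 2L],
    stringsAsFactors = FALSE
  ))

  truth <- list(alpha = setNames(alpha, first_year + seq_len(n_years) - 1L),
                omega = omega,
                b = structure(b, dimnames = list(lattice$cells$cell,
                                                 first_year + seq_len(n_years) - 1L)),
                sigma2 = sigma2, tau2 = tau2,
                routes_per_cell = routes_per_cell, turnover = turnover,
                seed = seed)
  list(data = data, lattice = lattice, truth = truth)
}
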