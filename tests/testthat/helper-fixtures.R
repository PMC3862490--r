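# Shared fixtures, all built in code.

# lattice over an arbitrary set of occupied blocks (routes at block centers)
lattice_from_blocks <- function(blocks, resolution = 1, ...) {
  build_lattice(data.frame(start_lon = blocks[, 1L] + resolution / 2,
                           start_lat = blocks[, 2L] + resolution / 2),
                resolution = resolution, ...)
}

# full nx x ny grid lattice with lower-left corner at origin
grid_lattice <- function(nx, ny, origin = c(0, 0), ...) {
  g <- expand.grid(lon = origin[1L] + seq_len(nx) - 1L,
                   lat = origin[2L] + seq_len(ny) - 1L)
  lattice_from_blocks(as.matrix(g), ...)
}

# connected subsets of the 3x3 grid used for small-lattice ICAR checks
small_connected_blocks <- function() {
  list(
    line2 = cbind(0:1, 0),
    line3 = cbind(0:2, 0),
    lshape = rbind(c(0, 0), c(1, 0), c(0, 1)),
    square4 = rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1)),
    tee = rbind(c(0, 1), c(1, 1), c(2, 1), c(1, 0)),
    ring8 = rbind(c(0, 0), c(1, 0), c(2, 0), c(2, 1), c(2, 2),
                  c(1, 2), c(0, 2), c(0, 1)),
    full9 = as.matrix(expand.grid(0:2, 0:2))
  )
}

# independent tiny BFS used only to verify connectivity claims
graph_components_for_test <- function(W) {
  C <- nrow(W); comp <- integer(C); k <- 0L
  for (s in seq_len(C)) {
    if (comp[s]) next
    k <- k + 1L; q <- s; comp[s] <- k
    while (length(q)) {
      v <- q[1L]; q <- q[-1L]
      nb <- which(W[v, ] > 0 & comp == 0L); comp[nb] <- k; q <- c(q, nb)
    }
  }
  comp
}

# hand-built car_fit with fully controlled draws, for exact trend algebra
fake_fit <- function(lattice, alpha, b, sigma2 = NULL, n_chains = 2L) {
  draws <- nrow(alpha)
  T <- ncol(alpha)
  C <- nrow(lattice$cells)
  if (is.null(sigma2)) sigma2 <- numeric(draws)
  stopifnot(dim(b)[1L] == draws, dim(b)[2L] == C, dim(b)[3L] == T)
  years <- seq_len(T) + 1998L
  dimnames(b) <- list(NULL, lattice$cells$cell, years)
  colnames(alpha) <- years
  structure(list(
    alpha = alpha, omega = matrix(0, draws, 1L), b = b,
    sigma2 = sigma2, tau2 = rep(1, draws),
    chain = rep(seq_len(n_chains), length.out = draws),
    years = years, cells = lattice$cells$cell,
    lattice = lattice, control = car_control(n_chains = n_chains, seed = 1),
    observer_mode = "observer-route",
    acceptance = matrix(0.44, 1, 3), n_total = draws,
    n_per_chain = draws %/% n_chains
  ), class = "car_fit")
}

# constant-abundance fake fit: every draw has abundance n[t] in all cells
fake_fit_abundance <- function(n_by_year, n_cells = 2L, draws = 5L) {
  lat <- grid_lattice(n_cells, 1L)
  T <- length(n_by_year)
  alpha <- matrix(rep(log(n_by_year), each = draws), draws, T)
  b <- array(0, c(draws, n_cells, T))
  fake_fit(lat, alpha, b)
}

# small survey dataset written by hand (3 routes, 2 cells, 3 years)
tiny_survey <- function() {
  survey_data(data.frame(
    route_id = rep(c("r1", "r2", "r3"), each = 3L),
    observer_id = rep(c("oA", "oB", "oC"), each = 3L),
    year = rep(2000:2002, 3L),
    count = c(4L, 5L, 6L, 2L, 3L, 1L, 7L, 8L, 9L),
    start_lon = rep(c(0.2, 0.7, 1.5), each = 3L),
    start_lat = rep(c(0.5, 0.9, 0.4), each = 3L),
    stringsAsFactors = FALSE))
}
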