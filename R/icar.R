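## Intrinsic CAR (ICAR) Gaussian Markov random field on the lattice.
## Joint (improper) density for a year's field B, up to a constant:
##   p(B | tau2)  propto  tau2^{-(C-1)/2} exp( -(1/(2 tau2)) sum_{c<k} w_ck (b_c - b_k)^2 )
## i.e. precision (1/tau2) (D - W), rank C-1; made proper on the
## sum-to-zero subspace. Full conditional of one cell:
##   b_c | B_{-c} ~ N( mean of neighbors, tau2 / n_c ).

#' ICAR full-conditional mean and variance for one cell
#'
#' @param lattice a `car_lattice`.
#' @param cell cell index (1-based) or cell id string.
#' @param b the current field, length = number of cells (only neighbors of
#'   `cell` are read).
#' @param tau2 conditional variance parameter (> 0).
#' @return list with `mean` (average of neighbor values) and `variance`
#'   (`tau2 / n_c`).
#' @export
icar_conditional <- function(lattice, cell, b, tau2) {
  ci <- resolve_cell(lattice, cell)
  if (tau2 <= 0) stop("'tau2' must be positive")
  if (length(b) != nrow(lattice$cells)) stop("field length does not match lattice")
  nbr <- lattice$nb[[ci]]
  if (length(nbr) == 0L)
    stop("cell ", lattice$cells$cell[ci],
         " has no neighbors; ICAR is undefined on isolated cells")
  list(mean = mean(b[nbr]), variance = tau2 / length(nbr))
}

#' ICAR log-density of a field (up to an additive constant)
#'
#' Pairwise-difference form with rank C-1:
#' `-(1/(2 tau2)) * sum_{c<k} w_ck (b_c - b_k)^2 - ((C-1)/2) log(tau2)`.
#'
#' @param lattice a `car_lattice` (connected).
#' @param b field vector; must be centered (mean zero) — the intrinsic
#'   model is only proper on the sum-to-zero subspace.
#' @param tau2 conditional variance parameter.
#' @param strict error (TRUE, default) or just warn on an uncentered field.
#' @return log-density up to a constant not involving `b` or `tau2`.
#' @export
icar_log_density <- function(lattice, b, tau2, strict = TRUE) {
  C <- nrow(lattice$cells)
  if (length(b) != C) stop("field length does not match lattice")
  if (tau2 <= 0) stop("'tau2' must be positive")
  if (abs(mean(b)) > 1e-8) {
    msg <- "field is not centered (sum-to-zero constraint violated)"
    if (strict) stop(msg) else warning(msg)
  }
  ss <- icar_pairwise_ss(lattice, b)
  -ss / (2 * tau2) - (C - 1) / 2 * log(tau2)
}

## sum over adjacent pairs c<k of (b_c - b_k)^2; equals b' (D - W) b
icar_pairwise_ss <- function(lattice, b) {
  e <- which(upper.tri(lattice$W) & lattice$W == 1L, arr.ind = TRUE)
  sum((b[e[, 1L]] - b[e[, 2L]])^2)
}

#' Draw centered ICAR fields
#'
#' Samples from the proper Gaussian obtained by restricting the ICAR
#' precision `(1/tau2)(D - W)` to the sum-to-zero subspace, via the
#' eigendecomposition of the graph Laplacian: the field is a combination
#' of the eigenvectors with nonzero eigenvalue `l_j`, each with variance
#' `tau2 / l_j`. Draws are exactly mean-centered.
#'
#' @param lattice a connected `car_lattice`.
#' @param tau2 conditional variance parameter (> 0).
#' @param n number of independent fields.
#' @return `C x n` matrix of centered fields (a vector if `n = 1` and
#'   `drop = TRUE`).
#' @param drop return a vector for `n = 1`.
#' @export
sample_icar_field <- function(lattice, tau2, n = 1, drop = FALSE) {
  if (tau2 <= 0) stop("'tau2' must be positive")
  C <- nrow(lattice$cells)
  L <- diag(rowSums(lattice$W)) - lattice$W
  eg <- eigen(L, symmetric = TRUE)
  lam <- eg$values
  pos <- lam > max(lam) * 1e-10
  if (sum(!pos) > 1L)
    stop("lattice graph is disconnected; ICAR field undefined")
  V <- eg$vectors[, pos, drop = FALSE]
  z <- matrix(rnorm(sum(pos) * n), sum(pos), n)
  x <- V %*% (z * sqrt(tau2 / lam[pos]))
  x <- sweep(x, 2L, colMeans(x))  # exact centering (numerically ~1e-16 anyway)
  if (n == 1L && drop) drop(x) else x
}

resolve_cell <- function(lattice, cell) {
  if (is.character(cell)) {
    ci <- match(cell, lattice$cells$cell)
    if (is.na(ci)) stop("unknown cell id: ", cell)
    return(ci)
  }
  ci <- as.integer(cell)
  if (is.na(ci) || ci < 1L || ci > nrow(lattice$cells)) stop("cell index out of range")
  ci
}
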