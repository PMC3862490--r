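## Trends: expected theoretical-route abundance per cell-year, and the
## interval-specific geometric-mean trend 100(B - 1)% with
## B = (n_{c,b} / n_{c,a})^{1/(b-a)}.

#' Posterior draws of expected theoretical-route abundance
#'
#' The abundance index `n_{c,t}` of a hypothetical route in cell `c` at
#' year `t`. With the default lognormal retransformation the observer
#' effect is integrated out: `n_{c,t} = exp(alpha_t + b_{c,t} + sigma2/2)`
#' (the mean of `exp(alpha + b + omega)` over `omega ~ N(0, sigma2)`).
#' `retransform = "none"` drops the `sigma2/2` term. Because `sigma2` is
#' shared across years within a draw, the two choices give identical
#' trends; they differ only in the reported abundance level.
#'
#' @param fit a `car_fit`.
#' @param cell cell id string or index.
#' @param year calendar year within the fitted range.
#' @param retransform `"lognormal"` (default) or `"none"`.
#' @return numeric vector, one abundance per retained draw.
#' @export
expected_abundance <- function(fit, cell, year,
                               retransform = c("lognormal", "none")) {
  retransform <- match.arg(retransform)
  stopifnot(inherits(fit, "car_fit"))
  ci <- resolve_cell(fit$lattice, cell)
  ti <- match(year, fit$years)
  if (is.na(ti)) stop("year ", year, " outside the fitted range ",
                      min(fit$years), "-", max(fit$years))
  eta <- fit$alpha[, ti] + fit$b[, ci, ti]
  if (retransform == "lognormal") eta <- eta + fit$sigma2 / 2
  exp(eta)
}

#' Geometric-mean yearly trend between two abundances
#'
#' `100 * ((n_b / n_a)^(1 / span) - 1)`: the percentage yearly change
#' whose compounding over `span` years takes abundance `n_a` to `n_b`.
#' Vectorized over draws.
#'
#' @param n_a,n_b positive start and end abundances.
#' @param span interval length in years (> 0).
#' @return trend in percent per year (always > -100 for positive
#'   abundances).
#' @examples
#' trend_percent(100, 200, 10)  # a doubling over 10 years: ~7.18 %/yr
#' @export
trend_percent <- function(n_a, n_b, span) {
  if (any(span <= 0)) stop("'span' must be positive")
  if (any(n_a <= 0) || any(n_b <= 0)) stop("abundances must be positive")
  100 * ((n_b / n_a)^(1 / span) - 1)
}

trend_from_abundance <- trend_percent

#' Summarize posterior draws by median and central credible interval
#'
#' @param draws nonempty numeric vector.
#' @param level credible level (default 0.95: 2.5/97.5 percentiles,
#'   type-7 interpolation).
#' @param point `"median"` (default) or `"mean"` point estimate.
#' @return named vector `c(estimate, lo, hi)`.
#' @export
summarize_draws <- function(draws, level = 0.95, point = c("median", "mean")) {
  point <- match.arg(point)
  if (!length(draws)) stop("empty draw vector")
  qs <- quantile(draws, c((1 - level) / 2, 1 - (1 - level) / 2),
                 names = FALSE, type = 7)
  est <- if (point == "median") median(draws) else mean(draws)
  c(estimate = est, lo = qs[1L], hi = qs[2L])
}

#' Interval-specific trend for one cell
#'
#' Per retained draw, computes the geometric-mean yearly change
#' `B = (n_{c,b}/n_{c,a})^{1/(b-a)}` and the trend `100(B-1)%`, then
#' summarizes across draws.
#'
#' @param fit a `car_fit`.
#' @param cell cell id string or index.
#' @param year_a,year_b interval endpoints, `year_a < year_b`, within the
#'   fitted range.
#' @param level credible level.
#' @param point point-estimate type, see [summarize_draws()].
#' @param keep_draws retain the per-draw trend vector in the result.
#' @return object of class `trend_estimate`: list with `target`,
#'   `year_a`, `year_b`, `estimate` (% per year), `lo`, `hi`, `level`,
#'   and (optionally) `draws`.
#' @export
cell_trend <- function(fit, cell, year_a, year_b, level = 0.95,
                       point = "median", keep_draws = FALSE) {
  if (year_a >= year_b) stop("'year_a' must be before 'year_b'")
  n_a <- expected_abundance(fit, cell, year_a)
  n_b <- expected_abundance(fit, cell, year_b)
  tr <- trend_from_abundance(n_a, n_b, year_b - year_a)
  s <- summarize_draws(tr, level, point)
  ci <- resolve_cell(fit$lattice, cell)
  structure(list(target = fit$lattice$cells$cell[ci],
                 year_a = year_a, year_b = year_b,
                 estimate = s[["estimate"]], lo = s[["lo"]], hi = s[["hi"]],
                 level = level, draws = if (keep_draws) tr),
            class = "trend_estimate")
}

#' @export
print.trend_estimate <- function(x, ...) {
  cat(sprintf("%s %d-%d: %+.2f%%/yr [%.2f; %.2f] (%d%% CrI)\n",
              x$target, x$year_a, x$year_b, x$estimate, x$lo, x$hi,
              round(100 * x$level)), sep = "")
  invisible(x)
}

#' Trend table for all cells over one or more intervals
#'
#' @param fit a `car_fit`.
#' @param intervals list of `c(year_a, year_b)` pairs (or a single pair).
#' @param level,point as in [cell_trend()].
#' @return data.frame `target, year_a, year_b, estimate, lo, hi`.
#' @export
cell_trends <- function(fit, intervals, level = 0.95, point = "median") {
  if (!is.list(intervals)) intervals <- list(intervals)
  rows <- lapply(intervals, function(iv) {
    do.call(rbind, lapply(fit$cells, function(cc) {
      tr <- cell_trend(fit, cc, iv[1L], iv[2L], level, point)
      data.frame(target = tr$target, year_a = tr$year_a, year_b = tr$year_b,
                 estimate = tr$estimate, lo = tr$lo, hi = tr$hi,
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}

#' Write a trend table to CSV
#'
#' Columns `target,year_a,year_b,median,lo95,hi95` (names reflect the
#' default summary).
#'
#' @param trends data.frame from [cell_trends()] or [region_trend()] rows.
#' @param path output CSV path.
#' @export
write_trends <- function(trends, path) {
  out <- trends
  names(out)[names(out) == "estimate"] <- "median"
  names(out)[names(out) == "lo"] <- "lo95"
  names(out)[names(out) == "hi"] <- "hi95"
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Export per-cell trends as a GeoJSON feature collection
#'
#' One polygon feature per lattice cell with the trend summary as
#' properties; suitable for mapping.
#'
#' @param fit a `car_fit`.
#' @param trends data.frame from [cell_trends()] (a single interval).
#' @param path output `.geojson` path.
#' @export
write_trend_geojson <- function(fit, trends, path) {
  cl <- fit$lattice$cells
  res <- fit$lattice$resolution
  feats <- lapply(seq_len(nrow(trends)), function(i) {
    j <- match(trends$target[i], cl$cell)
    ring <- list(c(cl$lon[j], cl$lat[j]), c(cl$lon[j] + res, cl$lat[j]),
                 c(cl$lon[j] + res, cl$lat[j] + res), c(cl$lon[j], cl$lat[j] + res),
                 c(cl$lon[j], cl$lat[j]))
    list(type = "Feature",
         properties = list(cell = trends$target[i],
                           year_a = trends$year_a[i], year_b = trends$year_b[i],
                           trend = trends$estimate[i],
                           lo = trends$lo[i], hi = trends$hi[i]),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
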