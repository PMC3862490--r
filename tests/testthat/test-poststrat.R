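# Region overlap proportions, area-normalized weights, and aggregation.

rect_ring <- function(x1, y1, x2, y2) {
  cbind(c(x1, x2, x2, x1, x1), c(y1, y1, y2, y2, y1))
}

test_that("overlap proportion handles exact, disjoint, and half cells", {
  bbox <- c(10, 46, 11, 45)  # upper-left / lower-right
  expect_equal(cell_region_proportion(bbox, rect_ring(10, 45, 11, 46)), 1.0)
  expect_equal(cell_region_proportion(bbox, rect_ring(20, 20, 22, 22)), 0.0)
  # meridian split: spherical band area is longitude-uniform, so the
  # western half is exactly half the area
  expect_equal(cell_region_proportion(bbox, rect_ring(10, 45, 10.5, 46)), 0.5,
               tolerance = 1e-12)
  # a latitude split is NOT half: the equatorward part is bigger
  south <- cell_region_proportion(bbox, rect_ring(10, 45, 11, 45.5))
  expect_gt(south, 0.5)
  expect_equal(south, (sin(45.5 * pi / 180) - sin(45 * pi / 180)) /
                 (sin(46 * pi / 180) - sin(45 * pi / 180)), tolerance = 1e-12)
})

test_that("holes and multipolygons are subtracted and summed", {
  bbox <- c(0, 1, 1, 0)
  outer <- rect_ring(0, 0, 1, 1)
  hole <- rect_ring(0.25, 0.25, 0.75, 0.75)[5:1, ]  # orientation is ignored
  with_hole <- list(outer, hole)
  p <- cell_region_proportion(bbox, with_hole)
  # the hole spans half the longitude and half the latitude band
  hole_frac <- 0.5 * (sin(0.75 * pi / 180) - sin(0.25 * pi / 180)) /
    (sin(pi / 180) - 0)
  expect_equal(p, 1 - hole_frac, tolerance = 1e-12)
  two_parts <- list(list(rect_ring(0, 0, 0.25, 1)), list(rect_ring(0.5, 0, 0.75, 1)))
  expect_equal(cell_region_proportion(bbox, two_parts), 0.5, tolerance = 1e-12)
  expect_error(cell_region_proportion(bbox, cbind(0:1, 0:1)), "3 vertices")
})

test_that("region weights equal 1 for whole same-latitude cells", {
  lat <- grid_lattice(2, 1, origin = c(5, 40))
  spec <- region_weights(rect_ring(5, 40, 7, 41), lat, "r")
  expect_equal(nrow(spec), 2L)
  expect_equal(spec$w_prime, c(1, 1), tolerance = 1e-12)
  expect_equal(spec$w_norm, c(1, 1), tolerance = 1e-12)
  one <- region_weights(rect_ring(5, 40, 6, 41), lat)
  expect_equal(nrow(one), 1L)
  expect_equal(one$w_norm, 1, tolerance = 1e-12)
})

test_that("area normalization uses the closed-form spherical ratio", {
  # two whole cells at latitudes 0-1 and 59-60, bridged into one lattice
  lat <- lattice_from_blocks(rbind(c(0, 0), c(0, 59)), connectivity = "bridge")
  region <- list(list(rect_ring(0, 0, 1, 1)), list(rect_ring(0, 59, 1, 60)))
  spec <- region_weights(region, lat, "two-lat")
  expect_equal(spec$w_prime, c(1, 1), tolerance = 1e-10)
  d2r <- pi / 180
  ratio <- (sin(1 * d2r) - sin(0)) / (sin(60 * d2r) - sin(59 * d2r))
  i_eq <- which(lat$cells$lat == 0)
  i_60 <- which(lat$cells$lat == 59)
  expect_equal(spec$w_norm[i_eq] / spec$w_norm[i_60], ratio, tolerance = 1e-10)
  expect_equal(mean(spec$w_norm), 1, tolerance = 1e-10)  # mean-normalized
})

test_that("weights are invariant to uniform area rescaling", {
  lat <- grid_lattice(3, 1, origin = c(0, 30))
  spec1 <- region_weights(rect_ring(0, 30, 3, 31), lat)
  lat2 <- lat
  lat2$cells$area_km2 <- lat$cells$area_km2 * 1e6
  spec2 <- region_weights(rect_ring(0, 30, 3, 31), lat2)
  expect_equal(spec1$w_norm, spec2$w_norm, tolerance = 1e-12)
})

test_that("no overlap and empty specs are rejected", {
  lat <- grid_lattice(2, 1)
  expect_error(region_weights(rect_ring(50, 50, 51, 51), lat), "does not overlap")
})

test_that("single-cell regions reproduce the cell trend exactly", {
  fit <- fake_fit_abundance(c(100, 130, 160), n_cells = 2, draws = 8)
  spec <- region_weights(rect_ring(0, 0, 1, 1), fit$lattice, "one")
  rt <- region_trend(fit, spec, 1999, 2001, keep_draws = TRUE)
  ct <- cell_trend(fit, "0,0", 1999, 2001, keep_draws = TRUE)
  expect_equal(rt$estimate, ct$estimate, tolerance = 1e-12)
  expect_equal(rt$draws, ct$draws, tolerance = 1e-12)
})

test_that("region trends are the w''-weighted mean of cell trends per draw", {
  # three same-latitude cells, w' chosen to give weights 1:2:3, per-draw
  # cell trends fixed at 0, 6, 12 percent/yr -> region trend 8 every draw
  lat <- grid_lattice(3, 1)
  draws <- 6; T <- 2
  alpha <- matrix(0, draws, T)
  b <- array(0, c(draws, 3, T))
  growth <- log(1 + c(0, 6, 12) / 100)
  for (cc in 1:3) b[, cc, 2] <- growth[cc]
  b[, , 1] <- b[, , 1] - mean(b[1, , 1])
  b[, , 2] <- sweep(b[, , 2], 1L, rowMeans(b[, , 2]))
  alpha[, 2] <- mean(growth)  # put the removed field mean back in the intercept
  fit <- fake_fit(lat, alpha, b)
  spec <- region_weights(data.frame(cell = lat$cells$cell,
                                    w_prime = c(1, 2, 3) / 3),
                         lat, "wmean")
  # same-latitude cells: w'' proportional to w'
  expect_equal(spec$w_norm / sum(spec$w_norm), c(1, 2, 3) / 6, tolerance = 1e-9)
  rt <- region_trend(fit, spec, 1999, 2000, keep_draws = TRUE)
  expect_equal(rt$draws, rep(8, draws), tolerance = 1e-6)
  # equal weights + equal trends: region trend equals the common trend
  spec_eq <- region_weights(data.frame(cell = lat$cells$cell[1:2],
                                       w_prime = c(1, 1)), lat, "eq")
  fit_c <- fake_fit_abundance(c(100, 105), n_cells = 3, draws = 4)
  rt_eq <- region_trend(fit_c, spec_eq, 1999, 2000)
  expect_equal(rt_eq$estimate, 5, tolerance = 1e-12)
})

test_that("region trends are convex combinations of member-cell trends", {
  set.seed(61)
  lat <- grid_lattice(3, 2)
  draws <- 25; C <- 6; T <- 4
  fit <- fake_fit(lat, matrix(rnorm(draws * T, 2, 0.4), draws, T),
                  array(rnorm(draws * C * T, 0, 0.5), c(draws, C, T)))
  spec <- region_weights(data.frame(cell = lat$cells$cell,
                                    w_prime = runif(C, 0.1, 1)), lat, "rand")
  rt <- region_trend(fit, spec, 1999, 2002, keep_draws = TRUE)$draws
  cell_tr <- sapply(lat$cells$cell, function(cc)
    cell_trend(fit, cc, 1999, 2002, keep_draws = TRUE)$draws)
  expect_true(all(rt >= apply(cell_tr, 1L, min) - 1e-10))
  expect_true(all(rt <= apply(cell_tr, 1L, max) + 1e-10))
  # point-estimate mode averages the posterior point estimates
  pe <- region_trend(fit, spec, 1999, 2002, mode = "point-estimate")
  w <- spec$w_norm / sum(spec$w_norm)
  med <- sapply(lat$cells$cell, function(cc) cell_trend(fit, cc, 1999, 2002)$estimate)
  expect_equal(pe$estimate, sum(w * med), tolerance = 1e-12)
  expect_true(is.na(pe$lo))
})

test_that("GeoJSON regions round-trip into region weights", {
  td <- withr::local_tempdir()
  gj <- file.path(td, "regions.geojson")
  writeLines(jsonlite::toJSON(list(
    type = "FeatureCollection",
    features = list(list(
      type = "Feature",
      properties = list(name = "west"),
      geometry = list(type = "Polygon",
                      coordinates = list(list(c(0, 0), c(1.5, 0), c(1.5, 1),
                                              c(0, 1), c(0, 0))))
    ))), auto_unbox = TRUE, digits = NA), gj)
  regions <- read_region_geojson(gj)
  expect_named(regions, "west")
  lat <- grid_lattice(3, 1)
  spec <- region_weights(regions$west, lat, "west")
  expect_equal(nrow(spec), 2L)
  expect_equal(spec$w_prime, c(1, 0.5), tolerance = 1e-12)
})
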