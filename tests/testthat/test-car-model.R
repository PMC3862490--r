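# Likelihood, sampler contracts, and convergence diagnostics.

test_that("log-likelihood matches Poisson closed forms and a term-by-term oracle", {
  lat <- grid_lattice(2, 1)
  one <- survey_data(data.frame(route_id = "r1", observer_id = "o1", year = 2000,
                                count = 0L, start_lon = 0.5, start_lat = 0.5))
  st <- list(alpha = 0, omega = 0, b = matrix(0, 2, 1))
  expect_equal(log_likelihood(one, lat, st), -1)   # Poisson(1) at 0

  two <- one; two$count <- 2L
  st2 <- list(alpha = log(2), omega = 0, b = matrix(0, 2, 1))
  expect_equal(log_likelihood(two, lat, st2), log(2^2 * exp(-2) / 2))

  # 10 random records vs a scalar dpois sum computed record by record
  set.seed(41)
  raw <- data.frame(
    route_id = paste0("r", 1:5)[sample(5, 10, TRUE)], observer_id = "o",
    year = rep(2000:2001, 5), count = rpois(10, 4),
    start_lat = 0.5, stringsAsFactors = FALSE)
  raw <- raw[!duplicated(raw[c("route_id", "year")]), ]
  raw$start_lon <- ifelse(raw$route_id %in% c("r1", "r2"), 0.5, 1.5)
  df <- survey_data(raw)
  idxK <- length(unique(paste(df$observer_id, df$route_id)))
  st3 <- list(alpha = c(0.3, -0.2), omega = rnorm(idxK, 0, 0.1),
              b = matrix(rnorm(4, 0, 0.2), 2, 2))
  ll <- log_likelihood(df, lat, st3)
  # oracle: recompute each record's mean by hand
  oracle <- 0
  obs_levels <- sort(unique(paste(df$observer_id, df$route_id, sep = "\r")))
  for (i in seq_len(nrow(df))) {
    t <- df$year[i] - 1999
    k <- match(paste(df$observer_id[i], df$route_id[i], sep = "\r"), obs_levels)
    cc <- match(assign_route(df$start_lon[i], df$start_lat[i])$cell, lat$cells$cell)
    lam <- exp(st3$alpha[t] + st3$omega[k] + st3$b[cc, t])
    oracle <- oracle + dpois(df$count[i], lam, log = TRUE)
  }
  expect_equal(ll, oracle, tolerance = 1e-12)
})

test_that("log-likelihood rejects mismatched state dimensions", {
  lat <- grid_lattice(2, 1)
  d <- tiny_survey()
  expect_error(log_likelihood(d, lat, list(alpha = 1, omega = 0, b = matrix(0, 2, 3))),
               "dimensions")
})

test_that("the same configuration and seed give identical draws", {
  sim <- simulate_survey(3, 3, 4, seed = 5)
  ctl <- car_control(n_chains = 2, n_keep = 400, n_burn = 200, seed = 99)
  f1 <- fit_car(sim$data, sim$lattice, ctl)
  f2 <- fit_car(sim$data, sim$lattice, ctl)
  expect_identical(f1$alpha, f2$alpha)
  expect_identical(f1$b, f2$b)
  expect_identical(f1$sigma2, f2$sigma2)
  f3 <- fit_car(sim$data, sim$lattice, car_control(n_chains = 2, n_keep = 400,
                                                   n_burn = 200, seed = 100))
  expect_false(identical(f1$alpha, f3$alpha))
})

test_that("every retained draw satisfies the per-year sum-to-zero constraint", {
  sim <- simulate_survey(3, 3, 4, seed = 6)
  fit <- fit_car(sim$data, sim$lattice,
                 car_control(n_chains = 2, n_keep = 300, n_burn = 100, seed = 2))
  year_means <- apply(fit$b, c(1L, 3L), mean)
  expect_lt(max(abs(year_means)), 1e-12)
  expect_true(all(fit$sigma2 > 0))
  expect_true(all(fit$tau2 > 0))
})

test_that("intercepts recover log mean counts when counts are large", {
  # two-cell lattice, one observer per route, big Poisson counts: the
  # posterior for alpha_t concentrates at the log empirical mean
  set.seed(43)
  n_years <- 8
  years <- 2000:(1999 + n_years)
  mu <- 500
  df <- do.call(rbind, lapply(1:2, function(r) data.frame(
    route_id = paste0("r", r), observer_id = paste0("o", r),
    year = years[1:n_years], count = rpois(n_years, mu),
    start_lon = r - 0.5, start_lat = 0.5, stringsAsFactors = FALSE)))
  d <- survey_data(df)
  lat <- grid_lattice(2, 1)
  fit <- fit_car(d, lat, car_control(n_chains = 2, n_keep = 2000, n_burn = 1500, seed = 3))
  emp <- log(tapply(d$count, d$year, mean))
  post_mean <- colMeans(fit$alpha)
  post_sd <- apply(fit$alpha, 2L, sd)
  expect_true(all(abs(post_mean - emp) < 3 * post_sd))
})

test_that("credible intervals cover simulation truth", {
  # single-replicate recovery at desk scale (the multi-replicate coverage
  # harness lives in the acceptance suite)
  # a single replicate is one Bernoulli trial against a 95% interval, so
  # check the 99.9% interval here; nominal 95% coverage is verified over
  # 20 replicates in the acceptance suite
  sim <- simulate_survey(5, 5, 8, sigma2 = 0.1, tau2 = 0.5, seed = 17)
  fit <- fit_car(sim$data, sim$lattice,
                 car_control(n_chains = 3, n_keep = 3000, n_burn = 1000, seed = 4))
  ci_s <- quantile(fit$sigma2, c(0.0005, 0.9995))
  ci_t <- quantile(fit$tau2, c(0.0005, 0.9995))
  expect_true(ci_s[1] < 0.1 && 0.1 < ci_s[2])
  expect_true(ci_t[1] < 0.5 && 0.5 < ci_t[2])
  expect_lt(max(convergence(fit)), 1.1)
})

test_that("all-zero years trigger the weak-identification warning", {
  d <- tiny_survey()
  d$count[d$year == 2001] <- 0L
  lat <- build_lattice(d)
  expect_warning(fit_car(d, lat, car_control(n_chains = 1, n_keep = 50,
                                             n_burn = 20, seed = 1)),
                 "weakly identified")
})

test_that("Gelman-Rubin matches the standard B/W formula", {
  # identical chains: B = 0, so Rhat = sqrt((n-1)/n) -> 1 for long chains
  expect_equal(gelman_rubin(cbind(1:10000, 1:10000)), 1.0, tolerance = 1e-4)
  expect_gt(gelman_rubin(cbind(rnorm(50, 0, 0.1), rnorm(50, 10, 0.1))), 10)
  # direct-formula oracle on small printed arrays
  x <- cbind(c(1.2, 0.8, 1.1, 0.9), c(1.6, 1.4, 1.7, 1.3), c(0.7, 1.0, 0.9, 0.8))
  n <- 4; m <- 3
  W <- mean(apply(x, 2, var))
  B <- n * var(colMeans(x))
  oracle <- sqrt(((n - 1) / n * W + B / n) / W)
  expect_equal(gelman_rubin(x), oracle, tolerance = 1e-12)
  expect_equal(gelman_rubin(list(x[, 1], x[, 2], x[, 3])), oracle)
  expect_error(gelman_rubin(x[, 1, drop = FALSE]), "2 chains")
  expect_error(gelman_rubin(list(1:3, 1:4)), "equal lengths")
})

test_that("draw export writes a labeled CSV and a manifest", {
  sim <- simulate_survey(3, 3, 3, seed = 8)
  fit <- fit_car(sim$data, sim$lattice,
                 car_control(n_chains = 2, n_keep = 100, n_burn = 50, seed = 5))
  stem <- file.path(withr::local_tempdir(), "fit")
  paths <- write_draws(fit, stem)
  dr <- read.csv(paths[1L], check.names = FALSE)
  expect_equal(nrow(dr), fit$n_total)
  expect_true(all(c("chain", "iter", "alpha_1999", "sigma2", "tau2") %in% names(dr)))
  man <- jsonlite::read_json(paths[2L])
  expect_equal(man$config$n_chains, 2L)
  expect_true("rhat" %in% names(man))
  expect_equal(man$n_total_draws, fit$n_total)
})
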