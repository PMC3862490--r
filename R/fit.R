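## Model configuration, likelihood, and the MCMC driver.

#' Sampler and prior configuration
#'
#' Defaults follow long-standing practice for this model class: vague
#' `N(0, 1e6)` priors on year intercepts, inverse-gamma(0.001, 0.001)
#' hyperpriors on the observer and CAR variances, 3 chains, 20,000
#' retained draws pooled across chains after 5,000 burn-in iterations
#' each, and random-walk proposals adapted toward 0.44 acceptance during
#' burn-in only.
#'
#' @param n_chains number of chains.
#' @param n_keep total retained draws pooled across chains.
#' @param n_burn burn-in iterations per chain (discarded; adaptation
#'   happens here and is then frozen).
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param alpha_prior_var prior variance of the year intercepts.
#' @param ig_shape,ig_rate inverse-gamma hyperprior parameters shared by
#'   `sigma2` and `tau2`.
#' @param target_accept proposal adaptation target acceptance rate.
#' @param observer_mode `"observer-route"` (one random effect per
#'   observer-route combination, the survey tradition; default) or
#'   `"observer"`.
#' @param seed integer seed; a fixed seed gives bit-reproducible chains.
#' @return list of class `car_control`.
#' @export
car_control <- function(n_chains = 3, n_keep = 20000, n_burn = 5000, thin = 1,
                        alpha_prior_var = 1e6, ig_shape = 0.001, ig_rate = 0.001,
                        target_accept = 0.44,
                        observer_mode = c("observer-route", "observer"),
                        seed = 1L) {
  observer_mode <- match.arg(observer_mode)
  stopifnot(n_chains >= 1, n_keep >= 1, n_burn >= 0, thin >= 1,
            alpha_prior_var > 0, ig_shape > 0, ig_rate > 0,
            target_accept > 0, target_accept < 1)
  structure(list(n_chains = as.integer(n_chains), n_keep = as.integer(n_keep),
                 n_burn = as.integer(n_burn), thin = as.integer(thin),
                 alpha_prior_var = alpha_prior_var,
                 ig_shape = ig_shape, ig_rate = ig_rate,
                 target_accept = target_accept, observer_mode = observer_mode,
                 seed = as.integer(seed)),
            class = "car_control")
}

#' Poisson log-likelihood of a parameter state
#'
#' Sum over records of the Poisson log-mass at the observed count with
#' mean `exp(alpha_t + omega_K(i,t) + b_c(i),t)`.
#'
#' @param data a `car_survey` data.frame.
#' @param lattice the `car_lattice` the state's fields live on.
#' @param state list with `alpha` (length T, in year order), `omega`
#'   (length K, in the order of `index_survey`'s observer levels), `b`
#'   (C x T matrix).
#' @param observer_mode observer-effect indexing, as in [car_control()].
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(data, lattice, state,
                           observer_mode = c("observer-route", "observer")) {
  idx <- index_survey(data, lattice, match.arg(observer_mode))
  b <- as.matrix(state$b)
  if (length(state$alpha) != idx$T || length(state$omega) != idx$K ||
      nrow(b) != idx$C || ncol(b) != idx$T)
    stop("state dimensions do not match dataset/lattice (T=", idx$T,
         ", K=", idx$K, ", C=", idx$C, ")")
  eta <- state$alpha[idx$year_idx] + state$omega[idx$obs_idx] +
    b[cbind(idx$cell_idx, idx$year_idx)]
  sum(stats::dpois(idx$y, exp(eta), log = TRUE))
}

#' Fit the spatial trend model by Metropolis-within-Gibbs MCMC
#'
#' Runs `n_chains` independent chains of the compiled sampler. Each
#' chain: random-walk Metropolis updates for every year intercept,
#' observer(-route) effect and cell-year spatial effect (proposal scales
#' adapted toward `target_accept` during burn-in, then frozen), conjugate
#' inverse-gamma Gibbs updates for `sigma2` and `tau2`, and per-sweep
#' sum-to-zero recentering of each year's spatial field (the removed mean
#' is absorbed by the year intercept).
#'
#' @param data a `car_survey` data.frame (see [survey_data()],
#'   [simulate_survey()]).
#' @param lattice a `car_lattice` from [build_lattice()].
#' @param control a [car_control()] configuration.
#' @return object of class `car_fit` with elements `alpha` (draws x T),
#'   `omega` (draws x K), `b` (draws x C x T array), `sigma2`, `tau2`
#'   (vectors), `chain` (chain id per draw), `years`, `cells`, `lattice`,
#'   `control`, `acceptance` (per-chain post-burn-in rates), `n_total`.
#'   Every retained draw has each year's `b` field centered to mean zero.
#' @export
fit_car <- function(data, lattice, control = car_control()) {
  stopifnot(inherits(lattice, "car_lattice"), inherits(control, "car_control"))
  idx <- index_survey(data, lattice, control$observer_mode)
  T <- idx$T; K <- idx$K; C <- idx$C
  if (any(lattice$cells$n_nbr == 0L))
    stop("lattice has isolated cells; rebuild with a connectivity policy")

  ## initial year intercepts: log(mean count + 0.5); global fallback for
  ## years with no records
  ybar <- tapply(idx$y, idx$year_idx, mean)
  a0 <- rep(log(mean(idx$y) + 0.5), T)
  a0[as.integer(names(ybar))] <- log(ybar + 0.5)
  zero_years <- which(vapply(seq_len(T), function(t)
    all(idx$y[idx$year_idx == t] == 0) || !any(idx$year_idx == t), logical(1)))
  if (length(zero_years))
    warning("year(s) with no positive counts: ",
            paste(idx$years[zero_years], collapse = ", "),
            " (intercept weakly identified)")
  if (!all(is.finite(a0))) stop("non-finite likelihood at initialization")

  keep_per_chain <- ceiling(control$n_keep / control$n_chains)
  n_iter <- control$n_burn + keep_per_chain * control$thin

  res <- vector("list", control$n_chains)
  for (ch in seq_len(control$n_chains)) {
    set.seed((control$seed + 7919L * (ch - 1L)) %% .Machine$integer.max)
    jit <- 0.1 * (ch - 1L)  # overdispersed starts for chains 2+
    omega0 <- if (jit > 0) rnorm(K, 0, jit) else numeric(K)
    b0 <- if (jit > 0) rnorm(C * T, 0, jit) else numeric(C * T)
    b0 <- as.vector(scale(matrix(b0, C, T), center = TRUE, scale = FALSE))
    res[[ch]] <- car_mcmc_cpp(
      as.integer(idx$y), idx$year_idx - 1L, idx$obs_idx - 1L, idx$cell_idx - 1L,
      T, K, C, lattice$nb,
      n_iter, control$n_burn, control$thin,
      control$alpha_prior_var, control$ig_shape, control$ig_rate,
      a0 + rnorm(T, 0, jit), omega0, b0, 1.0, 1.0,
      control$target_accept)
  }

  alpha <- do.call(rbind, lapply(res, `[[`, "alpha"))
  omega <- do.call(rbind, lapply(res, `[[`, "omega"))
  bflat <- do.call(rbind, lapply(res, `[[`, "b"))
  draws <- nrow(alpha)
  colnames(alpha) <- idx$years
  colnames(omega) <- idx$obs_labels
  b <- array(bflat, dim = c(draws, C, T),
             dimnames = list(NULL, lattice$cells$cell, idx$years))
  structure(list(
    alpha = alpha, omega = omega, b = b,
    sigma2 = unlist(lapply(res, `[[`, "sigma2")),
    tau2 = unlist(lapply(res, `[[`, "tau2")),
    chain = rep(seq_len(control$n_chains), each = keep_per_chain),
    years = idx$years, cells = lattice$cells$cell,
    lattice = lattice, control = control,
    observer_mode = idx$observer_mode,
    acceptance = do.call(rbind, lapply(res, `[[`, "accept")),
    n_total = draws, n_per_chain = keep_per_chain
  ), class = "car_fit")
}

#' @export
print.car_fit <- function(x, ...) {
  cat("Spatial trend model fit:", x$n_total, "retained draws (",
      x$control$n_chains, "chains x", x$n_per_chain, ")\n")
  cat("  years", min(x$years), "-", max(x$years), "|", length(x$cells),
      "cells |", ncol(x$omega), "observer effects (", x$observer_mode, ")\n")
  cat(sprintf("  posterior medians: sigma2 = %.3g, tau2 = %.3g\n",
              median(x$sigma2), median(x$tau2)))
  invisible(x)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Standard between/within-chain variance formulation:
#' `Rhat = sqrt(((n-1)/n * W + B/n) / W)` with `W` the mean within-chain
#' variance and `B` the between-chain variance of chain means times `n`.
#'
#' @param x a matrix (iterations x chains) or a list of >= 2 equal-length
#'   numeric vectors, one per chain.
#' @return the Rhat statistic.
#' @export
gelman_rubin <- function(x) {
  if (is.list(x)) {
    len <- lengths(x)
    if (length(unique(len)) != 1L) stop("chains must have equal lengths")
    x <- do.call(cbind, x)
  }
  x <- as.matrix(x)
  m <- ncol(x); n <- nrow(x)
  if (m < 2L) stop("need at least 2 chains")
  if (n < 2L) stop("need at least 2 iterations per chain")
  W <- mean(apply(x, 2L, var))
  B <- n * var(colMeans(x))
  vplus <- (n - 1) / n * W + B / n
  if (W == 0) return(if (B == 0) 1.0 else Inf)
  sqrt(vplus / W)
}

#' Convergence summary for a fit
#'
#' Rhat for every year intercept, the two variance components, and
#' (optionally) every cell-year spatial effect.
#'
#' @param fit a `car_fit`.
#' @param spatial include the per-cell-year fields (slower output).
#' @return named numeric vector of Rhat values.
#' @export
convergence <- function(fit, spatial = FALSE) {
  stopifnot(inherits(fit, "car_fit"))
  split_mat <- function(v) matrix(v, ncol = fit$control$n_chains)
  out <- c(
    setNames(apply(fit$alpha, 2L, function(v) gelman_rubin(split_mat(v))),
             paste0("alpha_", fit$years)),
    sigma2 = gelman_rubin(split_mat(fit$sigma2)),
    tau2 = gelman_rubin(split_mat(fit$tau2)))
  if (spatial) {
    bflat <- matrix(fit$b, nrow = dim(fit$b)[1L])
    rb <- apply(bflat, 2L, function(v) gelman_rubin(split_mat(v)))
    names(rb) <- paste0("b_", outer(fit$cells, fit$years, paste, sep = "_"))
    out <- c(out, rb)
  }
  out
}

#' Persist posterior draws and a run manifest
#'
#' Writes a flat CSV (one row per chain x iteration with labeled columns
#' for every parameter) and a JSON manifest recording the configuration,
#' seed, acceptance rates and Rhat per parameter block.
#'
#' @param fit a `car_fit`.
#' @param stem output path stem (writes `<stem>_draws.csv` and
#'   `<stem>_manifest.json`).
#' @return invisibly, the two paths.
#' @export
write_draws <- function(fit, stem) {
  bflat <- matrix(fit$b, nrow = dim(fit$b)[1L])
  colnames(bflat) <- paste0("b_", outer(fit$cells, fit$years, paste, sep = "_"))
  df <- data.frame(chain = fit$chain,
                   iter = sequence(rep(fit$n_per_chain, fit$control$n_chains)),
                   alpha = fit$alpha, sigma2 = fit$sigma2, tau2 = fit$tau2,
                   bflat, check.names = FALSE)
  names(df) <- sub("^alpha\\.", "alpha_", names(df))
  draws_path <- paste0(stem, "_draws.csv")
  write.csv(df, draws_path, row.names = FALSE)
  rh <- convergence(fit)
  manifest <- list(
    config = unclass(fit$control),
    n_total_draws = fit$n_total, n_draws_per_chain = fit$n_per_chain,
    years = fit$years, n_cells = length(fit$cells),
    acceptance = as.data.frame(fit$acceptance),
    rhat = as.list(rh))
  man_path <- paste0(stem, "_manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(draws_path, man_path))
}
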