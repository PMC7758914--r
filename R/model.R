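#' Model specification for the BYM spatiotemporal fit
#'
#' Collects the likelihood family, the space-time interaction switch, the
#' time coding, prior hyperparameters and sampler settings.
#'
#' The model for block `i` at round with time value `t` is
#' `eta_it = alpha + beta * t + u_i + v_i (+ delta_i * t)`, with
#' `y_it ~ Binomial(n_it, plogis(eta_it))` for binary indicators and
#' `y_it ~ Poisson(n_it * exp(eta_it))` for count indicators. `u` carries the
#' intrinsic CAR spatial prior on the contiguity graph, `v` iid
#' `N(0, 1/tau_v)` noise, and `delta` (interaction only) iid
#' `N(0, 1/tau_delta)` per-block trend deviations, centred so that `beta`
#' remains the state-average trend.
#'
#' @param family `"binary"` (binomial-logit) or `"count"` (Poisson-log).
#' @param include_interaction include per-block linear-trend deviations?
#' @param time_values optional named map from round label to time value; the
#'   default codes rounds as years since the first round (0, 1, 2, ...).
#' @param a_tau,b_tau gamma prior shape/rate shared by `tau_u`, `tau_v`,
#'   `tau_delta` (weakly informative default `Gamma(1, 5e-4)`).
#' @param prec_alpha,prec_beta normal prior precisions of intercept and
#'   state-average slope.
#' @param iterations,burnin,thin,chains MCMC settings per chain.
#' @param fixed_tau optional length-3 vector `(tau_u, tau_v, tau_delta)`;
#'   non-`NA` entries are held fixed instead of sampled (used by the
#'   quadrature validation harness).
#' @return a `bym_model_spec`.
#' @export
model_spec <- function(family = c("binary", "count"),
                       include_interaction = FALSE,
                       time_values = NULL,
                       a_tau = 1, b_tau = 5e-4,
                       prec_alpha = 1e-3, prec_beta = 1e-3,
                       iterations = 5000L, burnin = 2000L, thin = 2L,
                       chains = 4L,
                       fixed_tau = c(NA_real_, NA_real_, NA_real_)) {
  family <- match.arg(family)
  stopifnot(a_tau > 0, b_tau > 0, prec_alpha > 0, prec_beta > 0,
            iterations > burnin, burnin >= 0, thin >= 1, chains >= 1,
            length(fixed_tau) == 3L)
  if (!is.null(time_values)) {
    tv <- as.numeric(time_values)
    if (is.unsorted(tv, strictly = TRUE))
      stop("time_values must be strictly increasing")
  }
  structure(list(family = family,
                 include_interaction = isTRUE(include_interaction),
                 time_values = time_values,
                 a_tau = a_tau, b_tau = b_tau,
                 prec_alpha = prec_alpha, prec_beta = prec_beta,
                 iterations = as.integer(iterations),
                 burnin = as.integer(burnin), thin = as.integer(thin),
                 chains = as.integer(chains),
                 fixed_tau = as.numeric(fixed_tau)),
            class = "bym_model_spec")
}

# time values for a dataset's rounds under a spec
round_times <- function(rounds, spec) {
  if (is.null(spec$time_values)) return(as.numeric(rounds - min(rounds)))
  tv <- spec$time_values
  if (!all(as.character(rounds) %in% names(tv)))
    stop("time_values missing an entry for some round")
  as.numeric(tv[as.character(rounds)])
}

# dataset -> blocks x rounds matrices aligned to the graph's block order
dataset_matrices <- function(dataset, graph) {
  if (!all(dataset$observations$block_id %in% graph$block_ids))
    stop("dataset contains blocks unknown to the graph")
  nb <- graph$n_blocks; nr <- length(dataset$rounds)
  y <- matrix(NA_real_, nb, nr,
              dimnames = list(graph$block_ids, dataset$rounds))
  n <- y
  o <- dataset$observations
  i <- match(o$block_id, graph$block_ids)
  r <- match(o$round, dataset$rounds)
  y[cbind(i, r)] <- o$y
  n[cbind(i, r)] <- o$n
  obs <- !is.na(y)
  y[!obs] <- 0; n[!obs] <- 1
  list(y = y, n = n, obs = obs)
}

#' Fit the BYM spatiotemporal model
#'
#' Runs the adaptive Metropolis-within-Gibbs sampler (`chains` independent
#' chains with dispersed starting values), conditioning on observed cells
#' only. Missing cells receive fitted-value draws through the posterior of
#' their linear predictor — this is the model-based imputation of blocks
#' with no respondents. Convergence is assessed by split-Rhat and effective
#' sample size; any split-Rhat above 1.05 sets `converged = FALSE` (flagged,
#' never silent).
#'
#' @param dataset an `indicator_dataset`.
#' @param graph a `block_graph`; its block ids define the spatial universe.
#' @param spec a `bym_model_spec`.
#' @param seed integer seed; the fit is deterministic given `seed`.
#' @return a `bym_fit` with posterior draws of all parameters, deviance
#'   draws, deviance at the posterior mean, and diagnostics.
#' @export
fit_bym <- function(dataset, graph, spec, seed) {
  stopifnot(inherits(dataset, "indicator_dataset"),
            inherits(graph, "block_graph"),
            inherits(spec, "bym_model_spec"))
  if (nrow(dataset$observations) == 0L) stop("dataset has no observed cells")
  if (spec$family != dataset$family)
    stop("spec family '", spec$family, "' does not match dataset family '",
         dataset$family, "'")
  if (missing(seed)) stop("a seed is required")
  validate_dataset(dataset, graph)

  m <- dataset_matrices(dataset, graph)
  tvals <- round_times(dataset$rounds, spec)
  nb <- graph$n_blocks
  nbr <- lapply(seq_len(nb), function(i) integer(0))
  e <- graph$edges
  for (k in seq_len(nrow(e))) {
    nbr[[e[k, 1L]]] <- c(nbr[[e[k, 1L]]], e[k, 2L] - 1L)
    nbr[[e[k, 2L]]] <- c(nbr[[e[k, 2L]]], e[k, 1L] - 1L)
  }
  fam_code <- if (spec$family == "binary") 0L else 1L

  # data-driven starting point: pooled level plus per-block empirical-link
  # residuals, split between u and v. Starting the random effects at their
  # empirical scale keeps chains out of the collapsed (huge-precision) mode.
  ybar <- sum(m$y[m$obs]) / sum(m$n[m$obs])
  ybar <- min(max(ybar, 1e-3), 1 - 1e-3)
  alpha0 <- if (fam_code == 0L) stats::qlogis(ybar) else log(max(ybar, 1e-3))
  ysum <- rowSums(m$y * m$obs); nsum <- rowSums(m$n * m$obs)
  pblk <- (ysum + 0.5) / (nsum + 1)
  eblk <- if (fam_code == 0L) stats::qlogis(pmin(pmax(pblk, 1e-3), 1 - 1e-3))
          else log(pmax(pblk, 1e-3))
  resid <- eblk - mean(eblk)
  sd_resid <- max(stats::sd(resid), 0.05, na.rm = TRUE)  # NA when nb = 1

  chains <- vector("list", spec$chains)
  for (ch in seq_len(spec$chains)) {
    set.seed(as.integer(seed) + (ch - 1L) * 1009L)
    u0 <- 0.7 * resid + stats::rnorm(nb, 0, 0.3 * sd_resid)
    u0 <- u0 - mean(u0)
    v0 <- 0.3 * resid + stats::rnorm(nb, 0, 0.3 * sd_resid)
    init <- c(alpha0 + stats::rnorm(1, 0, 0.3),
              stats::rnorm(1, 0, 0.1),
              1 / (0.7 * sd_resid)^2 * stats::runif(1, 0.5, 2),
              1 / (0.3 * sd_resid)^2 * stats::runif(1, 0.5, 2),
              stats::runif(1, 10, 100),
              u0, v0,
              if (spec$include_interaction) stats::rnorm(nb, 0, 0.05)
              else numeric(nb))
    ft <- spec$fixed_tau
    if (!is.na(ft[1])) init[3] <- ft[1]
    if (!is.na(ft[2])) init[4] <- ft[2]
    if (!is.na(ft[3])) init[5] <- ft[3]
    chains[[ch]] <- bym_mcmc_chain(
      m$y, m$n, m$obs, tvals, nbr, graph$edges, graph$components,
      graph$n_components, fam_code, spec$include_interaction,
      spec$a_tau, spec$b_tau, spec$prec_alpha, spec$prec_beta,
      ft, spec$iterations, spec$burnin, spec$thin, init)
  }

  comb <- function(name) do.call(c, lapply(chains, `[[`, name))
  combm <- function(name) do.call(rbind, lapply(chains, `[[`, name))
  kept <- length(chains[[1L]]$alpha)
  fit <- list(
    family = spec$family, include_interaction = spec$include_interaction,
    spec = spec, seed = as.integer(seed),
    block_ids = graph$block_ids, rounds = dataset$rounds, tvals = tvals,
    indicator_id = dataset$indicator_id,
    graph = graph, y = m$y, n = m$n, obs = m$obs,
    n_chains = spec$chains, n_kept_per_chain = kept,
    chain_id = rep(seq_len(spec$chains), each = kept),
    alpha = comb("alpha"), beta = comb("beta"),
    tau_u = comb("tau_u"), tau_v = comb("tau_v"),
    tau_delta = comb("tau_delta"),
    u = combm("u"), v = combm("v"), delta = combm("delta"),
    deviance_draws = comb("deviance"))
  colnames(fit$u) <- colnames(fit$v) <- colnames(fit$delta) <- graph$block_ids

  # deviance at the posterior mean of the parameters (plug-in, for DIC)
  pm <- list(alpha = mean(fit$alpha), beta = mean(fit$beta),
             u = colMeans(fit$u), v = colMeans(fit$v),
             delta = colMeans(fit$delta))
  fit$deviance_at_mean <- bym_deviance(pm, dataset, spec, graph = graph)

  fit$diagnostics <- fit_diagnostics(chains, spec$include_interaction)
  fit$max_rhat <- max(fit$diagnostics$rhat, na.rm = TRUE)
  fit$min_ess <- min(fit$diagnostics$ess, na.rm = TRUE)
  fit$converged <- is.finite(fit$max_rhat) && fit$max_rhat <= 1.05
  class(fit) <- "bym_fit"
  fit
}

#' @export
print.bym_fit <- function(x, ...) {
  cat(sprintf(
    "<bym_fit> '%s' (%s%s): %d blocks x %d rounds, %d draws (%d chains)\n",
    x$indicator_id, x$family,
    if (x$include_interaction) ", interaction" else "",
    length(x$block_ids), length(x$rounds),
    length(x$alpha), x$n_chains))
  cat(sprintf("  max split-Rhat %.3f, min ESS %.0f%s\n", x$max_rhat,
              x$min_ess,
              if (x$converged) "" else "  ** NOT CONVERGED **"))
  invisible(x)
}

# ---- diagnostics -----------------------------------------------------------

# split-Rhat for a draws matrix (iterations x chains)
split_rhat <- function(x) {
  ni <- nrow(x) %/% 2L
  if (ni < 2L) return(NA_real_)
  halves <- cbind(x[seq_len(ni), , drop = FALSE],
                  x[ni + seq_len(ni), , drop = FALSE])
  mns <- colMeans(halves)
  vrs <- apply(halves, 2L, stats::var)
  W <- mean(vrs)
  B <- ni * stats::var(mns)
  if (W < 1e-12) return(1)
  sqrt(((ni - 1) / ni * W + B / ni) / W)
}

# effective sample size across chains (initial-positive-sequence truncation)
ess_draws <- function(x) {
  ni <- nrow(x); nc <- ncol(x)
  if (ni < 4L) return(NA_real_)
  rho <- rowMeans(vapply(seq_len(nc), function(ch) {
    a <- stats::acf(x[, ch], lag.max = min(ni - 2L, 500L), plot = FALSE,
                    demean = TRUE)$acf[, 1, 1]
    a
  }, numeric(min(ni - 2L, 500L) + 1L)))
  # truncate where the paired sums turn negative
  s <- 0; t <- 1L
  while (t + 1L < length(rho)) {
    pair <- rho[t + 1L] + rho[t + 2L]
    if (!is.finite(pair) || pair < 0) break
    s <- s + pair
    t <- t + 2L
  }
  ess <- ni * nc / (1 + 2 * s)
  min(ess, ni * nc)
}

fit_diagnostics <- function(chains, interaction) {
  nm <- c("alpha", "beta", "tau_u", "tau_v")
  if (interaction) nm <- c(nm, "tau_delta")
  scalar <- lapply(nm, function(p)
    sapply(chains, `[[`, p))
  names(scalar) <- nm
  nb <- ncol(chains[[1L]]$u)
  vec <- list()
  for (p in c("u", "v", if (interaction) "delta")) {
    for (i in seq_len(nb)) {
      vec[[paste0(p, "[", i, "]")]] <-
        sapply(chains, function(ch) ch[[p]][, i])
    }
  }
  all <- c(scalar, vec)
  data.frame(
    param = names(all),
    rhat = vapply(all, function(m) if (stats::sd(m) > 1e-12) split_rhat(m) else 1,
                  numeric(1)),
    ess = vapply(all, function(m) if (stats::sd(m) > 1e-12) ess_draws(m)
                 else length(m), numeric(1)),
    row.names = NULL)
}

# ---- likelihood / deviance -------------------------------------------------

# linear predictor matrix (blocks x rounds) for one parameter state
eta_matrix <- function(params, tvals, interaction = TRUE) {
  nb <- length(params$u)
  d <- if (interaction && !is.null(params$delta)) params$delta else numeric(nb)
  outer(params$u + params$v, rep(1, length(tvals))) +
    params$alpha + outer(d, tvals) +
    outer(rep(1, nb), params$beta * tvals)
}

#' Log-likelihood of a parameter state
#'
#' Sum over observed cells of the full binomial or Poisson log-pmf at the
#' linear predictor; missing cells contribute nothing.
#'
#' @param params list with `alpha`, `beta`, `u`, `v` and (for interaction
#'   models) `delta`, ordered by the graph's block ids.
#' @param dataset an `indicator_dataset`.
#' @param spec a `bym_model_spec` (supplies family and time coding).
#' @param graph the `block_graph` defining block order.
#' @return scalar log-likelihood.
#' @export
bym_log_likelihood <- function(params, dataset, spec, graph) {
  if (spec$family != dataset$family)
    stop("spec family does not match dataset family")
  m <- dataset_matrices(dataset, graph)
  if (!any(m$obs)) return(0)
  tvals <- round_times(dataset$rounds, spec)
  eta <- eta_matrix(params, tvals)
  if (spec$family == "binary") {
    sum(stats::dbinom(m$y[m$obs], m$n[m$obs],
                      stats::plogis(eta[m$obs]), log = TRUE))
  } else {
    sum(stats::dpois(m$y[m$obs], m$n[m$obs] * exp(eta[m$obs]), log = TRUE))
  }
}

#' Deviance of a parameter state
#'
#' `-2 *` [bym_log_likelihood()]; the saturated constant is omitted since it
#' cancels in DIC model comparison.
#'
#' @inheritParams bym_log_likelihood
#' @return scalar deviance.
#' @export
bym_deviance <- function(params, dataset, spec, graph) {
  -2 * bym_log_likelihood(params, dataset, spec, graph)
}

# ---- fitted values and smoothed levels -------------------------------------

#' Posterior draws of fitted cell values
#'
#' For every block-round cell — observed or missing — returns the posterior
#' draws of the fitted proportion (`plogis(eta)`, binary) or the rate per
#' maximum item (`exp(eta)`, count). Missing cells are thereby imputed from
#' the posterior of their linear predictor.
#'
#' @param fit a `bym_fit`.
#' @param round one round label, or `NULL` for all rounds (returns a list).
#' @return draws x blocks matrix (or list of them, named by round).
#' @export
fitted_draws <- function(fit, round = NULL) {
  stopifnot(inherits(fit, "bym_fit"))
  one <- function(r) {
    t <- fit$tvals[match(r, fit$rounds)]
    eta <- sweep(fit$u + fit$v + fit$delta * t, 1L,
                 fit$alpha + fit$beta * t, `+`)  # draws x blocks
    if (fit$family == "binary") stats::plogis(eta) else exp(eta)
  }
  if (!is.null(round)) return(one(round))
  out <- lapply(fit$rounds, one)
  names(out) <- as.character(fit$rounds)
  out
}

#' Smoothed block levels with 95% credible intervals
#'
#' Per block-round posterior median and the 2.5th/97.5th empirical quantiles
#' of the fitted values (the smoothed, and for missing cells imputed,
#' indicator levels).
#'
#' @param fit a `bym_fit` with at least 500 retained draws.
#' @return data frame `block_id, round, observed, median, lo, hi`.
#' @export
smoothed_levels <- function(fit) {
  stopifnot(inherits(fit, "bym_fit"))
  if (length(fit$alpha) < 500L)
    stop("need at least 500 posterior draws for smoothed levels")
  if (fit$min_ess < 500)
    warning("minimum effective sample size below 500; intervals may be noisy")
  out <- do.call(rbind, lapply(seq_along(fit$rounds), function(ri) {
    p <- fitted_draws(fit, fit$rounds[ri])
    q <- apply(p, 2L, stats::quantile, probs = c(0.5, 0.025, 0.975),
               names = FALSE)
    data.frame(block_id = fit$block_ids, round = fit$rounds[ri],
               observed = fit$obs[, ri],
               median = q[1L, ], lo = q[2L, ], hi = q[3L, ],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Persist posterior draws as a long table
#'
#' Columns `param,index,chain,iter,value`; scalar parameters have empty
#' `index`.
#'
#' @param fit a `bym_fit`.
#' @param file output CSV path.
#' @return `file`, invisibly.
#' @export
write_draws <- function(fit, file) {
  kept <- fit$n_kept_per_chain
  iter <- rep(seq_len(kept), times = fit$n_chains)
  sc <- function(p) data.frame(param = p, index = NA_integer_,
                               chain = fit$chain_id, iter = iter,
                               value = fit[[p]])
  vc <- function(p) do.call(rbind, lapply(seq_along(fit$block_ids),
    function(i) data.frame(param = p, index = i, chain = fit$chain_id,
                           iter = iter, value = fit[[p]][, i])))
  tab <- rbind(sc("alpha"), sc("beta"), sc("tau_u"), sc("tau_v"),
               if (fit$include_interaction) sc("tau_delta"),
               vc("u"), vc("v"),
               if (fit$include_interaction) vc("delta"))
  utils::write.csv(tab, file, row.names = FALSE)
  invisible(file)
}
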