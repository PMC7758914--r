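# Shared fixtures and independent oracles for the test suite.

# Two-block, two-round binary fixture used by the quadrature checks.
two_block_dataset <- function() {
  obs <- data.frame(
    block_id = c("A", "A", "B", "B"),
    round = c(1L, 2L, 1L, 2L),
    y = c(12, 20, 8, 15),
    n = c(40, 40, 40, 40))
  indicator_dataset("toy", "binary", obs)
}

two_block_graph <- function() {
  build_graph_from_edgelist(cbind("A", "B"), c("A", "B"))
}

# Dense-grid posterior for the 2-block, 2-round binomial model with
# fixed precisions (tau_u fixed, v suppressed by a huge fixed tau_v).
# Parameters: alpha, beta, w with u = (w, -w) (the sum-to-zero ICAR pair);
# ICAR prior on the pair: exp(-tau_u/2 * (u1 - u2)^2) = exp(-2 tau_u w^2).
# Returns posterior means and sds of alpha and beta by brute-force
# integration on an adaptive grid. Independent of the MCMC code path.
quadrature_2block <- function(dataset, tau_u = 1, prec_ab = 1e-3,
                              npts = 81) {
  o <- dataset$observations
  yA <- o$y[o$block_id == "A"]; nA <- o$n[o$block_id == "A"]
  yB <- o$y[o$block_id == "B"]; nB <- o$n[o$block_id == "B"]
  tv <- c(0, 1)
  logpost <- function(a, b, w) {
    etaA <- a + b * tv + w
    etaB <- a + b * tv - w
    sum(dbinom(yA, nA, plogis(etaA), log = TRUE)) +
      sum(dbinom(yB, nB, plogis(etaB), log = TRUE)) -
      0.5 * prec_ab * (a^2 + b^2) - 2 * tau_u * w^2
  }
  # locate the mode, then integrate on +/- 6 sd (Laplace-scaled) grids
  opt <- optim(c(0, 0, 0), function(p) -logpost(p[1], p[2], p[3]),
               hessian = TRUE)
  sds <- sqrt(diag(solve(opt$hessian)))
  gr <- lapply(1:3, function(k)
    seq(opt$par[k] - 6 * sds[k], opt$par[k] + 6 * sds[k],
        length.out = npts))
  lp <- array(NA_real_, c(npts, npts, npts))
  for (i in seq_len(npts))
    for (j in seq_len(npts))
      lp[i, j, ] <- vapply(gr[[3]],
                           function(w) logpost(gr[[1]][i], gr[[2]][j], w),
                           numeric(1))
  p <- exp(lp - max(lp)); p <- p / sum(p)
  m_a <- sum(apply(p, 1, sum) * gr[[1]])
  m_b <- sum(apply(p, 2, sum) * gr[[2]])
  s_a <- sqrt(sum(apply(p, 1, sum) * (gr[[1]] - m_a)^2))
  s_b <- sqrt(sum(apply(p, 2, sum) * (gr[[2]] - m_b)^2))
  list(mean_alpha = m_a, mean_beta = m_b, sd_alpha = s_a, sd_beta = s_b)
}

# 1-D quadrature posterior mean of plogis(alpha) for a single binomial cell
# with a diffuse normal prior on alpha.
quadrature_1cell_mean_p <- function(y, n, prec_alpha = 1e-3) {
  gr <- seq(-8, 8, length.out = 4001)
  lp <- dbinom(y, n, plogis(gr), log = TRUE) - 0.5 * prec_alpha * gr^2
  w <- exp(lp - max(lp)); w <- w / sum(w)
  sum(w * plogis(gr))
}

# Minimal stand-in posterior object for trend-resampling tests.
fake_trend_fit <- function(beta, delta_mat, block_ids) {
  list(include_interaction = !is.null(delta_mat),
       beta = beta, delta = delta_mat, block_ids = block_ids)
}

# Short sampler settings used when a test only needs a usable posterior,
# not publication-grade convergence.
quick_spec <- function(family, interaction, ...) {
  model_spec(family = family, include_interaction = interaction,
             iterations = 3000L, burnin = 1000L, thin = 2L, chains = 2L,
             ...)
}
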