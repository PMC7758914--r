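test_that("single-cell posterior matches 1-D quadrature", {
  ds <- indicator_dataset("one", "binary",
                          data.frame(block_id = "solo", round = 1L,
                                     y = 10, n = 20))
  g <- build_graph_from_edgelist(matrix(character(0), ncol = 2), "solo")
  # isolated block: u pinned at 0; v suppressed by a huge fixed precision
  sp <- model_spec("binary", iterations = 4000, burnin = 1000, thin = 1,
                   chains = 2, fixed_tau = c(1, 1e8, NA))
  f <- fit_bym(ds, g, sp, seed = 31)
  oracle <- quadrature_1cell_mean_p(10, 20)
  expect_equal(mean(plogis(f$alpha)), oracle, tolerance = 0.01)
  expect_equal(oracle, 0.5, tolerance = 1e-3)  # symmetric data
})

test_that("sampler matches dense quadrature on the 2-block model
           with fixed precisions", {
  ds <- two_block_dataset()
  g <- two_block_graph()
  oracle <- quadrature_2block(ds, tau_u = 1)
  sp <- model_spec("binary", iterations = 6000, burnin = 2000, thin = 1,
                   chains = 4, fixed_tau = c(1, 1e8, NA))
  f <- fit_bym(ds, g, sp, seed = 12)
  # agreement within 0.02 on the logit scale (absolute)
  expect_lt(abs(mean(f$alpha) - oracle$mean_alpha), 0.02)
  expect_lt(abs(mean(f$beta) - oracle$mean_beta), 0.02)
  expect_lt(abs(sd(f$alpha) - oracle$sd_alpha), 0.02)
  expect_lt(abs(sd(f$beta) - oracle$sd_beta), 0.02)
})

test_that("exchangeable blocks get exchangeable spatial effects", {
  obs <- data.frame(block_id = c("A", "A", "B", "B"),
                    round = c(1L, 2L, 1L, 2L),
                    y = c(12, 18, 12, 18), n = rep(40, 4))
  ds <- indicator_dataset("sym", "binary", obs)
  f <- fit_bym(ds, two_block_graph(), quick_spec("binary", FALSE), seed = 4)
  expect_lt(abs(mean(f$u[, "A"]) - mean(f$u[, "B"])), 0.05)
})

test_that("fits are deterministic given the seed and flag convergence", {
  g <- make_lattice(3, 3)
  sim <- generate_dataset(g, truth_spec(beta0 = 0.1, n_range = c(30L, 60L)),
                          seed = 8)
  sp <- quick_spec("binary", FALSE)
  f1 <- fit_bym(sim$dataset, g, sp, seed = 99)
  f2 <- fit_bym(sim$dataset, g, sp, seed = 99)
  expect_identical(f1$alpha, f2$alpha)
  expect_identical(f1$u, f2$u)
  expect_identical(f1$deviance_draws, f2$deviance_draws)
  expect_type(f1$converged, "logical")
  expect_true(all(c("rhat", "ess") %in% names(f1$diagnostics)))
  expect_error(fit_bym(sim$dataset, g, sp), "seed")
})

test_that("log-likelihood and deviance follow the stated contracts", {
  g <- two_block_graph()
  ds_bin <- indicator_dataset("b", "binary",
                              data.frame(block_id = "A", round = 1L,
                                         y = 0, n = 19),
                              block_ids = c("A", "B"))
  sp <- model_spec("binary")
  pars <- list(alpha = 0, beta = 0, u = c(0, 0), v = c(0, 0),
               delta = c(0, 0))
  expect_equal(bym_log_likelihood(pars, ds_bin, sp, g), 19 * log(0.5))
  expect_equal(bym_deviance(pars, ds_bin, sp, g),
               -2 * bym_log_likelihood(pars, ds_bin, sp, g))

  ds_cnt <- indicator_dataset("c", "count",
                              data.frame(block_id = "A", round = 1L,
                                         y = 0, n = 7),
                              block_ids = c("A", "B"))
  spc <- model_spec("count")
  pars$alpha <- 0.3
  expect_equal(bym_log_likelihood(pars, ds_cnt, spc, g), -7 * exp(0.3))
  expect_error(bym_log_likelihood(pars, ds_cnt, sp, g), "family")

  # additivity: two identical indicators double the deviance
  obs2 <- data.frame(block_id = c("A", "B"), round = 1L, y = c(3, 4),
                     n = c(10, 12))
  d1 <- indicator_dataset("d", "binary", obs2)
  dev1 <- bym_deviance(pars, d1, sp, g)
  # same cells at two rounds with beta = 0 behaves as two copies
  obs_twice <- rbind(obs2, transform(obs2, round = 2L))
  d2 <- indicator_dataset("d", "binary", obs_twice)
  pars$beta <- 0
  expect_equal(bym_deviance(pars, d2, sp, g), 2 * dev1)
})

test_that("smoothed levels are monotone quantile summaries in [0,1]", {
  g <- make_lattice(3, 3)
  sim <- generate_dataset(g, truth_spec(beta0 = 0.15), seed = 5)
  f <- fit_bym(sim$dataset, g, quick_spec("binary", FALSE), seed = 17)
  sl <- smoothed_levels(f)
  expect_equal(nrow(sl), 9L * 4L)
  expect_true(all(sl$lo <= sl$median & sl$median <= sl$hi))
  expect_true(all(sl$lo >= 0 & sl$hi <= 1))
})

test_that("missing cells are imputed with wider uncertainty", {
  g <- make_lattice(6, 6)
  sim <- generate_dataset(g, truth_spec(beta0 = 0.1, sd_u = 0.7,
                                        sd_v = 0.2,
                                        n_range = c(40L, 40L)), seed = 14)
  # block with no respondents in any round: imputation rests on neighbours
  o <- sim$dataset$observations
  ds <- indicator_dataset("m", "binary", o[o$block_id != "r2c2", ],
                          rounds = sim$dataset$rounds,
                          block_ids = sim$dataset$block_ids)
  f <- fit_bym(ds, g, quick_spec("binary", FALSE), seed = 6)
  sl <- smoothed_levels(f)
  w <- sl$hi - sl$lo
  miss <- sl$block_id == "r2c2"
  expect_false(any(sl$observed[miss]))
  expect_true(all(is.finite(sl$median[miss])))
  # every imputed CrI wider than the median observed-cell width
  expect_true(all(w[miss] > median(w[sl$observed])))
})

test_that("shrinkage moves smoothed levels from raw toward pooled
           as fixed precisions grow", {
  g <- make_lattice(3, 3)
  sim <- generate_dataset(g, truth_spec(alpha0 = -0.3, sd_u = 0.8,
                                        sd_v = 0.3, rounds = 1L,
                                        n_range = c(60L, 60L)), seed = 23)
  raw <- raw_estimates(sim$dataset)
  pooled <- with(sim$dataset$observations, sum(y) / sum(n))
  dist_raw <- c(); dist_pool <- c()
  for (tau in c(0.1, 10, 1000)) {
    sp <- model_spec("binary", iterations = 2500, burnin = 1000, thin = 1,
                     chains = 2, fixed_tau = c(tau, tau, NA))
    f <- fit_bym(sim$dataset, g, sp, seed = 40)
    sl <- smoothed_levels(f)
    m <- sl$median[match(raw$block_id, sl$block_id)]
    dist_raw <- c(dist_raw, mean(abs(m - raw$value)))
    dist_pool <- c(dist_pool, mean(abs(m - pooled)))
  }
  expect_true(all(diff(dist_raw) > 0))   # tighter priors pull away from raw
  expect_true(all(diff(dist_pool) < 0))  # ... and toward the pooled level
})

test_that("count-family model recovers a rate trend", {
  g <- make_lattice(4, 4)
  sim <- generate_dataset(g, truth_spec(alpha0 = -1, beta0 = log(1.2),
                                        sd_u = 0.3, sd_v = 0.1,
                                        family = "count",
                                        n_range = c(40L, 80L)), seed = 77)
  f <- fit_bym(sim$dataset, g, quick_spec("count", FALSE), seed = 3)
  ci <- quantile(f$beta, c(0.025, 0.975))
  expect_true(ci[1] < log(1.2) && log(1.2) < ci[2])
  sl <- smoothed_levels(f)
  expect_true(all(sl$median > 0))
})

test_that("draws persist in the long param/index/chain/iter format", {
  g <- make_lattice(2, 2)
  sim <- generate_dataset(g, truth_spec(rounds = 2L), seed = 1)
  sp <- model_spec("binary", iterations = 1200, burnin = 200, thin = 2,
                   chains = 2)
  f <- fit_bym(sim$dataset, g, sp, seed = 2)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_draws(f, tmp)
  d <- read.csv(tmp)
  expect_setequal(names(d), c("param", "index", "chain", "iter", "value"))
  expect_setequal(unique(d$param), c("alpha", "beta", "tau_u", "tau_v",
                                     "u", "v"))
  expect_equal(sum(d$param == "alpha"), length(f$alpha))
  expect_equal(max(d$chain), 2L)
})
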