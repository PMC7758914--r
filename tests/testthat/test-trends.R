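test_that("DIC arithmetic follows dbar + pd with pd = dbar - d_at_mean", {
  f <- list(deviance_draws = rep(c(98, 102), 100), deviance_at_mean = 96)
  d <- compute_dic(f)
  expect_equal(d$dbar, 100)
  expect_equal(d$pd, 4)
  expect_equal(d$dic, 104)
  expect_equal(d$dic, d$dbar + d$pd)

  degen <- list(deviance_draws = rep(50, 200), deviance_at_mean = 50)
  dd <- compute_dic(degen)
  expect_equal(dd$pd, 0)
  expect_equal(dd$dic, dd$dbar)

  expect_error(compute_dic(list(deviance_draws = rnorm(50),
                                deviance_at_mean = 0)), "100")
})

test_that("pD approximates the parameter count in a conjugate normal toy", {
  # oracle: y_j ~ N(theta, s^2) known s, flat-ish prior; posterior
  # theta | y ~ N(ybar, s^2/n); plug-in pD is asymptotically 1 (one
  # parameter)
  set.seed(42)
  n <- 50; s <- 1.3
  y <- rnorm(n, 2, s)
  draws <- rnorm(20000, mean(y), s / sqrt(n))
  dev <- vapply(draws, function(th) -2 * sum(dnorm(y, th, s, log = TRUE)),
                numeric(1))
  d <- compute_dic(list(deviance_draws = dev,
                        deviance_at_mean = -2 * sum(dnorm(y, mean(draws), s,
                                                          log = TRUE))))
  expect_equal(d$pd, 1, tolerance = 0.05)
})

test_that("model selection takes the lower DIC with ties to simplicity", {
  g <- make_lattice(3, 3)
  sim <- generate_dataset(g, truth_spec(beta0 = 0.1), seed = 3)
  sp0 <- model_spec("binary", FALSE, iterations = 1500, burnin = 500,
                    thin = 1, chains = 2)
  sp1 <- model_spec("binary", TRUE, iterations = 1500, burnin = 500,
                    thin = 1, chains = 2)
  f0 <- fit_bym(sim$dataset, g, sp0, seed = 5)
  f1 <- fit_bym(sim$dataset, g, sp1, seed = 6)
  sel <- select_model(f0, f1)
  d0 <- compute_dic(f0)$dic; d1 <- compute_dic(f1)$dic
  expect_equal(sel$interaction_evidence, d1 < d0)
  expect_identical(sel$chosen$include_interaction,
                   sel$interaction_evidence)
  expect_equal(sel$dic_table$dic, c(d0, d1))

  # argument order and dataset identity are enforced
  expect_error(select_model(f1, f0), "no-interaction")
  sim2 <- generate_dataset(g, truth_spec(beta0 = 0.1), seed = 30)
  f0b <- fit_bym(sim2$dataset, g, sp0, seed = 5)
  expect_error(select_model(f0b, f1), "same dataset")

  # exact tie resolves to the simpler model
  t0 <- list(deviance_draws = rep(104, 200), deviance_at_mean = 104)
  t1 <- list(deviance_draws = rep(104, 200), deviance_at_mean = 104)
  expect_false(compute_dic(t1)$dic < compute_dic(t0)$dic)
})

test_that("trend classification implements the 97.5% probability rule", {
  # the three regimes, at CrIs of the kind block-level ANC trends produce
  expect_equal(classify_trend(0.36, 0.59), "decrease")
  expect_equal(classify_trend(1.02, 1.32), "increase")
  expect_equal(classify_trend(0.83, 1.23), "indeterminate")
  # boundary: interval touching 1.0 stays indeterminate
  expect_equal(classify_trend(1.0, 1.2), "indeterminate")
  expect_equal(classify_trend(0.8, 1.0), "indeterminate")
  expect_error(classify_trend(-0.1, 0.5), "positive")
  expect_error(classify_trend(1.4, 1.2), "exceed")

  # exhaustive and mutually exclusive over a random grid of valid bounds
  set.seed(7)
  lo <- exp(rnorm(500, 0, 0.5)); hi <- lo * exp(abs(rnorm(500, 0, 0.5)))
  cat <- classify_trend(lo, hi)
  expect_true(all(cat %in% c("increase", "decrease", "indeterminate")))
  expect_equal(cat == "increase", lo > 1)
  expect_equal(cat == "decrease", hi < 1)
})

test_that("degenerate posteriors give degenerate trend intervals", {
  f <- fake_trend_fit(beta = rep(log(1.1), 2000),
                      delta_mat = matrix(0, 2000, 3,
                                         dimnames = list(NULL, c("a", "b", "c"))),
                      block_ids = c("a", "b", "c"))
  tr <- block_trends(f, resamples = 2000, seed = 1)
  expect_equal(tr$or_point, rep(1.1, 3), tolerance = 1e-12)
  expect_equal(tr$lo, tr$hi)
})

test_that("independent-mode resampling matches closed-form lognormal
           quantiles", {
  set.seed(101)
  nd <- 20000
  mu_b <- log(1.2); s_b <- 0.05; s_d <- 0.05
  f <- fake_trend_fit(beta = rnorm(nd, mu_b, s_b),
                      delta_mat = matrix(rnorm(nd * 2, 0, s_d), nd, 2),
                      block_ids = c("x", "y"))
  tr <- block_trends(f, resamples = 10000, seed = 5, mode = "independent")
  s_sum <- sqrt(s_b^2 + s_d^2)
  expect_equal(tr$lo, rep(qlnorm(0.025, mu_b, s_sum), 2), tolerance = 0.01)
  expect_equal(tr$hi, rep(qlnorm(0.975, mu_b, s_sum), 2), tolerance = 0.01)
  expect_equal(tr$or_point, rep(exp(mu_b), 2), tolerance = 0.01)
})

test_that("joint mode preserves posterior correlation; independent breaks it", {
  nd <- 5000
  beta <- rnorm(nd, 0.2, 0.3)
  delta <- matrix(-beta + 0.1, nd, 1)  # perfectly anti-correlated
  f <- fake_trend_fit(beta, delta, "only")
  joint <- block_trends(f, 2000, seed = 2, mode = "joint")
  indep <- block_trends(f, 2000, seed = 2, mode = "independent")
  expect_equal(joint$lo, joint$hi)             # degenerate: all sums = 0.1
  expect_equal(joint$or_point, exp(0.1))
  expect_gt(indep$hi - indep$lo, 0.5)          # marginals ignore correlation
})

test_that("resampling is reproducible and falls back without interaction", {
  nd <- 3000
  f <- fake_trend_fit(rnorm(nd, 0.1, 0.05), NULL, c("p", "q", "r"))
  f$include_interaction <- FALSE
  t1 <- block_trends(f, 1500, seed = 9)
  t2 <- block_trends(f, 1500, seed = 9)
  expect_identical(t1, t2)
  expect_equal(length(unique(t1$or_point)), 1L)  # one shared trend
  expect_equal(nrow(t1), 3L)
  expect_error(block_trends(f, 500, seed = 1), "1000")
})

test_that("indicator summaries count categories exhaustively", {
  tr <- data.frame(block_id = letters[1:6],
                   or_point = c(1.3, 1.2, 0.7, 0.8, 1.0, 1.01),
                   lo = c(1.1, 1.05, 0.5, 0.6, 0.9, 0.85),
                   hi = c(1.5, 1.4, 0.9, 0.95, 1.1, 1.2))
  tr$category <- classify_trend(tr$lo, tr$hi)
  s <- summarize_indicator(tr, indicator_id = "demo")
  expect_equal(s$n_increase + s$n_decrease + s$n_indeterminate, 6L)
  expect_equal(s$n_increase, 2L)
  expect_equal(s$n_decrease, 2L)
  expect_equal(c(s$or_min, s$or_max), range(tr$or_point))
})

test_that("trend GeoJSON writer annotates features", {
  g <- make_lattice(2, 2)
  tmp_in <- withr::local_tempfile(fileext = ".geojson")
  tmp_out <- withr::local_tempfile(fileext = ".geojson")
  write_lattice_geojson(g, tmp_in)
  tr <- data.frame(block_id = g$block_ids,
                   or_point = c(1.2, 0.8, 1.0, 1.1),
                   lo = c(1.1, 0.7, 0.9, 0.9),
                   hi = c(1.3, 0.9, 1.1, 1.3))
  tr$category <- classify_trend(tr$lo, tr$hi)
  write_trends_geojson(tmp_in, tr, tmp_out)
  gj <- jsonlite::fromJSON(tmp_out, simplifyVector = FALSE)
  p1 <- gj$features[[1]]$properties
  expect_equal(p1$or_point, tr$or_point[tr$block_id == p1$block_id])
  expect_true(all(vapply(gj$features,
                         function(f) !is.null(f$properties$category),
                         logical(1))))
})
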