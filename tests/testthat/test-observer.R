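test_that("likelihood is positive and collapses to a delta for tiny noise", {
  g <- std_grid()
  L <- likelihood_over_grid(1.4, g, w_m = 0.1)
  expect_true(all(L > 0))
  # near-noiseless likelihood pins the posterior mean to the measurement
  p <- prior_mln(g, 0.1, 1.1)
  expect_equal(posterior_mean(1.3, p, w_m = 0.001), 1.3, tolerance = g$step)
  # constant-SD variant is symmetric in (t - t_m); grid chosen so the
  # measurement sits exactly on a grid point
  gs <- duration_grid(0.4, 2.4, 1001)
  Lc <- likelihood_over_grid(1.4, gs, w_m = 0.1, constant_sd = 0.2)
  i <- which(gs$points == 1.4)
  k <- 50
  expect_equal(Lc[i + seq_len(k)], Lc[i - seq_len(k)], tolerance = 1e-10)
  expect_error(likelihood_over_grid(-1, g, 0.1), "positive")
})

test_that("posterior mean matches the conjugate closed form with constant noise", {
  g <- duration_grid(0.05, 6, 8192)
  set.seed(42)
  for (i in 1:20) {
    mu0 <- runif(1, 0.8, 2); s0 <- runif(1, 0.05, 0.4)
    sL <- runif(1, 0.05, 0.4); tm <- runif(1, 0.7, 2.2)
    prior <- prior_gaussian(g, mu0, s0)
    te <- posterior_mean(tm, prior, w_m = 1, constant_sd = sL)
    closed <- (s0^2 * tm + sL^2 * mu0) / (s0^2 + sL^2)
    expect_equal(te, closed, tolerance = 1e-3 * closed)
  }
})

test_that("posterior mean is monotone in the measurement for all families", {
  g <- std_grid()
  priors <- list(prior_uniform(g, 1.17, 1.68),
                 prior_gaussian(g, 1.4, 0.15),
                 prior_mln(g, 0.1, 1.1))
  tm <- seq(0.7, 2.3, length.out = 200)
  for (p in priors) {
    te <- posterior_mean(tm, p, w_m = 0.12)
    expect_true(all(diff(te) >= -1e-12))
    expect_true(all(te >= g$lower & te <= g$upper))
  }
})

test_that("posterior mean is bounded between measurement and prior mean", {
  # unimodal symmetric prior + constant-SD likelihood: shrinkage interpolates
  g <- duration_grid(0.05, 6, 4096)
  prior <- prior_gaussian(g, 1.4, 0.2)
  for (tm in c(0.9, 1.2, 1.6, 2.0)) {
    te <- posterior_mean(tm, prior, w_m = 1, constant_sd = 0.15)
    expect_gte(te, min(tm, 1.4) - 1e-6)
    expect_lte(te, max(tm, 1.4) + 1e-6)
  }
})

test_that("degenerate and concentrated priors behave as limits dictate", {
  g <- std_grid()
  p <- prior_uniform(g, 1.17, 1.68)
  # a prior with no support anywhere is degenerate
  p0 <- p
  p0$density <- rep(0, g$n_points)
  expect_error(posterior_mean(2.5, p0, w_m = 0.1), "degenerate")
  # all mass on a single grid point: the estimate is that point, even when
  # the likelihood there is astronomically small
  p1 <- p
  p1$density <- c(1 / g$step, rep(0, g$n_points - 1))
  expect_equal(posterior_mean(2.5, p1, w_m = 1e-3), g$lower)
})

test_that("simulated trials are noiseless in the zero-noise limit", {
  g <- std_grid()
  p <- prior_mln(g, 0.1, 1.1)
  pars <- observer_params("mln", w_m = 1e-6, delta_w_p = 0, p_sd = 0.1,
                          p_r = 1.1)
  set.seed(1)
  expect_equal(simulate_trial(1.4, pars, p), 1.4, tolerance = 1e-3)
})

test_that("simulated datasets are reproducible and correctly sized", {
  stim <- std_stimuli()
  pars <- observer_params("mln", w_m = 0.1, delta_w_p = 0.05, p_sd = 0.1,
                          p_r = 1.1)
  a <- simulate_dataset(pars, stim, 1000, seed = 7)
  expect_identical(nrow(a), 3000L)
  expect_identical(a, simulate_dataset(pars, stim, 1000, seed = 7))
  b <- simulate_dataset(pars, stim, 1000, seed = 8)
  expect_false(identical(a$t_p, b$t_p))
  # simulate_dataset does not disturb the caller's RNG stream
  set.seed(3); x1 <- rnorm(1)
  set.seed(3); invisible(simulate_dataset(pars, stim, 10, seed = 7))
  expect_identical(rnorm(1), x1)
})

test_that("simulation shows central tendency and the scalar property", {
  stim <- std_stimuli()
  pars <- observer_params("mln", w_m = 0.1, delta_w_p = 0.02, p_sd = 0.1,
                          p_r = 1.05)
  tr <- simulate_dataset(pars, stim, 4000, seed = 5)
  d <- stim$durations
  m <- vapply(d, function(x) mean(tr$t_p[tr$t_s == x]), numeric(1))
  s <- vapply(d, function(x) sd(tr$t_p[tr$t_s == x]), numeric(1))
  expect_gt(m[1], d[1])   # shortest over-reproduced
  expect_lt(m[3], d[3])   # longest under-reproduced
  expect_true(all(diff(s) > 0))  # SD grows with duration
})

test_that("noisier clocks never weaken the extreme-duration bias", {
  g <- std_grid()
  p <- prior_mln(g, 0.1, 1.1)
  pars <- function(wm) observer_params("mln", w_m = wm, delta_w_p = 0,
                                       p_sd = 0.1, p_r = 1.1)
  ts <- c(1.17, 1.68)
  bias <- sapply(c(0.05, 0.1, 0.15, 0.2), function(wm)
    abs(bias_curve(pars(wm), p, ts)$bias))
  expect_true(all(diff(t(bias))[, 1] >= -1e-9))
  expect_true(all(diff(t(bias))[, 2] >= -1e-9))
})

test_that("bias vanishes for flat priors and at a symmetric prior's centre", {
  g <- std_grid()
  flat <- prior_uniform(g, g$lower, g$upper)
  # constant-SD likelihood over a flat prior: estimate equals measurement
  te <- posterior_mean(c(1.2, 1.4, 1.6), flat, w_m = 1, constant_sd = 0.05)
  expect_equal(te, c(1.2, 1.4, 1.6), tolerance = 1e-3)
  # symmetric prior: noiseless bias at the centre is zero
  sym <- prior_gaussian(g, 1.4, 0.12)
  pars <- observer_params("mln", w_m = 0.1, delta_w_p = 0, p_sd = 0.12,
                          p_r = 1.1)
  b <- bias_curve(pars, sym, 1.4)
  expect_equal(b$bias, 0, tolerance = g$step)
})

test_that("Monte-Carlo and noiseless bias curves agree on average", {
  g <- std_grid()
  p <- prior_mln(g, 0.15, 1.1)
  pars <- observer_params("mln", w_m = 0.05, delta_w_p = 0.02, p_sd = 0.15,
                          p_r = 1.1)
  ts <- c(1.2, 1.4, 1.6)
  b0 <- bias_curve(pars, p, ts)
  b1 <- bias_curve(pars, p, ts, n_rep = 20000, seed = 2)
  expect_lt(max(abs(b1$bias - b0$bias)), 0.01)
})
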