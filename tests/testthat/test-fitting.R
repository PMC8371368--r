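test_that("mean-centering anchors reproductions to the mean stimulus", {
  tr <- toy_trials(c(1.17, 1.4, 1.68), c(1.5, 1.7, 1.9))
  cc <- center_reproductions(tr)
  expect_equal(mean(cc$t_p) - mean(cc$t_s), 0, tolerance = 1e-12)

  # single trial: reproduction moves to the presented duration
  one <- center_reproductions(toy_trials(1.4, 2.0))
  expect_equal(one$t_p, 1.4)

  # already-anchored tables are unchanged
  tr2 <- toy_trials(c(1.2, 1.6), c(1.1, 1.7))
  expect_equal(center_reproductions(tr2)$t_p, tr2$t_p)
  expect_error(center_reproductions(data.frame()), "non-empty")
})

test_that("quantile profiles recover known distribution quantiles", {
  set.seed(11)
  tr <- toy_trials(rep(c(1, 2), each = 1000), runif(2000))
  q <- quantile_profile(tr)
  expect_equal(unclass(q)[1, c(1, 3, 5)], c(0.1, 0.5, 0.9),
               tolerance = 0.03, ignore_attr = TRUE)
  expect_true(all(apply(unclass(q), 1, function(r) all(diff(r) >= 0))))

  const <- quantile_profile(toy_trials(rep(1.4, 9), rep(1.23, 9)))
  expect_equal(as.numeric(const), rep(1.23, 5))
})

test_that("quantile RMSE has its closed form and symmetry", {
  set.seed(2)
  tr <- toy_trials(rep(c(1.17, 1.4, 1.68), each = 50), rlnorm(150, 0.3, 0.2))
  a <- quantile_profile(tr)
  expect_identical(quantile_rmse(a, a), 0)
  b <- a
  b[2, 3] <- b[2, 3] + 0.09
  expect_equal(quantile_rmse(a, b), 0.09 / sqrt(15))
  expect_equal(quantile_rmse(a, b), quantile_rmse(b, a))
  expect_error(quantile_rmse(a, unclass(a)[1:2, ]), "mismatch")
})

test_that("default grids reproduce the standard search ranges", {
  mln <- grid_spec("mln")
  expect_equal(range(mln$params$w_m), c(0.005, 0.2))
  expect_equal(range(mln$params$delta_w_p), c(0.0001, 0.15))
  expect_equal(range(mln$params$p_sd), c(0.01, 0.3))
  expect_equal(range(mln$params$p_r), c(1.02, 1.2))
  expect_equal(lengths(mln$params), c(w_m = 20L, delta_w_p = 20L,
                                      p_sd = 20L, p_r = 10L))
  expect_equal(prod(lengths(mln$params)), 80000L)
  expect_equal(lengths(grid_spec("uniform")$params), c(w_m = 20L, w_p = 20L))
  # reduced grids are subsets of the full grids
  red <- grid_spec("mln", profile = "reduced")
  for (nm in names(red$params))
    expect_true(all(red$params[[nm]] %in% mln$params[[nm]]))
  expect_error(grid_spec("uniform", p_r = 1.1), "unknown parameter")
})

test_that("a singleton grid returns exactly that vector", {
  stim <- std_stimuli()
  pars <- observer_params("mln", w_m = 0.1, delta_w_p = 0.05, p_sd = 0.12,
                          p_r = 1.1)
  tr <- simulate_dataset(pars, stim, 100, seed = 3)
  spec <- grid_spec("mln", w_m = 0.1, delta_w_p = 0.05, p_sd = 0.12, p_r = 1.1)
  fit <- grid_search(tr, spec, stim, n_sim = 100, seed = 4)
  expect_identical(nrow(fit$table), 1L)
  expect_equal(fit$best,
               c(w_m = 0.1, delta_w_p = 0.05, p_sd = 0.12, p_r = 1.1))
  expect_equal(fit$average, fit$best)
  expect_equal(sum(fit$aic_weights), 1)
})

test_that("grid search is deterministic and sized as the Cartesian product", {
  stim <- std_stimuli()
  pars <- observer_params("mln", w_m = 0.1, delta_w_p = 0.05, p_sd = 0.12,
                          p_r = 1.1)
  tr <- simulate_dataset(pars, stim, 200, seed = 3)
  spec <- grid_spec("mln", w_m = c(0.06, 0.1, 0.14), delta_w_p = c(0.02, 0.05),
                    p_sd = c(0.08, 0.12), p_r = c(1.05, 1.1))
  f1 <- fit_observer(tr, spec = spec, stimuli = stim, n_sim = 200, seed = 9)
  f2 <- fit_observer(tr, spec = spec, stimuli = stim, n_sim = 200, seed = 9)
  expect_identical(nrow(f1$table), 3L * 2L * 2L * 2L)
  expect_identical(f1$table$rmse, f2$table$rmse)
  expect_lte(f1$rmse, min(f1$table$rmse))
  # averaged parameters stay inside the grid's convex hull
  for (nm in names(spec$params)) {
    expect_gte(f1$average[[nm]], min(spec$params[[nm]]))
    expect_lte(f1$average[[nm]], max(spec$params[[nm]]))
  }
})

test_that("AIC weighting averages the grid as expected", {
  fake <- function(rmse) {
    tab <- data.frame(w_m = c(0.05, 0.1, 0.15), delta_w_p = 0.05,
                      p_sd = 0.1, p_r = 1.1, rmse = rmse)
    list(table = tab, n_quantile_cells = 15, family = "mln")
  }
  # equal RMSE: equal weights, arithmetic-mean average
  eq <- aic_average(fake(rep(0.03, 3)))
  expect_equal(eq$weights, rep(1 / 3, 3))
  expect_equal(eq$average[["w_m"]], 0.1)
  expect_equal(sum(eq$weights), 1, tolerance = 1e-9)
  # a 10x better vector dominates the average
  dom <- aic_average(fake(c(0.003, 0.03, 0.03)))
  expect_equal(dom$average[["w_m"]], 0.05, tolerance = 1e-3)
  # infinite RMSE gets zero weight; all-infinite is an error
  inf <- aic_average(fake(c(Inf, 0.03, 0.03)))
  expect_equal(inf$weights[1], 0)
  expect_error(aic_average(fake(rep(Inf, 3))), "infinite")
})

test_that("appending a strictly worse vector leaves the best unchanged", {
  fake <- list(table = data.frame(w_m = c(0.05, 0.1), delta_w_p = 0.05,
                                  p_sd = 0.1, p_r = 1.1,
                                  rmse = c(0.02, 0.04)),
               n_quantile_cells = 15, family = "mln")
  before <- aic_average(fake)
  fake$table <- rbind(fake$table,
                      data.frame(w_m = 0.2, delta_w_p = 0.05, p_sd = 0.1,
                                 p_r = 1.1, rmse = 0.4))
  after <- aic_average(fake)
  expect_identical(which.min(fake$table$rmse), 1L)
  # the new vector's weight bounds the shift of the average
  w_new <- after$weights[3]
  expect_lt(abs(after$average[["w_m"]] - before$average[["w_m"]]),
            w_new * 0.2 + 1e-12)
})

test_that("the fitted pull ratio tracks the generating pull", {
  # maximal pull (p_r = 1.02) lands the averaged p_r in the bottom third of
  # the grid and below the estimate for no-pull data (p_r = 1.2); a noisy
  # generating clock makes the prior shape matter
  stim <- std_stimuli()
  spec <- grid_spec("mln", profile = "reduced",
                    p_r = seq(1.02, 1.2, length.out = 10))
  fit_pr <- function(p_r, seed) {
    pars <- observer_params("mln", w_m = 0.1179, delta_w_p = 0.0474,
                            p_sd = 0.0711, p_r = p_r)
    tr <- simulate_dataset(pars, stim, 1000, seed = seed)
    fit_observer(tr, spec = spec, stimuli = stim, n_sim = 500,
                 seed = seed + 1)$average[["p_r"]]
  }
  rng <- range(spec$params$p_r)
  no_pull <- fit_pr(1.2, 61)
  max_pull <- fit_pr(1.02, 62)
  expect_lte(max_pull, rng[1] + diff(rng) / 3)
  expect_gt(no_pull, max_pull)
})

test_that("fitting rejects multi-participant tables and mismatched stimuli", {
  tr <- rbind(toy_trials(1.4, 1.5), toy_trials(1.4, 1.4))
  tr$participant <- c("a", "b")
  expect_error(fit_observer(tr), "one participant")
  tr2 <- toy_trials(rep(c(1.2, 1.5), 10), rep(1.4, 20))
  expect_error(
    fit_observer(tr2, stimuli = std_stimuli(),
                 spec = grid_spec("mln", w_m = 0.1, delta_w_p = 0.05,
                                  p_sd = 0.1, p_r = 1.1)),
    "must match")
})
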