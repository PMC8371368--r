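## The generative observer: Weber-scaled measurement, posterior-mean readout,
## and noisy reproduction.

#' Observer parameter vector
#'
#' Bundles the parameters of one Bayesian observer model.  The measurement
#' stage draws \eqn{t_m \sim N(t_s, w_m t_s)} (scalar property: SD grows
#' linearly with the timed duration).  The reproduction stage draws
#' \eqn{t_p \sim N(t_e, SD_{rep})}.  For the uniform and gaussian families
#' \eqn{SD_{rep} = w_p t_e}; for the mln family the reproduction Weber
#' fraction is tied to the measurement stage via \eqn{w_p = w_m + \Delta w_p}
#' (additive motor noise), so \eqn{SD_{rep} = (w_m + \Delta w_p) t_e} in the
#' default \code{"scaled"} mode, or \eqn{w_m t_e + \Delta w_p} in the
#' \code{"literal"} mode.
#'
#' @param family One of \code{"uniform"}, \code{"gaussian"}, \code{"mln"}.
#' @param w_m Measurement (clock) Weber fraction; positive.
#' @param w_p Reproduction Weber fraction (uniform/gaussian families only).
#' @param delta_w_p Additive motor-noise parameter (mln family only); >= 0.
#' @param p_sd Prior width in seconds (gaussian: SD of the prior; mln:
#'   linear-space SD of the middle component).
#' @param p_r Pull ratio of the mln component means; >= 1.
#' @param reproduction_noise \code{"scaled"} (default) or \code{"literal"};
#'   mln family only, see above.
#' @return An \code{observer_params} object.
#' @export
observer_params <- function(family = c("mln", "uniform", "gaussian"),
                            w_m, w_p = NULL, delta_w_p = NULL,
                            p_sd = NULL, p_r = NULL,
                            reproduction_noise = c("scaled", "literal")) {
  family <- match.arg(family)
  reproduction_noise <- match.arg(reproduction_noise)
  if (!is.numeric(w_m) || w_m <= 0) stop("`w_m` must be positive", call. = FALSE)
  if (family %in% c("uniform", "gaussian")) {
    if (is.null(w_p) || w_p <= 0)
      stop("`w_p` must be positive for the ", family, " family", call. = FALSE)
    delta_w_p <- NULL
  } else {
    if (is.null(delta_w_p) || delta_w_p < 0)
      stop("`delta_w_p` must be >= 0 for the mln family", call. = FALSE)
    w_p <- NULL
  }
  if (family == "uniform") { p_sd <- NULL; p_r <- NULL }
  if (family == "gaussian") {
    if (is.null(p_sd) || p_sd <= 0)
      stop("`p_sd` must be positive for the gaussian family", call. = FALSE)
    p_r <- NULL
  }
  if (family == "mln") {
    if (is.null(p_sd) || p_sd <= 0)
      stop("`p_sd` must be positive for the mln family", call. = FALSE)
    if (is.null(p_r) || p_r < 1)
      stop("`p_r` must be >= 1 for the mln family", call. = FALSE)
  }
  structure(list(family = family, w_m = w_m, w_p = w_p, delta_w_p = delta_w_p,
                 p_sd = p_sd, p_r = p_r,
                 reproduction_noise = if (family == "mln") reproduction_noise else NULL),
            class = "observer_params")
}

#' @export
print.observer_params <- function(x, ...) {
  vals <- unlist(x[c("w_m", "w_p", "delta_w_p", "p_sd", "p_r")])
  cat(sprintf("Observer parameters (%s family):\n", x$family))
  for (nm in names(vals)) cat(sprintf("  %-9s %g\n", nm, vals[[nm]]))
  if (!is.null(x$reproduction_noise))
    cat("  reproduction noise mode:", x$reproduction_noise, "\n")
  invisible(x)
}

## Effective reproduction SD given the internal estimate t_e.
reproduction_sd <- function(params, t_e) {
  if (params$family == "mln") {
    if (identical(params$reproduction_noise, "literal"))
      params$w_m * t_e + params$delta_w_p
    else
      (params$w_m + params$delta_w_p) * t_e
  } else {
    params$w_p * t_e
  }
}

#' Likelihood of a measurement over the duration grid
#'
#' For an internal measurement \code{t_m}, returns the likelihood
#' \eqn{L(t) = N(t_m; t, w_m t)} evaluated at every grid duration \code{t}.
#' By default this is the proper normal density in \code{t_m} (including the
#' \eqn{1/(w_m t)} normalization); \code{normalized = FALSE} returns the raw
#' standardized Gaussian kernel \eqn{\phi((t - t_m)/(w_m t))} without the
#' Jacobian, for sensitivity checks.  A constant (non-Weber) likelihood SD
#' can be supplied via \code{constant_sd}.
#'
#' @param t_m Internal measurement in seconds; positive scalar.
#' @param grid A \code{duration_grid}.
#' @param w_m Measurement Weber fraction; positive.
#' @param normalized Include the proper density normalization? Default TRUE.
#' @param constant_sd If non-NULL, use this fixed SD instead of \code{w_m t}.
#' @return Numeric vector of likelihood values per grid point (not normalized
#'   over \code{t}).
#' @export
likelihood_over_grid <- function(t_m, grid, w_m, normalized = TRUE,
                                 constant_sd = NULL) {
  if (!is.numeric(t_m) || length(t_m) != 1L || t_m <= 0)
    stop("`t_m` must be a single positive number", call. = FALSE)
  if (is.null(constant_sd) && w_m <= 0)
    stop("`w_m` must be positive", call. = FALSE)
  t <- grid$points
  sd <- if (is.null(constant_sd)) w_m * t else rep(constant_sd, length(t))
  if (normalized) stats::dnorm(t_m, mean = t, sd = sd)
  else exp(-0.5 * ((t - t_m) / sd)^2)
}

#' Posterior-mean (BLS) estimate of a duration
#'
#' Maps an internal measurement to the internal estimate by integrating the
#' Weber-scaled likelihood against the prior with the rectangle rule:
#' \deqn{t_e = \frac{\sum_t t \, \pi(t) L(t)}{\sum_t \pi(t) L(t)}.}
#' Vectorized over \code{t_m}.
#'
#' @param t_m Internal measurement(s) in seconds; positive.
#' @param prior A \code{prior_density}.
#' @param w_m Measurement Weber fraction; positive.
#' @param normalized,constant_sd Passed to \code{\link{likelihood_over_grid}}.
#' @return Estimate(s) \code{t_e} in seconds, bounded by the grid.
#' @export
posterior_mean <- function(t_m, prior, w_m, normalized = TRUE,
                           constant_sd = NULL) {
  if (any(t_m <= 0)) stop("`t_m` must be positive", call. = FALSE)
  t <- prior$grid$points
  sd <- if (is.null(constant_sd)) w_m * t else rep(constant_sd, length(t))
  ## log posterior weight, stabilized by a per-measurement max shift so that
  ## narrow priors far from extreme measurements do not underflow
  z2 <- sweep(outer(t_m, t, "-"), 2, sd, "/")^2
  logL <- -0.5 * z2
  if (normalized)
    logL <- sweep(logL, 2, log(sd) + 0.5 * log(2 * pi), "-")
  logW <- sweep(logL, 2, log(prior$density), "+")
  mx <- apply(logW, 1, max)
  if (any(!is.finite(mx)))
    stop("degenerate posterior: prior and likelihood have no common support",
         call. = FALSE)
  W <- exp(logW - mx)
  as.numeric((W %*% t) / rowSums(W))
}

## Precompute t_e on a lattice of t_m values for fast interpolation during
## simulation.  The lattice spans beyond the grid so that extreme measurement
## draws interpolate rather than extrapolate.
posterior_mean_table <- function(prior, w_m, n_lattice = 512L,
                                 normalized = TRUE) {
  g <- prior$grid
  lo <- g$lower * 0.5
  hi <- g$upper * 1.5
  tm <- seq(lo, hi, length.out = n_lattice)
  te <- posterior_mean(tm, prior, w_m, normalized = normalized)
  list(t_m = tm, t_e = te)
}

interp_te <- function(table, t_m) {
  stats::approx(table$t_m, table$t_e, xout = t_m, rule = 2)$y
}

#' Simulate one reproduction trial
#'
#' Draws a measurement \eqn{t_m \sim N(t_s, w_m t_s)}, computes the
#' posterior-mean estimate \eqn{t_e}, and draws the reproduction
#' \eqn{t_p \sim N(t_e, SD_{rep})}.  Non-positive draws of \code{t_m} or
#' \code{t_p} are rejected and redrawn (durations are positive).
#'
#' @param t_s Presented duration in seconds; positive.
#' @param params An \code{observer_params}.
#' @param prior A \code{prior_density} matching \code{params$family}.
#' @return A single reproduced duration \code{t_p} in seconds.
#' @export
simulate_trial <- function(t_s, params, prior) {
  if (t_s <= 0) stop("`t_s` must be positive", call. = FALSE)
  repeat {
    t_m <- stats::rnorm(1L, t_s, params$w_m * t_s)
    if (t_m > 0) break
  }
  t_e <- posterior_mean(t_m, prior, params$w_m)
  sd_rep <- reproduction_sd(params, t_e)
  repeat {
    t_p <- stats::rnorm(1L, t_e, sd_rep)
    if (t_p > 0) break
  }
  t_p
}

#' Simulate a full trial table for one observer
#'
#' Simulates \code{n_per_duration} reproductions of every stimulus duration,
#' using a posterior-mean lookup table for speed (dense lattice of
#' measurements, linear interpolation).
#'
#' @param params An \code{observer_params}.
#' @param stimuli A \code{stimulus_set}.
#' @param n_per_duration Trials per stimulus duration; >= 1.
#' @param seed Integer seed; the table is reproducible given the seed.
#' @param grid Optional \code{duration_grid}; default
#'   \code{make_grid(stimuli)}.
#' @param participant,group Labels stored in the table.
#' @return A data frame with columns \code{participant}, \code{group},
#'   \code{t_s}, \code{t_p}.
#' @examples
#' stim <- geometric_durations(1.4, 1.2, -1:1)
#' pars <- observer_params("mln", w_m = 0.1, delta_w_p = 0.05,
#'                         p_sd = 0.1, p_r = 1.1)
#' head(simulate_dataset(pars, stim, 10, seed = 1))
#' @export
simulate_dataset <- function(params, stimuli, n_per_duration, seed,
                             grid = NULL, participant = "p1", group = "none") {
  if (n_per_duration < 1) stop("`n_per_duration` must be >= 1", call. = FALSE)
  if (is.null(grid)) grid <- make_grid(stimuli)
  prior <- default_prior(params, stimuli, grid)
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_seed(old), add = TRUE)
  set.seed(as.integer(seed))
  tab <- posterior_mean_table(prior, params$w_m)
  ts_all <- rep(stimuli$durations, each = n_per_duration)
  n <- length(ts_all)
  t_m <- stats::rnorm(n, ts_all, params$w_m * ts_all)
  t_m <- redraw_nonpositive(t_m, ts_all, params$w_m * ts_all)
  t_e <- interp_te(tab, t_m)
  sd_rep <- reproduction_sd(params, t_e)
  t_p <- stats::rnorm(n, t_e, sd_rep)
  t_p <- redraw_nonpositive(t_p, t_e, sd_rep)
  data.frame(participant = participant, group = group, t_s = ts_all, t_p = t_p,
             stringsAsFactors = FALSE)
}

## Rejection-resample entries that fell at or below zero.
redraw_nonpositive <- function(x, mean, sd, max_iter = 100L) {
  bad <- which(x <= 0)
  it <- 0L
  while (length(bad) && it < max_iter) {
    x[bad] <- stats::rnorm(length(bad), mean[bad], sd[bad])
    bad <- bad[x[bad] <= 0]
    it <- it + 1L
  }
  if (length(bad)) x[bad] <- .Machine$double.eps
  x
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

## Default prior implied by a parameter vector and stimulus set.
default_prior <- function(params, stimuli, grid) {
  d <- stimuli$durations
  switch(params$family,
    uniform = prior_uniform(grid, min(d), max(d)),
    gaussian = prior_gaussian(grid, stats::median(d), params$p_sd),
    mln = {
      scale <- if (!is.null(stimuli$scale)) stimuli$scale else stats::median(d)
      terms <- if (!is.null(stimuli$terms)) stimuli$terms
               else seq_along(d) - (length(d) + 1L) %/% 2L
      prior_mln(grid, params$p_sd, params$p_r, scale = scale, terms = terms)
    })
}

#' Central-tendency bias curve
#'
#' Expected reproduction bias \eqn{E[t_p] - t_s} over a dense sweep of
#' presented durations.  With \code{n_rep = 0} (default) the noiseless
#' shortcut \eqn{t_m = t_s} is used, so the curve is the deterministic
#' posterior-mean bias; with \code{n_rep > 0} the bias is estimated by Monte
#' Carlo over full simulated trials.
#'
#' @param params An \code{observer_params}.
#' @param prior A \code{prior_density}.
#' @param t_s_dense Presented durations (seconds), inside the prior grid.
#' @param n_rep Monte-Carlo repetitions per duration; 0 for noiseless.
#' @param seed Seed used when \code{n_rep > 0}.
#' @return Data frame with columns \code{t_s} and \code{bias} (seconds).
#' @export
bias_curve <- function(params, prior, t_s_dense, n_rep = 0L, seed = 1L) {
  g <- prior$grid
  if (any(t_s_dense < g$lower) || any(t_s_dense > g$upper))
    stop("`t_s_dense` must lie inside the prior grid", call. = FALSE)
  if (n_rep == 0L) {
    t_e <- posterior_mean(t_s_dense, prior, params$w_m)
    return(data.frame(t_s = t_s_dense, bias = t_e - t_s_dense))
  }
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_seed(old), add = TRUE)
  set.seed(as.integer(seed))
  tab <- posterior_mean_table(prior, params$w_m)
  bias <- vapply(t_s_dense, function(ts) {
    t_m <- stats::rnorm(n_rep, ts, params$w_m * ts)
    t_m <- redraw_nonpositive(t_m, rep(ts, n_rep), rep(params$w_m * ts, n_rep))
    t_e <- interp_te(tab, t_m)
    sd_rep <- reproduction_sd(params, t_e)
    t_p <- stats::rnorm(n_rep, t_e, sd_rep)
    t_p <- redraw_nonpositive(t_p, t_e, sd_rep)
    mean(t_p) - ts
  }, numeric(1))
  data.frame(t_s = t_s_dense, bias = bias)
}
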