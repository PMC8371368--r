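## Recovery of a mixture-lognormal prior from a target density curve by
## direct (Nelder-Mead) search.

#' Target prior-density curve
#'
#' A nonnegative density sampled on a duration grid, to be approximated by a
#' lognormal mixture.  Durations are in seconds.
#'
#' @param durations Ascending durations in seconds.
#' @param density Nonnegative density values, one per duration.
#' @param window Fit window in seconds; default \code{c(0.2, 1.6)}
#'   (200--1600 ms).
#' @return A \code{target_density} object.
#' @export
target_density <- function(durations, density, window = c(0.2, 1.6)) {
  if (length(durations) != length(density) || length(durations) < 2L)
    stop("`durations` and `density` must be equal-length vectors (>= 2)",
         call. = FALSE)
  if (is.unsorted(durations, strictly = TRUE))
    stop("`durations` must be strictly ascending", call. = FALSE)
  if (any(density < 0)) stop("`density` must be nonnegative", call. = FALSE)
  if (window[1] < min(durations) || window[2] > max(durations))
    stop("fit window must lie within the duration grid of the target",
         call. = FALSE)
  structure(list(durations = as.numeric(durations),
                 density = as.numeric(density),
                 window = as.numeric(window)),
            class = "target_density")
}

#' Fit a lognormal mixture to a target density curve
#'
#' Approximates a target prior-density curve by a mixture of moment-matched
#' lognormal components (one per presented stimulus duration, 6 by default)
#' by minimizing the summed squared difference (SSD) between the target and
#' the mixture density over the fit window, using the Nelder-Mead simplex.
#' The target is linearly interpolated onto a 1-ms lattice over the window
#' before the SSD is computed, so the objective does not depend on the target
#' file's native resolution.
#'
#' Three modes control which quantities are free:
#' \describe{
#'   \item{\code{"free"}}{component locations, weights, and one shared CV
#'     (SD/mean ratio, scalar scaling) are all estimated;}
#'   \item{\code{"fixed_weights"}}{weights pinned to 1/K; locations and the
#'     shared CV estimated;}
#'   \item{\code{"fixed_locations"}}{locations pinned to the presented
#'     stimulus durations; weights and the shared CV estimated.}
#' }
#' Weights are constrained to \code{weight_bounds} (default 1/15 to 10/15)
#' through a bounded-logistic reparametrization with renormalization, backed
#' by a steep penalty so that renormalized weights stay inside the bounds.
#'
#' Each restart runs from a randomized feasible start; the first restart
#' always uses the canonical start (equal weights, components located at the
#' stimuli), so the search can never return a fit worse than that start.
#'
#' @param target A \code{target_density} (see \code{\link{target_density}}).
#' @param stimuli A \code{stimulus_set} whose durations locate the components.
#' @param mode \code{"free"}, \code{"fixed_weights"} or
#'   \code{"fixed_locations"}.
#' @param n_restarts Number of simplex restarts (default 10).
#' @param seed Integer seed for the randomized starts.
#' @param weight_bounds Lower and upper weight bound.
#' @param maxit,reltol Nelder-Mead iteration cap and relative tolerance.
#' @return A \code{mixture_fit}: restarts sorted by SSD, with \code{$best}
#'   (component data frame: mean, sd, weight), \code{$ssd}, \code{$mode}.
#' @export
fit_mixture <- function(target, stimuli,
                        mode = c("free", "fixed_weights", "fixed_locations"),
                        n_restarts = 10L, seed = 1L,
                        weight_bounds = c(1 / 15, 10 / 15),
                        maxit = 5000L, reltol = 1e-8) {
  mode <- match.arg(mode)
  if (!inherits(target, "target_density"))
    stop("`target` must be a target_density", call. = FALSE)
  locs0 <- stimuli$durations
  k <- length(locs0)
  lo <- weight_bounds[1]; hi <- weight_bounds[2]
  if (k * lo > 1 || k * hi < 1)
    stop(sprintf("infeasible weight bounds: %d weights in [%.3g, %.3g] cannot sum to 1",
                 k, lo, hi), call. = FALSE)
  if (n_restarts < 1L) stop("`n_restarts` must be >= 1", call. = FALSE)

  win <- target$window
  lattice <- seq(win[1], win[2], by = 0.001)
  tgt <- stats::approx(target$durations, target$density, xout = lattice,
                       rule = 2)$y

  weights_from_theta <- function(theta) {
    b <- lo + (hi - lo) * stats::plogis(theta)
    b / sum(b)
  }
  unpack <- function(theta) {
    i <- 0L
    if (mode %in% c("free", "fixed_weights")) {
      means <- exp(theta[i + seq_len(k)]); i <- i + k
    } else means <- locs0
    if (mode %in% c("free", "fixed_locations")) {
      w <- weights_from_theta(theta[i + seq_len(k)]); i <- i + k
    } else w <- rep(1 / k, k)
    cv <- exp(theta[i + 1L])
    list(means = means, weights = w, cv = cv)
  }
  objective <- function(theta) {
    p <- unpack(theta)
    if (any(!is.finite(p$means)) || any(p$means <= 0) || !is.finite(p$cv))
      return(1e10)
    dens <- mixture_lognormal_density(lattice, p$means, p$cv * p$means,
                                      p$weights)
    ssd <- sum((tgt - dens)^2)
    viol <- sum(pmax(0, lo - p$weights)^2 + pmax(0, p$weights - hi)^2)
    ssd + 1e8 * viol
  }
  theta_canonical <- {
    th <- numeric(0)
    if (mode %in% c("free", "fixed_weights")) th <- c(th, log(locs0))
    if (mode %in% c("free", "fixed_locations")) th <- c(th, rep(0, k))
    c(th, log(0.15))
  }

  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_seed(old), add = TRUE)
  set.seed(as.integer(seed))
  restarts <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    theta0 <- if (r == 1L) theta_canonical else {
      th <- numeric(0)
      if (mode %in% c("free", "fixed_weights"))
        th <- c(th, log(locs0 * stats::runif(k, 0.8, 1.2)))
      if (mode %in% c("free", "fixed_locations"))
        th <- c(th, stats::rnorm(k))
      c(th, log(stats::runif(1, 0.05, 0.4)))
    }
    ## chained simplex: restart from the incumbent until no further
    ## improvement (Nelder-Mead's reltol stop triggers early on ridges)
    opt <- stats::optim(theta0, objective, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = reltol))
    for (pass in 1:4) {
      opt2 <- stats::optim(opt$par, objective, method = "Nelder-Mead",
                           control = list(maxit = maxit, reltol = reltol))
      if (opt2$value >= opt$value * (1 - 1e-6)) { opt <- opt2; break }
      opt <- opt2
    }
    p <- unpack(opt$par)
    ord <- order(p$means)
    comps <- data.frame(mean = p$means[ord], sd = (p$cv * p$means)[ord],
                        weight = p$weights[ord])
    dens <- mixture_lognormal_density(lattice, comps$mean, comps$sd,
                                      comps$weight)
    restarts[[r]] <- list(components = comps, ssd = sum((tgt - dens)^2),
                          cv = p$cv, convergence = opt$convergence,
                          restart = r)
  }
  restarts <- restarts[order(vapply(restarts, `[[`, numeric(1), "ssd"))]
  best <- restarts[[1L]]
  structure(list(restarts = restarts, best = best$components,
                 ssd = best$ssd, cv = best$cv, mode = mode, seed = seed,
                 window = win, stimuli = stimuli,
                 weight_bounds = weight_bounds),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("Lognormal mixture fit (mode %s, %d restarts, seed %d)\n",
              x$mode, length(x$restarts), x$seed))
  cat(sprintf("  fit window %g-%g s; best SSD %.4g\n",
              x$window[1], x$window[2], x$ssd))
  cat("  components (linear-space moments):\n")
  print(x$best, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.mixture_fit <- function(object, ...) object$best

#' Density of a fitted (or specified) lognormal mixture
#'
#' Renders a \code{mixture_fit} (or a raw component data frame) as a density.
#' When \code{grid} is a \code{duration_grid} the density is normalized on
#' the grid by the rectangle rule (identical to
#' \code{\link{prior_mln_free}}); when \code{grid} is a plain numeric vector
#' the raw (infinite-support) mixture density is returned.
#'
#' @param fit A \code{mixture_fit} or a data frame with columns \code{mean},
#'   \code{sd}, \code{weight}.
#' @param grid A \code{duration_grid} or numeric vector of durations.
#' @return Numeric density values.
#' @export
mixture_density <- function(fit, grid) {
  comps <- if (inherits(fit, "mixture_fit")) fit$best else fit
  if (inherits(grid, "duration_grid")) {
    p <- prior_mln_free(grid, comps$mean, comps$sd,
                        comps$weight / sum(comps$weight))
    p$density
  } else {
    mixture_lognormal_density(grid, comps$mean, comps$sd, comps$weight)
  }
}

#' @export
plot.mixture_fit <- function(x, target = NULL, ...) {
  tt <- seq(x$window[1], x$window[2], by = 0.001)
  dens <- mixture_density(x, tt)
  graphics::plot(tt, dens, type = "l", xlab = "duration (s)",
                 ylab = "density (1/s)",
                 main = sprintf("mixture fit (%s)", x$mode), ...)
  if (!is.null(target))
    graphics::lines(target$durations, target$density, lty = 2, col = "grey40")
  graphics::segments(x$best$mean, 0, x$best$mean, -0.1 * max(dens) * x$best$weight * length(x$best$weight))
  invisible(x)
}
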