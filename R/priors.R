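## Prior families over durations, all represented as rectangle-rule normalized
## densities on a shared duration_grid.

new_prior_density <- function(grid, density, family, components = NULL) {
  density[density < 0] <- 0
  total <- sum(density) * grid$step
  if (total <= 0)
    stop("prior density is zero everywhere on the grid", call. = FALSE)
  structure(list(grid = grid, density = density / total, family = family,
                 components = components),
            class = "prior_density")
}

#' Uniform prior over the stimulus range
#'
#' Constant density on \code{[dmin, dmax]} and zero elsewhere, normalized on
#' the integration grid.  The edges snap to the nearest grid points so that
#' all prior families share one grid.
#'
#' @param grid A \code{duration_grid}.
#' @param dmin,dmax Support bounds in seconds, \code{dmin < dmax}; must lie
#'   inside the grid.
#' @return A \code{prior_density}.
#' @export
prior_uniform <- function(grid, dmin, dmax) {
  if (dmax <= dmin) stop("`dmax` must exceed `dmin`", call. = FALSE)
  if (dmin < grid$lower - grid$step / 2 || dmax > grid$upper + grid$step / 2)
    stop("uniform support must lie inside the grid", call. = FALSE)
  t <- grid$points
  inside <- t >= dmin - grid$step / 2 & t <= dmax + grid$step / 2
  new_prior_density(grid, as.numeric(inside), "uniform")
}

#' Truncated Gaussian prior
#'
#' Normal density with mean \code{center} and standard deviation \code{p_sd},
#' evaluated on the (strictly positive) grid and renormalized.  Because the
#' grid never reaches zero, the renormalization implements truncation of the
#' prior below zero.
#'
#' @param grid A \code{duration_grid}.
#' @param center Prior mean in seconds (conventionally the median stimulus
#'   duration, e.g. 1.4 s).
#' @param p_sd Prior standard deviation in seconds; positive.
#' @return A \code{prior_density}.
#' @export
prior_gaussian <- function(grid, center, p_sd) {
  if (p_sd <= 0) stop("`p_sd` must be positive", call. = FALSE)
  if (center <= 0) stop("`center` must be positive", call. = FALSE)
  new_prior_density(grid, stats::dnorm(grid$points, center, p_sd), "gaussian")
}

## Moment-matched lognormal: linear-space mean m and SD s.
## sigma^2 = log(1 + s^2/m^2), mu = log(m) - sigma^2/2.
lnorm_params <- function(m, s) {
  sigma2 <- log(1 + (s / m)^2)
  list(meanlog = log(m) - sigma2 / 2, sdlog = sqrt(sigma2))
}

mixture_lognormal_density <- function(t, means, sds, weights) {
  dens <- numeric(length(t))
  for (i in seq_along(means)) {
    p <- lnorm_params(means[i], sds[i])
    dens <- dens + weights[i] * stats::dlnorm(t, p$meanlog, p$sdlog)
  }
  dens
}

#' Mixture-lognormal (MLN) prior on a geometric lattice
#'
#' The prior is an equal-weight mixture of K lognormal components whose
#' linear-space means follow the geometric series
#' \eqn{m_i = \mathrm{scale} \times p_r^{k_i}} and whose linear-space standard
#' deviations scale with the means (scalar property):
#' \eqn{s_i = p_{sd} \, m_i / \mathrm{scale}}, so that \code{p_sd} is the SD
#' of the component at the middle (scale) duration.  Components are
#' parametrized by moment matching, i.e. the stated mean and SD are the
#' linear-space moments of each lognormal.
#'
#' The pull ratio \code{p_r} controls the central tendency encoded in the
#' prior: \code{p_r} equal to the stimulus ratio places the components at the
#' presented durations (no pull), while \code{p_r = 1} collapses all
#' components onto the scale duration (maximal pull; the mixture degenerates
#' to a single lognormal).
#'
#' @param grid A \code{duration_grid}.
#' @param p_sd Linear-space SD (seconds) of the middle component; positive.
#' @param p_r Common ratio of the component means; must be >= 1.
#' @param scale Scale factor (seconds) of the geometric series; default 1.4.
#' @param terms Integer exponents; default \code{-1:1} (three components).
#' @return A \code{prior_density}; \code{$components} is a data frame with
#'   columns \code{mean}, \code{sd}, \code{weight}.
#' @examples
#' g <- make_grid(stimulus_set(c(1.17, 1.4, 1.68)))
#' prior_mln(g, p_sd = 0.1, p_r = 1.05)
#' @export
prior_mln <- function(grid, p_sd, p_r, scale = 1.4, terms = -1:1) {
  if (p_sd <= 0) stop("`p_sd` must be positive", call. = FALSE)
  if (p_r < 1) stop("`p_r` must be >= 1 (1 is total collapse to the centre)",
                    call. = FALSE)
  if (scale <= 0) stop("`scale` must be positive", call. = FALSE)
  terms <- sort(as.integer(terms))
  means <- scale * p_r^terms
  sds <- p_sd * means / scale
  k <- length(means)
  weights <- rep(1 / k, k)
  comps <- data.frame(mean = means, sd = sds, weight = weights)
  new_prior_density(grid, mixture_lognormal_density(grid$points, means, sds, weights),
                    "mln", components = comps)
}

#' Free-form lognormal mixture prior
#'
#' An arbitrary-location, arbitrary-weight mixture of moment-matched lognormal
#' components, normalized on the grid.  Used for simulations that approximate
#' a uniform prior with many equidistant narrow components, or a unimodal
#' prior with wide components.
#'
#' @param grid A \code{duration_grid}.
#' @param means Linear-space component means (seconds), inside the grid.
#' @param sds Linear-space component SDs (seconds); positive.
#' @param weights Component weights; must sum to 1 within 1e-9.  Default
#'   equal weights.
#' @return A \code{prior_density} of family \code{"mln"}.
#' @export
prior_mln_free <- function(grid, means, sds, weights = NULL) {
  k <- length(means)
  if (length(sds) == 1L) sds <- rep(sds, k)
  if (is.null(weights)) weights <- rep(1 / k, k)
  if (length(sds) != k || length(weights) != k)
    stop("`means`, `sds` and `weights` must have equal length", call. = FALSE)
  if (any(means <= 0) || any(sds <= 0))
    stop("component means and sds must be positive", call. = FALSE)
  if (any(means < grid$lower) || any(means > grid$upper))
    stop("all component means must lie inside the grid", call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-9)
    stop("`weights` must sum to 1 within 1e-9", call. = FALSE)
  comps <- data.frame(mean = means, sd = sds, weight = weights)
  new_prior_density(grid, mixture_lognormal_density(grid$points, means, sds, weights),
                    "mln", components = comps)
}

#' Moments of a prior density on its grid
#'
#' Rectangle-rule mean and standard deviation of a \code{prior_density}.
#'
#' @param prior A \code{prior_density}.
#' @return Named numeric vector with \code{mean} and \code{sd} (seconds).
#' @export
prior_moments <- function(prior) {
  t <- prior$grid$points
  w <- prior$density * prior$grid$step
  m <- sum(t * w)
  v <- sum((t - m)^2 * w)
  c(mean = m, sd = sqrt(v))
}

#' @export
print.prior_density <- function(x, ...) {
  cat(sprintf("Prior density (%s) on [%.4g, %.4g] s, %d grid points\n",
              x$family, x$grid$lower, x$grid$upper, x$grid$n_points))
  if (!is.null(x$components)) {
    cat(sprintf("  %d lognormal component(s); linear-space means: %s\n",
                nrow(x$components),
                paste(signif(x$components$mean, 4), collapse = ", ")))
  }
  m <- prior_moments(x)
  cat(sprintf("  grid mean %.4g s, grid sd %.4g s\n", m["mean"], m["sd"]))
  invisible(x)
}

#' @export
plot.prior_density <- function(x, ...) {
  graphics::plot(x$grid$points, x$density, type = "l",
                 xlab = "duration (s)", ylab = "density (1/s)",
                 main = sprintf("%s prior", x$family), ...)
  invisible(x)
}

#' @export
as.data.frame.prior_density <- function(x, ...) {
  data.frame(duration_s = x$grid$points, density = x$density)
}
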