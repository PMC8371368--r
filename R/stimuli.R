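#' Construct a stimulus set from a geometric series
#'
#' Presented durations in multi-duration reproduction tasks are often laid out
#' as a geometric series \eqn{d_i = a \, r^{k_i}} with scale factor \eqn{a}
#' (seconds), common ratio \eqn{r} and integer exponents \eqn{k_i}.  The
#' canonical three-duration set used throughout this package is
#' \code{geometric_durations(1.4, 1.2, -1:1)}, i.e. 1.167, 1.4 and 1.68 s.
#'
#' @param scale Geometric scale factor in seconds; must be positive.
#' @param ratio Common ratio (dimensionless); must be positive.
#' @param terms Integer exponents of the series; non-empty.
#' @return A \code{stimulus_set} object: a list with \code{durations} (sorted
#'   ascending, seconds), \code{scale}, \code{ratio} and \code{terms}.
#' @examples
#' geometric_durations(1.4, 1.2, -1:1)
#' @export
geometric_durations <- function(scale, ratio, terms) {
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) || scale <= 0)
    stop("`scale` must be a single positive number", call. = FALSE)
  if (!is.numeric(ratio) || length(ratio) != 1L || !is.finite(ratio) || ratio <= 0)
    stop("`ratio` must be a single positive number", call. = FALSE)
  if (length(terms) == 0L || any(terms != round(terms)))
    stop("`terms` must be a non-empty vector of integers", call. = FALSE)
  terms <- sort(as.integer(terms))
  durations <- scale * ratio^terms
  structure(list(durations = sort(durations), scale = scale, ratio = ratio,
                 terms = terms),
            class = "stimulus_set")
}

#' Construct a stimulus set from explicit durations
#'
#' @param durations Strictly positive durations in seconds; sorted ascending
#'   internally.
#' @return A \code{stimulus_set} object (with \code{scale}, \code{ratio} and
#'   \code{terms} set to \code{NULL}).
#' @export
stimulus_set <- function(durations) {
  if (length(durations) == 0L || !is.numeric(durations) ||
      any(!is.finite(durations)) || any(durations <= 0))
    stop("`durations` must be positive finite numbers", call. = FALSE)
  structure(list(durations = sort(as.numeric(durations)), scale = NULL,
                 ratio = NULL, terms = NULL),
            class = "stimulus_set")
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat("Stimulus set:", paste(signif(x$durations, 4), collapse = ", "), "s\n")
  if (!is.null(x$scale))
    cat(sprintf("  geometric series: scale %g s, ratio %g, terms %s\n",
                x$scale, x$ratio, paste(x$terms, collapse = "/")))
  invisible(x)
}

#' Build the numerical-integration grid for a stimulus set
#'
#' The posterior over durations is integrated by the rectangle (Riemann sum)
#' rule on an equidistant grid whose support extends beyond the stimulus range
#' so that the posterior density is negligible at the edges.  The default
#' factors 0.5 and 1.5 applied to the shortest and longest stimulus reproduce
#' the standard 0.585--2.52 s support for the 1.17/1.4/1.68 s set.
#'
#' @param stimuli A \code{stimulus_set}.
#' @param lower_factor,upper_factor Multipliers of the minimum and maximum
#'   stimulus duration giving the grid bounds; \code{0 < lower_factor <=
#'   upper_factor}.
#' @param n_points Number of equidistant grid points (>= 2). The default of
#'   1024 keeps the rectangle-rule error far below the fitting tolerance at
#'   second-scale durations.
#' @return A \code{duration_grid}: list with \code{lower}, \code{upper},
#'   \code{n_points}, \code{step} and the grid \code{points} (seconds).
#' @examples
#' make_grid(stimulus_set(c(1.17, 1.4, 1.68)))
#' @export
make_grid <- function(stimuli, lower_factor = 0.5, upper_factor = 1.5,
                      n_points = 1024L) {
  if (!inherits(stimuli, "stimulus_set"))
    stop("`stimuli` must be a stimulus_set", call. = FALSE)
  if (length(stimuli$durations) == 0L)
    stop("empty stimulus set", call. = FALSE)
  if (lower_factor <= 0 || upper_factor < lower_factor)
    stop("need 0 < lower_factor <= upper_factor", call. = FALSE)
  if (n_points < 2L)
    stop("`n_points` must be at least 2", call. = FALSE)
  lower <- lower_factor * min(stimuli$durations)
  upper <- upper_factor * max(stimuli$durations)
  if (upper <= lower)
    stop("degenerate grid: upper bound must exceed lower bound", call. = FALSE)
  duration_grid(lower, upper, n_points)
}

#' Construct a duration grid directly from bounds
#'
#' @param lower,upper Grid bounds in seconds, \code{0 < lower < upper}.
#' @param n_points Number of equidistant points.
#' @return A \code{duration_grid} object.
#' @export
duration_grid <- function(lower, upper, n_points = 1024L) {
  if (lower <= 0 || upper <= lower)
    stop("need 0 < lower < upper", call. = FALSE)
  n_points <- as.integer(n_points)
  if (n_points < 2L) stop("`n_points` must be at least 2", call. = FALSE)
  step <- (upper - lower) / (n_points - 1L)
  structure(list(lower = lower, upper = upper, n_points = n_points,
                 step = step, points = seq(lower, upper, length.out = n_points)),
            class = "duration_grid")
}

#' @export
print.duration_grid <- function(x, ...) {
  cat(sprintf("Duration grid: %.4g to %.4g s, %d points (step %.3g s)\n",
              x$lower, x$upper, x$n_points, x$step))
  invisible(x)
}
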