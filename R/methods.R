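## S3 methods for fitted observer models.

#' @export
print.observer_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Bayesian observer fit (%s prior family)\n", x$family))
  cat(sprintf("  grid vectors: %d, simulated trials per duration: %d, seed %d\n",
              nrow(x$table), x$n_sim, x$seed))
  cat(sprintf("  best quantile RMSE: %.*g s\n", digits, x$rmse))
  cat("  best vector:     ",
      paste(sprintf("%s = %.*g", names(x$best), digits, x$best),
            collapse = ", "), "\n")
  cat("  AIC-averaged:    ",
      paste(sprintf("%s = %.*g", names(x$average), digits, x$average),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.observer_fit <- function(object, n_top = 5L, ...) {
  tab <- object$table
  ord <- order(tab$rmse)
  top <- tab[ord[seq_len(min(n_top, nrow(tab)))], , drop = FALSE]
  w <- object$aic_weights
  structure(list(fit = object, top = top,
                 ess = 1 / sum(w^2),
                 weight_best = w[object$best_index]),
            class = "summary.observer_fit")
}

#' @export
print.summary.observer_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  Akaike-weight of best vector: %.3f; effective number of vectors: %.1f\n",
              x$weight_best, x$ess))
  cat("\nBest-fitting grid vectors:\n")
  print(x$top, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Extract fitted observer parameters
#'
#' @param object An \code{observer_fit}.
#' @param type \code{"average"} (AIC-weighted model average, default) or
#'   \code{"best"} (minimum-RMSE grid vector).
#' @param ... Unused.
#' @return Named numeric vector of parameter estimates.
#' @export
coef.observer_fit <- function(object, type = c("average", "best"), ...) {
  type <- match.arg(type)
  if (type == "average") object$average else object$best
}

## observer_params built from a fitted vector.
fitted_params <- function(object, type = "best") {
  v <- as.list(coef(object, type = type))
  do.call(vector_params, list(object$family, as.data.frame(v)))
}

#' Predicted reproduction quantiles of a fitted observer
#'
#' Simulates the fitted observer and returns the model-predicted quantile
#' profile over the fitted stimulus durations.
#'
#' @param object An \code{observer_fit}.
#' @param type Parameter vector to use: \code{"best"} (default) or
#'   \code{"average"}.
#' @param n_sim Simulated trials per duration; default the fit's setting.
#' @param seed Seed; default the fit's seed.
#' @param ... Unused.
#' @return A \code{quantile_profile}.
#' @export
predict.observer_fit <- function(object, type = c("best", "average"),
                                 n_sim = NULL, seed = NULL, ...) {
  type <- match.arg(type)
  if (is.null(n_sim)) n_sim <- object$n_sim
  if (is.null(seed)) seed <- object$seed
  pars <- fitted_params(object, type)
  grid <- make_grid(object$stimuli, n_points = object$n_grid_points)
  sim <- simulate_dataset(pars, object$stimuli, n_sim, seed = seed,
                          grid = grid)
  quantile_profile(sim, probs = object$probs)
}

#' Quantile residuals of a fitted observer
#'
#' Observed minus predicted reproduction quantiles, per duration and
#' probability.
#'
#' @param object An \code{observer_fit}.
#' @param ... Passed to \code{\link{predict.observer_fit}}.
#' @return Numeric matrix (durations by probabilities) in seconds.
#' @export
residuals.observer_fit <- function(object, ...) {
  pred <- predict(object, ...)
  unclass(object$observed) - unclass(pred)
}

#' Simulate trial tables from a fitted observer
#'
#' @param object An \code{observer_fit}.
#' @param nsim Number of tables to simulate.
#' @param seed Base seed; table \code{i} uses \code{seed + i - 1}.
#' @param n_per_duration Trials per duration; default the fit's \code{n_sim}.
#' @param type Parameter vector to use (\code{"best"} or \code{"average"}).
#' @param ... Unused.
#' @return A list of trial data frames (a single data frame if
#'   \code{nsim = 1}).
#' @export
simulate.observer_fit <- function(object, nsim = 1, seed = NULL,
                                  n_per_duration = NULL,
                                  type = c("best", "average"), ...) {
  type <- match.arg(type)
  if (is.null(seed)) seed <- object$seed
  if (is.null(n_per_duration)) n_per_duration <- object$n_sim
  pars <- fitted_params(object, type)
  grid <- make_grid(object$stimuli, n_points = object$n_grid_points)
  out <- lapply(seq_len(nsim), function(i)
    simulate_dataset(pars, object$stimuli, n_per_duration,
                     seed = seed + i - 1, grid = grid))
  if (nsim == 1) out[[1]] else out
}

#' Plot observed against predicted reproduction quantiles
#'
#' One line per quantile probability: observed (solid, points) and model
#' predicted (dashed) reproduction quantiles across the presented durations.
#'
#' @param x An \code{observer_fit}.
#' @param type Parameter vector to use for predictions.
#' @param ... Further graphical arguments passed to \code{matplot}.
#' @export
plot.observer_fit <- function(x, type = c("best", "average"), ...) {
  type <- match.arg(type)
  pred <- predict(x, type = type)
  durs <- attr(x$observed, "durations")
  obs <- unclass(x$observed)
  prd <- unclass(pred)
  ylim <- range(obs, prd)
  graphics::matplot(durs, obs, type = "b", pch = 16, lty = 1,
                    col = seq_len(ncol(obs)),
                    xlab = expression(t[s] ~ "(s)"),
                    ylab = expression(t[p] ~ "quantile (s)"),
                    ylim = ylim,
                    main = sprintf("%s observer fit", x$family), ...)
  graphics::matlines(durs, prd, lty = 2, col = seq_len(ncol(prd)))
  graphics::abline(0, 1, col = "grey70")
  graphics::legend("topleft", bty = "n", lty = c(1, 2), pch = c(16, NA),
                   legend = c("observed", "predicted"))
  invisible(x)
}
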