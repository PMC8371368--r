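## Grid-search estimation: mean-centering, quantile profiles, quantile RMSE,
## exhaustive search over parameter grids, and AIC-weighted model averaging.

#' Mean-center reproductions
#'
#' Removes structural over-/under-reproduction before fitting central
#' tendency: from each reproduction the grand mean reproduction is subtracted
#' and the grand mean presented duration is added, so that the mean of the
#' centered \code{t_p} equals the mean \code{t_s} exactly.
#'
#' @param trials Trial data frame with columns \code{t_s} and \code{t_p}
#'   (one participant).
#' @return The trial data frame with centered \code{t_p}.
#' @export
center_reproductions <- function(trials) {
  check_trials(trials)
  trials$t_p <- trials$t_p - mean(trials$t_p) + mean(trials$t_s)
  trials
}

check_trials <- function(trials) {
  if (!is.data.frame(trials) || nrow(trials) == 0L)
    stop("`trials` must be a non-empty data frame", call. = FALSE)
  if (!all(c("t_s", "t_p") %in% names(trials)))
    stop("`trials` must have columns t_s and t_p", call. = FALSE)
  if (any(trials$t_s <= 0) || any(trials$t_p <= 0))
    stop("t_s and t_p must be positive", call. = FALSE)
  invisible(trials)
}

#' Per-duration reproduction quantiles
#'
#' Empirical quantiles of the reproduced duration, per presented duration,
#' using interpolated order statistics (type 7, the default of mainstream
#' statistical environments).
#'
#' @param trials Trial data frame with columns \code{t_s} and \code{t_p}.
#' @param probs Quantile probabilities in (0, 1); default
#'   \code{c(0.1, 0.3, 0.5, 0.7, 0.9)}.
#' @return A \code{quantile_profile}: numeric matrix, one row per duration
#'   (ascending; row names are the durations) and one column per probability.
#' @export
quantile_profile <- function(trials, probs = c(0.1, 0.3, 0.5, 0.7, 0.9)) {
  check_trials(trials)
  if (any(probs <= 0) || any(probs >= 1))
    stop("`probs` must lie strictly inside (0, 1)", call. = FALSE)
  durs <- sort(unique(trials$t_s))
  q <- t(vapply(durs, function(d) {
    stats::quantile(trials$t_p[trials$t_s == d], probs = probs,
                    type = 7, names = FALSE)
  }, numeric(length(probs))))
  dimnames(q) <- list(format(durs, trim = TRUE), paste0(probs * 100, "%"))
  structure(q, durations = durs, probs = probs, class = "quantile_profile")
}

#' @export
print.quantile_profile <- function(x, ...) {
  cat("Reproduction quantiles (s) per presented duration:\n")
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

#' Root-mean-square error between two quantile profiles
#'
#' @param observed,predicted \code{quantile_profile}s over the same durations
#'   and probabilities.
#' @return RMSE in seconds across all duration-by-probability cells.
#' @export
quantile_rmse <- function(observed, predicted) {
  if (!identical(dim(observed), dim(predicted)))
    stop("quantile profiles have mismatched shapes", call. = FALSE)
  if (max(abs(attr(observed, "durations") - attr(predicted, "durations"))) > 1e-8 ||
      max(abs(attr(observed, "probs") - attr(predicted, "probs"))) > 1e-12)
    stop("quantile profiles cover different durations or probabilities",
         call. = FALSE)
  sqrt(mean((unclass(observed) - unclass(predicted))^2))
}

#' Parameter grid specification
#'
#' Equidistant search grids per parameter.  The full defaults are the
#' standard ranges: w_m and w_p in [0.005, 0.2] with 20 values,
#' delta_w_p in [0.0001, 0.15] with 20 values, p_sd in [0.01, 0.3] with 20
#' values, and p_r in [1.02, 1.2] with 10 values.  The \code{"reduced"}
#' profile keeps every second or third value of the full grids (6-7 values
#' per parameter, 5 for p_r) for desk-scale runs, so every reduced grid
#' point is also a full grid point.
#'
#' @param family Model family: \code{"mln"}, \code{"uniform"} or
#'   \code{"gaussian"}.
#' @param profile \code{"full"} (default) or \code{"reduced"}.
#' @param ... Per-parameter overrides, each a numeric vector of grid values
#'   (e.g. \code{w_m = seq(0.05, 0.15, length.out = 4)}).
#' @return A \code{grid_spec}: list with \code{family} and \code{params}, a
#'   named list of grid-value vectors in canonical order.
#' @export
grid_spec <- function(family = c("mln", "uniform", "gaussian"),
                      profile = c("full", "reduced"), ...) {
  family <- match.arg(family)
  profile <- match.arg(profile)
  full <- list(w_m = seq(0.005, 0.2, length.out = 20),
               w_p = seq(0.005, 0.2, length.out = 20),
               delta_w_p = seq(0.0001, 0.15, length.out = 20),
               p_sd = seq(0.01, 0.3, length.out = 20),
               p_r = seq(1.02, 1.2, length.out = 10))
  if (profile == "reduced") {
    ## thin to a subset of the full grid values (every 2nd/3rd point), so a
    ## vector that lies on the full grid keeps nearby representatives
    full$w_m <- full$w_m[seq(3, 18, by = 3)]
    full$w_p <- full$w_p[seq(3, 18, by = 3)]
    full$delta_w_p <- full$delta_w_p[seq(1, 19, by = 3)]
    full$p_sd <- full$p_sd[seq(2, 20, by = 3)]
    full$p_r <- full$p_r[seq(1, 9, by = 2)]
  }
  defaults <- switch(family,
    uniform = full[c("w_m", "w_p")],
    gaussian = full[c("w_m", "w_p", "p_sd")],
    mln = full[c("w_m", "delta_w_p", "p_sd", "p_r")])
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad))
    stop("unknown parameter(s) for the ", family, " family: ",
         paste(bad, collapse = ", "), call. = FALSE)
  for (nm in names(overrides)) {
    v <- sort(as.numeric(overrides[[nm]]))
    if (length(v) < 1L || any(!is.finite(v)))
      stop("invalid grid values for ", nm, call. = FALSE)
    defaults[[nm]] <- v
  }
  structure(list(family = family, params = defaults, profile = profile),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("Grid specification (%s family, %s profile):\n", x$family,
              x$profile))
  for (nm in names(x$params)) {
    v <- x$params[[nm]]
    cat(sprintf("  %-9s [%g, %g] x %d\n", nm, min(v), max(v), length(v)))
  }
  cat("  vectors:", prod(vapply(x$params, length, integer(1))), "\n")
  invisible(x)
}

## Number of free parameters per family (for AIC).
family_k <- function(family) {
  switch(family, uniform = 2L, gaussian = 3L, mln = 4L)
}

#' Fit a Bayesian observer model to a trial table
#'
#' Exhaustive (linear) grid search: for every parameter vector in the
#' Cartesian grid, the observer is simulated for \code{n_sim} trials per
#' stimulus duration under common random numbers, the simulated reproduction
#' quantiles (10/30/50/70/90\% by default) are compared with the observed
#' ones, and the RMSE across all duration-by-probability cells is recorded.
#' The best vector minimizes the RMSE (ties broken by the first vector in
#' grid order); parameter estimates are additionally summarised by
#' AIC-weighted model averaging over all grid vectors
#' (see \code{\link{aic_average}}).
#'
#' Observed reproductions are mean-centered by default so that only the
#' central tendency pattern, not structural over-/under-reproduction, drives
#' the fit.
#'
#' @param trials Trial data frame (one participant) with columns \code{t_s}
#'   and \code{t_p} in seconds.
#' @param family Model family; ignored if \code{spec} is supplied.
#' @param stimuli A \code{stimulus_set}; default inferred from the distinct
#'   \code{t_s} values in \code{trials}.
#' @param spec A \code{grid_spec}; default \code{grid_spec(family)}.
#' @param n_sim Simulated trials per duration and grid vector; default 1000.
#' @param seed Integer seed driving the common random numbers.
#' @param center Mean-center observed reproductions first? Default TRUE.
#' @param probs Quantile probabilities of the objective.
#' @param n_grid_points Integration grid resolution (default 1024).
#' @param n_lattice Posterior-mean lookup-lattice resolution (default 512).
#' @return An \code{observer_fit} object with components \code{table} (one
#'   row per grid vector with its RMSE), \code{best}, \code{average},
#'   \code{rmse}, \code{observed}, and the settings used.  Supports
#'   \code{print}, \code{summary}, \code{coef}, \code{predict}, \code{plot},
#'   \code{simulate} and \code{residuals}.
#' @seealso \code{\link{grid_search}} for the spec-first calling convention.
#' @examples
#' stim <- geometric_durations(1.4, 1.2, -1:1)
#' truth <- observer_params("mln", w_m = 0.09, delta_w_p = 0.05,
#'                          p_sd = 0.12, p_r = 1.1)
#' trials <- simulate_dataset(truth, stim, 200, seed = 1)
#' spec <- grid_spec("mln", w_m = c(0.05, 0.09, 0.13), delta_w_p = 0.05,
#'                   p_sd = 0.12, p_r = c(1.05, 1.1, 1.15))
#' fit <- fit_observer(trials, spec = spec, stimuli = stim,
#'                     n_sim = 200, seed = 2)
#' coef(fit)
#' @export
fit_observer <- function(trials, family = c("mln", "uniform", "gaussian"),
                         stimuli = NULL, spec = NULL, n_sim = 1000L,
                         seed = 1L, center = TRUE,
                         probs = c(0.1, 0.3, 0.5, 0.7, 0.9),
                         n_grid_points = 1024L, n_lattice = 512L) {
  cl <- match.call()
  check_trials(trials)
  if ("participant" %in% names(trials) &&
      length(unique(trials$participant)) > 1L)
    stop("fit one participant at a time; split the table first", call. = FALSE)
  if (is.null(spec)) spec <- grid_spec(match.arg(family))
  family <- spec$family
  if (is.null(stimuli)) stimuli <- stimulus_set(unique(trials$t_s))
  durs <- stimuli$durations
  obs_durs <- sort(unique(trials$t_s))
  if (length(obs_durs) != length(durs) || max(abs(obs_durs - durs)) > 1e-6)
    stop("distinct t_s values in `trials` must match `stimuli`", call. = FALSE)

  centered <- if (center) center_reproductions(trials) else trials
  observed <- quantile_profile(centered, probs)

  eng <- grid_search_engine(observed, spec, stimuli, n_sim = n_sim,
                            seed = seed, probs = probs,
                            n_grid_points = n_grid_points,
                            n_lattice = n_lattice, center = center)
  n_cells <- length(durs) * length(probs)
  fit <- structure(list(call = cl, family = family, spec = spec,
                        stimuli = stimuli, table = eng$table,
                        best = eng$best, best_index = eng$best_index,
                        rmse = eng$best_rmse, observed = observed,
                        n_quantile_cells = n_cells, n_sim = n_sim,
                        seed = seed, centered = center, probs = probs,
                        n_grid_points = n_grid_points,
                        n_lattice = n_lattice),
                   class = "observer_fit")
  avg <- aic_average(fit)
  fit$average <- avg$average
  fit$aic_weights <- avg$weights
  fit
}

#' Grid search with an explicit grid specification
#'
#' Spec-first calling convention for \code{\link{fit_observer}}: the model
#' family is taken from \code{spec}.
#'
#' @param trials Trial data frame (one participant).
#' @param spec A \code{grid_spec}.
#' @param stimuli A \code{stimulus_set}.
#' @param n_sim Simulated trials per duration and vector.
#' @param seed Integer seed (common random numbers across the grid).
#' @param ... Further arguments passed to \code{\link{fit_observer}}.
#' @return An \code{observer_fit}.
#' @export
grid_search <- function(trials, spec, stimuli, n_sim = 1000L, seed = 1L, ...) {
  fit_observer(trials, spec = spec, stimuli = stimuli, n_sim = n_sim,
               seed = seed, ...)
}

## The search engine.  Works on an observed quantile profile; exploits that
## the posterior-mean lattice depends only on (w_m, prior) and that the prior
## depends only on a subset of the parameters, so lattices are cached and the
## same base normal draws (common random numbers) are reused for every
## vector.
grid_search_engine <- function(observed, spec, stimuli, n_sim, seed, probs,
                               n_grid_points, n_lattice, center = TRUE) {
  family <- spec$family
  params <- spec$params
  grid <- make_grid(stimuli, n_points = n_grid_points)
  durs <- stimuli$durations
  n_dur <- length(durs)

  vectors <- expand.grid(params, KEEP.OUT.ATTRS = FALSE)
  n_vec <- nrow(vectors)

  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_seed(old), add = TRUE)
  set.seed(as.integer(seed))
  ## Common random numbers across all grid vectors, stratified per duration
  ## (Latin-hypercube pairing of the two noise stages): the simulated
  ## reproduction quantiles estimate the same model quantiles as plain
  ## sampling but with far lower variance, so RMSE differences across the
  ## grid reflect the parameters, not sampling noise.
  strat <- stats::qnorm((seq_len(n_sim) - 0.5) / n_sim)
  Z1 <- vapply(seq_len(n_dur), function(j) sample(strat), numeric(n_sim))
  Z2 <- vapply(seq_len(n_dur), function(j) sample(strat), numeric(n_sim))
  pool <- stats::rnorm(8192L)  # reserve draws for rejected (non-positive) samples

  ## prior cache key per vector
  prior_key <- switch(family,
    uniform = rep("u", n_vec),
    gaussian = sprintf("%.12g", vectors$p_sd),
    mln = sprintf("%.12g|%.12g", vectors$p_sd, vectors$p_r))
  lattice_key <- sprintf("%s|%.12g", prior_key, vectors$w_m)

  prior_cache <- new.env(parent = emptyenv())
  lattice_cache <- new.env(parent = emptyenv())
  get_prior <- function(i) {
    k <- prior_key[i]
    p <- get0(k, prior_cache, inherits = FALSE)
    if (is.null(p)) {
      pars <- vector_params(family, vectors[i, , drop = FALSE])
      p <- default_prior(pars, stimuli, grid)
      assign(k, p, prior_cache)
    }
    p
  }
  get_lattice <- function(i) {
    k <- lattice_key[i]
    tab <- get0(k, lattice_cache, inherits = FALSE)
    if (is.null(tab)) {
      tab <- posterior_mean_table(get_prior(i), vectors$w_m[i],
                                  n_lattice = n_lattice)
      assign(k, tab, lattice_cache)
    }
    tab
  }

  ts_mat <- matrix(rep(durs, each = n_sim), n_sim, n_dur)
  rmse <- numeric(n_vec)
  n_degenerate <- 0L
  for (i in seq_len(n_vec)) {
    pars <- vector_params(family, vectors[i, , drop = FALSE])
    tab <- tryCatch(get_lattice(i), error = function(e) NULL)
    if (is.null(tab)) {
      rmse[i] <- Inf
      n_degenerate <- n_degenerate + 1L
      next
    }
    t_m <- ts_mat * (1 + pars$w_m * Z1)
    t_m <- fix_nonpositive_crn(t_m, ts_mat, pars$w_m * ts_mat, pool)
    t_e <- matrix(interp_te(tab, t_m), n_sim, n_dur)
    sd_rep <- reproduction_sd(pars, t_e)
    t_p <- t_e + sd_rep * Z2
    t_p <- fix_nonpositive_crn(t_p, t_e, sd_rep, pool)
    ## center the simulated reproductions the same way as the observed ones,
    ## so the objective is invariant to structural shifts on both sides
    if (center) t_p <- t_p - mean(t_p) + mean(ts_mat)
    pred <- matrix(0, n_dur, length(probs))
    for (j in seq_len(n_dur))
      pred[j, ] <- stats::quantile(t_p[, j], probs = probs, type = 7,
                                   names = FALSE)
    rmse[i] <- sqrt(mean((unclass(observed) - pred)^2))
  }
  if (n_degenerate > 0L)
    warning(n_degenerate,
            " grid vector(s) produced a degenerate posterior; RMSE set to Inf",
            call. = FALSE)
  if (all(!is.finite(rmse)))
    stop("no grid vector produced a finite RMSE", call. = FALSE)

  table <- cbind(vectors, rmse = rmse)
  best_index <- which.min(rmse)  # which.min takes the first minimum: grid-order tie-break
  best <- unlist(vectors[best_index, , drop = TRUE])
  list(table = table, best = best, best_index = best_index,
       best_rmse = rmse[best_index])
}

## Deterministic replacement of non-positive entries using a fixed draw pool,
## so results stay identical across grid vectors and runs.
fix_nonpositive_crn <- function(x, mean, sd, pool) {
  bad <- which(x <= 0)
  if (!length(bad)) return(x)
  k <- 0L
  for (idx in bad) {
    repeat {
      k <- k + 1L
      if (k > length(pool)) { x[idx] <- .Machine$double.eps; break }
      cand <- mean[idx] + sd[idx] * pool[k]
      if (cand > 0) { x[idx] <- cand; break }
    }
  }
  x
}

vector_params <- function(family, row) {
  switch(family,
    uniform = observer_params("uniform", w_m = row$w_m, w_p = row$w_p),
    gaussian = observer_params("gaussian", w_m = row$w_m, w_p = row$w_p,
                               p_sd = row$p_sd),
    mln = observer_params("mln", w_m = row$w_m, delta_w_p = row$delta_w_p,
                          p_sd = row$p_sd, p_r = row$p_r))
}

#' AIC-weighted model averaging over the grid
#'
#' Converts each grid vector's quantile RMSE into an AIC value via a Gaussian
#' quasi-likelihood on the quantile residuals,
#' \eqn{AIC_i = n \log(RMSE_i^2) + 2k} with \eqn{n} the number of
#' duration-by-probability cells, and averages the parameter vectors with
#' Akaike weights \eqn{w_i = \exp(-\Delta_i/2) / \sum_j \exp(-\Delta_j/2)}.
#' Vectors with infinite RMSE receive weight zero.
#'
#' @param fit An \code{observer_fit} (or any list with \code{table},
#'   \code{n_quantile_cells} and \code{family}).
#' @param k Number of free parameters; default 2 (uniform), 3 (gaussian) or
#'   4 (mln).
#' @return List with \code{average} (named parameter vector), \code{weights}
#'   (per grid vector, summing to 1), \code{aic} and \code{k}.
#' @export
aic_average <- function(fit, k = NULL) {
  if (is.null(k)) k <- family_k(fit$family)
  tab <- fit$table
  rmse <- tab$rmse
  if (all(!is.finite(rmse))) stop("all RMSE values are infinite", call. = FALSE)
  n <- fit$n_quantile_cells
  ## floor avoids log(0) when a simulated profile matches exactly
  aic <- ifelse(is.finite(rmse), n * log(pmax(rmse, 1e-12)^2) + 2 * k, Inf)
  delta <- aic - min(aic)
  w <- exp(-delta / 2)
  w[!is.finite(rmse)] <- 0
  w <- w / sum(w)
  par_cols <- setdiff(names(tab), "rmse")
  avg <- vapply(par_cols, function(nm) sum(w * tab[[nm]]), numeric(1))
  list(average = avg, weights = w, aic = aic, k = k)
}
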