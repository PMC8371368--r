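## Synthetic cohorts with known ground-truth parameters, mimicking the
## healthy-control vs memory-impaired contrast (noisier clock, stronger
## prior pull in the impaired group).

#' Specify a synthetic cohort
#'
#' Each group draws per-participant mln observer parameters from independent
#' Gaussians (truncated to the standard grid ranges), then simulates a full
#' trial table per participant.  The default two groups mirror a
#' healthy-control (HC, n = 25) versus memory-impaired (MCI, n = 10)
#' contrast: the impaired group has a higher mean clock Weber fraction
#' \code{w_m} and a lower mean pull ratio \code{p_r} (components pulled
#' closer to the centre).
#'
#' @param groups Named list; each element a list with \code{n} and per
#'   parameter \code{mean} and \code{sd} entries (\code{w_m},
#'   \code{delta_w_p}, \code{p_sd}, \code{p_r}).
#' @param n_trials_per_duration Trials per stimulus duration per participant.
#' @param stimuli A \code{stimulus_set}.
#' @param seed Integer seed.
#' @return A \code{cohort_spec} object.
#' @export
cohort_spec <- function(groups = NULL, n_trials_per_duration = 60L,
                        stimuli = geometric_durations(1.4, 1.2, -1:1),
                        seed = 1L) {
  if (is.null(groups)) {
    groups <- list(
      HC = list(n = 25L,
                w_m = list(mean = 0.06, sd = 0.02),
                delta_w_p = list(mean = 0.05, sd = 0.02),
                p_sd = list(mean = 0.12, sd = 0.03),
                p_r = list(mean = 1.15, sd = 0.03)),
      MCI = list(n = 10L,
                 w_m = list(mean = 0.11, sd = 0.02),
                 delta_w_p = list(mean = 0.05, sd = 0.02),
                 p_sd = list(mean = 0.12, sd = 0.03),
                 p_r = list(mean = 1.06, sd = 0.02)))
  }
  ranges <- list(w_m = c(0.005, 0.2), delta_w_p = c(0.0001, 0.15),
                 p_sd = c(0.01, 0.3), p_r = c(1.02, 1.2))
  for (g in names(groups)) {
    if (is.null(groups[[g]]$n) || groups[[g]]$n < 1)
      stop("each group needs n >= 1", call. = FALSE)
    for (p in names(ranges)) {
      m <- groups[[g]][[p]]$mean
      if (is.null(m) || m < ranges[[p]][1] || m > ranges[[p]][2])
        stop(sprintf("group %s: mean of %s must lie in [%g, %g]",
                     g, p, ranges[[p]][1], ranges[[p]][2]), call. = FALSE)
    }
  }
  structure(list(groups = groups, n_trials_per_duration = n_trials_per_duration,
                 stimuli = stimuli, seed = seed, ranges = ranges),
            class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' Draws ground-truth parameters per participant (Gaussian between-participant
#' variation, truncated to the valid ranges) and simulates each participant's
#' trial table with the mln observer.
#'
#' @param spec A \code{cohort_spec}.
#' @return List with \code{trials} (data frame: participant, group, t_s, t_p)
#'   and \code{truth} (data frame: participant, group, w_m, delta_w_p, p_sd,
#'   p_r).
#' @examples
#' spec <- cohort_spec(groups = list(
#'   A = list(n = 2, w_m = list(mean = 0.06, sd = 0.01),
#'            delta_w_p = list(mean = 0.05, sd = 0.01),
#'            p_sd = list(mean = 0.12, sd = 0.02),
#'            p_r = list(mean = 1.15, sd = 0.02))),
#'   n_trials_per_duration = 20, seed = 7)
#' cohort <- generate_cohort(spec)
#' table(cohort$trials$participant)
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec"))
    stop("`spec` must be a cohort_spec", call. = FALSE)
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_seed(old), add = TRUE)
  set.seed(as.integer(spec$seed))
  grid <- make_grid(spec$stimuli)

  rtruncnorm1 <- function(mean, sd, lo, hi) {
    repeat {
      x <- stats::rnorm(1L, mean, sd)
      if (x >= lo && x <= hi) return(x)
    }
  }

  truth <- list(); trials <- list(); idx <- 0L
  for (g in names(spec$groups)) {
    gr <- spec$groups[[g]]
    for (j in seq_len(gr$n)) {
      idx <- idx + 1L
      id <- sprintf("%s_%02d", g, j)
      pars <- lapply(names(spec$ranges), function(p)
        rtruncnorm1(gr[[p]]$mean, gr[[p]]$sd,
                    spec$ranges[[p]][1], spec$ranges[[p]][2]))
      names(pars) <- names(spec$ranges)
      truth[[idx]] <- data.frame(participant = id, group = g,
                                 w_m = pars$w_m, delta_w_p = pars$delta_w_p,
                                 p_sd = pars$p_sd, p_r = pars$p_r,
                                 stringsAsFactors = FALSE)
      op <- observer_params("mln", w_m = pars$w_m, delta_w_p = pars$delta_w_p,
                            p_sd = pars$p_sd, p_r = pars$p_r)
      ## per-participant seed derived deterministically from the cohort seed
      trials[[idx]] <- simulate_dataset(op, spec$stimuli,
                                        spec$n_trials_per_duration,
                                        seed = (spec$seed * 1000L + idx) %% .Machine$integer.max,
                                        grid = grid, participant = id,
                                        group = g)
    }
  }
  list(trials = do.call(rbind, trials), truth = do.call(rbind, truth))
}

#' Central-tendency slope of a trial table
#'
#' Ordinary least-squares slope of the per-duration mean reproduction on the
#' presented duration.  A slope of 1 means veridical reproduction; slopes
#' below 1 indicate central tendency (regression towards the mean).
#'
#' @param trials Trial data frame with columns \code{t_s} and \code{t_p};
#'   at least two distinct durations.
#' @return The slope (dimensionless).
#' @export
central_tendency_slope <- function(trials) {
  check_trials(trials)
  durs <- sort(unique(trials$t_s))
  if (length(durs) < 2L)
    stop("need at least two distinct presented durations", call. = FALSE)
  means <- vapply(durs, function(d) mean(trials$t_p[trials$t_s == d]),
                  numeric(1))
  unname(stats::coef(stats::lm(means ~ durs))[2])
}
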