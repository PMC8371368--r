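# Shared fixtures: the canonical three-duration task and small helpers.

std_stimuli <- function() geometric_durations(1.4, 1.2, -1:1)

std_grid <- function(n_points = 1024L) {
  make_grid(stimulus_set(c(1.17, 1.4, 1.68)), n_points = n_points)
}

# rectangle-rule integral of a prior density over [a, b]
grid_integral <- function(prior, a = NULL, b = NULL) {
  t <- prior$grid$points
  keep <- rep(TRUE, length(t))
  if (!is.null(a)) keep <- keep & t >= a
  if (!is.null(b)) keep <- keep & t <= b
  sum(prior$density[keep]) * prior$grid$step
}

# tiny trial table with known values
toy_trials <- function(t_s, t_p) {
  data.frame(participant = "p1", group = "none", t_s = t_s, t_p = t_p,
             stringsAsFactors = FALSE)
}

# the standard on-grid mln truth vector used in recovery checks
ongrid_truth <- function() {
  c(w_m = 0.005 + 8 * 0.195 / 19,
    delta_w_p = 0.0001 + 6 * 0.1499 / 19,
    p_sd = 0.01 + 7 * 0.29 / 19,
    p_r = 1.1)
}
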