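## CSV/YAML/JSON interchange.  Trial tables are seconds with dot decimals;
## prior-density curves may be in milliseconds when the column name says so.

#' Write and read trial tables
#'
#' Trial CSVs carry the header \code{participant,group,t_s,t_p} with
#' durations in seconds.
#'
#' @param trials Trial data frame.
#' @param path File path.
#' @return \code{read_trials} returns the validated trial data frame;
#'   \code{write_trials} returns \code{path} invisibly.
#' @export
write_trials <- function(trials, path) {
  check_trials(trials)
  if (is.null(trials$participant)) trials$participant <- "p1"
  if (is.null(trials$group)) trials$group <- "none"
  utils::write.csv(trials[, c("participant", "group", "t_s", "t_p")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("participant", "group", "t_s", "t_p"), names(x))
  if (length(missing))
    stop("trial CSV is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  bad <- which(!is.finite(x$t_s) | !is.finite(x$t_p) | x$t_s <= 0 | x$t_p <= 0)
  if (length(bad))
    stop("trial CSV has non-positive or missing durations in row(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  x
}

#' Write and read prior-density curves
#'
#' Two-column CSV interchange for density curves.  On write, the columns are
#' \code{duration_s,density}.  On read, a \code{duration_ms} column is
#' converted to seconds (densities are rescaled accordingly).
#'
#' @param prior A \code{prior_density} (or data frame with columns
#'   \code{duration_s} and \code{density}).
#' @param path File path.
#' @return \code{read_prior_density} returns a data frame with columns
#'   \code{duration_s} and \code{density}.
#' @export
write_prior_density <- function(prior, path) {
  df <- if (inherits(prior, "prior_density")) as.data.frame(prior) else prior
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_prior_density
#' @export
read_prior_density <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("duration_ms" %in% names(x)) {
    x$duration_s <- x$duration_ms / 1000
    x$density <- x$density * 1000  # 1/ms -> 1/s
    x$duration_ms <- NULL
  }
  if (!all(c("duration_s", "density") %in% names(x)))
    stop("density CSV needs columns duration_s (or duration_ms) and density",
         call. = FALSE)
  x[order(x$duration_s), c("duration_s", "density")]
}

#' Read a target density curve for mixture recovery
#'
#' @param path CSV path (columns \code{duration_s} or \code{duration_ms},
#'   and \code{density}).
#' @param window Fit window in seconds.
#' @return A \code{target_density}.
#' @export
read_target_density <- function(path, window = c(0.2, 1.6)) {
  x <- read_prior_density(path)
  target_density(x$duration_s, x$density, window = window)
}

#' Read a grid-search configuration file
#'
#' YAML with keys \code{model}, optional per-parameter \code{lo}/\code{hi}/
#' \code{count} blocks, and optional \code{n_sim} and \code{seed}.
#'
#' @param path YAML file path.
#' @return List with \code{spec} (a \code{grid_spec}), \code{n_sim},
#'   \code{seed}.
#' @export
read_grid_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$model))
    stop("config must name a `model` (uniform/gaussian/mln)", call. = FALSE)
  par_names <- switch(cfg$model,
    uniform = c("w_m", "w_p"),
    gaussian = c("w_m", "w_p", "p_sd"),
    mln = c("w_m", "delta_w_p", "p_sd", "p_r"),
    stop("unknown model: ", cfg$model, call. = FALSE))
  overrides <- list()
  for (p in par_names) {
    blk <- cfg[[p]]
    if (!is.null(blk)) {
      if (is.null(blk$lo) || is.null(blk$hi) || is.null(blk$count))
        stop("parameter block ", p, " needs lo, hi and count", call. = FALSE)
      overrides[[p]] <- seq(blk$lo, blk$hi, length.out = blk$count)
    }
  }
  profile <- if (!is.null(cfg$profile)) cfg$profile else "full"
  spec <- do.call(grid_spec, c(list(family = cfg$model, profile = profile),
                               overrides))
  list(spec = spec,
       n_sim = if (!is.null(cfg$n_sim)) cfg$n_sim else 1000L,
       seed = if (!is.null(cfg$seed)) cfg$seed else 1L)
}

## Manifest written next to every CLI output: settings + seed + version.
write_manifest <- function(path, command, settings) {
  manifest <- list(command = command,
                   package = "mlntiming",
                   version = as.character(utils::packageVersion("mlntiming")),
                   settings = settings)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
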