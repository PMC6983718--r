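#' Configuration for synthetic tubulin polymerisation curves
#'
#' A logistic (sigmoidal) fluorescence-vs-time curve with additive Gaussian
#' noise, sampled like the reference assay: 61 points at 1-min spacing over
#' 60 min. Non-polymerising controls are flat at `f_min` (amplitude 0).
#'
#' @param f_min,f_max fluorescence plateau values (a.u.); `f_max >= f_min`.
#' @param t50 half-rise time (min).
#' @param slope logistic rate (1/min).
#' @param noise_sd additive Gaussian noise SD (a.u.).
#' @param n_points samples (default 61).
#' @param dt sampling interval (min, default 1).
#' @param polymerising logical; `FALSE` collapses the amplitude to zero.
#' @return list of class `polymer_sim_config`.
#' @export
polymer_sim_config <- function(f_min = 5, f_max = 105, t50 = 20, slope = 0.35,
                               noise_sd = 2, n_points = 61L, dt = 1,
                               polymerising = TRUE) {
  if (f_max < f_min) stop("f_max must be >= f_min")
  if (dt <= 0) stop("dt must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (n_points < 2) stop("n_points must be >= 2")
  structure(as.list(environment()), class = "polymer_sim_config")
}

#' Simulate one polymerisation curve
#'
#' @param config a [polymer_sim_config()].
#' @param seed integer seed.
#' @return object of class `polymerisation_curve`: `data` (data.frame
#'   `time_min`, `fluorescence`), `truth` (the noiseless parameters and the
#'   planted `polymerising` label).
#' @export
simulate_polymerisation_curve <- function(config, seed) {
  stopifnot(inherits(config, "polymer_sim_config"))
  cfg <- config
  tt <- (seq_len(cfg$n_points) - 1) * cfg$dt
  amp <- if (cfg$polymerising) cfg$f_max - cfg$f_min else 0
  clean <- cfg$f_min + amp / (1 + exp(-cfg$slope * (tt - cfg$t50)))
  y <- with_seed(derive_seed(seed, "polymer-noise"),
                 clean + stats::rnorm(length(tt), 0, cfg$noise_sd))
  structure(list(data = data.frame(time_min = tt, fluorescence = y),
                 truth = list(f_min = cfg$f_min,
                              f_max = if (cfg$polymerising) cfg$f_max else cfg$f_min,
                              t50 = cfg$t50, slope = cfg$slope,
                              polymerising = cfg$polymerising)),
            class = "polymerisation_curve")
}

#' @export
print.polymerisation_curve <- function(x, ...) {
  cat(sprintf("polymerisation_curve: %d points over %g min (%s)\n",
              nrow(x$data), max(x$data$time_min),
              if (x$truth$polymerising) "polymerising" else "non-polymerising"))
  invisible(x)
}
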