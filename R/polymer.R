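#' Fit a four-parameter logistic to a tubulin polymerisation curve
#'
#' Least-squares fit of
#' `f(t) = f_min + (f_max - f_min) / (1 + exp(-slope * (t - t50)))`
#' characterising a fluorescence-based polymerisation assay by its minimum
#' and maximum fluorescence, the time at 50% of the amplitude and the slope.
#' Initialisation: `f_min = min(y)`, `f_max = max(y)`, `t50` at the
#' half-range crossing, slope from the central difference there. A
#' non-converging fit returns `converged = FALSE` with the last iterate
#' (or the initial values if no iterate exists).
#'
#' @param curve data.frame with `time_min` and `fluorescence` (>= 8 points),
#'   or a [simulate_polymerisation_curve()] result.
#' @param positive_slope constrain the slope to be positive (default TRUE).
#' @return object of class `sigmoid_fit`: `f_min`, `f_max`, `t50`, `slope`,
#'   `residual_rms`, `converged`, `t50_reliable`, plus the data; supports
#'   `coef()`, `predict()`, `residuals()`, `print()`.
#' @export
fit_sigmoid <- function(curve, positive_slope = TRUE) {
  if (inherits(curve, "polymerisation_curve")) curve <- curve$data
  stopifnot(all(c("time_min", "fluorescence") %in% names(curve)))
  tt <- curve$time_min; y <- curve$fluorescence
  if (length(tt) < 8) stop("need >= 8 time points to fit")
  if (any(diff(tt) <= 0)) stop("times must be strictly increasing")
  y_min <- min(y); y_max <- max(y)
  amp <- y_max - y_min
  half <- y_min + amp / 2
  i_half <- which(y >= half)[1]
  if (is.na(i_half)) i_half <- ceiling(length(y) / 2)
  t50_0 <- tt[i_half]
  i0 <- max(2, min(length(y) - 1, i_half))
  dydt <- (y[i0 + 1] - y[i0 - 1]) / (tt[i0 + 1] - tt[i0 - 1])
  slope_0 <- if (amp > 0 && dydt > 0) 4 * dydt / amp else 0.25
  start <- list(fmin = y_min, fmax = y_max, t50 = t50_0, slope = slope_0)
  lower <- c(fmin = -Inf, fmax = -Inf, t50 = -Inf,
             slope = if (positive_slope) 1e-8 else -Inf)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ fmin + (fmax - fmin) / (1 + exp(-slope * (t - t50))),
                      data = data.frame(t = tt, y = y),
                      start = start, lower = lower,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # the nlsLM wrapper occasionally reports a singular initial gradient on
    # inputs the raw LM engine handles; retry with nls.lm before giving up
    raw <- tryCatch(
      minpack.lm::nls.lm(par = unlist(start),
                         fn = function(p) y - (p[1] + (p[2] - p[1]) /
                                                 (1 + exp(-p[4] * (tt - p[3])))),
                         lower = unname(lower),
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(raw)) {
      cf <- stats::setNames(raw$par, c("fmin", "fmax", "t50", "slope"))
      converged <- raw$info %in% 1:3
      resid <- raw$fvec
    } else {
      cf <- unlist(start)
      converged <- FALSE
      resid <- y - (cf["fmin"] + (cf["fmax"] - cf["fmin"]) /
                      (1 + exp(-cf["slope"] * (tt - cf["t50"]))))
    }
  } else {
    cf <- stats::coef(fit)
    converged <- isTRUE(fit$convInfo$isConv)
    resid <- stats::residuals(fit)
  }
  if (cf["fmax"] < cf["fmin"]) {  # canonical orientation
    cf[c("fmin", "fmax")] <- cf[c("fmax", "fmin")]
    cf["slope"] <- -cf["slope"]
  }
  rms <- sqrt(mean(resid^2))
  t50_reliable <- converged &&
    cf["t50"] >= tt[1] - 30 && cf["t50"] <= tt[length(tt)] + 30 &&
    (cf["fmax"] - cf["fmin"]) > 3 * rms
  structure(list(f_min = unname(cf["fmin"]), f_max = unname(cf["fmax"]),
                 t50 = unname(cf["t50"]), slope = unname(cf["slope"]),
                 residual_rms = rms, converged = converged,
                 t50_reliable = t50_reliable,
                 data = data.frame(time_min = tt, fluorescence = y)),
            class = "sigmoid_fit")
}

#' @export
coef.sigmoid_fit <- function(object, ...) {
  c(f_min = object$f_min, f_max = object$f_max,
    t50 = object$t50, slope = object$slope)
}

#' @export
predict.sigmoid_fit <- function(object, newdata = NULL, ...) {
  tt <- if (is.null(newdata)) object$data$time_min else newdata$time_min
  object$f_min + (object$f_max - object$f_min) /
    (1 + exp(-object$slope * (tt - object$t50)))
}

#' @export
residuals.sigmoid_fit <- function(object, ...) {
  object$data$fluorescence - predict(object)
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf(
    "sigmoid_fit: f_min %.4g, f_max %.4g, t50 %.4g min, slope %.4g /min\n",
    x$f_min, x$f_max, x$t50, x$slope))
  cat(sprintf("  residual RMS %.4g, converged: %s, t50 reliable: %s\n",
              x$residual_rms, x$converged, x$t50_reliable))
  invisible(x)
}

#' @export
plot.sigmoid_fit <- function(x, ...) {
  graphics::plot(x$data$time_min, x$data$fluorescence,
                 xlab = "time (min)", ylab = "fluorescence (a.u.)", ...)
  tt <- seq(min(x$data$time_min), max(x$data$time_min), length.out = 200)
  graphics::lines(tt, predict(x, data.frame(time_min = tt)), col = 2)
  invisible(x)
}

#' Classify a curve as polymerising or not
#'
#' A curve is polymerising when its fit converged and its realised amplitude
#' reaches the amplitude threshold; by default the threshold is 5x the fit's
#' residual RMS (a proxy for the baseline noise level). The realised
#' amplitude is the fitted curve's span within the observation window,
#' `|f(t_last) - f(t_first)|`, which equals `f_max - f_min` for a genuine
#' sigmoid but collapses for the degenerate near-linear fits that flat noisy
#' controls sometimes produce (slope near zero or t50 far outside the
#' assay, where the nominal amplitude is an extrapolation artefact).
#'
#' @param fit a [fit_sigmoid()] result.
#' @param amplitude_threshold absolute threshold in fluorescence units;
#'   default `5 * fit$residual_rms`.
#' @return `"polymerising"` or `"non_polymerising"`.
#' @export
classify_polymerisation <- function(fit, amplitude_threshold = NULL) {
  stopifnot(inherits(fit, "sigmoid_fit"))
  if (is.null(amplitude_threshold))
    amplitude_threshold <- 5 * fit$residual_rms
  tt <- range(fit$data$time_min)
  span <- abs(diff(predict(fit, data.frame(time_min = tt))))
  if (fit$converged && span >= amplitude_threshold)
    "polymerising" else "non_polymerising"
}

#' Compare microtubule counts per field of view between conditions
#'
#' One-tailed unpaired pooled-variance t-test with the alternative that
#' condition A (e.g. the MT-promoting protein) yields more MTs than
#' condition B (e.g. the tag-only control). Counts are entered directly
#' (they are scored manually under the microscope).
#'
#' @param counts_a,counts_b numeric MT counts per field, n >= 2 each.
#' @return list of class `mt_count_comparison`: per-condition means and n,
#'   `test` (a `ttest_result`).
#' @export
compare_mt_counts <- function(counts_a, counts_b) {
  if (length(counts_a) < 2 || length(counts_b) < 2) stop("need n >= 2 per condition")
  structure(list(mean_a = mean(counts_a), mean_b = mean(counts_b),
                 n_a = length(counts_a), n_b = length(counts_b),
                 test = one_tailed_unpaired_t(counts_a, counts_b, "greater")),
            class = "mt_count_comparison")
}

#' @export
print.mt_count_comparison <- function(x, ...) {
  cat(sprintf("MT counts per field: %.3g (n=%d) vs %.3g (n=%d)\n",
              x$mean_a, x$n_a, x$mean_b, x$n_b))
  print(x$test)
  invisible(x)
}
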