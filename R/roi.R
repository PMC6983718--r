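#' Photobleaching correction by exponential-decay fitting
#'
#' Fits `I(t) = A * exp(-t / tau) + C` to a per-frame intensity series (the
#' whole-frame mean of the movie, typically) and divides the series by the
#' fitted decay normalised to its value at t = 0. A constant series is
#' returned unchanged; a non-converging fit returns the input with a warning.
#'
#' @param series positive per-frame intensities.
#' @param times time points in seconds; defaults to `frame_interval`-spaced.
#' @param frame_interval seconds (used when `times` is missing; default 5).
#' @return corrected numeric series with attributes `tau`, `A`, `C`
#'   (NA when no fit was applied).
#' @export
bleach_correct <- function(series, times = NULL, frame_interval = 5) {
  if (any(!is.finite(series)) || any(series <= 0))
    stop("bleach_correct requires positive finite intensities")
  n <- length(series)
  if (is.null(times)) times <- (seq_len(n) - 1) * frame_interval
  if (n < 3 || stats::sd(series) == 0)
    return(structure(series, tau = NA_real_, A = NA_real_, C = NA_real_))
  # self-start by log-linear regression of log(y - C0), then polish with
  # Levenberg-Marquardt; the log-linear estimate stands in if polishing fails
  c0 <- min(series) - 0.05 * diff(range(series))
  ll <- stats::lm(log(series - c0) ~ times)
  if (!is.finite(stats::coef(ll)[2]) || stats::coef(ll)[2] >= 0) {
    warning("no decaying trend found; series returned uncorrected")
    return(structure(series, tau = NA_real_, A = NA_real_, C = NA_real_))
  }
  start <- c(A = exp(unname(stats::coef(ll)[1])),
             tau = -1 / unname(stats::coef(ll)[2]),
             C = max(c0, 0))
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start,
                       fn = function(p) series - (p[1] * exp(-times / p[2]) + p[3]),
                       lower = c(0, 1e-6, 0),
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  cf <- if (is.null(fit)) start else stats::setNames(fit$par, names(start))
  decay <- (cf["A"] * exp(-times / cf["tau"]) + cf["C"]) /
           (cf["A"] * exp(-times[1] / cf["tau"]) + cf["C"])
  structure(series / decay, tau = unname(cf["tau"]), A = unname(cf["A"]),
            C = unname(cf["C"]))
}

# Pixel mask helpers: circle/rect specified in um in the 0-based
# pixel-center coordinate frame.
circle_mask <- function(movie, center, radius) {
  d <- dim(movie$frames)[2:3]
  px <- movie$pixel_size
  xg <- matrix((0:(d[2] - 1)) * px, d[1], d[2], byrow = TRUE)
  yg <- matrix((0:(d[1] - 1)) * px, d[1], d[2])
  (xg - center[1])^2 + (yg - center[2])^2 <= radius^2
}

rect_mask <- function(movie, xlim, ylim) {
  d <- dim(movie$frames)[2:3]
  px <- movie$pixel_size
  xg <- matrix((0:(d[2] - 1)) * px, d[1], d[2], byrow = TRUE)
  yg <- matrix((0:(d[1] - 1)) * px, d[1], d[2])
  xg >= xlim[1] & xg <= xlim[2] & yg >= ylim[1] & yg <= ylim[2]
}

roi_in_bounds <- function(movie, center, radius) {
  d <- dim(movie$frames)[2:3]
  px <- movie$pixel_size
  center[1] - radius >= 0 && center[2] - radius >= 0 &&
    center[1] + radius <= (d[2] - 1) * px && center[2] + radius <= (d[1] - 1) * px
}

#' Detect nuclear envelope breakdown (NEB)
#'
#' NEB is called at the first frame whose nuclear mean intensity exceeds the
#' expanding pre-frame baseline by `k` baseline standard deviations -- the
#' operational version of "the first frame showing fluorescent protein influx
#' into the nucleus".
#'
#' @param movie a [time_lapse_movie()].
#' @param nucleus_center,nucleus_radius circle in um (pixel-center frame).
#' @param k detection threshold in baseline SDs (default 3).
#' @param min_baseline minimum number of pre-frames forming the baseline
#'   (default 5).
#' @details The exceedance must persist into the following frame (influx is
#'   sustained, single-frame noise blips are not); the last frame may
#'   trigger on its own.
#' @return the 1-based NEB frame index, or `NA` (with attribute
#'   `reason = "not found"`) when no frame qualifies.
#' @export
detect_neb <- function(movie, nucleus_center, nucleus_radius, k = 3,
                       min_baseline = 5L) {
  stopifnot(inherits(movie, "time_lapse_movie"))
  if (!roi_in_bounds(movie, nucleus_center, nucleus_radius))
    stop("nucleus circle extends beyond the image bounds")
  mask <- circle_mask(movie, nucleus_center, nucleus_radius)
  nt <- n_frames(movie)
  nuc <- vapply(seq_len(nt), function(i) mean(frame_matrix(movie, i)[mask]),
                numeric(1))
  if (nt < min_baseline + 1L)
    return(structure(NA_integer_, reason = "not found"))
  for (i in (min_baseline + 1L):nt) {
    base <- nuc[seq_len(i - 1L)]
    s <- stats::sd(base)
    if (s == 0) s <- .Machine$double.eps
    thr <- mean(base) + k * s
    if (nuc[i] > thr && (i == nt || nuc[i + 1L] > thr)) return(i)
  }
  structure(NA_integer_, reason = "not found")
}

#' Time from NEB to initial chromosome alignment
#'
#' The condensed-chromosome mask's aspect ratio (extent along the first
#' principal axis over extent along the second) is computed per frame; the
#' alignment time is `(first local maximum frame - neb_frame) *
#' frame_interval`, mirroring the "local maximum X:Y ratio" timing rule.
#'
#' @param masks list of logical matrices (one per frame), or `NULL` when
#'   `ratios` is given directly.
#' @param ratios optional precomputed per-frame aspect-ratio series.
#' @param neb_frame 1-based NEB frame index.
#' @param frame_interval seconds per frame (default 5).
#' @return duration in seconds, or `NA` with attribute `reason` when no
#'   local maximum exists before the series ends.
#' @export
alignment_time <- function(masks = NULL, ratios = NULL, neb_frame,
                           frame_interval = 5) {
  if (is.null(ratios)) {
    if (is.null(masks)) stop("supply masks or ratios")
    ratios <- vapply(masks, mask_aspect_ratio, numeric(1))
  }
  n <- length(ratios)
  if (neb_frame >= n) stop("neb_frame beyond the end of the series")
  for (i in max(2L, neb_frame + 1L):(n - 1L)) {
    if (ratios[i] > ratios[i - 1] && ratios[i] >= ratios[i + 1])
      return((i - neb_frame) * frame_interval)
  }
  structure(NA_real_, reason = "no local maximum before series end")
}

# Ratio of mask extents along its two principal axes (>= 1).
mask_aspect_ratio <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 2) return(NA_real_)
  xy <- cbind(idx[, 2], idx[, 1])
  xy <- sweep(xy, 2, colMeans(xy))
  ev <- eigen(stats::cov(xy), symmetric = TRUE)$vectors
  proj <- xy %*% ev
  ext <- apply(proj, 2, function(v) diff(range(v)))
  max(ext) / max(min(ext), .Machine$double.eps)
}

#' NEB-aligned nuclear and spindle-region fluorescence dynamics
#'
#' For each of `n_points` frames starting `pre_frames` before NEB (the
#' reference window is 20 points at 5 s, from 15 s before to 80 s after
#' NEB), computes the mean and per-pixel SD of intensity in a nuclear circle
#' (by convention slightly smaller than the nucleus) and in a spindle
#' region (a rectangle bounding the pole-pole axis), plus two derived
#' series: `ratio` (nuclear mean / spindle mean) and `sd_ratio` (nuclear SD
#' / spindle SD). Zero-variance denominators are guarded to 1 and flagged.
#'
#' @param movie a [time_lapse_movie()].
#' @param nucleus_center,nucleus_radius circle in um.
#' @param spindle_xlim,spindle_ylim spindle-region rectangle in um.
#' @param neb_frame 1-based NEB frame index.
#' @param n_points number of frames in the window (default 20).
#' @param pre_frames frames before NEB included (default 3, i.e. -15 s).
#' @return object of class `dynamics_summary`: data.frame `series`
#'   (`t_s`, `nuc_mean`, `nuc_sd`, `spin_mean`, `spin_sd`, `ratio`,
#'   `sd_ratio`, `zero_variance`), `n_replicates = 1`.
#' @export
nuclear_spindle_dynamics <- function(movie, nucleus_center, nucleus_radius,
                                     spindle_xlim, spindle_ylim, neb_frame,
                                     n_points = 20L, pre_frames = 3L) {
  stopifnot(inherits(movie, "time_lapse_movie"))
  if (!roi_in_bounds(movie, nucleus_center, nucleus_radius))
    stop("nucleus circle extends beyond the image bounds")
  d <- dim(movie$frames)[2:3]
  px <- movie$pixel_size
  if (spindle_xlim[1] < 0 || spindle_ylim[1] < 0 ||
      spindle_xlim[2] > (d[2] - 1) * px || spindle_ylim[2] > (d[1] - 1) * px)
    stop("spindle region extends beyond the image bounds")
  first <- neb_frame - pre_frames
  last <- first + n_points - 1L
  if (first < 1L || last > n_frames(movie))
    stop(sprintf("window of %d frames from frame %d does not fit in the movie",
                 n_points, first))
  nmask <- circle_mask(movie, nucleus_center, nucleus_radius)
  smask <- rect_mask(movie, spindle_xlim, spindle_ylim)
  rows <- lapply(first:last, function(i) {
    fm <- frame_matrix(movie, i)
    nv <- fm[nmask]; sv <- fm[smask]
    data.frame(t_s = (i - neb_frame) * movie$frame_interval,
               nuc_mean = mean(nv), nuc_sd = stats::sd(nv),
               spin_mean = mean(sv), spin_sd = stats::sd(sv))
  })
  ser <- do.call(rbind, rows)
  zv <- ser$spin_mean == 0 | ser$spin_sd == 0
  ser$ratio <- ifelse(ser$spin_mean == 0, 1, ser$nuc_mean / ser$spin_mean)
  ser$sd_ratio <- ifelse(ser$spin_sd == 0,
                         ifelse(ser$nuc_sd == 0, 1, NA), ser$nuc_sd / ser$spin_sd)
  ser$zero_variance <- zv
  structure(list(series = ser, n_replicates = 1L), class = "dynamics_summary")
}

#' Aggregate per-embryo dynamics into replicate mean and SEM
#'
#' @param summaries list of `dynamics_summary` objects with equal-length,
#'   identically timed series.
#' @return a `dynamics_summary` whose `series` holds the pointwise replicate
#'   mean of each statistic plus `ratio_sem` and `sd_ratio_sem`
#'   (`NA` for a single replicate); `n_replicates` is recorded.
#' @export
aggregate_replicates <- function(summaries) {
  stopifnot(length(summaries) >= 1,
            all(vapply(summaries, inherits, logical(1), "dynamics_summary")))
  lens <- vapply(summaries, function(s) nrow(s$series), integer(1))
  if (length(unique(lens)) != 1) stop("series length mismatch across replicates")
  tt <- summaries[[1]]$series$t_s
  for (s in summaries)
    if (!isTRUE(all.equal(s$series$t_s, tt)))
      stop("series time points differ across replicates")
  n <- length(summaries)
  pick <- function(col) sapply(summaries, function(s) s$series[[col]])
  agg <- data.frame(t_s = tt)
  for (col in c("nuc_mean", "nuc_sd", "spin_mean", "spin_sd", "ratio", "sd_ratio")) {
    m <- pick(col)
    if (is.null(dim(m))) m <- matrix(m, ncol = n)
    agg[[col]] <- rowMeans(m)
  }
  sem <- function(col) {
    m <- pick(col)
    if (is.null(dim(m))) m <- matrix(m, ncol = n)
    if (n < 2) rep(NA_real_, nrow(m)) else apply(m, 1, stats::sd) / sqrt(n)
  }
  agg$ratio_sem <- sem("ratio")
  agg$sd_ratio_sem <- sem("sd_ratio")
  structure(list(series = agg, n_replicates = n), class = "dynamics_summary")
}

#' @export
print.dynamics_summary <- function(x, ...) {
  cat(sprintf("dynamics_summary: %d time points, %d replicate(s)\n",
              nrow(x$series), x$n_replicates))
  cat(sprintf("  sd_ratio: pre-NEB mean %.3g, post-NEB peak %.3g\n",
              mean(x$series$sd_ratio[x$series$t_s < 0], na.rm = TRUE),
              suppressWarnings(max(x$series$sd_ratio[x$series$t_s >= 0], na.rm = TRUE))))
  invisible(x)
}

#' Post-NEB peak of the nuclear/spindle SD ratio
#'
#' Convenience accessor for the condition-contrast statistic: the maximum of
#' the `sd_ratio` series at t >= 0.
#'
#' @param summary a `dynamics_summary`.
#' @return numeric peak value.
#' @export
sd_ratio_peak <- function(summary) {
  stopifnot(inherits(summary, "dynamics_summary"))
  with(summary$series, max(sd_ratio[t_s >= 0], na.rm = TRUE))
}
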