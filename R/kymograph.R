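#' Kymograph parameters
#'
#' @param gauss_sigma Gaussian filter scale, in kymograph bins (default 3.0,
#'   the reference smoothing applied before Otsu thresholding).
#' @param profile_width number of 1-px-spaced perpendicular offsets averaged
#'   on each side of the pole-pole axis (default 2, i.e. a 5-px-wide band).
#' @param n_space,n_time kymograph bin counts (space x time). The default
#'   time raster (201 bins over a 200-s movie, ~1 s/bin) is finer than the
#'   5-s frame cadence; columns between frames are linearly interpolated, so
#'   the sigma = 3 bin filter smooths over ~3 s rather than 15 s.
#' @return list of class `kymograph_params`.
#' @export
kymograph_params <- function(gauss_sigma = 3.0, profile_width = 2L,
                             n_space = 112L, n_time = 201L) {
  stopifnot(gauss_sigma >= 0, profile_width >= 0, n_space >= 2, n_time >= 2)
  structure(list(gauss_sigma = gauss_sigma, profile_width = profile_width,
                 n_space = as.integer(n_space), n_time = as.integer(n_time)),
            class = "kymograph_params")
}

new_kymograph <- function(matrix, space_extent, time_extent, n_spindles,
                          native_dt = NULL) {
  stopifnot(is.matrix(matrix), nrow(matrix) >= 2, ncol(matrix) >= 2,
            space_extent > 0, time_extent > 0)
  structure(list(matrix = matrix, space_extent = space_extent,
                 time_extent = time_extent, n_spindles = n_spindles,
                 native_dt = native_dt),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("kymograph: %d space bins x %d time bins (%.3g um x %.3g s), %d spindle(s)\n",
              nrow(x$matrix), ncol(x$matrix), x$space_extent, x$time_extent,
              x$n_spindles))
  invisible(x)
}

#' Extract a single-spindle kymograph along the pole-pole axis
#'
#' For every frame, intensity is sampled by bilinear interpolation at
#' `n_space` evenly spaced points along the pole-A-to-pole-B segment and
#' averaged over `profile_width` 1-px perpendicular offsets on each side.
#' Rows are space (pole A at row 1), columns are time. The space axis is the
#' normalised pole-pole axis; `space_extent` records the median physical
#' pole-pole distance.
#'
#' @param movie a [time_lapse_movie()].
#' @param track a [track_poles()] result covering all frames of the movie.
#' @param params a [kymograph_params()].
#' @return a `kymograph` with `n_spindles = 1`.
#' @export
extract_spindle_profile <- function(movie, track, params = kymograph_params()) {
  stopifnot(inherits(movie, "time_lapse_movie"))
  nt <- n_frames(movie)
  if (nrow(track) != nt)
    stop("track and movie cover different numbers of frames")
  S <- params$n_space
  px <- movie$pixel_size
  per_frame <- matrix(0, S, nt)
  frac <- seq(0, 1, length.out = S)
  offs <- if (params$profile_width > 0)
    (-params$profile_width):(params$profile_width) else 0L
  for (i in seq_len(nt)) {
    fm <- frame_matrix(movie, i)
    ax <- track$ax[i] / px; ay <- track$ay[i] / px
    bx <- track$bx[i] / px; by <- track$by[i] / px
    dx <- bx - ax; dy <- by - ay
    len <- sqrt(dx^2 + dy^2)
    if (len == 0) { nxv <- 0; nyv <- 0 } else { nxv <- -dy / len; nyv <- dx / len }
    acc <- numeric(S)
    for (o in offs) {
      xq <- ax + frac * dx + o * nxv
      yq <- ay + frac * dy + o * nyv
      acc <- acc + bilinear_sample(fm, xq, yq)
    }
    per_frame[, i] <- acc / length(offs)
  }
  # resample the per-frame profiles onto the (finer) kymograph time raster
  Tn <- params$n_time
  kym <- matrix(0, S, Tn)
  tq <- seq(1, nt, length.out = Tn)
  f0 <- pmin(floor(tq), nt - 1L); w <- tq - f0
  for (j in seq_len(Tn))
    kym[, j] <- (1 - w[j]) * per_frame[, f0[j]] + w[j] * per_frame[, f0[j] + 1L]
  dist_um <- sqrt((track$bx - track$ax)^2 + (track$by - track$ay)^2)
  new_kymograph(kym, space_extent = stats::median(dist_um),
                time_extent = (nt - 1) * movie$frame_interval, n_spindles = 1L,
                native_dt = movie$frame_interval)
}

#' Composite (average) kymograph over several spindles
#'
#' Element-wise mean of the input matrices after resampling each to a common
#' grid (axis length is already normalised per spindle; matrices of unequal
#' bin counts are resampled bilinearly). The composite's nominal extents
#' default to the reference display convention, 14 um x 200 s. A warning is
#' emitted when the number of contributing spindles is outside the reference
#' range of 6-10.
#'
#' @param kymographs non-empty list of `kymograph` objects.
#' @param space_extent,time_extent nominal extents of the composite grid.
#' @return a `kymograph` with `n_spindles = length(kymographs)`.
#' @export
composite_kymograph <- function(kymographs, space_extent = 14, time_extent = 200) {
  if (!length(kymographs)) stop("need at least one kymograph")
  stopifnot(all(vapply(kymographs, inherits, logical(1), "kymograph")))
  n <- length(kymographs)
  if (n < 6 || n > 10)
    warning(sprintf("composite built from %d spindles (reference range is 6-10)", n))
  dims <- vapply(kymographs, function(k) dim(k$matrix), integer(2))
  S <- dims[1, 1]; Tn <- dims[2, 1]
  mats <- lapply(kymographs, function(k) {
    m <- k$matrix
    if (nrow(m) == S && ncol(m) == Tn) return(m)
    resample_matrix(m, S, Tn)
  })
  acc <- Reduce(`+`, mats) / n
  nds <- unlist(lapply(kymographs, function(k) k$native_dt))
  new_kymograph(acc, space_extent, time_extent, n,
                native_dt = if (length(nds)) max(nds) else NULL)
}

# Bilinear resampling of a matrix onto a new grid (normalised coordinates).
resample_matrix <- function(m, S, Tn) {
  ry <- seq(0, nrow(m) - 1, length.out = S)
  rx <- seq(0, ncol(m) - 1, length.out = Tn)
  out <- matrix(0, S, Tn)
  for (j in seq_len(Tn))
    out[, j] <- bilinear_sample(m, rep(rx[j], S), ry)
  out
}

#' Otsu's threshold
#'
#' Histogram thresholding maximising the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2` over the `n_bins - 1` interior bin edges of an
#' equal-width histogram spanning the data range. Ties are broken by
#' averaging all maximising edges.
#'
#' @param x numeric matrix or vector with at least two distinct values.
#' @param n_bins histogram resolution (default 256).
#' @return the threshold intensity (a bin-edge value).
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  v <- as.numeric(x)
  if (!length(v) || !all(is.finite(v))) stop("input must be finite and non-empty")
  lo <- min(v); hi <- max(v)
  if (lo == hi) stop("cannot threshold a constant image")
  edges <- seq(lo, hi, length.out = n_bins + 1L)[2:n_bins]
  sv <- sort(v)
  cs <- cumsum(sv)
  n <- length(sv)
  total <- cs[n]
  n0 <- findInterval(edges, sv)         # count of values <= edge
  valid <- n0 > 0 & n0 < n
  if (!any(valid)) stop("degenerate histogram: no valid split")
  n0 <- n0[valid]; edges <- edges[valid]
  s0 <- cs[n0]
  w0 <- n0 / n; w1 <- 1 - w0
  m0 <- s0 / n0; m1 <- (total - s0) / (n - n0)
  bcv <- w0 * w1 * (m0 - m1)^2
  best <- max(bcv)
  mean(edges[bcv == best])
}

#' Otsu-level microtubule growth-profile contour of a kymograph
#'
#' Gaussian-filters the kymograph (sigma in bins, edge-replicating borders),
#' computes the Otsu threshold of the filtered matrix and extracts the
#' iso-level contour (marching squares with linear interpolation). The
#' growth front at each time bin is the extent of the contiguous
#' supra-threshold run of space bins starting at the pole (the pole closer
#' to the supra-threshold mass), so signal spreading from the opposite pole
#' cannot short-circuit it. `front_speed` is the least-squares slope of the
#' front position over its rising phase (between 10% and 90% of the front's
#' range, a robust window since the front saturates once it reaches the
#' equator); `flatness = 1 / (1 + |front_speed| * T / space_extent)` maps a
#' static profile to 1 and a fast-growing one towards 0.
#'
#' @param kymo a `kymograph`.
#' @param params a [kymograph_params()] (only `gauss_sigma` is used).
#' @return object of class `growth_profile_contour`: `threshold`, `boundary`
#'   (data.frame `time_s`, `position_um`), `front_position` (um per time
#'   bin, raw), `front_time_s`, `front_speed` (um/s), `flatness`, `pole`
#'   (`"A"` row 1 or `"B"` last row), `fit_window` (time-bin indices used).
#' @export
growth_profile_contour <- function(kymo, params = kymograph_params()) {
  stopifnot(inherits(kymo, "kymograph"))
  fm <- gaussian_blur(kymo$matrix, params$gauss_sigma)
  if (diff(range(fm)) == 0) stop("contour undefined: constant kymograph")
  thr <- otsu_threshold(fm)
  S <- nrow(fm); Tn <- ncol(fm)
  du <- kymo$space_extent / (S - 1)
  dt <- kymo$time_extent / (Tn - 1)
  supra <- fm >= thr
  if (sum(colSums(supra) > 0) < 3)
    stop("contour undefined: fewer than 3 supra-threshold time columns")
  # pole nearer the supra-threshold mass
  idx <- seq_len(S)
  masses <- colSums(supra)
  com <- sum(idx * rowSums(supra)) / max(1, sum(supra))
  from_a <- com <= (S + 1) / 2
  # farthest supra-threshold bin from the pole at each time, restricted to
  # the pole's half-spindle (the opposite pole owns the other half) and
  # requiring the inward neighbour to be supra-threshold too (noise guard)
  half <- ceiling(S / 2)
  farthest <- function(col) {
    v <- if (from_a) col else rev(col)
    v <- v[seq_len(half)]
    ok <- v & c(TRUE, v[-length(v)])
    w <- which(ok)
    if (!length(w)) 0L else w[length(w)]
  }
  front_bins <- apply(supra, 2, farthest)
  front_um <- pmax(0, front_bins - 1) * du
  # marching-squares iso-contour on the filtered matrix (x = time, y = space)
  cl <- grDevices::contourLines(x = seq(0, kymo$time_extent, length.out = Tn),
                                y = seq(0, kymo$space_extent, length.out = S),
                                z = t(fm), levels = thr)
  boundary <- if (length(cl)) {
    do.call(rbind, lapply(cl, function(s)
      data.frame(time_s = s$x, position_um = s$y)))
  } else data.frame(time_s = numeric(0), position_um = numeric(0))
  # rising-phase window: the central 25-75% span of the front's advance
  # (the steep NEB-triggered rise); saturated columns (front pinned near its
  # ceiling once it reaches the equator) are censored, not data
  rng <- range(front_um)
  lo <- rng[1] + 0.15 * diff(rng)
  hi <- rng[1] + 0.85 * diff(rng)
  i_end <- if (any(front_um >= hi)) which(front_um >= hi)[1] else Tn
  sat <- rng[1] + 0.9 * diff(rng)
  i_sat <- if (any(front_um >= sat)) which(front_um >= sat)[1] else Tn
  i_end <- min(i_end, i_sat)
  before <- which(front_um[seq_len(i_end)] <= lo)
  i_start <- if (length(before)) max(before) else 1L
  if (i_end - i_start < 1L) { i_start <- max(1L, i_end - 1L); i_end <- min(Tn, i_start + 1L) }
  win <- i_start:i_end
  # the speed is the least-squares slope of the front position over its
  # rising phase, evaluated at the movie's native frame times: between
  # frames the kymograph columns are intensity cross-fades, and the front
  # position along a cross-fade is an interpolation artefact, not motion
  front_speed <- 0
  if (diff(rng) > 0 && length(win) >= 2 && stats::sd(front_um[win]) > 0) {
    nd <- kymo$native_dt %||% dt
    stride <- max(1L, round(nd / dt))
    native <- seq(1L, Tn, by = stride)
    # prefer native points strictly inside the rising band: the first jump
    # out of the pre-rise plateau carries one-time offsets (comet birth
    # offset, blur lead) that are not front motion
    interior <- native[front_um[native] > lo & front_um[native] < hi &
                         native >= min(win) & native <= max(win)]
    wn <- if (length(interior) >= 2 && stats::sd(front_um[interior]) > 0) {
      interior
    } else {
      native[native >= min(win) - stride / 2 & native <= max(win) + stride / 2]
    }
    if (length(wn) >= 2 && stats::sd(front_um[wn]) > 0) {
      tt <- (wn - 1) * dt
      front_speed <- unname(stats::coef(stats::lm(front_um[wn] ~ tt))[2])
    } else {
      tt <- (win - 1) * dt
      front_speed <- unname(stats::coef(stats::lm(front_um[win] ~ tt))[2])
    }
  }
  flatness <- 1 / (1 + abs(front_speed) * kymo$time_extent / kymo$space_extent)
  structure(list(threshold = thr, boundary = boundary,
                 front_position = front_um,
                 front_time_s = (seq_len(Tn) - 1) * dt,
                 front_speed = front_speed, flatness = flatness,
                 pole = if (from_a) "A" else "B", fit_window = win),
            class = "growth_profile_contour")
}

#' @export
print.growth_profile_contour <- function(x, ...) {
  cat(sprintf(
    "growth-profile contour: threshold %.4g, front speed %.4g um/s, flatness %.3f (pole %s)\n",
    x$threshold, x$front_speed, x$flatness, x$pole))
  invisible(x)
}
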