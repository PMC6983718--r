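#' Detect candidate spindle poles in a single frame
#'
#' Candidates are local maxima of a band-pass (difference-of-Gaussians)
#' filtered frame lying above an intensity threshold, refined to subpixel
#' precision by an intensity-weighted centroid of the above-half-maximum
#' part of the band-passed peak in a small window (recentered once).
#' Coordinates are 0-based pixel indices referring to pixel centers,
#' x right / y down.
#'
#' @param frame 2-d numeric matrix (rows = y, cols = x).
#' @param params list: `sigma_small`, `sigma_large` (DoG scales, px;
#'   defaults 1.5 and 4), `threshold_k` (threshold = mean + k * sd of the
#'   filtered frame; default 4), `refine_radius` (centroid window, px;
#'   default 3), `min_separation` (px between accepted maxima; default 4).
#' @return data.frame `x`, `y`, `intensity` sorted by intensity descending;
#'   zero rows for empty or constant frames.
#' @export
detect_poles <- function(frame, params = list()) {
  stopifnot(is.matrix(frame))
  p <- utils::modifyList(list(sigma_small = 2, sigma_large = 6,
                              threshold_k = 4, refine_radius = 4L,
                              min_separation = 4), params)
  empty <- data.frame(x = numeric(0), y = numeric(0), intensity = numeric(0))
  if (length(frame) == 0 || diff(range(frame)) == 0) return(empty)
  bp <- gaussian_blur(frame, p$sigma_small) - gaussian_blur(frame, p$sigma_large)
  thr <- mean(bp) + p$threshold_k * stats::sd(bp)
  ny <- nrow(bp); nx <- ncol(bp)
  if (ny < 3 || nx < 3) return(empty)
  core <- bp[2:(ny - 1), 2:(nx - 1)]
  is_max <- core > thr
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    is_max <- is_max & core >= bp[2:(ny - 1) + dy, 2:(nx - 1) + dx]
  }
  hits <- which(is_max, arr.ind = TRUE)
  if (nrow(hits) == 0) return(empty)
  cand <- data.frame(y = hits[, 1] + 1, x = hits[, 2] + 1,  # 1-based matrix idx
                     intensity = bp[cbind(hits[, 1] + 1, hits[, 2] + 1)])
  cand <- cand[order(-cand$intensity), ]
  # greedy non-maximum suppression by min_separation
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    d2 <- (cand$x[keep] - cand$x[i])^2 + (cand$y[keep] - cand$y[i])^2
    if (all(d2 >= p$min_separation^2)) keep[i] <- TRUE
  }
  cand <- cand[keep, , drop = FALSE]
  r <- p$refine_radius
  bp_pos <- pmax(bp, 0)
  # subpixel refinement: intensity-weighted centroid of the above-half-max
  # part of the band-passed peak (the half-max cut rejects neighbouring
  # signal such as comet streams), window recentered once
  centroid_pass <- function(cyi, cxi) {
    iy <- max(1, round(cyi) - r):min(ny, round(cyi) + r)
    ix <- max(1, round(cxi) - r):min(nx, round(cxi) + r)
    w <- bp_pos[iy, ix, drop = FALSE]
    w <- pmax(w - 0.5 * max(w), 0)
    sw <- sum(w)
    if (sw == 0) return(c(cxi, cyi))
    c(sum(rep(ix, each = length(iy)) * w) / sw,
      sum(rep(iy, times = length(ix)) * w) / sw)
  }
  out <- lapply(seq_len(nrow(cand)), function(i) {
    c1 <- centroid_pass(cand$y[i], cand$x[i])
    c2 <- centroid_pass(c1[2], c1[1])
    c2 - 1  # matrix index -> 0-based pixel coordinates
  })
  out <- do.call(rbind, out)
  res <- data.frame(x = out[, 1], y = out[, 2], intensity = cand$intensity)
  res[order(-res$intensity), ]
}

#' Track the two spindle poles through a movie
#'
#' Links the two brightest persistent detections frame to frame by
#' minimal-summed-displacement assignment (so pole identities never swap),
#' interpolates gaps of at most `max_gap` frames linearly (flagging them with
#' confidence 0) and aborts on longer gaps.
#'
#' @param movie a [time_lapse_movie()].
#' @param params detection parameters (see [detect_poles()]) plus `max_gap`
#'   (frames, default 2), `max_candidates` considered per frame (default 6)
#'   and `median_window` (odd; running-median smoothing of the linked track,
#'   default 3, `1` disables).
#' @return object of class `spindle_track`: data.frame with `frame`,
#'   `time_s`, `ax`, `ay`, `bx`, `by` (um, subpixel) and `confidence`
#'   (1 detected, 0 interpolated); attributes `pixel_size`, `frame_interval`.
#' @export
track_poles <- function(movie, params = list()) {
  stopifnot(inherits(movie, "time_lapse_movie"))
  p <- utils::modifyList(list(max_gap = 2L, max_candidates = 6L,
                              median_window = 3L, max_move = 3), params)
  nt <- n_frames(movie)
  dets <- lapply(seq_len(nt), function(i)
    detect_poles(frame_matrix(movie, i), p))
  ok <- vapply(dets, function(d) nrow(d) >= 2, logical(1))
  if (!any(ok))
    stop("pole tracking failed: no frame has >= 2 candidate detections")
  if (mean(ok) < 0.8)
    warning(sprintf("only %.0f%% of frames have >= 2 pole candidates", 100 * mean(ok)))
  pos <- matrix(NA_real_, nt, 4)  # ax ay bx by (px)
  first <- which(ok)[1]
  d0 <- dets[[first]]
  pos[first, ] <- c(d0$x[1], d0$y[1], d0$x[2], d0$y[2])
  prev <- pos[first, ]
  gap <- 0L
  for (i in seq_len(nt)[-seq_len(first)]) {
    d <- dets[[i]]
    assigned <- FALSE
    if (nrow(d) >= 2) {
      d <- utils::head(d, p$max_candidates)
      best <- NULL; best_cost <- Inf
      for (ia in seq_len(nrow(d))) for (ib in seq_len(nrow(d))) {
        if (ia == ib) next
        da <- (d$x[ia] - prev[1])^2 + (d$y[ia] - prev[2])^2
        db <- (d$x[ib] - prev[3])^2 + (d$y[ib] - prev[4])^2
        # poles move slowly: candidates jumping further than max_move px
        # per linked frame are transient comet signal, not poles
        lim <- (p$max_move * (gap + 1L))^2
        if (da > lim || db > lim) next
        cost <- da + db
        if (cost < best_cost) { best_cost <- cost; best <- c(ia, ib) }
      }
      if (!is.null(best)) {
        pos[i, ] <- c(d$x[best[1]], d$y[best[1]], d$x[best[2]], d$y[best[2]])
        prev <- pos[i, ]
        gap <- 0L
        assigned <- TRUE
      }
    }
    if (!assigned) {
      gap <- gap + 1L
      if (gap > p$max_gap)
        stop(sprintf("pole tracking aborted: gap longer than %d frames at frame %d",
                     p$max_gap, i))
    }
  }
  conf <- as.numeric(!is.na(pos[, 1]))
  for (j in 1:4) {  # fill leading/internal gaps by linear interpolation
    known <- which(!is.na(pos[, j]))
    pos[, j] <- stats::approx(known, pos[known, j], xout = seq_len(nt),
                              rule = 2)$y
  }
  if (p$median_window > 1) {
    # poles move slowly and smoothly; a 3-frame running median suppresses
    # single-frame localisation glitches (comets crossing a pole) without
    # biasing linear motion
    for (j in 1:4) pos[, j] <- stats::runmed(pos[, j], p$median_window,
                                             endrule = "keep")
  }
  track <- data.frame(frame = seq_len(nt),
                      time_s = frame_times(movie),
                      ax = pos[, 1] * movie$pixel_size,
                      ay = pos[, 2] * movie$pixel_size,
                      bx = pos[, 3] * movie$pixel_size,
                      by = pos[, 4] * movie$pixel_size,
                      confidence = conf)
  structure(track, class = c("spindle_track", "data.frame"),
            pixel_size = movie$pixel_size,
            frame_interval = movie$frame_interval)
}

#' Pole-pole (centrosome-centrosome) distance series
#'
#' @param track a [track_poles()] result (or any data.frame with the same
#'   columns in um).
#' @return object of class `pole_distance_series`: data.frame `time_s`,
#'   `distance_um`.
#' @export
pole_distance_series <- function(track) {
  stopifnot(all(c("time_s", "ax", "ay", "bx", "by") %in% names(track)))
  d <- sqrt((track$bx - track$ax)^2 + (track$by - track$ay)^2)
  structure(data.frame(time_s = track$time_s, distance_um = d),
            class = c("pole_distance_series", "data.frame"))
}

#' Compare two sets of spindle-length measurements
#'
#' Box summaries (median, quartiles, full range) per group and a one-tailed
#' unpaired pooled-variance t-test with alternative `treated < control`
#' (inhibited spindles are expected to be shorter).
#'
#' @param control,treated numeric vectors of pole-pole distances (um), n >= 2.
#' @param alternative direction of the treated-vs-control alternative;
#'   default `"less"`.
#' @return object of class `distance_comparison`: `control`/`treated` box
#'   summaries, `n_control`, `n_treated`, `test` (a `ttest_result`).
#' @export
compare_distance_sets <- function(control, treated, alternative = "less") {
  if (length(control) < 2 || length(treated) < 2)
    stop("need n >= 2 per group")
  structure(list(control = box_summary(control), treated = box_summary(treated),
                 n_control = length(control), n_treated = length(treated),
                 test = one_tailed_unpaired_t(treated, control, alternative)),
            class = "distance_comparison")
}

#' @export
print.distance_comparison <- function(x, ...) {
  cat("Spindle-length comparison (pole-pole distance, um)\n")
  cat("  control: "); print(x$control)
  cat("  treated: "); print(x$treated)
  print(x$test)
  invisible(x)
}
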