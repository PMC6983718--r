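#' Time-lapse movie container
#'
#' A calibrated T x Y x X intensity stack: the substrate of all imaging
#' analyses in this package. Frames are stored as a numeric 3-d array indexed
#' `[frame, y, x]`; coordinates are 0-based pixel indices (x right, y down)
#' referring to pixel centers, and physical positions are `index * pixel_size`.
#'
#' @param frames numeric array `T x Y x X` (or a list of equally sized
#'   matrices, which is stacked).
#' @param pixel_size pixel size in micrometres per pixel.
#' @param frame_interval time between frames in seconds (the reference
#'   acquisition cadence is 5 s).
#' @param dtype_range numeric length-2; representable intensity range
#'   (default 16-bit, `c(0, 65535)`).
#' @return An object of class `time_lapse_movie` with elements `frames`,
#'   `pixel_size`, `frame_interval`, `dtype_range`.
#' @export
time_lapse_movie <- function(frames, pixel_size, frame_interval,
                             dtype_range = c(0, 65535)) {
  if (is.list(frames)) {
    frames <- aperm(simplify2array(frames), c(3, 1, 2))
  }
  stopifnot(is.array(frames), length(dim(frames)) == 3L)
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be > 0")
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be > 0")
  if (min(frames) < dtype_range[1] || max(frames) > dtype_range[2])
    stop("frame intensities fall outside dtype_range")
  structure(
    list(frames = frames, pixel_size = pixel_size,
         frame_interval = frame_interval, dtype_range = dtype_range),
    class = "time_lapse_movie")
}

#' @export
print.time_lapse_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "time_lapse_movie: %d frames of %d x %d px (%.3g um/px, %.3g s/frame, %.0f s total)\n",
    d[1], d[2], d[3], x$pixel_size, x$frame_interval, (d[1] - 1) * x$frame_interval))
  invisible(x)
}

n_frames <- function(movie) dim(movie$frames)[1]

frame_matrix <- function(movie, i) movie$frames[i, , ]

frame_times <- function(movie) (seq_len(n_frames(movie)) - 1) * movie$frame_interval

#' Write a movie as multi-page TIFF with a JSON calibration sidecar
#'
#' One 16-bit page per frame; calibration (and any extra metadata such as
#' ground truth) goes to `<path>.json`.
#'
#' @param movie a [time_lapse_movie()].
#' @param path output TIFF path.
#' @param metadata optional list merged into the sidecar JSON.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(movie, path, metadata = list()) {
  pages <- lapply(seq_len(n_frames(movie)),
                  function(i) frame_matrix(movie, i) / movie$dtype_range[2])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  side <- c(list(pixel_size = movie$pixel_size,
                 frame_interval = movie$frame_interval,
                 dtype_range = movie$dtype_range), metadata)
  jsonlite::write_json(side, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a movie written by [write_movie_tiff()]
#'
#' @param path TIFF path; `<path>.json` must hold the calibration sidecar.
#' @return a [time_lapse_movie()].
#' @export
read_movie_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  rng <- side$dtype_range %||% c(0, 65535)
  frames <- lapply(pages, function(p) round(p * rng[2]))
  time_lapse_movie(frames, side$pixel_size, side$frame_interval, rng)
}
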