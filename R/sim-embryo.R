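#' Configuration for the synthetic embryo movie generator
#'
#' Describes a single mitotic spindle in a syncytial embryo as imaged by
#' spinning-disc confocal microscopy: two centrosomes (spindle poles) moving
#' apart on a horizontal axis, a nuclear disk between them whose fluorescence
#' steps up at nuclear envelope breakdown (NEB), and EB1-like plus-end comets
#' nucleated at the poles as a Poisson process. Before NEB comets emanate
#' radially away from the nucleus; from NEB on they are directed towards the
#' spindle equator. Movies are rendered directly as 2-d projections.
#'
#' The `mora_inhibited` condition differs from `control` only through
#' `inhibition_factors`: a multiplier on comet nucleation rate and speed and
#' an additive uniform nucleoplasmic influx at NEB (modelling EB1 entering
#' the nuclear space without forming comets).
#'
#' @param image_size integer (Y, X) pixels.
#' @param pixel_size micrometres per pixel.
#' @param frame_interval seconds between frames (reference cadence 5 s).
#' @param n_frames number of frames (41 frames at 5 s span 200 s).
#' @param pole_separation_start,pole_separation_end pole-pole distance in um
#'   at the first and last frame (linear in between).
#' @param nucleus_radius um.
#' @param neb_frame 1-based frame index of NEB.
#' @param comet_nucleation_rate comets per second per spindle (split evenly
#'   between the two poles).
#' @param comet_speed um/s.
#' @param comet_lifetime_mean s (exponential lifetimes).
#' @param psf_sigma um; isotropic Gaussian comet/PSF width.
#' @param background_level camera counts.
#' @param noise list with `poisson_gain` (counts per photon; Poisson shot
#'   noise on the signal) and `gaussian_sd` (additive read noise, counts).
#' @param condition `"control"` or `"mora_inhibited"`.
#' @param inhibition_factors list with `nucleation`, `speed` (multipliers
#'   applied in the inhibited condition) and `influx` (additive uniform
#'   nucleoplasmic intensity appearing at NEB in the inhibited condition).
#' @param pole_amplitude,pole_sigma centrosome spot rendering (counts, um).
#' @param comet_amplitude counts.
#' @param neb_influx diffuse nucleoplasmic intensity step at NEB, both
#'   conditions (counts; ramped over 2 frames).
#' @param neb_burst transient multiplier on nucleation for `burst_duration`
#'   seconds after NEB (the radial expansion of comets into the nucleus).
#' @param burst_duration s.
#' @param spindle_fill_amplitude peak diffuse spindle-band intensity as the
#'   mature spindle forms (scaled by the nucleation factor); `spindle_fill_tau`
#'   is its rise time constant (s) and `spindle_fill_sigma` its transverse
#'   width (um).
#' @param comet_jitter_deg angular jitter of post-NEB comet directions.
#' @param comet_birth_offset um; comets initiate this far from the pole
#'   center along their direction (the pericentriolar periphery).
#' @param equator_overlap um; post-NEB comets terminate this far past the
#'   spindle equator (antiparallel-overlap capture at the midzone).
#' @param chromosome_peak_frame frame at which the simulated condensed-
#'   chromosome mask reaches its maximal aspect ratio (for alignment-timing
#'   tests); `NULL` disables mask generation.
#' @return validated list of class `embryo_sim_config`.
#' @export
embryo_sim_config <- function(image_size = c(96L, 96L),
                              pixel_size = 0.2,
                              frame_interval = 5,
                              n_frames = 41L,
                              pole_separation_start = 10,
                              pole_separation_end = 15,
                              nucleus_radius = 4,
                              neb_frame = 10L,
                              comet_nucleation_rate = 8,
                              comet_speed = 0.3,
                              comet_lifetime_mean = 40,
                              psf_sigma = 0.25,
                              background_level = 100,
                              noise = list(poisson_gain = 1, gaussian_sd = 2),
                              condition = c("control", "mora_inhibited"),
                              inhibition_factors = list(nucleation = 0.2,
                                                        speed = 0.2,
                                                        influx = 40),
                              pole_amplitude = 2400,
                              pole_sigma = 0.35,
                              comet_amplitude = 200,
                              neb_influx = 25,
                              neb_burst = 1.5,
                              burst_duration = 25,
                              spindle_fill_amplitude = 60,
                              spindle_fill_tau = 60,
                              spindle_fill_sigma = 1.0,
                              comet_jitter_deg = 6,
                              comet_birth_offset = 1.2,
                              equator_overlap = 0.5,
                              chromosome_peak_frame = neb_frame + 6L) {
  condition <- match.arg(condition)
  cfg <- as.list(environment())
  class(cfg) <- "embryo_sim_config"
  validate_embryo_sim_config(cfg)
  cfg
}

validate_embryo_sim_config <- function(cfg) {
  nonneg <- c("pole_separation_start", "pole_separation_end", "nucleus_radius",
              "comet_nucleation_rate", "comet_speed", "comet_lifetime_mean",
              "psf_sigma", "background_level", "pole_amplitude", "pole_sigma",
              "comet_amplitude", "neb_influx", "burst_duration",
              "spindle_fill_amplitude")
  for (f in nonneg)
    if (cfg[[f]] < 0) stop(sprintf("'%s' must be >= 0", f))
  if (cfg$frame_interval <= 0) stop("frame_interval must be > 0")
  if (cfg$pixel_size <= 0) stop("pixel_size must be > 0")
  if (cfg$n_frames < 1) stop("n_frames must be >= 1")
  if (cfg$neb_frame >= cfg$n_frames) stop("neb_frame must be < n_frames")
  if (cfg$noise$gaussian_sd < 0 || cfg$noise$poisson_gain < 0)
    stop("noise parameters must be >= 0")
  half_x <- (cfg$image_size[2] - 1) / 2 * cfg$pixel_size
  half_y <- (cfg$image_size[1] - 1) / 2 * cfg$pixel_size
  margin <- 3 * cfg$pole_sigma
  if (cfg$pole_separation_end / 2 + margin > half_x ||
      cfg$pole_separation_start / 2 + margin > half_x)
    stop("spindle poles fall outside the image bounds for this image_size")
  if (cfg$nucleus_radius + cfg$pixel_size > min(half_x, half_y))
    stop("nucleus falls outside the image bounds for this image_size")
  invisible(cfg)
}

# Pole positions (um, 0-based pixel-center frame of reference) at frame i.
pole_positions_um <- function(cfg, frames = seq_len(cfg$n_frames)) {
  cx <- (cfg$image_size[2] - 1) / 2 * cfg$pixel_size
  cy <- (cfg$image_size[1] - 1) / 2 * cfg$pixel_size
  t_total <- (cfg$n_frames - 1) * cfg$frame_interval
  tt <- (frames - 1) * cfg$frame_interval
  frac <- if (t_total > 0) tt / t_total else 0
  sep <- cfg$pole_separation_start +
    (cfg$pole_separation_end - cfg$pole_separation_start) * frac
  data.frame(frame = frames, time_s = tt,
             ax = cx - sep / 2, ay = cy,
             bx = cx + sep / 2, by = cy)
}

condition_factors <- function(cfg) {
  if (cfg$condition == "mora_inhibited") {
    list(nucleation = cfg$inhibition_factors$nucleation,
         speed = cfg$inhibition_factors$speed,
         influx = cfg$inhibition_factors$influx)
  } else {
    list(nucleation = 1, speed = 1, influx = 0)
  }
}

# Draw comet birth events for one pole by thinning a homogeneous Poisson
# process; the nucleation rate is per pole and carries a transient burst
# after NEB (the radial comet expansion into the nuclear space). Births are
# drawn from a burn-in of 3 mean lifetimes before frame 1 so the aster is at
# Poisson steady state when the movie starts.
draw_comet_events <- function(cfg, pole, fac) {
  t_end <- (cfg$n_frames - 1) * cfg$frame_interval
  t_neb <- (cfg$neb_frame - 1) * cfg$frame_interval
  t_start <- -3 * cfg$comet_lifetime_mean
  base <- cfg$comet_nucleation_rate / 2 * fac$nucleation
  rate_fun <- function(t) {
    base * ifelse(t >= t_neb & t < t_neb + cfg$burst_duration, cfg$neb_burst, 1)
  }
  rmax <- base * max(1, cfg$neb_burst)
  if (rmax <= 0 || t_end <= t_start) return(numeric(0))
  n <- stats::rpois(1, rmax * (t_end - t_start))
  if (n == 0) return(numeric(0))
  tt <- sort(stats::runif(n, t_start, t_end))
  keep <- stats::runif(n) < rate_fun(tt) / rmax
  tt[keep]
}

# Time at which a straight path leaves the image; used to truncate comet
# lifetimes so every rendered comet stays within bounds.
path_exit_time <- function(x0, y0, vx, vy, xmax, ymax) {
  tx <- if (vx > 0) (xmax - x0) / vx else if (vx < 0) (0 - x0) / vx else Inf
  ty <- if (vy > 0) (ymax - y0) / vy else if (vy < 0) (0 - y0) / vy else Inf
  max(0, min(tx, ty))
}

# Additive Gaussian spot rendered into a local patch (x, y in 0-based px).
add_gaussian_spot <- function(img, x, y, amp, sigma_px) {
  r <- ceiling(3 * sigma_px) + 1L
  ny <- nrow(img); nx <- ncol(img)
  ix <- max(0L, floor(x) - r):min(nx - 1L, ceiling(x) + r)
  iy <- max(0L, floor(y) - r):min(ny - 1L, ceiling(y) + r)
  if (!length(ix) || !length(iy)) return(img)
  gx <- exp(-((ix - x)^2) / (2 * sigma_px^2))
  gy <- exp(-((iy - y)^2) / (2 * sigma_px^2))
  img[iy + 1L, ix + 1L] <- img[iy + 1L, ix + 1L] + amp * outer(gy, gx)
  img
}

#' Simulate a fluorescence time-lapse movie of one embryonic spindle
#'
#' Renders the scene described by [embryo_sim_config()] and applies the
#' camera noise model (Poisson shot noise on the signal, then additive
#' Gaussian read noise, then clipping to the dtype range). Random draws are
#' split into independent streams per entity (comet events per pole, comet
#' kinematics, noise) derived from the master seed, so identical
#' `(config, seed)` pairs give bit-identical movies and changing, say, the
#' noise level does not perturb the comet history.
#'
#' @param config an [embryo_sim_config()].
#' @param seed integer master seed.
#' @return list with `movie` (a [time_lapse_movie()]) and `truth`, the
#'   exported ground truth: `pole_positions` (per-frame um), `comet_tracks`
#'   (birth/death times, origin, velocity), `neb_frame`,
#'   `chromosome_masks` / `chromosome_aspect_ratio` (if enabled) and the
#'   config/condition.
#' @export
simulate_embryo_movie <- function(config, seed) {
  stopifnot(inherits(config, "embryo_sim_config"))
  validate_embryo_sim_config(config)
  cfg <- config
  fac <- condition_factors(cfg)
  ny <- cfg$image_size[1]; nx <- cfg$image_size[2]
  px <- cfg$pixel_size
  t_neb <- (cfg$neb_frame - 1) * cfg$frame_interval
  poles <- pole_positions_um(cfg)
  cx <- (nx - 1) / 2 * px; cy <- (ny - 1) / 2 * px
  xmax <- (nx - 1) * px; ymax <- (ny - 1) * px
  speed <- cfg$comet_speed * fac$speed

  tracks <- list()
  for (pole in c("a", "b")) {
    births <- with_seed(derive_seed(seed, paste0("comet-events-", pole)),
                       draw_comet_events(cfg, pole, fac))
    if (!length(births)) next
    kin <- with_seed(derive_seed(seed, paste0("comet-kinematics-", pole)), {
      list(angle_jitter = stats::runif(length(births), -1, 1),
           pre_angle = stats::runif(length(births), -80, 80),
           life = stats::rexp(length(births), rate = 1 / cfg$comet_lifetime_mean))
    })
    fr <- pmax(1L, pmin(cfg$n_frames, floor(births / cfg$frame_interval) + 1))
    pp <- poles[fr, , drop = FALSE]
    if (pole == "a") {
      x0 <- pp$ax; y0 <- pp$ay; ox <- pp$bx; oy <- pp$by
    } else {
      x0 <- pp$bx; y0 <- pp$by; ox <- pp$ax; oy <- pp$ay
    }
    out_angle <- atan2(y0 - cy, x0 - cx)
    eq_angle <- atan2(oy - y0, ox - x0)
    pre <- births < t_neb
    ang <- ifelse(pre,
                  out_angle + kin$pre_angle * pi / 180,
                  eq_angle + kin$angle_jitter * cfg$comet_jitter_deg * pi / 180)
    vx <- speed * cos(ang); vy <- speed * sin(ang)
    # comets initiate at the pericentriolar periphery, not the centrosome core
    x0 <- pmin(pmax(x0 + cfg$comet_birth_offset * cos(ang), 0), xmax)
    y0 <- pmin(pmax(y0 + cfg$comet_birth_offset * sin(ang), 0), ymax)
    death <- births + kin$life
    if (speed > 0) {
      exit_t <- mapply(path_exit_time, x0, y0, vx, vy,
                       MoreArgs = list(xmax = xmax, ymax = ymax))
      death <- pmin(death, births + exit_t)
      # post-NEB comets are captured shortly past the spindle equator
      eq_x <- if (pole == "a") cx + cfg$equator_overlap else cx - cfg$equator_overlap
      t_eq <- ifelse(!pre & vx != 0, (eq_x - x0) / vx, Inf)
      t_eq[t_eq < 0] <- Inf
      death <- pmin(death, births + t_eq)
    }
    tr <- data.frame(pole = pole, t_birth = births, t_death = death,
                     x0 = x0, y0 = y0, vx = vx, vy = vy)
    tracks[[pole]] <- tr[tr$t_death > 0, , drop = FALSE]  # burn-in survivors only
  }
  comet_tracks <- if (length(tracks)) do.call(rbind, tracks) else
    data.frame(pole = character(0), t_birth = numeric(0), t_death = numeric(0),
               x0 = numeric(0), y0 = numeric(0), vx = numeric(0), vy = numeric(0))
  rownames(comet_tracks) <- NULL

  # nucleus / spindle-band pixel geometry (0-based pixel centers, um)
  xs <- (0:(nx - 1)) * px; ysv <- (0:(ny - 1)) * px
  xg <- matrix(xs, ny, nx, byrow = TRUE)
  yg <- matrix(ysv, ny, nx)
  nuc_mask <- (xg - cx)^2 + (yg - cy)^2 <= cfg$nucleus_radius^2
  band_gauss <- exp(-((yg - cy)^2) / (2 * cfg$spindle_fill_sigma^2))

  frames <- array(0, dim = c(cfg$n_frames, ny, nx))
  for (i in seq_len(cfg$n_frames)) {
    tt <- (i - 1) * cfg$frame_interval
    img <- matrix(cfg$background_level, ny, nx)
    if (tt >= t_neb) {
      ramp <- min(1, (tt - t_neb + cfg$frame_interval) / (2 * cfg$frame_interval))
      img[nuc_mask] <- img[nuc_mask] + (cfg$neb_influx + fac$influx) * ramp
      fill <- cfg$spindle_fill_amplitude * fac$nucleation *
        (1 - exp(-(tt - t_neb) / cfg$spindle_fill_tau))
      inband <- xg >= poles$ax[i] - 1 & xg <= poles$bx[i] + 1
      img[inband] <- img[inband] + fill * band_gauss[inband]
    }
    img <- add_gaussian_spot(img, poles$ax[i] / px, poles$ay[i] / px,
                             cfg$pole_amplitude, cfg$pole_sigma / px)
    img <- add_gaussian_spot(img, poles$bx[i] / px, poles$by[i] / px,
                             cfg$pole_amplitude, cfg$pole_sigma / px)
    alive <- which(comet_tracks$t_birth <= tt & comet_tracks$t_death > tt)
    for (k in alive) {
      dt <- tt - comet_tracks$t_birth[k]
      img <- add_gaussian_spot(img,
                               (comet_tracks$x0[k] + comet_tracks$vx[k] * dt) / px,
                               (comet_tracks$y0[k] + comet_tracks$vy[k] * dt) / px,
                               cfg$comet_amplitude, cfg$psf_sigma / px)
    }
    frames[i, , ] <- img
  }

  frames <- with_seed(derive_seed(seed, "noise"), {
    vals <- as.vector(frames)
    g <- cfg$noise$poisson_gain
    if (g > 0) vals <- stats::rpois(length(vals), vals * g) / g
    if (cfg$noise$gaussian_sd > 0)
      vals <- vals + stats::rnorm(length(vals), 0, cfg$noise$gaussian_sd)
    array(pmin(pmax(round(vals), 0), 65535), dim = dim(frames))
  })

  truth <- list(pole_positions = poles, comet_tracks = comet_tracks,
                neb_frame = cfg$neb_frame, condition = cfg$condition,
                config = cfg)
  if (!is.null(cfg$chromosome_peak_frame)) {
    cm <- simulate_chromosome_masks(cfg, xg, yg, cx, cy)
    truth$chromosome_masks <- cm$masks
    truth$chromosome_aspect_ratio <- cm$ratio
    truth$chromosome_peak_frame <- cfg$chromosome_peak_frame
  }
  list(movie = time_lapse_movie(frames, px, cfg$frame_interval), truth = truth)
}

# Condensed-chromosome masks: an area-preserving ellipse whose X:Y aspect
# ratio ramps from 1 to a planted local maximum at chromosome_peak_frame
# (chromosome congression to the metaphase plate), then relaxes.
simulate_chromosome_masks <- function(cfg, xg, yg, cx, cy) {
  base <- cfg$nucleus_radius / 2
  peak <- cfg$chromosome_peak_frame
  ratio <- rep(1, cfg$n_frames)
  for (i in seq_len(cfg$n_frames)) {
    if (i <= cfg$neb_frame) ratio[i] <- 1
    else if (i <= peak) ratio[i] <- 1 + 1.5 * (i - cfg$neb_frame) / (peak - cfg$neb_frame)
    else ratio[i] <- max(1, 2.5 - 0.15 * (i - peak))
  }
  masks <- vector("list", cfg$n_frames)
  for (i in seq_len(cfg$n_frames)) {
    a <- base * sqrt(ratio[i]); b <- base / sqrt(ratio[i])
    masks[[i]] <- ((xg - cx) / a)^2 + ((yg - cy) / b)^2 <= 1
  }
  list(masks = masks, ratio = ratio)
}
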