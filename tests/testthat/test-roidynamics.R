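test_that("bleach correction inverts a known exponential decay within 1%", {
  t <- (0:40) * 5
  for (tau in c(50, 100, 200)) {
    flat <- rep(800, 41)
    corrected <- bleach_correct(flat * exp(-t / tau), t)
    expect_lt(max(abs(corrected - flat) / flat), 0.01)
    expect_equal(attr(corrected, "tau"), tau, tolerance = 0.05)
  }
})

test_that("bleach correction passes constants through and rejects bad input", {
  x <- rep(5, 10)
  expect_identical(as.numeric(bleach_correct(x)), x)
  expect_error(bleach_correct(c(1, -2, 3)), "positive")
  expect_error(bleach_correct(c(1, NA, 3)), "positive")
})

test_that("NEB is detected at a constructed step and not in flat movies", {
  base <- matrix(100, 48, 48)
  frames <- replicate(20, base, simplify = FALSE)
  mask_step <- spindledyn:::circle_mask(movie_from_frames(frames), c(4.7, 4.7), 2)
  for (i in 12:20) { f <- frames[[i]]; f[mask_step] <- 160; frames[[i]] <- f }
  mv <- movie_from_frames(lapply(seq_along(frames), function(i)
    frames[[i]] + matrix(rnorm(48 * 48, 0, 2), 48, 48) + 10))
  expect_equal(as.integer(detect_neb(mv, c(4.7, 4.7), 2)), 12L)

  flat <- movie_from_frames(lapply(1:15, function(i)
    matrix(100 + rnorm(48 * 48, 0, 2), 48, 48)))
  expect_true(is.na(detect_neb(flat, c(4.7, 4.7), 2)))
  expect_error(detect_neb(mv, c(0.5, 0.5), 2), "bounds")
})

test_that("NEB detection on simulations hits the true frame within one frame", {
  cfg <- embryo_sim_config()
  ctr <- default_nucleus_center(cfg)
  hits <- vapply(1:10, function(s) {
    sim <- simulate_embryo_movie(cfg, s)
    as.numeric(detect_neb(sim$movie, ctr, 0.9 * cfg$nucleus_radius))
  }, numeric(1))
  expect_gte(mean(abs(hits - cfg$neb_frame) <= 1), 0.95)
})

test_that("NEB detection is monotone in influx amplitude", {
  make_mv <- function(amp) {
    base <- matrix(100, 48, 48)
    frames <- replicate(20, base, simplify = FALSE)
    msk <- spindledyn:::circle_mask(movie_from_frames(frames), c(4.7, 4.7), 2)
    for (i in 10:20) {
      f <- frames[[i]]; f[msk] <- f[msk] + amp; frames[[i]] <- f
    }
    set.seed(1)
    movie_from_frames(lapply(frames, function(f)
      f + matrix(rnorm(48 * 48, 0, 2), 48, 48) + 5))
  }
  det <- vapply(c(10, 30, 90), function(a)
    as.numeric(detect_neb(make_mv(a), c(4.7, 4.7), 2)), numeric(1))
  expect_true(all(diff(det) <= 0))
})

test_that("alignment time finds the first local maximum of the X:Y ratio", {
  expect_equal(alignment_time(ratios = c(1.0, 1.2, 1.5, 1.4, 1.3),
                              neb_frame = 1, frame_interval = 5), 10)
  expect_true(is.na(alignment_time(ratios = c(1, 1.2, 1.4, 1.6, 1.8),
                                   neb_frame = 1, frame_interval = 5)))
  sim <- simulate_embryo_movie(embryo_sim_config(), 8)
  at <- alignment_time(masks = sim$truth$chromosome_masks,
                       neb_frame = sim$truth$neb_frame, frame_interval = 5)
  expect_equal(at,
               (sim$truth$chromosome_peak_frame - sim$truth$neb_frame) * 5)
})

test_that("uniform intensity gives ratio one and flagged zero-variance sd_ratio", {
  mv <- movie_from_frames(replicate(25, matrix(50, 60, 60), simplify = FALSE))
  d <- nuclear_spindle_dynamics(mv, c(5.9, 5.9), 2, c(2, 10), c(4, 8),
                                neb_frame = 5)
  expect_true(all(d$series$ratio == 1))
  expect_true(all(d$series$sd_ratio == 1))
  expect_true(all(d$series$zero_variance))
  expect_equal(nrow(d$series), 20)
  expect_equal(d$series$t_s, seq(-15, 80, by = 5))
})

test_that("ratio metrics are scale invariant; sd is offset invariant", {
  cfg <- embryo_sim_config(n_frames = 30L, neb_frame = 8L)
  sim <- simulate_embryo_movie(cfg, 4)
  ctr <- default_nucleus_center(cfg)
  args <- list(nucleus_center = ctr, nucleus_radius = 0.9 * cfg$nucleus_radius,
               spindle_xlim = c(2, 17), spindle_ylim = c(7.5, 11.5),
               neb_frame = 8L)
  d1 <- do.call(nuclear_spindle_dynamics, c(list(sim$movie), args))
  scaled <- time_lapse_movie(sim$movie$frames * 2, cfg$pixel_size, 5,
                             dtype_range = c(0, 2^17))
  d2 <- do.call(nuclear_spindle_dynamics, c(list(scaled), args))
  expect_equal(d2$series$ratio, d1$series$ratio, tolerance = 1e-12)
  expect_equal(d2$series$sd_ratio, d1$series$sd_ratio, tolerance = 1e-12)
  offset <- time_lapse_movie(sim$movie$frames + 500, cfg$pixel_size, 5)
  d3 <- do.call(nuclear_spindle_dynamics, c(list(offset), args))
  expect_equal(d3$series$nuc_sd, d1$series$nuc_sd, tolerance = 1e-12)
  expect_equal(d3$series$sd_ratio, d1$series$sd_ratio, tolerance = 1e-12)
})

test_that("control sd_ratio rises sharply after NEB and then declines", {
  cfg <- embryo_sim_config()
  ctr <- default_nucleus_center(cfg)
  stats_per_seed <- lapply(1:8, function(s) {
    sim <- simulate_embryo_movie(cfg, s)
    tr <- track_poles(sim$movie)
    d <- nuclear_spindle_dynamics(sim$movie, ctr, 0.9 * cfg$nucleus_radius,
                                  range(c(tr$ax, tr$bx)),
                                  c(ctr[2] - 2, ctr[2] + 2),
                                  sim$truth$neb_frame)
    ser <- d$series
    list(pre = mean(ser$sd_ratio[ser$t_s < 0]), peak = sd_ratio_peak(d),
         last = ser$sd_ratio[nrow(ser)])
  })
  ratios <- vapply(stats_per_seed, function(x) x$peak / x$pre, numeric(1))
  expect_gte(median(ratios), 3)
  declines <- vapply(stats_per_seed, function(x) x$last < x$peak, logical(1))
  expect_true(all(declines))
})

test_that("inhibited embryos keep the post-NEB sd_ratio peak below control", {
  cfg_c <- embryo_sim_config(condition = "control")
  cfg_m <- embryo_sim_config(condition = "mora_inhibited")
  ctr <- default_nucleus_center(cfg_c)
  peaks <- function(cfg, s) {
    sim <- simulate_embryo_movie(cfg, s)
    tr <- track_poles(sim$movie)
    sd_ratio_peak(nuclear_spindle_dynamics(
      sim$movie, ctr, 0.9 * cfg$nucleus_radius, range(c(tr$ax, tr$bx)),
      c(ctr[2] - 2, ctr[2] + 2), sim$truth$neb_frame))
  }
  for (s in 1:4) expect_lt(peaks(cfg_m, s), peaks(cfg_c, s))
})

test_that("replicate aggregation averages pointwise with SEM bookkeeping", {
  cfg <- embryo_sim_config(n_frames = 30L, neb_frame = 8L)
  ctr <- default_nucleus_center(cfg)
  one <- function(s) {
    sim <- simulate_embryo_movie(cfg, s)
    nuclear_spindle_dynamics(sim$movie, ctr, 0.9 * cfg$nucleus_radius,
                             c(2, 17), c(7.5, 11.5), 8L)
  }
  d1 <- one(1)
  single <- aggregate_replicates(list(d1))
  expect_equal(single$n_replicates, 1L)
  expect_true(all(is.na(single$series$ratio_sem)))
  copies <- aggregate_replicates(list(d1, d1, d1))
  expect_true(all(copies$series$ratio_sem == 0))
  expect_equal(copies$series$ratio, d1$series$ratio)
  nine <- aggregate_replicates(lapply(1:9, one))
  expect_equal(nine$n_replicates, 9L)
  expect_equal(nine$series$ratio,
               rowMeans(sapply(lapply(1:9, one), function(d) d$series$ratio)))
  short <- d1; short$series <- short$series[1:10, ]
  expect_error(aggregate_replicates(list(d1, short)), "length")
})
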