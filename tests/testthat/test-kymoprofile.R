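test_that("otsu_threshold equals exhaustive brute force on seeded 8-bit images", {
  set.seed(123)
  for (i in 1:20) {
    img <- matrix(sample(0:255, 32 * 32, replace = TRUE), 32, 32)
    expect_identical(otsu_threshold(img), brute_force_otsu(img))
  }
})

test_that("otsu_threshold separates a two-delta histogram and rejects constants", {
  img <- matrix(c(rep(0, 512), rep(255, 512)), 32, 32)
  thr <- otsu_threshold(img)
  expect_true(thr > 0 && thr < 255)
  expect_true(all(img[img <= thr] == 0) && all(img[img > thr] == 255))
  expect_error(otsu_threshold(matrix(7, 8, 8)), "constant")
})

test_that("uniform movies give constant kymograph matrices", {
  mv <- movie_from_frames(replicate(5, matrix(42, 40, 60), simplify = FALSE))
  tr <- data.frame(frame = 1:5, time_s = (0:4) * 5,
                   ax = rep(2, 5), ay = rep(4, 5),
                   bx = rep(10, 5), by = rep(4, 5), confidence = 1)
  ky <- extract_spindle_profile(mv, tr)
  expect_true(all(ky$matrix == 42))
  expect_equal(ky$n_spindles, 1L)
})

test_that("a spot at 30% of the axis peaks at the matching space bin", {
  S <- 112L
  frames <- lapply(1:5, function(i)
    frame_with_spots(40, 60, rbind(c(2 + 0.3 * 40, 20)), amp = 500,
                     sigma = 1.5, background = 0))
  mv <- movie_from_frames(frames)
  tr <- data.frame(frame = 1:5, time_s = (0:4) * 5,
                   ax = rep(2 * 0.2, 5), ay = rep(20 * 0.2, 5),
                   bx = rep(42 * 0.2, 5), by = rep(20 * 0.2, 5),
                   confidence = 1)
  ky <- extract_spindle_profile(mv, tr, kymograph_params(n_space = S))
  peak_bin <- which.max(ky$matrix[, 1])
  expect_lte(abs(peak_bin - round(0.3 * S)), 1)
})

test_that("kymograph time extent follows the acquisition: 41 frames at 5 s = 200 s", {
  cfg <- embryo_sim_config()
  sim <- simulate_embryo_movie(cfg, 2)
  ky <- extract_spindle_profile(sim$movie, track_poles(sim$movie))
  expect_equal(ky$time_extent, 200)
})

test_that("composite of identical kymographs is the identity and averages otherwise", {
  cfg <- embryo_sim_config(n_frames = 8L, neb_frame = 4L)
  sim <- simulate_embryo_movie(cfg, 3)
  ky <- extract_spindle_profile(sim$movie, track_poles(sim$movie))
  comp <- suppressWarnings(composite_kymograph(rep(list(ky), 3)))
  expect_equal(comp$matrix, ky$matrix)
  expect_equal(comp$n_spindles, 3L)
  expect_warning(composite_kymograph(rep(list(ky), 3)), "6-10")
  sims <- lapply(4:9, function(s) {
    sm <- simulate_embryo_movie(cfg, s)
    extract_spindle_profile(sm$movie, track_poles(sm$movie))
  })
  expect_silent(comp6 <- composite_kymograph(sims))
  # direct resample-and-average oracle: same dims, so the composite is the
  # plain element-wise mean
  expect_equal(comp6$matrix,
               Reduce(`+`, lapply(sims, function(k) k$matrix)) / 6)
  expect_equal(comp6$space_extent, 14)
  expect_error(composite_kymograph(list()), "at least one")
})

test_that("a static step kymograph has zero front speed and flatness one", {
  S <- 60L; Tn <- 41L
  m <- matrix(10, S, Tn)
  m[1:18, ] <- 200  # supra region fixed at the first 3 um for all t
  ky <- spindledyn:::new_kymograph(m, space_extent = 10, time_extent = 200,
                                   n_spindles = 1L)
  gp <- growth_profile_contour(ky)
  expect_equal(gp$front_speed, 0)
  expect_equal(gp$flatness, 1)
  expect_true(all(diff(gp$front_position) == 0))
})

test_that("contour geometry is invariant under affine intensity rescaling", {
  cfg <- embryo_sim_config(n_frames = 21L)
  sim <- simulate_embryo_movie(cfg, 6)
  ky <- extract_spindle_profile(sim$movie, track_poles(sim$movie))
  gp1 <- growth_profile_contour(ky)
  ky2 <- ky; ky2$matrix <- 3.5 * ky$matrix + 40
  gp2 <- growth_profile_contour(ky2)
  expect_equal(gp2$threshold, 3.5 * gp1$threshold + 40, tolerance = 1e-8)
  expect_equal(gp2$front_position, gp1$front_position, tolerance = 1e-8)
  expect_equal(gp2$front_speed, gp1$front_speed, tolerance = 1e-6)
})

test_that("contour extraction rejects degenerate kymographs", {
  m <- matrix(5, 30, 30)
  ky <- spindledyn:::new_kymograph(m, 10, 200, 1L)
  expect_error(growth_profile_contour(ky), "constant")
})

test_that("front speed recovers the comet speed on control simulations", {
  errs <- vapply(1:6, function(s) {
    v <- 0.25 + 0.05 * (s %% 3)
    sim <- simulate_embryo_movie(embryo_sim_config(comet_speed = v), s)
    gp <- growth_profile_contour(
      extract_spindle_profile(sim$movie, track_poles(sim$movie)))
    abs(gp$front_speed - v) / v
  }, numeric(1))
  expect_lt(median(errs), 0.15)
})

test_that("inhibited spindles give flatter growth profiles than controls", {
  for (s in 1:4) {
    g <- lapply(c("control", "mora_inhibited"), function(cond) {
      sim <- simulate_embryo_movie(embryo_sim_config(condition = cond), s)
      growth_profile_contour(
        extract_spindle_profile(sim$movie, track_poles(sim$movie)))
    })
    expect_gt(g[[1]]$front_speed, g[[2]]$front_speed)
    expect_gt(g[[2]]$flatness, g[[1]]$flatness)
  }
})
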