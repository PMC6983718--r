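# Independent oracles used across the suite. These deliberately use naive,
# direct computations (loops, full enumeration, closed forms) so they share
# no code path with the implementation they check.

# Exhaustive Otsu: evaluate the between-class variance at every interior bin
# edge by partitioning the actual data, and average tied maximisers.
brute_force_otsu <- function(x, n_bins = 256L) {
  v <- as.numeric(x)
  lo <- min(v); hi <- max(v)
  edges <- seq(lo, hi, length.out = n_bins + 1L)[2:n_bins]
  best <- -Inf; winners <- numeric(0)
  n <- length(v)
  for (e in edges) {
    left <- v[v <= e]; right <- v[v > e]
    n0 <- length(left)
    if (n0 == 0 || n0 == n) next
    w0 <- n0 / n; w1 <- 1 - w0
    m0 <- sum(left) / n0; m1 <- sum(right) / (n - n0)
    bcv <- w0 * w1 * (m0 - m1)^2
    if (bcv > best) { best <- bcv; winners <- e }
    else if (bcv == best) winners <- c(winners, e)
  }
  mean(winners)
}

# Naive per-record re-evaluation of the AP-MS keep rules.
brute_force_apms_keep <- function(records, control_db, params) {
  ctrl <- stats::setNames(control_db$control_score, control_db$protein_id)
  kept <- character(0)
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    ok <- r$unique_peptides >= params$min_unique_peptides &&
      r$coverage_pct >= params$min_coverage_pct &&
      r$ms_score >= params$min_ms_score
    if (ok && r$protein_id %in% names(ctrl)) {
      ok <- r$ms_score >= params$control_fold * unname(ctrl[[r$protein_id]])
    }
    if (ok) kept <- c(kept, r$protein_id)
  }
  sort(kept)
}

# One-tailed pooled-variance t-test p-value by numerical integration of the
# t density (independent of pt / t.test).
integrate_t_pvalue <- function(x, y, alternative = "less") {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  df <- nx + ny - 2
  dens <- function(u) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + u^2 / df)^(-(df + 1) / 2)
  }
  if (alternative == "less") {
    stats::integrate(dens, -Inf, tstat, rel.tol = 1e-12)$value
  } else {
    stats::integrate(dens, tstat, Inf, rel.tol = 1e-12)$value
  }
}

# Monte-Carlo permutation p-value for the one-tailed comparison, returned
# with its binomial standard error.
permutation_t_pvalue <- function(x, y, alternative = "less", B = 1e5L) {
  z <- c(x, y); z2 <- z^2
  nx <- length(x); n <- length(z)
  Sz <- sum(z); Szz <- sum(z2)
  tstat_from_sel <- function(sx, sxx) {
    ny <- n - nx
    mx <- sx / nx; my <- (Sz - sx) / ny
    vx <- (sxx - nx * mx^2) / (nx - 1)
    vy <- ((Szz - sxx) - ny * my^2) / (ny - 1)
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (n - 2)
    (mx - my) / sqrt(sp2 * (1 / nx + 1 / ny))
  }
  t_obs <- tstat_from_sel(sum(x), sum(x^2))
  hits <- 0L
  for (b in seq_len(B)) {
    sel <- sample.int(n, nx)
    t_b <- tstat_from_sel(sum(z[sel]), sum(z2[sel]))
    if (alternative == "less") {
      if (t_b <= t_obs) hits <- hits + 1L
    } else {
      if (t_b >= t_obs) hits <- hits + 1L
    }
  }
  p <- hits / B
  list(p = p, se = sqrt(p * (1 - p) / B))
}

# RMS pole-position error in pixels against ground truth, minimised over
# the two possible pole-label pairings (labels are arbitrary).
pole_rms_px <- function(track, gt, pixel_size) {
  e1 <- mean(((track$ax - gt$ax)^2 + (track$ay - gt$ay)^2 +
                (track$bx - gt$bx)^2 + (track$by - gt$by)^2) / 2)
  e2 <- mean(((track$ax - gt$bx)^2 + (track$ay - gt$by)^2 +
                (track$bx - gt$ax)^2 + (track$by - gt$ay)^2) / 2)
  sqrt(min(e1, e2)) / pixel_size
}

# Mean-squared error (um^2) variant used for pooled RMS across seeds.
pole_mse_um2 <- function(track, gt) {
  e1 <- mean(((track$ax - gt$ax)^2 + (track$ay - gt$ay)^2 +
                (track$bx - gt$bx)^2 + (track$by - gt$by)^2) / 2)
  e2 <- mean(((track$ax - gt$bx)^2 + (track$ay - gt$by)^2 +
                (track$bx - gt$ax)^2 + (track$by - gt$ay)^2) / 2)
  min(e1, e2)
}

# Small synthetic frame with Gaussian spots at given 0-based positions.
frame_with_spots <- function(ny, nx, spots, amp = 1000, sigma = 2,
                             background = 10) {
  img <- matrix(background, ny, nx)
  xs <- matrix(0:(nx - 1), ny, nx, byrow = TRUE)
  ys <- matrix(0:(ny - 1), ny, nx)
  for (i in seq_len(nrow(spots))) {
    img <- img + amp * exp(-((xs - spots[i, 1])^2 + (ys - spots[i, 2])^2) /
                             (2 * sigma^2))
  }
  img
}

# Movie wrapper around a list of frames with default calibration.
movie_from_frames <- function(frames, pixel_size = 0.2, frame_interval = 5) {
  time_lapse_movie(frames, pixel_size, frame_interval)
}

default_nucleus_center <- function(cfg = embryo_sim_config()) {
  c((cfg$image_size[2] - 1) / 2, (cfg$image_size[1] - 1) / 2) * cfg$pixel_size
}
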