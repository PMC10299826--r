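test_that("per-frame speeds are exact finite differences", {
  fps <- 240
  n <- 100
  still <- trajectory(t = (0:(n - 1)) / fps, x = rep(0.5, n), y = rep(0.4, n))
  expect_equal(traj_speeds(still), rep(0, n - 1))

  # uniform motion at 0.5 m/s along x
  mov <- trajectory(t = (0:(n - 1)) / fps,
                    x = 0.1 + (0:(n - 1)) * 0.5 / fps, y = rep(0.4, n))
  expect_equal(traj_speeds(mov), rep(0.5, n - 1), tolerance = 1e-12)
  expect_length(traj_speeds(mov), n - 1)

  expect_error(traj_speeds(trajectory(0, 0.1, 0.1, fps = 240)), "2 frames")
  expect_error(trajectory(c(0, 0.1, 0.05), 1:3, 1:3), "increasing")
  expect_error(trajectory(c(0, 0.1, 0.3), 1:3, 1:3), "uniform")
})

test_that("visit segmentation finds dwell episodes and excludes edge grazes", {
  lay <- fixture_layout()
  fps <- 240

  # a path that never comes within the focal radius: no segments
  far <- trajectory((0:499) / fps, x = seq(0, 1, length.out = 500),
                    y = rep(0.1, 500))
  expect_equal(nrow(segment_visits(far, lay)), 0L)

  # dwell 2 s at the first stimulus centre
  dwell_frames <- 2 * fps
  xs <- c(seq(0.05, 0.299, length.out = 200), rep(0.30, dwell_frames),
          seq(0.301, 0.6, length.out = 200))
  dwell <- trajectory((seq_along(xs) - 1) / fps, xs, rep(0.40, length(xs)))
  segs <- segment_visits(dwell, lay)
  inside <- segs[segs$stimulus_id == "S100" & !segs$excluded, ]
  expect_equal(nrow(inside), 1L)
  expect_gte(inside$hover_time, 2)

  # a 0.1 s graze clipping the focal rim is excluded
  graze_y <- lay$y[1] + lay$focal_radius[1] - 0.002
  n_in <- round(0.1 * fps)
  gx <- c(seq(0.1, 0.24, length.out = 100),
          seq(0.25, 0.35, length.out = n_in),
          seq(0.36, 0.5, length.out = 100))
  graze <- trajectory((seq_along(gx) - 1) / fps, gx, rep(graze_y, length(gx)))
  gsegs <- segment_visits(graze, lay)
  expect_true(nrow(gsegs) >= 1)
  expect_true(all(gsegs$excluded))
})

test_that("segment durations conserve the analysed time", {
  lay <- fixture_layout()
  gen <- generate_trajectory(trajectory_spec(
    lay, data.frame(stimulus_id = c("S100", "S0"),
                    intent = c("accept", "reject"))), seed = 2)
  traj <- gen$trajectory
  segs <- segment_visits(traj, lay)
  fps <- attr(traj, "fps")
  in_frames <- sum(segs$end_frame - segs$start_frame + 1L)
  # every frame is either inside some focal area (counted once here,
  # the layout's focal areas are disjoint) or outside
  dist1 <- sqrt((traj$x - lay$x[1])^2 + (traj$y - lay$y[1])^2)
  dist2 <- sqrt((traj$x - lay$x[2])^2 + (traj$y - lay$y[2])^2)
  expect_equal(in_frames,
               sum(dist1 <= lay$focal_radius[1]) +
                 sum(dist2 <= lay$focal_radius[2]))
  expect_equal(in_frames / fps + (nrow(traj) - in_frames) / fps,
               nrow(traj) / fps)
})

test_that("exact 1-D two-means matches the exhaustive-partition oracle", {
  expect_equal(two_means_threshold(c(0.01, 0.02, 0.40, 0.45))$threshold, 0.22)
  expect_equal(two_means_threshold(c(0, 1))$threshold, 0.5)
  expect_error(two_means_threshold(rep(0.3, 5)), "distinct")
  expect_error(two_means_threshold(0.3), "distinct")

  # naive oracle: recompute every contiguous split's WCSS directly
  oracle <- function(x) {
    x <- sort(x)
    w <- vapply(seq_len(length(x) - 1), function(i) {
      lo <- x[1:i]; hi <- x[-(1:i)]
      sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    }, numeric(1))
    i <- which.min(w)
    (mean(x[1:i]) + mean(x[-(1:i)])) / 2
  }
  set.seed(31)
  for (n in c(2, 3, 5, 17, 60, 200)) {
    x <- c(stats::rnorm(ceiling(n / 2), 0.05, 0.02),
           stats::rnorm(floor(n / 2), 0.4, 0.05))[1:n]
    x <- pmax(x, 0)
    if (length(unique(x)) < 2) next
    expect_equal(two_means_threshold(x)$threshold, oracle(x),
                 tolerance = 1e-12)
  }

  # planted bimodal mixture: every label recovered by the threshold
  lab <- rep(c("low", "high"), each = 50)
  sp <- c(stats::rnorm(50, 0.02, 0.004), stats::rnorm(50, 0.35, 0.04))
  thr <- two_means_threshold(sp)$threshold
  expect_identical(ifelse(sp < thr, "low", "high"), lab)
})

test_that("visit classification respects the threshold and exclusions", {
  segs <- data.frame(
    stimulus_id = c("S100", "S0", "S100"),
    start_frame = c(1, 100, 200), end_frame = c(50, 120, 210),
    duration = c(0.5, 0.21, 0.04), hover_time = c(0.5, 0.21, 0.04),
    mean_speed = c(0.01, 0.40, 0.30), median_speed = c(0.01, 0.40, 0.30),
    excluded = c(FALSE, FALSE, TRUE)
  )
  cls <- classify_visits(segs, threshold = 0.22)
  expect_equal(cls$classification, c("accept", "reject", "excluded"))

  ev <- visits_to_events(cls, high_stimulus = "S100", bee_id = 9)
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$category, c("CA", "CR"))
  expect_equal(attr(ev, "n_excluded"), 1L)
  expect_equal(ev$response_time, c(0.5, 0.21))
  expect_error(visits_to_events(cls, high_stimulus = "S77"), "not among")

  # reject on the higher-ranked colour becomes an incorrect rejection
  cls2 <- cls
  cls2$mean_speed[1] <- 0.4
  cls2 <- classify_visits(cls2, 0.22)
  expect_equal(visits_to_events(cls2, "S100")$category, c("IR", "CR"))
})

test_that("classification is invariant to rotation and translation", {
  lay <- fixture_layout()
  plan <- data.frame(stimulus_id = c("S100", "S0", "S100"),
                     intent = c("accept", "reject", "reject"))
  gen <- generate_trajectory(trajectory_spec(lay, plan), seed = 4)
  traj <- gen$trajectory

  classify_all <- function(traj, lay) {
    segs <- segment_visits(traj, lay)
    thr <- two_means_threshold(segs$mean_speed[!segs$excluded])$threshold
    classify_visits(segs, thr)$classification
  }
  base <- classify_all(traj, lay)

  # rotate by 30 degrees about the arena centre and translate
  th <- pi / 6; shift <- c(0.35, -0.2)
  rot <- function(x, y) {
    cbind(cos(th) * x - sin(th) * y + shift[1],
          sin(th) * x + cos(th) * y + shift[2])
  }
  pxy <- rot(traj$x, traj$y)
  lxy <- rot(lay$x, lay$y)
  traj2 <- trajectory(traj$t, pxy[, 1], pxy[, 2], fps = attr(traj, "fps"))
  lay2 <- stimulus_layout(lay$stimulus_id, lxy[, 1], lxy[, 2])
  expect_identical(classify_all(traj2, lay2), base)
})
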