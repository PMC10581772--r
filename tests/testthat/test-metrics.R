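nest <- generate_nest_map()

test_that("bins under the minimum-detection rule keep only observed time", {
  det <- detections_fixture(t = 9 * 3600 + (0:8) / 3,
                            x = rep(20, 9), y = rep(35, 9))
  m <- compute_bin_metrics(det, nest, "1 min")
  expect_equal(nrow(m), 1)
  expect_equal(m$time_observed, 3)        # 9 detections at 3 fps
  expect_true(is.na(m$speed))
  expect_true(is.na(m$time_on_brood))
  expect_true(is.na(m$dispersion))
  expect_true(is.na(m$exit_distance))
})

test_that("a bee sitting on one point has zero speed, zero dispersion, one visited cell", {
  det <- detections_fixture(t = 9 * 3600 + (0:29) / 3,
                            x = rep(20, 30), y = rep(35, 30))
  m <- compute_bin_metrics(det, nest, "1 min")
  expect_equal(m$speed, 0)
  expect_equal(m$dispersion, 0)
  nx <- ceiling(nest$width_cm / 2.5); ny <- ceiling(nest$height_cm / 2.5)
  expect_equal(m$nest_visited, 1 / (2 * nx * ny))
  expect_equal(m$time_on_brood, 1)        # (20, 35) is mid-frame
  expect_equal(m$time_on_honey + m$time_on_brood + m$time_on_exit_frame, 1)
})

test_that("speed follows 3 fps kinematics: 1 cm in 1/3 s is 3 cm/s", {
  det <- detections_fixture(t = 9 * 3600 + c(0, 1 / 3),
                            x = c(20, 21), y = c(35, 35))
  m <- compute_bin_metrics(det, nest, "1 min", min_detections = 2)
  expect_equal(m$speed, 3, tolerance = 1e-6)
})

test_that("pairs with gaps over the speed threshold are excluded", {
  # second pair has a 5 s hole: only the two 1/3 s pairs may count
  t <- 9 * 3600 + c(0, 1 / 3, 1 / 3 + 5, 1 / 3 + 5 + 1 / 3)
  det <- detections_fixture(t = t, x = c(0, 1, 30, 31) + 5,
                            y = rep(35, 4))
  m <- compute_bin_metrics(det, nest, "1 min", min_detections = 2)
  expect_equal(m$speed, 3, tolerance = 1e-6)
})

test_that("dispersion equals the brute-force RMS distance from the centroid", {
  set.seed(12)
  x <- runif(50, 5, 45); y <- runif(50, 5, 70)
  det <- detections_fixture(t = 9 * 3600 + (0:49) / 3, x = x, y = y)
  m <- compute_bin_metrics(det, nest, "1 min")
  oracle <- sqrt(mean((x - mean(x))^2 + (y - mean(y))^2))
  expect_equal(m$dispersion, oracle, tolerance = 1e-12)
  expect_equal(m$exit_distance,
               median(sqrt((x - nest$exit_point[["x"]])^2 +
                             (y - nest$exit_point[["y"]])^2)),
               tolerance = 1e-12)
})

test_that("unsorted detections are a hard error", {
  det <- detections_fixture(t = 9 * 3600 + c(1, 0), x = c(1, 2) + 4,
                            y = c(35, 35))
  unsorted <- as.data.frame(det)[c(2, 1), ]
  expect_error(compute_bin_metrics(unsorted, nest), "sorted")
})

test_that("frame fractions always partition on non-null bins", {
  run <- small_run()
  m1 <- run$m1
  ok <- !is.na(m1$time_on_honey)
  expect_true(any(ok))
  expect_equal(m1$time_on_honey[ok] + m1$time_on_brood[ok] +
                 m1$time_on_exit_frame[ok], rep(1, sum(ok)),
               tolerance = 1e-9)
})

test_that("raising the detection-count threshold never increases non-null bins", {
  run <- small_run()
  det_day <- run$det[as.Date(timestamp, tz = "UTC") == as.Date("2019-08-22")]
  det_day <- det_day[bee_id %in% unique(bee_id)[1:6]]
  counts <- sapply(c(5, 10, 20, 50), function(th) {
    m <- compute_bin_metrics(det_day, run$nest, "1 min",
                             min_detections = th)
    sum(!is.na(m$dispersion))
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("exit inference follows the two-threshold rule", {
  # disappearance near the exit -> exit
  m <- presence_fixture(time_observed = c(60, 1), exit_distance = c(10, NA))
  p <- infer_presence(m)
  expect_equal(p$exit_event, c(FALSE, TRUE))
  expect_equal(p$outside, c(FALSE, TRUE))

  # disappearance far from the exit -> occlusion, not exit
  m <- presence_fixture(time_observed = c(60, 0), exit_distance = c(30, NA))
  p <- infer_presence(m)
  expect_equal(sum(p$exit_event), 0)
  expect_equal(p$outside, c(FALSE, FALSE))

  # no previous-bin distance (filtered bin) -> treated as inside
  m <- presence_fixture(time_observed = c(1, 0), exit_distance = c(NA, NA))
  expect_equal(sum(infer_presence(m)$exit_event), 0)
})

test_that("the full automaton resolves one trip with re-entry", {
  m <- presence_fixture(time_observed = c(60, 1, 0, 0, 30, 60),
                        exit_distance = c(5, NA, NA, NA, 40, 12))
  p <- infer_presence(m)
  expect_equal(which(p$exit_event), 2)
  expect_equal(which(p$outside), c(2, 3, 4))
  expect_equal(which(p$enter_event), 5)
  expect_equal(sum(p$exit_event), 1)
})

test_that("presence inference rejects non-1-min input", {
  m <- presence_fixture(time_observed = c(60, 1), exit_distance = c(10, NA))
  data.table::setattr(m, "bin_size", 300)
  expect_error(infer_presence(m), "1-min")
})

test_that("aggregation combines children as detection-weighted means", {
  start <- as.POSIXct("2019-08-23 09:00:00", tz = "UTC")
  m <- presence_fixture(time_observed = rep(20, 60),
                        exit_distance = rep(10, 60))
  m[, `:=`(speed = NA_real_, n_detections = 60L)]
  m[1:2, speed := c(2, 4)]

  # all children flagged outside
  pres_out <- data.table::data.table(
    bee_id = 1L, bin_start = m$bin_start, outside = TRUE,
    exit_event = FALSE, enter_event = FALSE)
  agg <- aggregate_metrics(m, pres_out, "1 hour")
  expect_equal(agg$time_outside, 1)

  # equal-weight children -> plain mean of the non-null speeds
  pres_in <- data.table::copy(pres_out)[, outside := FALSE]
  agg <- aggregate_metrics(m, pres_in, "1 hour")
  expect_equal(agg$speed, 3)
  expect_equal(agg$time_outside, 0)
  expect_equal(agg$n_outside_trips, 0L)

  # flagging more bins outside never decreases time_outside
  pres_some <- data.table::copy(pres_in)[1:10, outside := TRUE]
  pres_more <- data.table::copy(pres_in)[1:25, outside := TRUE]
  expect_gte(aggregate_metrics(m, pres_more, "1 hour")$time_outside,
             aggregate_metrics(m, pres_some, "1 hour")$time_outside)
})

test_that("hourly averaging tracks direct recomputation from raw detections", {
  run <- small_run()
  det_day <- run$det[as.Date(timestamp, tz = "UTC") == as.Date("2019-08-22")]
  direct <- compute_bin_metrics(det_day, run$nest, "1 hour")
  m1 <- compute_bin_metrics(det_day, run$nest, "1 min")
  pres <- infer_presence(m1)
  avg <- aggregate_metrics(m1, pres, "1 hour")
  j <- merge(avg, direct, by = c("bee_id", "bin_start"),
             suffixes = c("_avg", "_direct"))
  ok <- !is.na(j$speed_avg) & !is.na(j$speed_direct) & j$n_detections_avg > 500
  expect_true(sum(ok) > 10)
  rel <- abs(j$speed_avg[ok] - j$speed_direct[ok]) / j$speed_direct[ok]
  expect_lt(max(rel), 0.05)
})

test_that("full-detection bees with no trips are never flagged outside", {
  cfg <- sim_config(n_bees = 8, detection_prob = 1, day_window = c(9, 10.5),
                    rng_seed = 3)
  nest2 <- generate_nest_map(cfg)
  col <- generate_colony(cfg, nest2)
  col$exit_propensity <- 0
  day <- simulate_day(col, nest2, "2019-08-22", FALSE, cfg)
  m1 <- compute_bin_metrics(day$detections, nest2, "1 min")
  p <- infer_presence(m1)
  expect_equal(sum(p$exit_event), 0)
  expect_equal(sum(p$outside), 0)
})
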