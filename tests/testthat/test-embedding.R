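# random but realistic-looking complete hourly metric rows
random_metric_rows <- function(n, seed = 1) {
  set.seed(seed)
  f1 <- runif(n); f2 <- runif(n, 0, 1 - f1)
  data.frame(time_on_honey = f1, time_on_brood = f2,
             time_on_exit_frame = 1 - f1 - f2,
             exit_distance = runif(n, 2, 80),
             time_observed = runif(n, 100, 3600),
             time_outside = rbeta(n, 1, 8),
             n_outside_trips = rpois(n, 0.5),
             speed = rlnorm(n, -0.5, 0.4),
             dispersion = rlnorm(n, 1, 0.4),
             nest_visited = rbeta(n, 2, 10))
}

two_day_schedule <- data.frame(
  date = as.Date(c("2019-08-23", "2019-08-25")), kind = "stress",
  stress_start = 10, stress_end = 13)

test_that("the behavioural matrix has one row per complete bee-day-hour, z-scored", {
  rows <- random_metric_rows(8)
  hm <- data.table::rbindlist(list(
    hourly_fixture(rows[1:2, ], 1:2, "2019-08-23", 9),
    hourly_fixture(rows[3:4, ], 1:2, "2019-08-23", 12),
    hourly_fixture(rows[5:6, ], 1:2, "2019-08-25", 9),
    hourly_fixture(rows[7:8, ], 1:2, "2019-08-25", 12)))
  bm <- build_behaviour_matrix(hm, two_day_schedule)
  expect_equal(dim(bm$matrix), c(8, 10))
  expect_equal(unname(colMeans(bm$matrix)), rep(0, 10), tolerance = 1e-9)
  expect_equal(unname(apply(bm$matrix, 2, sd)), rep(1, 10),
               tolerance = 1e-9)
  expect_equal(sort(unique(bm$info$hour_label)), c("heat", "morning"))

  # a row with a missing metric is excluded and counted
  hm2 <- data.table::copy(hm)
  hm2[1, speed := NA_real_]
  expect_message(bm2 <- build_behaviour_matrix(hm2, two_day_schedule),
                 "1 row")
  expect_equal(nrow(bm2$matrix), 7)
  expect_equal(bm2$dropped_rows, 1L)
})

test_that("zero-variance columns are dropped with a warning", {
  rows <- random_metric_rows(6)
  rows$time_outside <- 0              # nobody ever outside
  hm <- hourly_fixture(rows, 1:6, "2019-08-23", 9)
  expect_warning(bm <- build_behaviour_matrix(hm, two_day_schedule),
                 "time_outside")
  expect_false("time_outside" %in% bm$metrics)
  expect_equal(ncol(bm$matrix), 9)
})

test_that("matrix row count equals an independent tally of complete bee-hours", {
  run <- small_run()
  m1h <- run$m1h
  stress_day <- as.Date("2019-08-23")
  tally <- sum(sapply(c(9, 12), function(h) {
    sel <- m1h[bin_start == as.POSIXct(paste(stress_day, "00:00:00"),
                                       tz = "UTC") + h * 3600]
    sum(complete.cases(as.data.frame(sel)[, run$bm$metrics]))
  }))
  expect_equal(nrow(run$bm$matrix), tally)
})

test_that("PCA fractions sum to one, components are orthonormal, ordering non-increasing", {
  set.seed(31)
  bm <- make_bm(matrix(rnorm(200 * 6), 200, 6))
  p <- behaviour_pca(bm)
  expect_equal(sum(p$variance_fractions), 1, tolerance = 1e-9)
  expect_true(all(diff(p$variance_fractions) <= 1e-12))
  gram <- crossprod(p$rotation)
  expect_lt(max(abs(gram - diag(ncol(gram)))), 1e-9)
})

test_that("two perfectly correlated columns put all variance on one component", {
  set.seed(5)
  x <- rnorm(100)
  p <- behaviour_pca(make_bm(cbind(a = x, b = 2 * x + 3)))
  expect_equal(p$variance_fractions, c(1, 0), tolerance = 1e-12)
})

test_that("two-column PCA matches the closed-form correlation eigenvalues", {
  set.seed(6)
  X <- cbind(a = rnorm(500), b = rnorm(500))
  X[, "b"] <- 0.6 * X[, "a"] + sqrt(1 - 0.36) * X[, "b"]
  rho <- cor(X[, 1], X[, 2])
  p <- behaviour_pca(make_bm(X))
  expect_equal(p$variance_fractions, c((1 + rho) / 2, (1 - rho) / 2),
               tolerance = 1e-9)
})

test_that("the frame-fraction partition forces a numerically zero final component", {
  rows <- random_metric_rows(300, seed = 44)
  hm <- hourly_fixture(rows, 1:300, "2019-08-23", 9)
  bm <- build_behaviour_matrix(hm, two_day_schedule)
  p <- behaviour_pca(bm)
  expect_lt(min(p$variance_fractions), 1e-12)
})

test_that("projections are row-order invariant up to the sign convention", {
  set.seed(19)
  X <- matrix(rnorm(60 * 5), 60, 5)
  bm1 <- make_bm(X)
  perm <- sample(60)
  bm2 <- make_bm(X[perm, ])
  p1 <- behaviour_pca(bm1)
  p2 <- behaviour_pca(bm2)
  expect_equal(abs(p2$projections), abs(p1$projections[perm, ]),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("ward clustering separates distant clouds exactly and respects k bounds", {
  set.seed(77)
  X <- rbind(matrix(rnorm(40, 0, 0.1), 20, 2),
             matrix(rnorm(40, 50, 0.1), 20, 2))
  bm <- make_bm(X)
  cl <- ward_cluster(bm, k = 2)
  expect_equal(length(unique(cl$labels$label[1:20])), 1)
  expect_equal(length(unique(cl$labels$label[21:40])), 1)
  expect_false(cl$labels$label[1] == cl$labels$label[40])

  singletons <- ward_cluster(bm, k = 40)
  expect_equal(sort(unique(singletons$labels$label)), 1:40)
  expect_error(ward_cluster(bm, k = 41), "rows")

  expect_true(all(diff(cl$tree$height) >= -1e-9))  # merge monotonicity
})

test_that("ward merge sequence matches the exhaustive minimum-variance oracle", {
  set.seed(88)
  for (rep in 1:10) {
    n <- sample(4:8, 1)
    X <- matrix(rnorm(n * 3), n, 3)
    tree <- stats::hclust(dist(X), method = "ward.D2")
    expect_identical(hclust_merge_sets(tree), brute_ward(X))
  }
})

test_that("clusters are named by their dominant metric", {
  rows <- random_metric_rows(60, seed = 9)
  rows$time_on_brood[1:20] <- 0.95
  rows$time_on_honey[1:20] <- 0.03
  rows$time_on_exit_frame[1:20] <- 0.02
  rows$time_on_honey[21:40] <- 0.95
  rows$time_on_brood[21:40] <- 0.03
  rows$time_on_exit_frame[21:40] <- 0.02
  rows$time_on_honey[41:60] <- 0.3
  rows$time_on_brood[41:60] <- 0.3
  rows$time_on_exit_frame[41:60] <- 0.4
  rows$time_outside[41:60] <- 0.8
  hm <- hourly_fixture(rows, 1:60, "2019-08-23", 9)
  bm <- build_behaviour_matrix(hm, two_day_schedule)
  cl <- ward_cluster(bm, "morning", k = 3)
  desc <- describe_clusters(cl, bm)
  brood_cluster <- cl$labels$label[1]
  expect_equal(unname(desc$names[as.character(brood_cluster)]), "brood")
  outside_cluster <- cl$labels$label[41]
  expect_equal(unname(desc$names[as.character(outside_cluster)]),
               "going outside")
  expect_null(desc$ages)   # no age table supplied

  ages <- data.frame(bee_id = 1:60, age = runif(60, 1, 30))
  desc2 <- describe_clusters(cl, bm, ages)
  expect_equal(nrow(desc2$ages), 3)
})

test_that("cluster recovery: planted groups are found with high agreement", {
  cfg <- sim_config(
    n_bees = 45, day_window = c(8.9, 10.05), rng_seed = 17,
    sim_days = data.frame(date = as.Date("2019-08-23"), is_stress = TRUE),
    group_proportions = c(brood = 1 / 3, honey = 1 / 3, exit = 1 / 3,
                          outside = 0, diffuse = 0))
  ex <- simulate_experiment(cfg)
  det <- suppressMessages(filter_detections(ex$detections, 0.8))
  m1 <- compute_bin_metrics(det, ex$nest, "1 min")
  pres <- infer_presence(m1)
  m1h <- aggregate_metrics(m1, pres, "1 hour")
  bm <- suppressWarnings(suppressMessages(
    build_behaviour_matrix(m1h, make_schedule(cfg), hours = c(morning = 9))))
  cl <- ward_cluster(bm, "morning", k = 3)
  truth <- ex$profiles$group[match(cl$labels$bee_id, ex$profiles$bee_id)]
  ari <- mclust::adjustedRandIndex(cl$labels$label, truth)
  expect_gte(ari, 0.9)
})
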