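# Shared fixtures: all built in code, cached per test session so the
# heavier simulations run once.

.cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .cache)) assign(name, force(expr), envir = .cache)
  get(name, envir = .cache)
}

# A small two-day (control + stress) colony covering 8.00-14.00, reduced
# through the metrics stack. Used by embedding / correlation / pipeline
# tests.
small_run <- function() {
  cached("small_run", {
    cfg <- sim_config(
      n_bees = 24, day_window = c(8, 14),
      sim_days = data.frame(date = as.Date(c("2019-08-22", "2019-08-23")),
                            is_stress = c(FALSE, TRUE)),
      rng_seed = 11L)
    ex <- simulate_experiment(cfg)
    det <- suppressMessages(filter_detections(ex$detections, 0.8))
    m1 <- compute_bin_metrics(det, ex$nest, "1 min")
    pres <- infer_presence(m1)
    m1h <- aggregate_metrics(m1, pres, "1 hour")
    m5 <- aggregate_metrics(m1, pres, "5 min")
    bm <- suppressMessages(build_behaviour_matrix(m1h, ex$schedule))
    c(ex, list(config = cfg, det = det, m1 = m1, presence = pres,
               m1h = m1h, m5 = m5, bm = bm))
  })
}

# Hand-built 1-min metrics table for the exit/entry automaton: only the
# columns the automaton reads are meaningful.
presence_fixture <- function(time_observed, exit_distance,
                             bee_id = 1L,
                             start = as.POSIXct("2019-08-23 09:00:00",
                                                tz = "UTC")) {
  n <- length(time_observed)
  m <- data.table::data.table(
    bee_id = bee_id, bin_start = start + 60 * (seq_len(n) - 1),
    n_detections = as.integer(time_observed * 3),
    time_on_honey = NA_real_, time_on_brood = NA_real_,
    time_on_exit_frame = NA_real_, exit_distance = exit_distance,
    time_observed = time_observed, time_outside = NA_real_,
    n_outside_trips = NA_integer_, speed = NA_real_,
    dispersion = NA_real_, nest_visited = NA_real_)
  data.table::setattr(m, "bin_size", 60)
  data.table::setkey(m, bee_id, bin_start)
  m
}

# Synthetic detection-table builder for metric unit tests.
detections_fixture <- function(t, x, y, bee_id = 1L, side = 0L,
                               confidence = 0.95,
                               day = "2019-08-23") {
  d <- data.table::data.table(
    bee_id = bee_id,
    timestamp = as.POSIXct(paste(day, "00:00:00"), tz = "UTC") + t,
    x_cm = x, y_cm = y, side = side, orientation_rad = 0,
    confidence = confidence)
  data.table::setkey(d, bee_id, timestamp)
  d
}

# Minimal behaviour_matrix wrapper around an arbitrary numeric matrix
# (z-scored per column), for PCA / clustering tests that do not need the
# full metrics stack.
make_bm <- function(X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("m", seq_len(ncol(X)))
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  Z <- sweep(sweep(X, 2, center), 2, scale, "/")
  info <- data.table::data.table(bee_id = seq_len(nrow(X)),
                                 date = as.Date("2019-08-23"),
                                 hour_label = "morning")
  structure(list(matrix = Z, info = info, center = center, scale = scale,
                 metrics = colnames(Z), dropped_rows = 0L,
                 dropped_cols = character()),
            class = "behaviour_matrix")
}

# A complete synthetic hourly-metrics table: `rows` is a data.frame of
# metric values; timestamps place every row at the given clock hour.
hourly_fixture <- function(rows, bee_id, date, hour) {
  m <- data.table::data.table(
    bee_id = bee_id,
    bin_start = as.POSIXct(paste(date, "00:00:00"), tz = "UTC") +
      hour * 3600,
    n_detections = 10000L)
  for (cn in names(rows)) m[, (cn) := rows[[cn]]]
  data.table::setattr(m, "bin_size", 3600)
  data.table::setkey(m, bee_id, bin_start)
  m
}

# Exhaustive Ward agglomerator: at each step evaluates every pair merge and
# picks the one with the smallest increase in total within-cluster sum of
# squares (ties: lowest pair index). Returns the ordered list of merged
# member sets — the independent oracle for ward_cluster().
brute_ward <- function(X) {
  ss <- function(idx) {
    if (length(idx) == 1L) return(0)
    Xs <- X[idx, , drop = FALSE]
    sum(sweep(Xs, 2, colMeans(Xs))^2)
  }
  clusters <- as.list(seq_len(nrow(X)))
  merges <- vector("list", nrow(X) - 1L)
  for (step in seq_len(nrow(X) - 1L)) {
    best <- NULL; best_d <- Inf
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        d <- ss(c(clusters[[i]], clusters[[j]])) -
          ss(clusters[[i]]) - ss(clusters[[j]])
        if (d < best_d - 1e-12) { best_d <- d; best <- c(i, j) }
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merges[[step]] <- merged
    clusters[[best[1]]] <- merged
    clusters <- clusters[-best[2]]
  }
  merges
}

# Member sets merged at each step of an hclust tree, comparable to
# brute_ward() output.
hclust_merge_sets <- function(tree) {
  n <- nrow(tree$merge) + 1L
  sets <- vector("list", n - 1L)
  for (s in seq_len(n - 1L)) {
    members <- function(id) {
      if (id < 0) -id else sets[[id]]
    }
    sets[[s]] <- sort(c(members(tree$merge[s, 1]),
                        members(tree$merge[s, 2])))
  }
  sets
}

# The reference in-silico study: a 40-bee colony over three full recording
# days (control, heat-stress, unperturbed follow-up), reduced through the
# entire analysis stack. Cached: several acceptance checks share it.
study_run <- function() {
  cached("study_run", {
    cfg <- sim_config(
      n_bees = 40,
      sim_days = data.frame(
        date = as.Date(c("2019-08-22", "2019-08-23", "2019-08-24")),
        is_stress = c(FALSE, TRUE, FALSE)),
      rng_seed = 7L)
    nest <- generate_nest_map(cfg)
    profiles <- generate_colony(cfg, nest)
    m1 <- list(); pres <- list()
    for (d in seq_len(nrow(cfg$sim_days))) {
      day <- simulate_day(profiles, nest, cfg$sim_days$date[d],
                          cfg$sim_days$is_stress[d], cfg)
      det <- suppressMessages(filter_detections(day$detections, 0.8))
      m1d <- compute_bin_metrics(det, nest, "1 min")
      m1[[d]] <- m1d
      pres[[d]] <- infer_presence(m1d)
    }
    m1 <- data.table::rbindlist(m1)
    data.table::setattr(m1, "bin_size", 60)
    presence <- data.table::rbindlist(pres)
    m1h <- aggregate_metrics(m1, presence, "1 hour")
    m5 <- aggregate_metrics(m1, presence, "5 min")
    schedule <- make_schedule(cfg)
    schedule$kind[3] <- "other"   # follow-up day: grid only, not compared
    bm <- suppressMessages(build_behaviour_matrix(m1h, schedule))
    list(config = cfg, nest = nest, profiles = profiles,
         schedule = schedule, m1h = m1h, m5 = m5, bm = bm,
         pca = behaviour_pca(bm))
  })
}

# The component carrying the general-activity signature: among components
# retained by the Kaiser rule (variance fraction above that of one input
# metric), the one with the largest squared weight on speed, dispersion
# and fraction of nest visited, oriented so those weights are net
# positive.
activity_axis <- function(pca) {
  act <- c("speed", "dispersion", "nest_visited")
  keep <- which(pca$variance_fractions >= 1 / length(pca$variance_fractions))
  load2 <- colSums(pca$rotation[act, keep, drop = FALSE]^2)
  comp <- keep[which.max(load2)]
  sgn <- sign(sum(pca$rotation[act, comp]))
  list(component = comp, projections = sgn * pca$projections[, comp])
}
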