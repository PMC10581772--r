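#' Simulation configuration for a synthetic tagged-bee colony
#'
#' Builds the configuration object consumed by [generate_nest_map()],
#' [generate_colony()] and [simulate_day()]. Defaults emulate the recording
#' conditions of a three-frame observation hive filmed at 3 frames per
#' second, with an ambient heat stress applied between 10.00 and 13.00 on
#' stress days. Planted behavioural groups (brood-area, honey-area,
#' exit-area, outside-going, diffuse) give downstream clustering something
#' real to recover.
#'
#' @param n_bees Number of tagged bees in the colony.
#' @param sim_days Data frame with columns `date` (coercible to `Date`) and
#'   `is_stress` (logical). Each row is one simulated day.
#' @param frame_rate Camera frame rate in detections per second.
#' @param stress_window Numeric length-2, start/end of the heat stress in
#'   hours of the day (default `c(10, 13)`).
#' @param day_window Numeric length-2, hours of the day actually simulated
#'   (default `c(0, 24)`, the full recording day). Narrow this to simulate
#'   only the hours an analysis needs.
#' @param group_proportions Named fractions over the five planted groups
#'   `brood`, `honey`, `exit`, `outside`, `diffuse`; must sum to 1.
#' @param age_means_per_group Named mean ages (days) per group. Brood bees
#'   are youngest and exit/outside-going bees oldest by default, mirroring
#'   honeybee age polyethism.
#' @param detection_prob Per-frame probability that an in-nest bee's tag is
#'   decoded (detection dropout).
#' @param heat_effects List with `speed_multiplier`, `dispersion_multiplier`,
#'   `relocation_target` (`"honey"` or `NA` for none), and
#'   `exit_rate_multiplier`. Applied only inside the stress window on
#'   stress days.
#' @param rng_seed Integer master seed; all randomness derives from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_bees = 200,
                       sim_days = data.frame(
                         date = as.Date(c("2019-08-22", "2019-08-23")),
                         is_stress = c(FALSE, TRUE)),
                       frame_rate = 3,
                       stress_window = c(10, 13),
                       day_window = c(0, 24),
                       group_proportions = c(brood = 0.30, honey = 0.20,
                                             exit = 0.15, outside = 0.15,
                                             diffuse = 0.20),
                       age_means_per_group = c(brood = 6, honey = 14,
                                               exit = 24, outside = 28,
                                               diffuse = 18),
                       detection_prob = 0.8,
                       heat_effects = list(speed_multiplier = 2,
                                           dispersion_multiplier = 1.5,
                                           relocation_target = "honey",
                                           exit_rate_multiplier = 3),
                       rng_seed = 1L) {
  if (abs(sum(group_proportions) - 1) > 1e-9)
    stop("group_proportions must sum to 1", call. = FALSE)
  if (detection_prob < 0 || detection_prob > 1)
    stop("detection_prob must lie in [0, 1]", call. = FALSE)
  if (frame_rate <= 0) stop("frame_rate must be positive", call. = FALSE)
  if (n_bees < 0) stop("n_bees must be non-negative", call. = FALSE)
  sim_days$date <- as.Date(sim_days$date)
  if (anyDuplicated(sim_days$date)) stop("sim_days dates must be unique",
                                         call. = FALSE)
  stopifnot(length(stress_window) == 2, stress_window[1] < stress_window[2],
            length(day_window) == 2, day_window[1] < day_window[2])
  groups <- c("brood", "honey", "exit", "outside", "diffuse")
  if (!setequal(names(group_proportions), groups))
    stop("group_proportions must be named over: ",
         paste(groups, collapse = ", "), call. = FALSE)
  cfg <- list(n_bees = as.integer(n_bees), sim_days = sim_days,
              frame_rate = frame_rate, stress_window = stress_window,
              day_window = day_window,
              group_proportions = group_proportions[groups],
              age_means_per_group = age_means_per_group[groups],
              detection_prob = detection_prob, heat_effects = heat_effects,
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "sim_config"
  cfg
}

# Hive geometry: a two-sided 49.0 x 74.2 cm comb area per side (origin at
# the top-left, x rightward, y downward), three equal-height frames stacked
# honey / brood / exit from top to bottom, nest entrance at the lower right
# of the exit frame.
HIVE_WIDTH_CM <- 49.0
HIVE_HEIGHT_CM <- 74.2

rect_poly <- function(x0, y0, x1, y1) {
  matrix(c(x0, y0, x1, y0, x1, y1, x0, y1), ncol = 2, byrow = TRUE,
         dimnames = list(NULL, c("x", "y")))
}

#' Generate the two-sided nest-content map
#'
#' Partitions each hive side into three equal-height frames (honey on top,
#' brood in the middle, exit at the bottom) and overlays content sub-regions
#' (honey stores, brood nest, pollen band, empty comb) with a peripheral
#' catch-all. The nest entrance sits at the lower right of the exit frame on
#' side 0.
#'
#' @param config A [sim_config()] object (geometry is currently fixed, the
#'   argument is accepted for forward compatibility).
#' @return A list of class `nest_map` with elements `width_cm`, `height_cm`,
#'   `frames` (y-bands), `regions` (per-side ordered polygon list) and
#'   `exit_point`.
#' @export
generate_nest_map <- function(config = sim_config()) {
  W <- HIVE_WIDTH_CM; H <- HIVE_HEIGHT_CM
  b <- H / 3
  frames <- data.frame(frame = c("honey", "brood", "exit"),
                       y_min = c(0, b, 2 * b), y_max = c(b, 2 * b, H))
  one_side <- function(side) {
    list(
      list(side = side, region = "honey", frame = "honey",
           poly = rect_poly(4, 3, W - 4, b - 3)),
      list(side = side, region = "brood", frame = "brood",
           poly = rect_poly(10, b + 4, W - 10, 2 * b - 4)),
      list(side = side, region = "pollen", frame = "brood",
           poly = rect_poly(4, b + 4, 10, 2 * b - 4)),
      list(side = side, region = "pollen", frame = "brood",
           poly = rect_poly(W - 10, b + 4, W - 4, 2 * b - 4)),
      list(side = side, region = "empty_comb", frame = "exit",
           poly = rect_poly(4, 2 * b + 3, W - 4, H - 6))
    )
  }
  nest <- list(width_cm = W, height_cm = H, frames = frames,
               regions = c(one_side(0L), one_side(1L)),
               exit_point = c(x = W - 4, y = H - 3, side = 0))
  class(nest) <- "nest_map"
  nest
}

#' Look up frame and content region for nest positions
#'
#' Vectorised point lookup against a [generate_nest_map()] map. Frames are
#' half-open horizontal bands (top edge inclusive, the bottom hive edge
#' closed), so every interior point maps to exactly one frame. Content
#' regions are matched in stored order, first match wins; points inside a
#' frame but outside every content polygon get region `"periphery"`.
#'
#' @param nest A `nest_map`.
#' @param x,y Numeric position vectors in cm.
#' @param side Integer side indicator (0 or 1), recycled if length 1.
#' @return A data.frame with columns `frame` and `region`; out-of-bounds
#'   points get the sentinel `"out_of_bounds"` in both columns.
#' @export
locate_points <- function(nest, x, y, side = 0L) {
  stopifnot(inherits(nest, "nest_map"), length(x) == length(y))
  side <- as.integer(rep_len(side, length(x)))
  oob <- is.na(x) | is.na(y) | x < 0 | x > nest$width_cm |
    y < 0 | y > nest$height_cm | !(side %in% c(0L, 1L))
  band <- findInterval(y, c(nest$frames$y_min, nest$height_cm),
                       rightmost.closed = TRUE)
  band[band < 1L] <- NA_integer_
  band[band > 3L] <- NA_integer_
  frame <- nest$frames$frame[band]
  region <- rep(NA_character_, length(x))
  for (s in c(0L, 1L)) {
    idx <- which(!oob & side == s)
    if (length(idx) == 0L) next
    unmatched <- idx
    for (reg in nest$regions) {
      if (reg$side != s || length(unmatched) == 0L) next
      hit <- point_in_polygon(x[unmatched], y[unmatched], reg$poly)
      region[unmatched[hit]] <- reg$region
      unmatched <- unmatched[!hit]
    }
    region[unmatched] <- "periphery"
  }
  frame[oob] <- "out_of_bounds"
  region[oob] <- "out_of_bounds"
  data.frame(frame = frame, region = region, stringsAsFactors = FALSE)
}

# Sample a uniform point inside an axis-aligned region polygon.
sample_in_region <- function(nest, region_name, side, n = 1L) {
  polys <- Filter(function(r) r$region == region_name && r$side == side,
                  nest$regions)
  if (length(polys) == 0L) stop("no region named ", region_name)
  p <- polys[[1L]]$poly
  cbind(x = stats::runif(n, min(p[, 1]), max(p[, 1])),
        y = stats::runif(n, min(p[, 2]), max(p[, 2])))
}

#' Generate the colony of bee profiles
#'
#' Draws one profile per bee: planted behavioural group, age, home centre,
#' home scale (spatial spread of its mean-reverting walk), base walking
#' speed and an outside-trip rate. Group counts follow
#' `config$group_proportions` by largest-remainder rounding, exit and
#' outside-going bees live near the nest entrance, and brood bees are the
#' youngest group by construction.
#'
#' @param config A [sim_config()].
#' @param nest A `nest_map`, defaulting to [generate_nest_map()].
#' @return A data.frame of class `bee_profiles`, one row per bee, with
#'   columns `bee_id`, `group`, `age`, `home_x`, `home_y`, `side`,
#'   `home_scale`, `base_speed`, `exit_propensity`.
#' @export
generate_colony <- function(config, nest = generate_nest_map(config)) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_bees
  groups <- names(config$group_proportions)
  if (n == 0L) {
    out <- data.frame(bee_id = integer(), group = character(),
                      age = numeric(), home_x = numeric(), home_y = numeric(),
                      side = integer(), home_scale = numeric(),
                      base_speed = numeric(), exit_propensity = numeric())
    class(out) <- c("bee_profiles", "data.frame")
    return(out)
  }
  # largest-remainder allocation of group counts
  target <- config$group_proportions * n
  counts <- floor(target)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(target - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  group <- rep(groups, times = counts)

  with_seed(derive_seed(config$rng_seed, 101L), {
    ex <- nest$exit_point
    home_x <- home_y <- numeric(n)
    side <- integer(n)
    home_scale <- numeric(n)
    for (i in seq_len(n)) {
      g <- group[i]
      if (g == "brood") {
        s <- sample(c(0L, 1L), 1L)
        p <- sample_in_region(nest, "brood", s)
        home_scale[i] <- 3
      } else if (g == "honey") {
        s <- sample(c(0L, 1L), 1L)
        p <- sample_in_region(nest, "honey", s)
        home_scale[i] <- 3
      } else if (g == "exit") {
        # at exact radius r up-left of the entrance, inside the exit frame
        s <- 0L
        r <- stats::runif(1, 1, 8); a <- stats::runif(1, pi, 1.5 * pi)
        p <- cbind(x = ex["x"] + r * cos(a), y = ex["y"] + r * sin(a))
        home_scale[i] <- 3.5
      } else if (g == "outside") {
        s <- 0L
        r <- stats::runif(1, 3, 14); a <- stats::runif(1, pi, 1.5 * pi)
        p <- cbind(x = ex["x"] + r * cos(a), y = ex["y"] + r * sin(a))
        home_scale[i] <- 4
      } else {
        s <- sample(c(0L, 1L), 1L)
        p <- cbind(x = stats::runif(1, 4, nest$width_cm - 4),
                   y = stats::runif(1, 4, nest$height_cm - 4))
        home_scale[i] <- 10
      }
      home_x[i] <- min(max(p[1, 1], 0.5), nest$width_cm - 0.5)
      home_y[i] <- min(max(p[1, 2], 0.5), nest$height_cm - 0.5)
      side[i] <- s
    }
    home_scale <- home_scale * stats::rlnorm(n, 0, 0.15)
    age_mean <- config$age_means_per_group[group]
    age <- pmax(1, stats::rnorm(n, age_mean, 0.25 * age_mean))
    # walking speed co-varies with role: brood workers are the most
    # active in-nest group, honey-store bees the least
    speed_mean <- c(brood = 0.8, honey = 0.45, exit = 0.55,
                    outside = 0.7, diffuse = 0.6)[group]
    base_speed <- unname(speed_mean) * stats::rlnorm(n, 0, 0.15)
    # entrance-area workers make short excursions often enough that the
    # time-outside metric carries real between-bee variance; deep-nest
    # workers almost never leave
    exit_propensity <- c(brood = 0.02, honey = 0.02, exit = 0.6,
                         outside = 1.5, diffuse = 0.02)[group]
    out <- data.frame(bee_id = seq_len(n), group = group, age = age,
                      home_x = home_x, home_y = home_y, side = side,
                      home_scale = home_scale, base_speed = base_speed,
                      exit_propensity = unname(exit_propensity))
    class(out) <- c("bee_profiles", "data.frame")
    out
  })
}

# AR(1) coefficient and per-step innovation sd that give a mean-reverting
# walk with target mean step speed `speed` (cm/s) and stationary spatial
# spread `scale` (cm) at the given frame rate. Mean 2-D step length of an
# isotropic Gaussian step with per-coordinate sd s is s*sqrt(pi/2).
ou_params <- function(speed, scale, frame_rate) {
  s <- speed / (frame_rate * sqrt(pi / 2))
  if (s >= scale) {
    list(phi = 0, s = scale)   # white-noise limit: spread caps the speed
  } else {
    list(phi = sqrt(1 - (s / scale)^2), s = s)
  }
}

# Piecewise AR(1) deviation series: `phase` is an integer vector over ticks
# selecting rows of `pars` (list of lists with phi, s); d0 is the initial
# deviation. Uses stats::filter for the recursion.
ar1_series <- function(phase, pars, d0) {
  n <- length(phase)
  out <- numeric(n)
  runs <- rle(phase)
  pos <- 1L
  prev <- d0
  for (k in seq_along(runs$lengths)) {
    len <- runs$lengths[k]
    p <- pars[[runs$values[k]]]
    idx <- pos:(pos + len - 1L)
    if (p$s == 0 && p$phi == 1) {
      out[idx] <- prev
    } else {
      e <- stats::rnorm(len, 0, p$s)
      out[idx] <- stats::filter(e, p$phi, method = "recursive",
                                init = prev)
    }
    prev <- out[idx[len]]
    pos <- pos + len
  }
  out
}

# Outside-trip intervals for one bee over [t0, t1) seconds-of-day, by a
# thinned Poisson exit process with rate `base_rate` (per second) scaled by
# `mult(t)` inside the stress window, and exponential trip durations with
# the given mean (s).
draw_trips <- function(t0, t1, base_rate, stress_lo, stress_hi, mult,
                       mean_trip = 600) {
  if (base_rate <= 0) return(matrix(numeric(0), ncol = 2))
  rmax <- base_rate * max(1, mult)
  trips <- list()
  t <- t0
  repeat {
    t <- t + stats::rexp(1, rmax)
    if (t >= t1) break
    rate_t <- base_rate * if (t >= stress_lo && t < stress_hi) mult else 1
    if (stats::runif(1) < rate_t / rmax) {
      dur <- stats::rexp(1, 1 / mean_trip)
      trips[[length(trips) + 1L]] <- c(t, min(t + dur, t1))
      t <- t + dur
      if (t >= t1) break
    }
  }
  if (length(trips) == 0L) matrix(numeric(0), ncol = 2)
  else do.call(rbind, trips)
}

#' Simulate one day of detections and temperature logging
#'
#' Each bee follows a mean-reverting random walk around its home centre,
#' emitting a detection per camera frame with probability
#' `config$detection_prob` while inside the nest and never while on an
#' outside trip. On stress days, inside the stress window, walk speed and
#' spatial spread are multiplied by the configured heat effects, brood-area
#' and diffuse bees drift toward the honey stores (home centre
#' linearly interpolated over 30 simulated minutes, restored after the
#' window), and the exit rate is boosted in proportion to a bee's exit
#' proximity and age. A four-sensor temperature log (room, honey, brood,
#' exit frame) at one-minute resolution tracks the stress.
#'
#' @param profiles A `bee_profiles` data frame from [generate_colony()].
#' @param nest A `nest_map`.
#' @param date The simulated date (coercible to `Date`).
#' @param is_stress Logical, whether the stress window applies.
#' @param config A [sim_config()].
#' @return A list with `detections` (data.table: `bee_id`, `timestamp`
#'   POSIXct UTC, `x_cm`, `y_cm`, `side`, `orientation_rad`, `confidence`),
#'   `temperature` (data.table: `sensor`, `timestamp`, `temp_c`), and
#'   `trips` (true outside intervals, for validation).
#' @export
simulate_day <- function(profiles, nest, date, is_stress, config) {
  stopifnot(inherits(config, "sim_config"))
  date <- as.Date(date)
  fr <- config$frame_rate
  w <- config$day_window
  sw <- config$stress_window * 3600
  he <- config$heat_effects
  n_ticks <- as.integer(round((w[2] - w[1]) * 3600 * fr))
  secs <- w[1] * 3600 + (seq_len(n_ticks) - 1) / fr
  stress_on <- is_stress & secs >= sw[1] & secs < sw[2]
  phase <- ifelse(stress_on, 2L, 1L)
  day0 <- as.POSIXct(paste0(format(date), " 00:00:00"), tz = "UTC")
  day_seed <- derive_seed(config$rng_seed, as.integer(date))

  relocating <- is_stress && !is.na(he$relocation_target %||% NA)
  # ramp factor for home relocation: 0 -> 1 over the first 30 min of the
  # window, held, then back to 0 over 30 min after the window ends
  ramp <- if (relocating) {
    up <- pmin(pmax((secs - sw[1]) / 1800, 0), 1)
    down <- pmin(pmax((secs - sw[2]) / 1800, 0), 1)
    up * (1 - down)
  } else rep(0, n_ticks)

  rows <- vector("list", nrow(profiles))
  trips_out <- vector("list", nrow(profiles))
  ex <- nest$exit_point

  with_seed(day_seed, {
    for (i in seq_len(nrow(profiles))) {
      b <- profiles[i, ]
      p1 <- ou_params(b$base_speed, b$home_scale, fr)
      p2 <- ou_params(b$base_speed * (he$speed_multiplier %||% 1),
                      b$home_scale * (he$dispersion_multiplier %||% 1), fr)
      pars <- list(p1, p2)
      # home path (relocation toward honey stores for in-nest workers)
      if (relocating && b$group %in% c("brood", "diffuse")) {
        tgt <- sample_in_region(nest, he$relocation_target, b$side)
        hx <- b$home_x + ramp * (tgt[1, 1] - b$home_x)
        hy <- b$home_y + ramp * (tgt[1, 2] - b$home_y)
      } else {
        hx <- b$home_x; hy <- b$home_y
      }
      if (b$base_speed == 0) {
        dx <- dy <- rep(0, n_ticks)
      } else {
        dx <- ar1_series(phase, pars, stats::rnorm(1, 0, b$home_scale))
        dy <- ar1_series(phase, pars, stats::rnorm(1, 0, b$home_scale))
      }
      x <- pmin(pmax(hx + dx, 0.05), nest$width_cm - 0.05)
      y <- pmin(pmax(hy + dy, 0.05), nest$height_cm - 0.05)

      # outside trips (two-state process; no detections while outside)
      d_exit_home <- sqrt((b$home_x - ex["x"])^2 + (b$home_y - ex["y"])^2)
      mult <- if (is_stress) {
        1 + ((he$exit_rate_multiplier %||% 1) - 1) *
          exp(-d_exit_home / 18.75) * min(b$age / 30, 1)
      } else 1
      trips <- draw_trips(w[1] * 3600, w[2] * 3600,
                          b$exit_propensity / 3600, sw[1], sw[2], mult)
      inside <- rep(TRUE, n_ticks)
      if (nrow(trips) > 0) {
        for (k in seq_len(nrow(trips))) {
          inside[secs >= trips[k, 1] & secs < trips[k, 2]] <- FALSE
        }
        trips_out[[i]] <- data.table::data.table(
          bee_id = b$bee_id, t_exit = day0 + trips[, 1],
          t_enter = day0 + trips[, 2])
      }
      keep <- inside & (stats::runif(n_ticks) < config$detection_prob)
      nk <- sum(keep)
      if (nk == 0L) next
      orient <- (stats::runif(1, 0, 2 * pi) +
                   cumsum(stats::rnorm(n_ticks, 0, 0.3))) %% (2 * pi)
      rows[[i]] <- data.table::data.table(
        bee_id = b$bee_id, timestamp = day0 + secs[keep],
        x_cm = x[keep], y_cm = y[keep], side = b$side,
        orientation_rad = orient[keep],
        confidence = stats::rbeta(nk, 8, 1))
    }
    det <- data.table::rbindlist(rows)
    if (nrow(det) > 0) data.table::setkey(det, bee_id, timestamp)
    temp <- simulate_temperature(date, is_stress, config)
    list(detections = det, temperature = temp,
         trips = data.table::rbindlist(trips_out), date = date,
         is_stress = is_stress)
  })
}

# Once-per-minute four-sensor temperature log. Room ramps 25 -> ~45 C
# during the stress window; honey/exit frames follow toward ~40 C, brood is
# thermoregulated at ~35 C and rises more slowly.
simulate_temperature <- function(date, is_stress, config) {
  w <- config$day_window
  sw <- config$stress_window * 3600
  day0 <- as.POSIXct(paste0(format(as.Date(date)), " 00:00:00"), tz = "UTC")
  secs <- seq(w[1] * 3600, w[2] * 3600 - 60, by = 60)
  relax <- function(base, peak, tau) {
    tt <- rep(base, length(secs))
    if (is_stress) {
      during <- secs >= sw[1] & secs < sw[2]
      after <- secs >= sw[2]
      tt[during] <- peak + (base - peak) * exp(-(secs[during] - sw[1]) / tau)
      t_end <- peak + (base - peak) * exp(-(sw[2] - sw[1]) / tau)
      tt[after] <- base + (t_end - base) * exp(-(secs[after] - sw[2]) / 1800)
    }
    tt
  }
  sensors <- list(room = relax(25, 45, 600), honey = relax(26, 40, 1800),
                  brood = relax(35, 40, 3600), exit = relax(26, 40, 1800))
  out <- data.table::rbindlist(lapply(names(sensors), function(s) {
    data.table::data.table(sensor = s, timestamp = day0 + secs,
                           temp_c = sensors[[s]] +
                             stats::rnorm(length(secs), 0, 0.15))
  }))
  data.table::setkey(out, sensor, timestamp)
  out
}

#' Simulate a full multi-day experiment
#'
#' Convenience wrapper: builds the nest map and colony once, simulates every
#' day in `config$sim_days`, and concatenates the outputs.
#'
#' @param config A [sim_config()].
#' @return A list with `nest`, `profiles`, `schedule` (see
#'   [make_schedule()]), `detections`, `temperature` and `trips`.
#' @export
simulate_experiment <- function(config) {
  nest <- generate_nest_map(config)
  profiles <- generate_colony(config, nest)
  days <- lapply(seq_len(nrow(config$sim_days)), function(i) {
    simulate_day(profiles, nest, config$sim_days$date[i],
                 config$sim_days$is_stress[i], config)
  })
  list(nest = nest, profiles = profiles, schedule = make_schedule(config),
       detections = data.table::rbindlist(lapply(days, `[[`, "detections")),
       temperature = data.table::rbindlist(lapply(days, `[[`, "temperature")),
       trips = data.table::rbindlist(lapply(days, `[[`, "trips")))
}

#' Build the experiment schedule from a simulation configuration
#'
#' Marks each simulated day `control` or `stress`. A day flagged neither
#' control nor stress can be introduced by editing the returned data frame
#' (kind `"other"`); such days are excluded from control-versus-stress
#' comparisons, as when a control day is invalidated by other
#' manipulations.
#'
#' @param config A [sim_config()].
#' @return Data frame with `date`, `kind`, `stress_start`, `stress_end`
#'   (hours; `NA` on non-stress days).
#' @export
make_schedule <- function(config) {
  kind <- ifelse(config$sim_days$is_stress, "stress", "control")
  data.frame(date = config$sim_days$date, kind = kind,
             stress_start = ifelse(kind == "stress",
                                   config$stress_window[1], NA_real_),
             stress_end = ifelse(kind == "stress",
                                 config$stress_window[2], NA_real_))
}
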