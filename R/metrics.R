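BIN_SECONDS <- c("1 min" = 60, "5 min" = 300, "1 hour" = 3600)

METRIC_COLUMNS <- c("time_on_honey", "time_on_brood", "time_on_exit_frame",
                    "exit_distance", "time_observed", "time_outside",
                    "n_outside_trips", "speed", "dispersion", "nest_visited")

bin_seconds <- function(bin) {
  if (is.numeric(bin)) return(as.numeric(bin))
  bs <- BIN_SECONDS[match.arg(bin, names(BIN_SECONDS))]
  unname(bs)
}

#' Compute behavioural metrics per bee per time bin
#'
#' For every bee and time bin, computes the space-use, detection and
#' movement metrics from confidence-filtered detections:
#' frame-occupancy fractions (`time_on_honey`, `time_on_brood`,
#' `time_on_exit_frame`, normalised over in-nest detections so they always
#' sum to 1), the median Euclidean distance to the nest exit
#' (`exit_distance`, cm), `time_observed` (detections / frame rate, capped
#' at the bin length, s), `speed` (mean displacement over inter-detection
#' time for consecutive same-side detection pairs with gap at most
#' `speed_max_gap` s, cm/s), `dispersion` (root-mean-square distance of
#' in-bin positions from their centroid, cm) and `nest_visited` (fraction
#' of `grid_cell`-cm square cells of the two-sided nest area visited).
#'
#' Bins with fewer than `min_detections` detections yield `NA` for all
#' movement and space-use metrics but keep `time_observed` — genuinely
#' missing bins are encoded as missing, never as zero. The returned table
#' is completed to the full per-day 1-min (or coarser) grid spanned by the
#' data, so bins in which a bee was never detected appear with
#' `time_observed = 0`.
#'
#' @param detections Detection table sorted by `(bee_id, timestamp)`
#'   (hard error otherwise), already confidence-filtered.
#' @param nest A `nest_map`.
#' @param bin `"1 min"`, `"5 min"` or `"1 hour"` (or a bin length in
#'   seconds).
#' @param frame_rate Camera frame rate (detections per second) used to
#'   convert detection counts to observed time.
#' @param min_detections Minimum detections per bin for non-null metrics.
#' @param speed_max_gap Maximum inter-detection gap (s) for a pair to
#'   contribute to speed; avoids teleport artefacts across dropouts.
#' @param grid_cell Side (cm) of the occupancy grid for `nest_visited`.
#' @return A `data.table` keyed by `(bee_id, bin_start)` with the metric
#'   columns plus `n_detections`; `time_outside` and `n_outside_trips` are
#'   `NA` here and are filled in by [infer_presence()] /
#'   [aggregate_metrics()]. Attribute `"bin_size"` holds the bin length in
#'   seconds.
#' @export
compute_bin_metrics <- function(detections, nest, bin = "1 min",
                                frame_rate = 3, min_detections = 10,
                                speed_max_gap = 2, grid_cell = 2.5) {
  bs <- bin_seconds(bin)
  det <- data.table::as.data.table(detections)
  if (nrow(det) == 0L) {
    out <- empty_metrics_table()
    data.table::setattr(out, "bin_size", bs)
    return(out)
  }
  ord <- order(det$bee_id, det$timestamp)
  if (any(ord != seq_len(nrow(det))))
    stop("detections must be sorted by (bee_id, timestamp)", call. = FALSE)

  ex <- nest$exit_point
  nx <- ceiling(nest$width_cm / grid_cell)
  ny <- ceiling(nest$height_cm / grid_cell)
  n_cells <- 2 * nx * ny

  work <- det[, list(bee_id, t = as.numeric(timestamp), x_cm, y_cm, side)]
  loc <- locate_points(nest, work$x_cm, work$y_cm, work$side)
  work[, `:=`(
    fh = loc$frame == "honey",
    fb = loc$frame == "brood",
    fe = loc$frame == "exit",
    dex = sqrt((x_cm - ex[["x"]])^2 + (y_cm - ex[["y"]])^2),
    cell = floor(x_cm / grid_cell) + nx * floor(y_cm / grid_cell) +
      nx * ny * side,
    bin = floor(t / bs) * bs)]
  work[, `:=`(gap = t - data.table::shift(t),
              dd = sqrt((x_cm - data.table::shift(x_cm))^2 +
                          (y_cm - data.table::shift(y_cm))^2),
              same = data.table::shift(side) == side &
                data.table::shift(bin) == bin),
       by = bee_id]
  work[, sp := ifelse(!is.na(gap) & same & gap > 0 &
                        gap <= speed_max_gap + 1e-9, dd / gap, NA_real_)]

  agg <- work[, list(
    n_detections = .N,
    n_in_nest = sum(fh | fb | fe),
    s_honey = sum(fh), s_brood = sum(fb), s_exitf = sum(fe),
    exit_distance = stats::median(dex),
    dispersion = sqrt(mean((x_cm - mean(x_cm))^2 + (y_cm - mean(y_cm))^2)),
    nest_visited = data.table::uniqueN(cell) / n_cells,
    sp_sum = sum(sp, na.rm = TRUE), sp_n = sum(!is.na(sp))),
    by = list(bee_id, bin)]

  # complete to the full per-day bin grid spanned by the data
  days <- unique(floor(agg$bin / 86400))
  grid_bins <- unlist(lapply(days, function(d) {
    rng <- range(agg$bin[floor(agg$bin / 86400) == d])
    seq(rng[1], rng[2], by = bs)
  }))
  grid <- data.table::CJ(bee_id = unique(det$bee_id), bin = grid_bins)
  out <- agg[grid, on = c("bee_id", "bin")]
  out[is.na(n_detections), `:=`(n_detections = 0L, n_in_nest = 0L)]

  thin <- out$n_detections < min_detections
  out[, `:=`(
    time_observed = pmin(n_detections / frame_rate, bs),
    time_on_honey = ifelse(thin | n_in_nest == 0, NA_real_,
                           s_honey / n_in_nest),
    time_on_brood = ifelse(thin | n_in_nest == 0, NA_real_,
                           s_brood / n_in_nest),
    time_on_exit_frame = ifelse(thin | n_in_nest == 0, NA_real_,
                                s_exitf / n_in_nest),
    exit_distance = ifelse(thin, NA_real_, exit_distance),
    dispersion = ifelse(thin, NA_real_, dispersion),
    nest_visited = ifelse(thin, NA_real_, nest_visited),
    speed = ifelse(thin | sp_n == 0, NA_real_, sp_sum / sp_n),
    time_outside = NA_real_,
    n_outside_trips = NA_integer_,
    bin_start = as.POSIXct(bin, origin = "1970-01-01", tz = "UTC"))]
  out <- out[, c("bee_id", "bin_start", "n_detections", METRIC_COLUMNS),
             with = FALSE]
  data.table::setkey(out, bee_id, bin_start)
  data.table::setattr(out, "bin_size", bs)
  out
}

empty_metrics_table <- function() {
  out <- data.table::data.table(
    bee_id = integer(), bin_start = as.POSIXct(character(), tz = "UTC"),
    n_detections = integer())
  for (m in METRIC_COLUMNS) out[, (m) := numeric()]
  out
}

#' Infer when each bee was inside or outside the nest
#'
#' Runs the two-threshold exit/entry automaton over per-bee 1-min bins: a
#' bee is estimated to have exited in bin `t_exit` if its time observed
#' there is below `t_obs` (2 s) *and* the median exit distance in bin
#' `t_exit - 1` is below `d_exit` (18.75 cm); it remains outside until the
#' first bin with time observed at or above `t_obs`. A disappearance far
#' from the exit is treated as in-nest occlusion, not an exit. The first
#' bin of each contiguous daily segment has no predecessor and is treated
#' as inside.
#'
#' @param one_min_metrics Output of [compute_bin_metrics()] at 1-min
#'   resolution (hard error otherwise: the inference is defined at the
#'   1-min scale only).
#' @param t_obs Minimum observed time (s) for a bin to count as present.
#' @param d_exit Maximum previous-bin median exit distance (cm) for a
#'   disappearance to count as an exit.
#' @return A `data.table` keyed by `(bee_id, bin_start)` with logical
#'   columns `outside`, `exit_event`, `enter_event`. Outside bins span
#'   `t_exit` up to (not including) `t_enter`.
#' @export
infer_presence <- function(one_min_metrics, t_obs = 2, d_exit = 18.75) {
  bs <- attr(one_min_metrics, "bin_size")
  if (is.null(bs) || bs != 60)
    stop("presence inference is defined on 1-min binned metrics only",
         call. = FALSE)
  m <- data.table::as.data.table(one_min_metrics)
  data.table::setorder(m, bee_id, bin_start)
  n <- nrow(m)
  bee <- m$bee_id
  tb <- as.numeric(m$bin_start)
  tobs <- m$time_observed
  edist <- m$exit_distance
  outside <- exit_event <- enter_event <- logical(n)
  state <- FALSE
  for (k in seq_len(n)) {
    new_seg <- k == 1L || bee[k] != bee[k - 1L] || tb[k] - tb[k - 1L] > 60
    if (new_seg) state <- FALSE
    if (!state) {
      if (!new_seg && tobs[k] < t_obs &&
          !is.na(edist[k - 1L]) && edist[k - 1L] < d_exit) {
        state <- TRUE
        exit_event[k] <- TRUE
      }
    } else if (tobs[k] >= t_obs) {
      state <- FALSE
      enter_event[k] <- TRUE
    }
    outside[k] <- state
  }
  out <- data.table::data.table(bee_id = bee, bin_start = m$bin_start,
                                outside = outside, exit_event = exit_event,
                                enter_event = enter_event)
  data.table::setkey(out, bee_id, bin_start)
  out
}

wtd_mean <- function(v, w) {
  ok <- !is.na(v) & !is.na(w) & w > 0
  if (!any(ok)) return(NA_real_)
  sum(v[ok] * w[ok]) / sum(w[ok])
}

#' Aggregate 1-min metrics and presence to 5-min or hourly bins
#'
#' Detection-weighted averaging of the 1-min metrics into a coarser grid:
#' frame fractions, speed, dispersion and nest_visited are averaged over
#' non-null children weighted by detection count; `exit_distance` is the
#' median of the non-null child medians; `time_observed` is the summed
#' observed time (capped at the bin length); `time_outside` is the
#' fraction of child bins flagged outside and `n_outside_trips` the count
#' of exit events in the window.
#'
#' @param one_min_metrics Output of [compute_bin_metrics()] at 1 min.
#' @param presence Output of [infer_presence()] on the same grid.
#' @param target `"5 min"` or `"1 hour"` (or seconds, an integer multiple
#'   of 60).
#' @return A `data.table` in the same layout as [compute_bin_metrics()],
#'   with `time_outside` and `n_outside_trips` filled in.
#' @export
aggregate_metrics <- function(one_min_metrics, presence,
                              target = "1 hour") {
  ps <- bin_seconds(target)
  if (ps %% 60 != 0) stop("target bin must be a multiple of 1 min",
                          call. = FALSE)
  m <- data.table::as.data.table(one_min_metrics)
  m <- presence[m, on = c("bee_id", "bin_start")]
  m[, parent := floor(as.numeric(bin_start) / ps) * ps]
  out <- m[, list(
    n_detections = sum(n_detections),
    time_observed = pmin(sum(time_observed), ps),
    time_on_honey = wtd_mean(time_on_honey, n_detections),
    time_on_brood = wtd_mean(time_on_brood, n_detections),
    time_on_exit_frame = wtd_mean(time_on_exit_frame, n_detections),
    exit_distance = if (all(is.na(exit_distance))) NA_real_
      else stats::median(exit_distance, na.rm = TRUE),
    speed = wtd_mean(speed, n_detections),
    dispersion = wtd_mean(dispersion, n_detections),
    nest_visited = wtd_mean(nest_visited, n_detections),
    time_outside = mean(outside),
    n_outside_trips = sum(exit_event)),
    by = list(bee_id, parent)]
  out[, bin_start := as.POSIXct(parent, origin = "1970-01-01", tz = "UTC")]
  out[, parent := NULL]
  out <- out[, c("bee_id", "bin_start", "n_detections", METRIC_COLUMNS),
             with = FALSE]
  data.table::setkey(out, bee_id, bin_start)
  data.table::setattr(out, "bin_size", ps)
  out
}
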