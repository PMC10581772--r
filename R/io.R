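#' Read and confidence-filter a detection table
#'
#' Reads a CSV of tag detections, drops rows below the decoding-confidence
#' threshold, and sorts by bee and time. The canonical columns are
#' `bee_id`, `timestamp` (ISO-8601, UTC), `x_cm`, `y_cm`, `side`,
#' `orientation_rad`, `confidence`; deposited tables with other column
#' names can be adapted with `column_map`.
#'
#' @param path CSV file path.
#' @param min_confidence Detections with `confidence` strictly below this
#'   are dropped (the threshold itself is kept). Default 0.8.
#' @param column_map Optional named character vector mapping canonical
#'   names to the file's column names, e.g. `c(bee_id = "tag_id")`.
#' @return A `data.table` keyed by `(bee_id, timestamp)`. An empty file
#'   yields an empty table. The number of rows dropped by the filter is
#'   reported via `message()` and attached as attribute `"n_filtered"`.
#' @export
read_detections <- function(path, min_confidence = 0.8, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  det <- data.table::fread(path, colClasses = list(character = "timestamp"))
  if (nrow(det) == 0L) {
    return(data.table::data.table(bee_id = integer(), timestamp = as.POSIXct(character(), tz = "UTC"),
                                  x_cm = numeric(), y_cm = numeric(),
                                  side = integer(), orientation_rad = numeric(),
                                  confidence = numeric()))
  }
  if (!is.null(column_map)) {
    data.table::setnames(det, unname(column_map), names(column_map),
                         skip_absent = FALSE)
  }
  assert_columns(det, c("bee_id", "timestamp", "x_cm", "y_cm", "side",
                        "confidence"), "detection table")
  ts <- as.POSIXct(strptime(det$timestamp, "%Y-%m-%dT%H:%M:%OS", tz = "UTC"))
  retry <- is.na(ts)
  if (any(retry))
    ts[retry] <- as.POSIXct(strptime(det$timestamp[retry],
                                     "%Y-%m-%d %H:%M:%OS", tz = "UTC"))
  bad <- which(is.na(ts) | !is.finite(det$x_cm) | !is.finite(det$y_cm) |
                 is.na(det$confidence))
  if (length(bad) > 0L) {
    stop(sprintf("malformed detection row(s), first at data line %d of %s",
                 bad[1], path), call. = FALSE)
  }
  det[, timestamp := ts]
  filter_detections(det, min_confidence)
}

#' Apply the detection-confidence filter
#'
#' Keeps rows with `confidence >= min_confidence` (boundary inclusive) and
#' sorts by `(bee_id, timestamp)`. Idempotent.
#'
#' @param det Detection table.
#' @param min_confidence Threshold in `[0, 1]`.
#' @return Filtered, keyed `data.table` with attribute `"n_filtered"`.
#' @export
filter_detections <- function(det, min_confidence = 0.8) {
  det <- data.table::as.data.table(det)
  n0 <- nrow(det)
  out <- det[confidence >= min_confidence]
  data.table::setkey(out, bee_id, timestamp)
  message(sprintf("detections: %d read, %d dropped below confidence %.3g, %d retained",
                  n0, n0 - nrow(out), min_confidence, nrow(out)))
  data.table::setattr(out, "n_filtered", n0 - nrow(out))
  out
}

#' Write a detection table to CSV
#'
#' Timestamps are serialised as ISO-8601 UTC with millisecond precision so
#' a 3 frames-per-second grid round-trips exactly.
#'
#' @param det Detection table.
#' @param path Output file path.
#' @export
write_detections <- function(det, path) {
  out <- data.table::as.data.table(det)
  out <- out[, list(bee_id, timestamp = format(timestamp, "%Y-%m-%dT%H:%M:%OS3",
                                               tz = "UTC"),
                    x_cm, y_cm, side, orientation_rad, confidence)]
  data.table::fwrite(out, path)
  invisible(path)
}

#' Serialise / read a nest map as JSON
#'
#' The JSON document stores the hive dimensions, per-side content regions
#' as polygon vertex lists (in lookup order), the frame bands and the exit
#' point.
#'
#' @param nest A `nest_map`.
#' @param path JSON file path.
#' @return `read_nest_map()` returns a `nest_map`.
#' @export
write_nest_map <- function(nest, path) {
  doc <- list(width_cm = nest$width_cm, height_cm = nest$height_cm,
              frames = nest$frames,
              regions = lapply(nest$regions, function(r)
                list(side = r$side, region = r$region, frame = r$frame,
                     poly = unname(apply(r$poly, 1, as.numeric, simplify = FALSE)))),
              exit_point = as.list(nest$exit_point))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_nest_map
#' @export
read_nest_map <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  nest <- list(width_cm = doc$width_cm, height_cm = doc$height_cm,
               frames = data.frame(
                 frame = vapply(doc$frames, function(f) f$frame, ""),
                 y_min = vapply(doc$frames, function(f) f$y_min, 0),
                 y_max = vapply(doc$frames, function(f) f$y_max, 0)),
               regions = lapply(doc$regions, function(r) {
                 poly <- do.call(rbind, lapply(r$poly, unlist))
                 colnames(poly) <- c("x", "y")
                 list(side = as.integer(r$side), region = r$region,
                      frame = r$frame, poly = poly)
               }),
               exit_point = c(x = doc$exit_point$x, y = doc$exit_point$y,
                              side = doc$exit_point$side))
  class(nest) <- "nest_map"
  nest
}

#' Write / read binned behavioural metrics as CSV
#'
#' Null metrics (bins failing the minimum-detection rule) are encoded as
#' empty fields, never as zero, and round-trip as `NA`.
#'
#' @param metrics A binned-metrics table (see [compute_bin_metrics()]).
#' @param path CSV file path.
#' @return `read_metrics()` returns a `data.table` with `bin_start` parsed
#'   back to POSIXct (UTC); the `bin_size` attribute is restored from the
#'   `bin_seconds` column.
#' @export
write_metrics <- function(metrics, path) {
  out <- data.table::as.data.table(metrics)
  out <- data.table::copy(out)
  out[, bin_start := format(bin_start, "%Y-%m-%dT%H:%M:%S", tz = "UTC")]
  data.table::fwrite(out, path, na = "")
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  m <- data.table::fread(path, colClasses = list(character = "bin_start"))
  if (nrow(m) > 0L) {
    m[, bin_start := as.POSIXct(bin_start, tz = "UTC",
                                format = "%Y-%m-%dT%H:%M:%S")]
    data.table::setkey(m, bee_id, bin_start)
  }
  m
}

#' Write / read the experiment schedule as JSON
#'
#' @param schedule Data frame with `date`, `kind` (`control`, `stress` or
#'   `other`), `stress_start`, `stress_end`.
#' @param path JSON file path.
#' @export
write_schedule <- function(schedule, path) {
  doc <- schedule
  doc$date <- format(as.Date(doc$date))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  doc <- as.data.frame(doc)
  doc$date <- as.Date(doc$date)
  if (is.null(doc$stress_start)) doc$stress_start <- NA_real_
  if (is.null(doc$stress_end)) doc$stress_end <- NA_real_
  if (anyDuplicated(doc$date)) stop("schedule dates must be unique",
                                    call. = FALSE)
  doc
}

#' Write a temperature log as CSV
#'
#' @param temperature Data frame with `sensor`, `timestamp`, `temp_c`.
#' @param path CSV file path.
#' @export
write_temperature <- function(temperature, path) {
  out <- data.table::as.data.table(temperature)
  out <- out[, list(sensor,
                    timestamp = format(timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
                    temp_c)]
  data.table::fwrite(out, path)
  invisible(path)
}
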