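#' Colony-level 5-min time series
#'
#' Cross-bee means per 5-min bin of the frame-occupancy fractions, speed
#' and dispersion, plus the fraction of tracked bees estimated to be
#' outside the nest — the colony-trend view of the data.
#'
#' @param metrics_5min 5-min metrics table from [aggregate_metrics()].
#' @return A `data.table` with one row per 5-min bin: `bin_start`,
#'   `n_bees` (bees with any non-null space-use data), `frac_outside`,
#'   and mean `time_on_honey`, `time_on_brood`, `time_on_exit_frame`,
#'   `speed`, `dispersion`.
#' @export
colony_summaries <- function(metrics_5min) {
  m <- data.table::as.data.table(metrics_5min)
  out <- m[, list(
    n_bees = sum(!is.na(time_on_honey)),
    frac_outside = mean(time_outside, na.rm = TRUE),
    time_on_honey = mean(time_on_honey, na.rm = TRUE),
    time_on_brood = mean(time_on_brood, na.rm = TRUE),
    time_on_exit_frame = mean(time_on_exit_frame, na.rm = TRUE),
    speed = mean(speed, na.rm = TRUE),
    dispersion = mean(dispersion, na.rm = TRUE)),
    by = bin_start]
  data.table::setorder(out, bin_start)
  out
}

#' Pipeline configuration
#'
#' Bundles the simulation settings with the analysis thresholds: the
#' detection-confidence threshold (0.8), minimum detections per bin (10),
#' the exit/entry thresholds `t_obs` (2 s) and `d_exit` (18.75 cm), and
#' the cluster counts (5 morning, 4 heat-stress).
#'
#' @param sim A [sim_config()] describing the synthetic colony (or `NULL`
#'   when detections are supplied externally to [run_pipeline()]).
#' @param min_confidence,min_detections,t_obs,d_exit,k_morning,k_heat
#'   Analysis thresholds; see description.
#' @param hours Named clock hours of the behavioural-matrix rows.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), min_confidence = 0.8,
                            min_detections = 10, t_obs = 2, d_exit = 18.75,
                            k_morning = 5, k_heat = 4,
                            hours = c(morning = 9, heat = 12)) {
  stopifnot(min_confidence >= 0, min_confidence <= 1, min_detections > 0,
            t_obs > 0, d_exit > 0, k_morning >= 1, k_heat >= 1)
  cfg <- list(sim = sim, min_confidence = min_confidence,
              min_detections = min_detections, t_obs = t_obs,
              d_exit = d_exit, k_morning = k_morning, k_heat = k_heat,
              hours = hours)
  class(cfg) <- "pipeline_config"
  cfg
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(as.character(jsonlite::serializeJSON(
    rapply(config, unclass, how = "replace"), digits = 12)), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full simulate-to-summary analysis pipeline
#'
#' Orchestrates simulate -> metrics -> presence inference -> embedding ->
#' clustering -> transitions -> correlation with one configuration,
#' writing every table as CSV plus a JSON manifest (config hash, seed, and
#' row counts at each filter stage) into `out_dir`. Days are simulated and
#' reduced one at a time, so only binned metrics are held across days.
#'
#' Outputs: `colony_5min.csv` (colony trends), `metrics_1h.csv`,
#' `pca_components.csv`, `pca_projections.csv`, `cluster_labels.csv`,
#' `cluster_summary.csv`, `transition_counts.csv`,
#' `transition_pct_diff.csv`, `correlation_series.csv`, `nest_map.json`,
#' `schedule.json`, `temperature.csv`, `manifest.json`.
#'
#' @param config A [pipeline_config()] with a simulation configuration.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional integer overriding `config$sim$rng_seed`.
#' @param keep_detections Write per-day detection CSVs too (off by
#'   default: they are large).
#' @return Invisibly, a list with all in-memory results (`metrics_1h`,
#'   `colony_5min`, `bm`, `pca`, `clusters`, `transitions`, `correlation`,
#'   `manifest`, ...).
#' @export
run_pipeline <- function(config, out_dir, seed = NULL,
                         keep_detections = FALSE) {
  stopifnot(inherits(config, "pipeline_config"),
            inherits(config$sim, "sim_config"))
  if (!is.null(seed)) config$sim$rng_seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- config$sim
  stage_counts <- list()

  nest <- generate_nest_map(sim)
  profiles <- generate_colony(sim, nest)
  schedule <- make_schedule(sim)
  write_nest_map(nest, file.path(out_dir, "nest_map.json"))
  write_schedule(schedule, file.path(out_dir, "schedule.json"))

  m1 <- list(); pres <- list(); temps <- list()
  for (d in seq_len(nrow(sim$sim_days))) {
    day <- simulate_day(profiles, nest, sim$sim_days$date[d],
                        sim$sim_days$is_stress[d], sim)
    n_raw <- nrow(day$detections)
    det <- suppressMessages(
      filter_detections(day$detections, config$min_confidence))
    stage_counts[[format(sim$sim_days$date[d])]] <- list(
      rows_in = n_raw, rows_dropped = attr(det, "n_filtered"),
      rows_out = nrow(det))
    if (keep_detections)
      write_detections(det, file.path(out_dir, sprintf(
        "detections_%s.csv", format(sim$sim_days$date[d]))))
    m1d <- compute_bin_metrics(det, nest, "1 min",
                               frame_rate = sim$frame_rate,
                               min_detections = config$min_detections)
    m1[[d]] <- m1d
    pres[[d]] <- infer_presence(m1d, t_obs = config$t_obs,
                                d_exit = config$d_exit)
    temps[[d]] <- day$temperature
  }
  m1 <- data.table::rbindlist(m1)
  data.table::setattr(m1, "bin_size", 60)
  data.table::setkey(m1, bee_id, bin_start)
  presence <- data.table::rbindlist(pres)
  data.table::setkey(presence, bee_id, bin_start)
  write_temperature(data.table::rbindlist(temps),
                    file.path(out_dir, "temperature.csv"))

  m5 <- aggregate_metrics(m1, presence, "5 min")
  m1h <- aggregate_metrics(m1, presence, "1 hour")
  colony <- colony_summaries(m5)
  write_metrics(m1h, file.path(out_dir, "metrics_1h.csv"))
  write_metrics_plain(colony, file.path(out_dir, "colony_5min.csv"))

  bm <- withCallingHandlers(
    build_behaviour_matrix(m1h, schedule, hours = config$hours),
    message = function(m) invokeRestart("muffleMessage"))
  stage_counts$behaviour_matrix <- list(
    rows_in = nrow(bm$matrix) + bm$dropped_rows,
    rows_dropped = bm$dropped_rows, rows_out = nrow(bm$matrix))
  pca <- behaviour_pca(bm)
  data.table::fwrite(data.table::data.table(
    metric = rownames(pca$rotation),
    round(pca$rotation, 10)), file.path(out_dir, "pca_components.csv"))
  data.table::fwrite(cbind(bm$info, data.table::as.data.table(
    round(pca$projections, 10))), file.path(out_dir, "pca_projections.csv"))

  cl_m <- ward_cluster(bm, "morning", k = config$k_morning)
  cl_h <- ward_cluster(bm, "heat", k = config$k_heat)
  ages <- profiles[, c("bee_id", "age")]
  desc_m <- describe_clusters(cl_m, bm, ages)
  desc_h <- describe_clusters(cl_h, bm, ages)
  labels <- rbind(cbind(period = "morning", cl_m$labels,
                        name = desc_m$names[as.character(cl_m$labels$label)]),
                  cbind(period = "heat", cl_h$labels,
                        name = desc_h$names[as.character(cl_h$labels$label)]))
  data.table::fwrite(labels, file.path(out_dir, "cluster_labels.csv"))
  data.table::fwrite(rbind(cbind(period = "morning", desc_m$summary),
                           cbind(period = "heat", desc_h$summary)),
                     file.path(out_dir, "cluster_summary.csv"))

  tt <- suppressMessages(compute_transitions(cl_m$labels, cl_h$labels))
  stage_counts$transitions <- list(
    rows_in = nrow(cl_m$labels) + nrow(cl_h$labels),
    rows_dropped = tt$n_excluded, rows_out = 2 * nrow(tt$pairs))
  write_matrix_csv(tt$counts, file.path(out_dir, "transition_counts.csv"))
  write_matrix_csv(round(tt$pct_diff, 6),
                   file.path(out_dir, "transition_pct_diff.csv"))

  corr <- correlation_series(m1h, schedule, bm)
  data.table::fwrite(corr$series[, list(
    day_kind, hour, median = round(median, 10), q25 = round(q25, 10),
    q75 = round(q75, 10), n_bees)],
    file.path(out_dir, "correlation_series.csv"))

  manifest <- list(config_hash = config_hash(config),
                   seed = sim$rng_seed, n_bees = sim$n_bees,
                   days = format(sim$sim_days$date),
                   stage_counts = stage_counts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(nest = nest, profiles = profiles, schedule = schedule,
                 metrics_1min = m1, presence = presence, metrics_5min = m5,
                 metrics_1h = m1h, colony_5min = colony, bm = bm, pca = pca,
                 clusters = list(morning = cl_m, heat = cl_h),
                 cluster_names = list(morning = desc_m, heat = desc_h),
                 transitions = tt, correlation = corr, manifest = manifest))
}

write_metrics_plain <- function(x, path) {
  out <- data.table::copy(data.table::as.data.table(x))
  if ("bin_start" %in% names(out))
    out[, bin_start := format(bin_start, "%Y-%m-%dT%H:%M:%S", tz = "UTC")]
  num <- names(out)[vapply(out, is.numeric, TRUE)]
  for (cn in num) data.table::set(out, j = cn, value = round(out[[cn]], 10))
  data.table::fwrite(out, path, na = "")
  invisible(path)
}

write_matrix_csv <- function(mat, path) {
  dt <- data.table::as.data.table(mat, keep.rownames = "morning")
  data.table::fwrite(dt, path, na = "")
  invisible(path)
}
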