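#' Build the behavioural-hour matrix
#'
#' Assembles the analysis matrix whose rows are behavioural hours — the 10
#' behavioural metrics of one bee during one clock hour of one stress-trial
#' day — and whose columns are the metrics. By default the morning hour
#' (9.00–10.00, before the stress) and the midday hour (12.00–13.00,
#' during the stress) of every stress day enter the matrix. Rows with any
#' missing metric are excluded (and counted); columns are then z-scored
#' (mean 0, sd 1) over the pooled rows, and the per-column means and sds
#' are stored for reuse as the common normalisation factors of the
#' temporal-correlation analysis.
#'
#' Zero-variance columns (e.g. no bee ever outside) cannot be z-scored and
#' are dropped with a warning.
#'
#' @param hourly_metrics Hourly metrics table ([aggregate_metrics()]).
#' @param schedule Schedule data frame (see [make_schedule()]); only days
#'   with `kind == "stress"` contribute rows.
#' @param hours Named integer vector of hour labels to starting clock
#'   hours, default `c(morning = 9, heat = 12)`.
#' @return An object of class `behaviour_matrix`: list with `matrix` (the
#'   z-scored rows), `info` (bee_id, date, hour_label per row), `center`,
#'   `scale`, `metrics`, `dropped_rows`, `dropped_cols`.
#' @export
build_behaviour_matrix <- function(hourly_metrics, schedule,
                                   hours = c(morning = 9, heat = 12)) {
  m <- data.table::as.data.table(hourly_metrics)
  stress_days <- as.Date(schedule$date[schedule$kind == "stress"])
  m[, date := as.Date(bin_start, tz = "UTC")]
  m[, hour := as.integer(format(bin_start, "%H", tz = "UTC"))]
  m[, hour_label := names(hours)[match(hour, hours)]]
  sel <- m[!is.na(hour_label) & date %in% stress_days]
  X <- as.matrix(sel[, METRIC_COLUMNS, with = FALSE])
  complete <- stats::complete.cases(X)
  dropped_rows <- sum(!complete)
  if (dropped_rows > 0)
    message(sprintf("behaviour matrix: %d row(s) with missing metrics dropped",
                    dropped_rows))
  X <- X[complete, , drop = FALSE]
  info <- sel[complete, list(bee_id, date, hour_label)]
  if (nrow(X) < 2L)
    stop("fewer than 2 complete behavioural hours: nothing to normalize",
         call. = FALSE)
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  degenerate <- scale < 1e-12
  if (any(degenerate)) {
    warning("dropping zero-variance metric column(s): ",
            paste(names(center)[degenerate], collapse = ", "),
            call. = FALSE)
    X <- X[, !degenerate, drop = FALSE]
    center <- center[!degenerate]
    scale <- scale[!degenerate]
  }
  Z <- sweep(sweep(X, 2, center), 2, scale, "/")
  out <- list(matrix = Z, info = info, center = center, scale = scale,
              metrics = colnames(Z), dropped_rows = dropped_rows,
              dropped_cols = names(degenerate)[degenerate])
  class(out) <- "behaviour_matrix"
  out
}

#' Principal component analysis of behavioural hours
#'
#' Eigen-decomposition of the z-scored behavioural matrix (equivalently,
#' of the metric correlation structure). Components carry a deterministic
#' sign convention: the largest-magnitude weight of each component is made
#' positive, so results are reproducible across linear-algebra backends.
#'
#' Because the three frame-occupancy fractions sum to one on every row,
#' the matrix carries one exact linear dependency and the final
#' component's variance fraction is numerically zero.
#'
#' @param bm A `behaviour_matrix`.
#' @return An object of class `behaviour_pca`: list with `rotation`
#'   (metrics x components weight matrix), `variance_fractions`
#'   (non-increasing, summing to 1), `projections` (row scores) and `info`
#'   (row keys).
#' @export
behaviour_pca <- function(bm) {
  stopifnot(inherits(bm, "behaviour_matrix"))
  if (nrow(bm$matrix) < 2L) stop("need at least 2 rows for PCA",
                                 call. = FALSE)
  fit <- stats::prcomp(bm$matrix, center = FALSE, scale. = FALSE)
  flip <- apply(fit$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  rotation <- sweep(fit$rotation, 2, flip, "*")
  projections <- sweep(fit$x, 2, flip, "*")
  vf <- fit$sdev^2 / sum(fit$sdev^2)
  out <- list(rotation = rotation, variance_fractions = vf,
              projections = projections, info = bm$info)
  class(out) <- "behaviour_pca"
  out
}

#' Ward hierarchical clustering of behavioural hours
#'
#' Agglomerative clustering with Ward's minimum-variance criterion on
#' Euclidean distances between z-scored metric rows, applied separately to
#' one period's rows (e.g. the morning hours), then cut into `k` groups.
#' Five clusters describe the morning period and four the heat-stress
#' period by default in the full pipeline.
#'
#' @param bm A `behaviour_matrix`.
#' @param hour_label Which period's rows to cluster (e.g. `"morning"`),
#'   or `NULL` for all rows.
#' @param k Number of clusters to cut (1 <= k <= rows).
#' @return An object of class `cluster_model`: list with `tree` (the
#'   `hclust` object), `k`, `labels` (data.table bee_id, date, label),
#'   `hour_label`, and `rows` (the clustered sub-matrix).
#' @export
ward_cluster <- function(bm, hour_label = NULL, k) {
  stopifnot(inherits(bm, "behaviour_matrix"))
  keep <- if (is.null(hour_label)) rep(TRUE, nrow(bm$matrix))
          else bm$info$hour_label == hour_label
  X <- bm$matrix[keep, , drop = FALSE]
  info <- bm$info[keep]
  if (k < 1 || k > nrow(X))
    stop(sprintf("k = %d outside 1..%d rows", k, nrow(X)), call. = FALSE)
  tree <- stats::hclust(stats::dist(X), method = "ward.D2")
  labels <- stats::cutree(tree, k = k)
  out <- list(tree = tree, k = k,
              labels = data.table::data.table(bee_id = info$bee_id,
                                              date = info$date,
                                              label = labels),
              hour_label = hour_label, rows = X)
  class(out) <- "cluster_model"
  out
}

# Candidate semantic names and the signed z-scored cluster-median metric
# that identifies each: greedy best-match assignment, leftover clusters
# become "peripheral/other".
CLUSTER_RULES <- list(
  `going outside` = c(metric = "time_outside", sign = 1),
  `near exit` = c(metric = "exit_distance", sign = -1),
  honey = c(metric = "time_on_honey", sign = 1),
  brood = c(metric = "time_on_brood", sign = 1),
  `high dispersion` = c(metric = "dispersion", sign = 1))

#' Summarise and name behavioural clusters
#'
#' Computes per-cluster metric medians and quartiles (on the raw metric
#' scale) and assigns a reproducible semantic name to each cluster by its
#' dominant metric: high time outside -> "going outside", low exit
#' distance -> "near exit", high time on honey -> "honey", high time on
#' brood -> "brood", high dispersion -> "high dispersion"; remaining
#' clusters are "peripheral/other". Names are allocated greedily by the
#' strongest standardised signature, so they do not depend on arbitrary
#' integer label order.
#'
#' @param model A `cluster_model`.
#' @param bm The `behaviour_matrix` the model was cut from.
#' @param ages Optional data frame with `bee_id` and `age` (days); when
#'   supplied, per-cluster age quartiles are added.
#' @return A list with `names` (cluster label -> semantic name),
#'   `summary` (long data.table: label, name, metric, q25, median, q75)
#'   and, if ages were given, `ages` (per-cluster age quartiles).
#' @export
describe_clusters <- function(model, bm, ages = NULL) {
  stopifnot(inherits(model, "cluster_model"),
            inherits(bm, "behaviour_matrix"))
  X <- model$rows
  raw <- sweep(sweep(X, 2, bm$scale, "*"), 2, bm$center, "+")
  labs <- sort(unique(model$labels$label))
  med_z <- t(vapply(labs, function(l)
    apply(X[model$labels$label == l, , drop = FALSE], 2, stats::median),
    numeric(ncol(X))))
  rownames(med_z) <- labs

  rules <- Filter(function(r) r[["metric"]] %in% colnames(X), CLUSTER_RULES)
  score <- matrix(-Inf, nrow = length(labs), ncol = length(rules),
                  dimnames = list(labs, names(rules)))
  for (j in seq_along(rules)) {
    score[, j] <- med_z[, rules[[j]][["metric"]]] *
      as.numeric(rules[[j]][["sign"]])
  }
  cluster_names <- stats::setNames(rep("peripheral/other", length(labs)),
                                   labs)
  sc <- score
  for (step in seq_len(min(length(labs), length(rules)))) {
    ij <- which(sc == max(sc), arr.ind = TRUE)[1, ]
    cluster_names[ij[1]] <- colnames(sc)[ij[2]]
    sc[ij[1], ] <- -Inf
    sc[, ij[2]] <- -Inf
  }

  qs <- data.table::rbindlist(lapply(labs, function(l) {
    sub <- raw[model$labels$label == l, , drop = FALSE]
    data.table::data.table(
      label = l, name = cluster_names[as.character(l)],
      n = nrow(sub), metric = colnames(sub),
      q25 = apply(sub, 2, stats::quantile, 0.25),
      median = apply(sub, 2, stats::median),
      q75 = apply(sub, 2, stats::quantile, 0.75))
  }))
  out <- list(names = cluster_names, summary = qs)
  if (!is.null(ages) && nrow(ages) > 0) {
    lab_age <- merge(model$labels, data.table::as.data.table(ages),
                     by = "bee_id")
    out$ages <- lab_age[, list(
      name = cluster_names[as.character(label[1])],
      q25 = stats::quantile(age, 0.25), median = stats::median(age),
      q75 = stats::quantile(age, 0.75), n = .N), by = label]
  }
  out
}
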