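#' Vector correlation of behavioural fingerprints
#'
#' The vector generalisation of the Pearson correlation coefficient
#' between a bee's metric vector at one hour and at another:
#' `C_i = sum_j X_ij Y_ij / sqrt(sum_j X_ij^2 * sum_j Y_ij^2)`.
#' Both matrices must already be normalised with *common* per-metric
#' factors (see [normalize_hours()]), so `C_i` measures persistence of the
#' bee's deviation profile from the colony average. Bees with a zero-norm
#' vector in either hour are excluded (returned as `NA`, with a logged
#' count). `C_i` is bounded in `[-1, 1]` by Cauchy-Schwarz.
#'
#' @param X,Y Numeric matrices, rows = bees (shared index), columns = the
#'   same metrics in the same order (hard error otherwise).
#' @return Numeric vector of per-bee coefficients.
#' @export
vector_correlation <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (!identical(dim(X), dim(Y)))
    stop("X and Y must have identical dimensions", call. = FALSE)
  if (!is.null(colnames(X)) && !is.null(colnames(Y)) &&
      !identical(colnames(X), colnames(Y)))
    stop("X and Y must share the same metric columns", call. = FALSE)
  nx <- rowSums(X^2)
  ny <- rowSums(Y^2)
  ok <- nx > 0 & ny > 0
  if (any(!ok))
    message(sprintf("vector correlation: %d zero-norm bee(s) excluded",
                    sum(!ok)))
  out <- rep(NA_real_, nrow(X))
  out[ok] <- rowSums(X * Y)[ok] / sqrt(nx[ok] * ny[ok])
  out
}

#' Normalise hourly metric rows with common factors
#'
#' Applies the stored per-metric mean and standard deviation of the pooled
#' behavioural matrix to an arbitrary set of hourly metric rows, so every
#' comparison hour is scaled identically.
#'
#' @param rows Data frame containing the metric columns.
#' @param bm A `behaviour_matrix` supplying `center` and `scale`.
#' @return Numeric matrix with one z-scored row per input row, restricted
#'   to the matrix's (non-degenerate) metric columns.
#' @export
normalize_hours <- function(rows, bm) {
  stopifnot(inherits(bm, "behaviour_matrix"))
  X <- as.matrix(data.table::as.data.table(rows)[, bm$metrics, with = FALSE])
  sweep(sweep(X, 2, bm$center), 2, bm$scale, "/")
}

#' Behavioural correlation series over the day
#'
#' For each control and stress day, correlates every bee's metric vector in
#' the reference hour (9.00-10.00 by default) with its vector at each
#' subsequent hour up to 9.00 the following day, using common
#' normalisation factors from the pooled behavioural matrix. Bees enter an
#' hour's comparison if they have complete metrics at the reference hour
#' and at that hour (pairwise inclusion). Per-hour medians and quartiles
#' are pooled across days of the same kind.
#'
#' @param hourly_metrics Hourly metrics table ([aggregate_metrics()]),
#'   covering the days in `schedule` (and the morning after, where
#'   available).
#' @param schedule Schedule data frame; days with kind `"control"` or
#'   `"stress"` contribute, others are ignored.
#' @param bm A `behaviour_matrix` supplying the common normalisation
#'   factors.
#' @param h1_hour Reference clock hour (default 9).
#' @param n_hours Number of hourly offsets after the reference (default 24,
#'   i.e. until 9.00 the next day).
#' @return A list with `series` (data.table: day_kind, hour, median, q25,
#'   q75, n_bees; `hour` is clock hours since midnight of the focal day,
#'   9..33) and `per_bee` (long table of individual coefficients).
#' @export
correlation_series <- function(hourly_metrics, schedule, bm, h1_hour = 9,
                               n_hours = 24) {
  m <- data.table::as.data.table(hourly_metrics)
  m <- m[stats::complete.cases(m[, bm$metrics, with = FALSE])]
  m[, t0 := as.numeric(bin_start)]
  days <- schedule[schedule$kind %in% c("control", "stress"), , drop = FALSE]
  if (nrow(days) == 0L) stop("schedule has no control or stress days",
                             call. = FALSE)
  per_bee <- list()
  for (d in seq_len(nrow(days))) {
    midnight <- as.numeric(as.POSIXct(paste0(format(days$date[d]),
                                             " 00:00:00"), tz = "UTC"))
    ref <- m[t0 == midnight + h1_hour * 3600]
    if (nrow(ref) == 0L)
      stop("reference hour missing on ", format(days$date[d]),
           call. = FALSE)
    Xall <- normalize_hours(ref, bm)
    for (off in 0:n_hours) {
      cmp <- m[t0 == midnight + (h1_hour + off) * 3600]
      both <- intersect(ref$bee_id, cmp$bee_id)
      if (length(both) == 0L) next
      X <- Xall[match(both, ref$bee_id), , drop = FALSE]
      Y <- normalize_hours(cmp[match(both, cmp$bee_id)], bm)
      ci <- suppressMessages(vector_correlation(X, Y))
      per_bee[[length(per_bee) + 1L]] <- data.table::data.table(
        day_kind = days$kind[d], date = days$date[d],
        hour = h1_hour + off, bee_id = both, C = ci)
    }
  }
  per_bee <- data.table::rbindlist(per_bee)
  per_bee <- per_bee[!is.na(C)]
  series <- per_bee[, list(median = stats::median(C),
                           q25 = stats::quantile(C, 0.25),
                           q75 = stats::quantile(C, 0.75),
                           n_bees = .N),
                    by = list(day_kind, hour)]
  data.table::setorder(series, day_kind, hour)
  list(series = series, per_bee = per_bee)
}
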