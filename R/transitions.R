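#' Morning-to-heat-stress cluster transition table
#'
#' Cross-tabulates, for bees clustered in both the morning and the
#' heat-stress period of the same day, their joint cluster membership.
#' Reports the counts `N[i, j]`, the joint fractions `F[i, j]` (summing to
#' 1 over bees observed in both periods), the marginal fractions `m[i]`
#' (morning) and `h[j]` (heat), the independence null
#' `F*[i, j] = m[i] * h[j]`, and the percent difference
#' `100 * (F - F*) / F*`. Cells with an empty marginal (`F* = 0`) have an
#' undefined percent difference and are reported as `NA`.
#'
#' The joint normalisation is used (rather than the row-conditional
#' fraction) because only the joint fraction is commensurate with the
#' product-of-marginals null; the row-conditional table `N[i, j] / N[i, .]`
#' is exposed as `conditional` for inspection.
#'
#' @param morning_labels,heat_labels Data frames with `bee_id`, `date`,
#'   `label` (e.g. `model$labels` from [ward_cluster()]).
#' @return An object of class `transition_table`: list with `counts`,
#'   `F`, `m`, `h`, `F_star`, `pct_diff` (percent), `conditional`,
#'   `pairs` (the matched bee-day label pairs) and `n_excluded` (bees
#'   labelled in only one period).
#' @export
compute_transitions <- function(morning_labels, heat_labels) {
  ml <- data.table::as.data.table(morning_labels)
  hl <- data.table::as.data.table(heat_labels)
  pairs <- merge(ml, hl, by = c("bee_id", "date"),
                 suffixes = c("_morning", "_heat"))
  if (nrow(pairs) == 0L)
    stop("no bees labelled in both periods", call. = FALSE)
  n_excluded <- (nrow(ml) - nrow(pairs)) + (nrow(hl) - nrow(pairs))
  if (n_excluded > 0)
    message(sprintf("transitions: %d single-period label(s) excluded",
                    n_excluded))
  counts <- table(morning = pairs$label_morning, heat = pairs$label_heat)
  counts <- unclass(counts)
  n <- sum(counts)
  F <- counts / n
  m <- rowSums(F)
  h <- colSums(F)
  F_star <- outer(m, h)
  pct_diff <- ifelse(F_star > 0, 100 * (F - F_star) / F_star, NA_real_)
  cond <- sweep(counts, 1, rowSums(counts), "/")
  out <- list(counts = counts, F = F, m = m, h = h, F_star = F_star,
              pct_diff = pct_diff, conditional = cond, pairs = pairs,
              n_excluded = n_excluded)
  class(out) <- "transition_table"
  out
}

#' Permutation envelope for transition percent differences
#'
#' Generates a per-cell null distribution of the percent difference by
#' permuting the heat-stress labels across bees (which preserves both
#' marginals' composition while breaking the pairing), and reports
#' per-cell quantiles of that distribution rather than p-values.
#'
#' @param table A `transition_table`.
#' @param n_permutations Number of permutations (>= 1).
#' @param seed Integer seed for the permutation stream.
#' @param probs Quantile probabilities to report.
#' @return A list with `observed` (the pct_diff matrix) and `quantiles`
#'   (array cells x probs).
#' @export
pct_diff_significance <- function(table, n_permutations = 1000, seed = 1L,
                                  probs = c(0.005, 0.025, 0.25, 0.5,
                                            0.75, 0.975, 0.995)) {
  stopifnot(inherits(table, "transition_table"), n_permutations >= 1)
  pairs <- table$pairs
  mi <- rownames(table$counts)
  hj <- colnames(table$counts)
  null_draws <- array(NA_real_,
                      dim = c(length(mi), length(hj), n_permutations),
                      dimnames = list(mi, hj, NULL))
  with_seed(seed, {
    for (p in seq_len(n_permutations)) {
      perm <- sample(pairs$label_heat)
      counts <- unclass(table(factor(pairs$label_morning, levels = mi),
                              factor(perm, levels = hj)))
      F <- counts / sum(counts)
      F_star <- outer(rowSums(F), colSums(F))
      null_draws[, , p] <- ifelse(F_star > 0, 100 * (F - F_star) / F_star,
                                  NA_real_)
    }
  })
  qs <- apply(null_draws, c(1, 2), stats::quantile, probs = probs,
              na.rm = TRUE)
  qs <- aperm(qs, c(2, 3, 1))
  dimnames(qs)[[3]] <- paste0("q", probs)
  list(observed = table$pct_diff, quantiles = qs)
}
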