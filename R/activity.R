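#' Euclidean magnitude of a triaxial acceleration sample
#'
#' @param ax,ay,az acceleration components in g-units (vectorised).
#' @return `sqrt(ax^2 + ay^2 + az^2)`.
#' @export
accel_magnitude <- function(ax, ay, az) sqrt(ax^2 + ay^2 + az^2)

#' Jerk-proportional activity metric per epoch
#'
#' Three-step reduction of a 100 Hz acceleration-magnitude series to one
#' activity value per 10-s epoch: (1) the magnitude cancels orientation,
#' (2) a moving standard deviation with a 5-sample window cancels the
#' gravitational offset (an SD is shift-invariant) and tracks the jerk,
#' (3) nonoverlapping 1000-sample block means (10 s at 100 Hz) give the
#' epoch metric.  The moving SD is centered, uses the sample (n-1)
#' denominator, and shrinks its window at the series boundaries; a
#' trailing partial block is dropped.
#'
#' @param magnitudes numeric vector, acceleration magnitude at `rate` Hz
#'   (see [accel_magnitude()]).
#' @param rate sampling rate in Hz (default 100).
#' @param epoch_s epoch length in seconds (default 10); block size is
#'   `rate * epoch_s` samples.
#' @param sd_window moving-SD window in samples (default 5).
#' @return One nonnegative metric value per complete epoch,
#'   `floor(length(magnitudes) / (rate * epoch_s))` values in all.
#' @export
jerk_metric <- function(magnitudes, rate = 100, epoch_s = 10,
                        sd_window = 5L) {
  block <- as.integer(rate * epoch_s)
  n_blocks <- length(magnitudes) %/% block
  if (n_blocks == 0L) {
    warning("series shorter than one ", epoch_s, "-s block; no epochs")
    return(numeric(0))
  }
  msd <- zoo::rollapply(magnitudes, width = sd_window, FUN = stats::sd,
                        align = "center", partial = TRUE)
  used <- msd[seq_len(n_blocks * block)]
  as.numeric(colMeans(matrix(used, nrow = block)))
}

#' Classify epoch activity metrics into low / middle / high
#'
#' A 3-cluster k-means on the scalar jerk metric, fitted per recording
#' (clusters are recording-specific; there is no cross-recording
#' calibration).  Initial centres are spread over the metric's quantiles,
#' which makes the fit deterministic and independent of epoch order.
#' Clusters are relabelled by ascending centre so the mapping is
#' monotone: a larger metric never receives a lower level.
#'
#' @param metrics numeric vector of per-epoch metrics (at least 3
#'   distinct values).
#' @param k number of levels (default 3).
#' @param seed retained for interface stability; the quantile-seeded fit
#'   is deterministic, so it has no effect.
#' @return Ordered factor with levels `low < middle < high` (or
#'   `level1 < ...` for `k != 3`), one per epoch.
#' @export
classify_levels <- function(metrics, k = 3L, seed = 1L) {
  ux <- sort(unique(metrics))
  if (length(ux) < k)
    stop("need at least ", k, " distinct metric values to form ", k,
         " activity clusters", call. = FALSE)
  centers <- stats::quantile(ux, (seq_len(k) * 2 - 1) / (2 * k),
                             names = FALSE)
  if (length(unique(centers)) < k)
    centers <- ux[round(seq(1, length(ux), length.out = k))]
  km <- stats::kmeans(metrics, centers = matrix(centers, ncol = 1),
                     iter.max = 100L)
  ord <- order(km$centers)
  labels <- if (k == 3L) c("low", "middle", "high")
            else paste0("level", seq_len(k))
  lev <- labels[match(km$cluster, ord)]
  factor(lev, levels = labels, ordered = TRUE)
}

#' Per-epoch activity profile of a raw acceleration recording
#'
#' Convenience wrapper: magnitude, jerk metric and k-means level in one
#' call.
#'
#' @param accel data frame with columns `ax`, `ay`, `az` (g-units) at
#'   `rate` Hz; a `t` column, if present, is ignored beyond ordering.
#' @param rate,epoch_s,seed see [jerk_metric()] and [classify_levels()].
#' @return Data frame with one row per complete epoch: `epoch`, `metric`,
#'   `level`.
#' @export
activity_profile <- function(accel, rate = 100, epoch_s = 10, seed = 1L) {
  stopifnot(all(c("ax", "ay", "az") %in% names(accel)))
  metric <- jerk_metric(accel_magnitude(accel$ax, accel$ay, accel$az),
                        rate = rate, epoch_s = epoch_s)
  data.frame(epoch = seq_along(metric) - 1L,
             metric = metric,
             level = classify_levels(metric, seed = seed))
}
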