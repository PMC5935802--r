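#' @keywords internal
"_PACKAGE"

iso8601 <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

default_origin <- function() {
  as.POSIXct("2020-01-01 00:00:00", tz = "UTC")
}

parse_timestamps <- function(x, file) {
  t <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%dT%H:%M:%OSZ")
  t2 <- as.POSIXct(x, tz = "UTC",
                   tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%dT%H:%M:%OS"),
                   optional = TRUE)
  t[is.na(t)] <- t2[is.na(t)]
  if (anyNA(t))
    stop("malformed timestamp in ", file, " at line(s) ",
         paste(utils::head(which(is.na(t)) + 1L, 5), collapse = ", "),
         " (data line numbers; header is line 1)", call. = FALSE)
  t
}

to_epochs <- function(t, epoch_s, origin, file) {
  if (is.null(origin)) origin <- min(t)
  rel <- as.numeric(difftime(t, origin, units = "secs"))
  ep <- rel / epoch_s
  off <- abs(ep - round(ep))
  # half-open [t, t + epoch_s) epochs: timestamps must sit on the grid
  bad <- which(off > 1e-6)
  if (length(bad))
    stop("timestamps in ", file, " are not aligned to the ", epoch_s,
         "-s epoch grid at line(s) ",
         paste(utils::head(bad + 1L, 5), collapse = ", "), call. = FALSE)
  as.integer(round(ep))
}

#' Read device-style delimited streams
#'
#' CSV schemas (headers required, timestamps ISO-8601 UTC, epochs
#' half-open `[t, t + interval)`):
#' * RSSI: `timestamp, receiver_id, beacon_id, rssi_dbm`
#' * steps: `timestamp, receiver_id, steps`
#' * ground truth: `timestamp, area_id`
#' * acceleration: `t, ax, ay, az` (seconds and g-units, 100 Hz)
#'
#' `read_streams()` reads whichever of the files exist in a directory
#' and epoch-indexes them against a common origin (the earliest
#' timestamp seen), so the streams stay mutually aligned.
#'
#' @param dir directory holding `rssi.csv`, `steps.csv` and optionally
#'   `truth.csv`, `accel.csv`, `config.json` (as written by
#'   [write_trial()]).
#' @param epoch_s epoch interval in seconds.
#' @return List with `rssi`, `steps`, `truth`, `accel`, `config`
#'   (missing files yield `NULL`), each epoch-indexed where applicable.
#' @export
read_streams <- function(dir, epoch_s = 10) {
  p <- function(f) file.path(dir, f)
  origin <- NULL
  scan_min <- function(f, col) {
    if (!file.exists(p(f))) return(NULL)
    d <- utils::read.csv(p(f), stringsAsFactors = FALSE)
    if (!nrow(d)) return(NULL)
    min(parse_timestamps(d[[col]], f))
  }
  mins <- c(scan_min("rssi.csv", "timestamp"),
            scan_min("steps.csv", "timestamp"),
            scan_min("truth.csv", "timestamp"))
  if (length(mins)) origin <- as.POSIXct(min(mins), tz = "UTC",
                                         origin = "1970-01-01")
  list(rssi = read_rssi(p("rssi.csv"), epoch_s, origin),
       steps = read_steps(p("steps.csv"), epoch_s, origin),
       truth = if (file.exists(p("truth.csv")))
         read_truth(p("truth.csv"), epoch_s, origin) else NULL,
       accel = if (file.exists(p("accel.csv")))
         utils::read.csv(p("accel.csv")) else NULL,
       config = if (file.exists(p("config.json")))
         jsonlite::read_json(p("config.json"), simplifyVector = TRUE)
       else NULL)
}

read_delim_epochs <- function(path, cols, epoch_s, origin) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(cols, names(d))
  if (length(miss))
    stop(basename(path), " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!nrow(d)) {
    warning(basename(path), " is empty")
    d$epoch <- integer(0)
    return(d)
  }
  t <- parse_timestamps(d$timestamp, basename(path))
  d$epoch <- to_epochs(t, epoch_s, origin, basename(path))
  d
}

#' @rdname read_streams
#' @param path file path.
#' @param origin timestamp of epoch 0 (POSIXct or `NULL` for the file's
#'   earliest timestamp, floored to the grid).
#' @export
read_rssi <- function(path, epoch_s = 10, origin = NULL) {
  d <- read_delim_epochs(path, c("timestamp", "receiver_id", "beacon_id",
                                 "rssi_dbm"), epoch_s, origin)
  data.frame(epoch = d$epoch, receiver_id = d$receiver_id,
             beacon_id = d$beacon_id, rssi = as.numeric(d$rssi_dbm),
             stringsAsFactors = FALSE)
}

#' @rdname read_streams
#' @export
read_steps <- function(path, epoch_s = 10, origin = NULL) {
  d <- read_delim_epochs(path, c("timestamp", "receiver_id", "steps"),
                         epoch_s, origin)
  data.frame(epoch = d$epoch, receiver_id = d$receiver_id,
             steps = as.integer(d$steps), stringsAsFactors = FALSE)
}

#' @rdname read_streams
#' @export
read_truth <- function(path, epoch_s = 10, origin = NULL) {
  d <- read_delim_epochs(path, c("timestamp", "area_id"), epoch_s, origin)
  data.frame(epoch = d$epoch, area_id = d$area_id,
             stringsAsFactors = FALSE)
}

#' Write a synthetic trial as device-style CSV exports
#'
#' Writes `rssi.csv`, `steps.csv`, `truth.csv`, optionally `accel.csv`,
#' and `config.json` under `dir`, in the schemas [read_streams()]
#' expects; the pair round-trips losslessly.
#'
#' @param trial a [simulate_trial()] result.
#' @param dir output directory (created if needed).
#' @param origin timestamp of epoch 0.
#' @return `dir`, invisibly.
#' @export
write_trial <- function(trial, dir, origin = default_origin()) {
  stopifnot(inherits(trial, "synthetic_trial"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  es <- trial$config$epoch_s
  ts <- function(epoch) iso8601(origin + epoch * es)
  utils::write.csv(
    data.frame(timestamp = ts(trial$rssi$epoch),
               receiver_id = trial$rssi$receiver_id,
               beacon_id = trial$rssi$beacon_id,
               rssi_dbm = trial$rssi$rssi),
    file.path(dir, "rssi.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(
    data.frame(timestamp = ts(trial$steps$epoch),
               receiver_id = trial$steps$receiver_id,
               steps = trial$steps$steps),
    file.path(dir, "steps.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(
    data.frame(timestamp = ts(trial$truth$epoch),
               area_id = trial$truth$area_id),
    file.path(dir, "truth.csv"), row.names = FALSE, quote = FALSE)
  if (!is.null(trial$accel))
    utils::write.csv(trial$accel, file.path(dir, "accel.csv"),
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(trial$config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write a localization trace as CSV
#'
#' Columns: `timestamp`, `epoch`, `map_area_raw`, `map_area_smoothed`,
#' `exception_flags`, then one `prob_<area>` column per area when
#' `wide = TRUE`.
#'
#' @param fit a [localize()] result.
#' @param path output file.
#' @param wide include per-area posterior probabilities.
#' @param origin timestamp of epoch 0.
#' @return `path`, invisibly.
#' @export
write_trace <- function(fit, path, wide = FALSE,
                        origin = default_origin()) {
  stopifnot(inherits(fit, "localization"))
  es <- fit$config$epoch_s
  d <- data.frame(timestamp = iso8601(origin + fit$trace$epoch * es),
                  epoch = fit$trace$epoch,
                  map_area_raw = fit$trace$map_raw,
                  map_area_smoothed = fit$trace$map_smooth,
                  exception_flags = fit$trace$exception,
                  stringsAsFactors = FALSE)
  if (wide) {
    probs <- as.data.frame(fit$posterior)
    names(probs) <- paste0("prob_", names(probs))
    d <- cbind(d, probs)
  }
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Full evaluation report of a trace against criterion truth
#'
#' Bundles the error decomposition, the dwelling-time agreement and both
#' confusion-matrix variants; serializable to JSON for the `evaluate`
#' command-line subcommand.
#'
#' @param fit a [localize()] result.
#' @param truth criterion trace (`epoch`, `area_id`).
#' @return List with elements `errors`, `agreement`, `confusion_all`,
#'   `confusion_nontransition`.
#' @export
evaluate_report <- function(fit, truth) {
  err <- error_report(fit, truth)
  agr <- tryCatch(dwelling_agreement(fit, truth), error = function(e) NULL)
  list(errors = unclass(err)[c("T_t", "T_nt", "T_total", "e_hat_t",
                               "e_hat_nt", "e_t", "e_nt", "e_bar_t",
                               "e_total")],
       agreement = if (is.null(agr)) NULL else
         list(p1 = agr$p1, p1_ci = agr$p1_ci, p2 = agr$p2,
              p2_ci = agr$p2_ci, icc = agr$icc,
              mean_diff = agr$mean_diff, fit_all = agr$fit_all,
              fit_over = agr$fit_over, fit_under = agr$fit_under,
              threshold_s = agr$threshold_s),
       confusion_all = unclass(confusion(fit, truth, "all")),
       confusion_nontransition =
         unclass(confusion(fit, truth, "nontransition")))
}

#' Tracking-quality plot
#'
#' Step plot of the reported area index over time, with the criterion
#' trace overlaid in red when supplied.
#'
#' @param fit a [localize()] result.
#' @param truth optional criterion trace.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, the plotted data frame.
#' @export
plot_tracking <- function(fit, truth = NULL, ...) {
  ids <- fit$graph$areas$area_id
  es <- fit$config$epoch_s
  tr <- fit$trace
  op <- graphics::par(mar = c(4, 6, 2, 1))
  on.exit(graphics::par(op))
  if (nrow(tr) == 0) {
    graphics::plot(NA, xlim = c(0, 1), ylim = c(0.5, length(ids) + 0.5),
                   xlab = "time (s)", ylab = "", yaxt = "n",
                   main = "Tracking (empty trace)", ...)
    graphics::axis(2, at = seq_along(ids), labels = ids, las = 1,
                   cex.axis = 0.7)
    return(invisible(tr))
  }
  y <- match(tr$map_smooth, ids)
  graphics::plot(tr$epoch * es, y, type = "s", col = "blue",
                 xlab = "time (s)", ylab = "", yaxt = "n",
                 ylim = c(0.5, length(ids) + 0.5),
                 main = "Tracking quality", ...)
  graphics::axis(2, at = seq_along(ids), labels = ids, las = 1,
                 cex.axis = 0.7)
  if (!is.null(truth)) {
    m <- match(truth$epoch, tr$epoch)
    graphics::lines(truth$epoch * es, match(truth$area_id, ids),
                    type = "s", col = "red")
    graphics::legend("topright", legend = c("estimated", "criterion"),
                     col = c("blue", "red"), lty = 1, cex = 0.8)
  }
  invisible(tr)
}

#' @export
plot.localization <- function(x, truth = NULL, ...) {
  plot_tracking(x, truth, ...)
}

#' Area-by-activity-level time matrix (lasagna layers)
#'
#' Accumulates seconds per (area, activity level) cell and orders the
#' area rows per the requested rule: `"absolute"` -- descending total
#' time; `"relative"` -- descending fraction of time at low-level
#' activity (rooms drift left/top, corridors and stairs right/bottom);
#' `"route"` -- order of first appearance in the trace.
#'
#' @param fit a [localize()] result (or any data frame with `epoch` and
#'   `map_smooth`).
#' @param activity epoch-aligned activity table from
#'   [activity_profile()] (`epoch`, `level`).
#' @param ordering row-ordering rule.
#' @return Matrix (areas x levels) of seconds, rows ordered.
#' @export
lasagna_matrix <- function(fit, activity,
                           ordering = c("absolute", "relative", "route")) {
  ordering <- match.arg(ordering)
  tr <- if (inherits(fit, "localization")) fit$trace else as.data.frame(fit)
  es <- if (inherits(fit, "localization")) fit$config$epoch_s else 10
  m <- match(tr$epoch, activity$epoch)
  ok <- !is.na(m)
  lev <- activity$level[m[ok]]
  area <- tr$map_smooth[ok]
  tab <- table(area, factor(lev, levels = levels(activity$level))) * es
  M <- matrix(tab, nrow = nrow(tab),
              dimnames = list(rownames(tab), colnames(tab)))
  ord <- switch(ordering,
    absolute = order(rowSums(M), decreasing = TRUE),
    relative = order(M[, 1] / pmax(rowSums(M), 1e-12), decreasing = TRUE),
    route = match(unique(area), rownames(M)))
  M[ord, , drop = FALSE]
}

#' Lasagna plot of localization and activity
#'
#' Heatmap of [lasagna_matrix()], colour from zero (dark blue) upward
#' (yellow).
#'
#' @inheritParams lasagna_matrix
#' @param ... passed to [graphics::image()].
#' @return Invisibly, the plotted matrix.
#' @export
plot_lasagna <- function(fit, activity,
                         ordering = c("absolute", "relative", "route"),
                         ...) {
  M <- lasagna_matrix(fit, activity, ordering)
  op <- graphics::par(mar = c(4, 6, 2, 1))
  on.exit(graphics::par(op))
  pal <- grDevices::hcl.colors(64, "viridis")
  graphics::image(seq_len(ncol(M)), seq_len(nrow(M)), t(M[rev(seq_len(nrow(M))), , drop = FALSE]),
                  col = pal, zlim = c(0, max(M, 1)), xaxt = "n", yaxt = "n",
                  xlab = "activity level", ylab = "",
                  main = paste0("Time by area and activity (",
                                match.arg(ordering), " order)"), ...)
  graphics::axis(1, at = seq_len(ncol(M)), labels = colnames(M))
  graphics::axis(2, at = seq_len(nrow(M)), labels = rev(rownames(M)),
                 las = 1, cex.axis = 0.7)
  invisible(M)
}

#' @export
plot.confusion_matrix <- function(x, ...) {
  M <- unclass(x)
  n <- nrow(M)
  op <- graphics::par(mar = c(6, 6, 2, 1))
  on.exit(graphics::par(op))
  pal <- grDevices::hcl.colors(64, "Blues 3", rev = TRUE)
  graphics::image(seq_len(n), seq_len(n), t(M[rev(seq_len(n)), ]),
                  col = pal, zlim = c(0, 1), xaxt = "n", yaxt = "n",
                  xlab = "", ylab = "",
                  main = paste0("Confusion (", attr(x, "variant"), ")"), ...)
  graphics::axis(1, at = seq_len(n), labels = colnames(M), las = 2,
                 cex.axis = 0.7)
  graphics::axis(2, at = seq_len(n), labels = rev(rownames(M)), las = 1,
                 cex.axis = 0.7)
  invisible(x)
}

#' Sweep the corridor weight of motion model 3
#'
#' Re-runs localization over a grid of corridor weights `w` (the study
#' grid is 0.25 to 1.25 by 0.25) on a set of simulated trials and
#' tabulates the error decomposition per `w` and trial.
#'
#' @param graph an [area_graph()].
#' @param trials trial presets to simulate (default 1:3).
#' @param w_values corridor-weight grid.
#' @param seed simulation seed (one trial realisation per trial id).
#' @param ... further arguments to [simulate_trial()].
#' @return Data frame with one row per (`w`, `trial`): `e_nt`, `e_t`,
#'   `e_bar_t`, `e_total` (percent).
#' @export
sweep_corridor_weight <- function(graph, trials = 1:3,
                                  w_values = seq(0.25, 1.25, by = 0.25),
                                  seed = 1L, ...) {
  rows <- list()
  for (tr in trials) {
    sim <- simulate_trial(graph, trial = tr, seed = seed + tr,
                          accel = FALSE, ...)
    for (w in w_values) {
      fit <- localize(graph, sim$rssi, sim$steps,
                      model = motion_model("model3", w = w))
      er <- error_report(fit, sim$truth)
      rows[[length(rows) + 1L]] <- data.frame(
        w = w, trial = tr, e_nt = er$e_nt, e_t = er$e_t,
        e_bar_t = er$e_bar_t, e_total = er$e_total)
    }
  }
  do.call(rbind, rows)
}
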