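#' Plan a walk over the area graph
#'
#' Expands an ordered visit plan into a continuous timeline of dwell and
#' travel segments and reduces it to an epoch-resolution ground-truth
#' trace.  Consecutive planned areas need not be adjacent: connecting
#' areas along the shortest walking path are inserted automatically
#' (traversed, not dwelt in).  Travel time on an edge is its distance
#' divided by the walking speed; while traversing an edge the walker is
#' attributed to the departure area for the first half and the arrival
#' area for the second.  Each epoch's true area is the one occupied for
#' the majority of the epoch; a trailing partial epoch is dropped.
#'
#' @param graph an [area_graph()].
#' @param plan data frame with columns `area_id` and `dwell_s`
#'   (seconds, > 0).
#' @param speed walking speed in m/s.
#' @param epoch_s epoch interval in seconds.
#' @return Data frame (`epoch`, `area_id`) of class `walk_plan` with the
#'   segment timeline attached as attribute `"timeline"` (columns
#'   `kind`, `from`, `to`, `t0`, `t1`, `length_m`) and the speed as
#'   attribute `"speed"`.
#' @export
plan_walk <- function(graph, plan, speed, epoch_s = 10) {
  stopifnot(inherits(graph, "area_graph"), speed > 0)
  plan <- as.data.frame(plan)
  stopifnot(all(c("area_id", "dwell_s") %in% names(plan)),
            all(plan$dwell_s > 0))
  unknown <- setdiff(plan$area_id, graph$areas$area_id)
  if (length(unknown))
    stop("plan visits unknown area(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)

  D <- area_distances(graph)
  edge_len <- function(a, b) D[a, b]   # adjacent pairs only

  seg <- list()
  t <- 0
  push <- function(kind, from, to, dur, len) {
    seg[[length(seg) + 1L]] <<- data.frame(
      kind = kind, from = from, to = to, t0 = t, t1 = t + dur,
      length_m = len, stringsAsFactors = FALSE)
    t <<- t + dur
  }
  for (i in seq_len(nrow(plan))) {
    a <- as.character(plan$area_id[i])
    push("dwell", a, a, plan$dwell_s[i], 0)
    if (i < nrow(plan)) {
      b <- as.character(plan$area_id[i + 1L])
      if (a == b) next
      path <- area_path(graph, a, b)
      if (length(path) < 2)
        stop("no walking path from ", a, " to ", b, call. = FALSE)
      for (j in seq_len(length(path) - 1L)) {
        len <- edge_len(path[j], path[j + 1L])
        push("travel", path[j], path[j + 1L], len / speed, len)
      }
    }
  }
  timeline <- do.call(rbind, seg)

  # piecewise-constant occupancy: travel attributed half to each endpoint
  occ <- timeline
  tr <- occ$kind == "travel"
  if (any(tr)) {
    first <- occ[tr, ]; second <- occ[tr, ]
    mid <- (first$t0 + first$t1) / 2
    first$t1 <- mid; first$to <- first$from
    second$t0 <- mid; second$from <- second$to
    occ <- rbind(occ[!tr, ], first, second)
  }
  occ <- occ[order(occ$t0), ]

  n_epochs <- floor(t / epoch_s)
  area <- character(n_epochs)
  for (k in seq_len(n_epochs)) {
    lo <- (k - 1) * epoch_s; hi <- k * epoch_s
    ov <- pmin(occ$t1, hi) - pmax(occ$t0, lo)
    keep <- ov > 0
    share <- tapply(ov[keep], occ$from[keep], sum)
    area[k] <- names(share)[which.max(share)]
  }
  structure(data.frame(epoch = seq_len(n_epochs) - 1L, area_id = area,
                       stringsAsFactors = FALSE),
            timeline = timeline, speed = speed, epoch_s = epoch_s,
            class = c("walk_plan", "data.frame"))
}

# walker position at instant t: list(a, b, f) -- in area `a` if f == 0,
# else fraction f along the edge a -> b
position_at <- function(timeline, t) {
  i <- findInterval(t, timeline$t0)
  i <- max(1L, min(i, nrow(timeline)))
  s <- timeline[i, ]
  if (s$kind == "dwell" || s$t1 == s$t0)
    list(a = s$from, b = s$from, f = 0)
  else
    list(a = s$from, b = s$to, f = (t - s$t0) / (s$t1 - s$t0))
}

#' Synthesize a beacon RSSI stream for a planned walk
#'
#' Emulates a wrist-worn receiver's 10-s proximity export.  At each
#' epoch's midpoint the walking distance from the walker to every beacon
#' is taken along the graph, and the reading follows a log-distance
#' multi-wall path-loss model,
#' `rssi = P_1m - 10 n log10(max(d, 1)) - wall_db * walls + noise`,
#' with Gaussian dBm noise; `walls` counts the area boundaries (graph
#' hops) between the walker and the beacon's area, since interior
#' partitions dominate indoor attenuation and give in-room beacons their
#' characteristic strong-signal margin.  Readings below the link cutoff (-90 dBm) are
#' dropped, as the radio does.  Beacons on a different floor than the
#' walker are suppressed entirely (cross-floor confusion is not observed
#' in practice; floors attenuate heavily).  With probability
#' `glitch_prob` per epoch one spurious strong reading (+`glitch_db`) of
#' a non-adjacent beacon is injected (reflection/scattering); with
#' probability `dropout_prob` the epoch's readings are removed entirely.
#'
#' @param truth a [plan_walk()] trace (carries the timeline).
#' @param graph an [area_graph()].
#' @param p1m reference power at 1 m, dBm (default -45).
#' @param pathloss path-loss exponent (default 2.5, typical indoor).
#' @param wall_db attenuation per area boundary crossed, dB (default 14,
#'   a typical interior wall plus geometry loss).
#' @param noise_sd dBm noise SD (default 4).
#' @param glitch_prob,glitch_db spurious-reading rate and boost.
#' @param dropout_prob whole-epoch dropout rate.
#' @param cutoff link cutoff in dBm (default -90).
#' @param d_own nominal receiver-beacon distance when inside the
#'   beacon's own area, metres.
#' @param receiver_id receiver label for the stream.
#' @return Data frame (`epoch`, `receiver_id`, `beacon_id`, `rssi`).
#' @export
synthesize_rssi <- function(truth, graph, p1m = -45, pathloss = 2.5,
                            wall_db = 14, noise_sd = 4,
                            glitch_prob = 0.02,
                            glitch_db = 15, dropout_prob = 0.05,
                            cutoff = -90, d_own = 2,
                            receiver_id = "r1") {
  timeline <- attr(truth, "timeline")
  epoch_s <- attr(truth, "epoch_s")
  stopifnot(!is.null(timeline), !is.null(epoch_s))
  D <- area_distances(graph)
  H <- igraph::distances(graph$igraph)   # hop counts = walls crossed
  A <- adjacency(graph)
  ids <- graph$areas$area_id
  floors <- stats::setNames(as.character(graph$areas$floor), ids)
  b_area <- graph$beacons$area_id
  b_id <- graph$beacons$beacon_id

  out <- vector("list", nrow(truth))
  for (k in seq_len(nrow(truth))) {
    if (stats::runif(1) < dropout_prob) next
    pos <- position_at(timeline, (truth$epoch[k]) * epoch_s + epoch_s / 2)
    # walking distance from the walker to each area's reference point
    if (pos$f == 0) {
      d_area <- pmax(D[pos$a, ], 0)
      d_area[pos$a] <- d_own
      here <- pos$a
    } else {
      L <- D[pos$a, pos$b]
      d_area <- pmin(pos$f * L + D[pos$a, ], (1 - pos$f) * L + D[pos$b, ])
      here <- if (pos$f < 0.5) pos$a else pos$b
    }
    fl <- floors[here]
    audible <- floors[b_area] == fl | floors[b_area] == "both" |
      fl == "both"
    d <- d_area[b_area]
    walls <- H[here, b_area]
    rssi <- p1m - 10 * pathloss * log10(pmax(d, 1)) - wall_db * walls +
      stats::rnorm(length(d), 0, noise_sd)
    keep <- audible & rssi >= cutoff
    if (stats::runif(1) < glitch_prob) {
      nonadj <- which(A[here, b_area] == 0 & b_area != here)
      if (length(nonadj)) {
        g <- nonadj[sample.int(length(nonadj), 1L)]
        rssi[g] <- rssi[g] + glitch_db
        keep[g] <- rssi[g] >= cutoff
      }
    }
    if (any(keep))
      out[[k]] <- data.frame(epoch = truth$epoch[k],
                             receiver_id = receiver_id,
                             beacon_id = b_id[keep],
                             rssi = round(rssi[keep], 1),
                             stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out))
    return(data.frame(epoch = integer(), receiver_id = character(),
                      beacon_id = character(), rssi = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Synthesize device-style step counts and raw acceleration
#'
#' Step counts mimic a pedometer at 10-s epochs: epochs containing
#' walking get `cadence * walking-seconds` steps (cadence = speed /
#' 0.7 m stride, about 2 steps/s at normal pace) plus 0-2 incidental
#' steps, so any epoch with more than ~1.5 s of walking exceeds the
#' 2-step threshold by construction; dwelling epochs get 0-2 steps.
#' Raw 100 Hz triaxial acceleration is a 1 g gravity baseline with
#' sensor noise, plus a vertical oscillation at step frequency during
#' walking whose amplitude grows with speed -- enough structure for the
#' jerk metric to separate moving from dwelling epochs.
#'
#' @param truth a [plan_walk()] trace.
#' @param rate accelerometer rate, Hz.
#' @param stride_m stride length used by the cadence model.
#' @param accel generate the (bulky) raw acceleration stream?
#' @param receiver_id receiver label for the step stream.
#' @return List with `steps` (`epoch`, `receiver_id`, `steps`) and
#'   `accel` (`t`, `ax`, `ay`, `az`; `NULL` unless requested).
#' @export
synthesize_motion <- function(truth, rate = 100, stride_m = 0.7,
                              accel = TRUE, receiver_id = "r1") {
  timeline <- attr(truth, "timeline")
  epoch_s <- attr(truth, "epoch_s")
  speed <- attr(truth, "speed")
  stopifnot(!is.null(timeline), !is.null(epoch_s))
  cadence <- speed / stride_m   # steps per second while walking

  tr <- timeline[timeline$kind == "travel", , drop = FALSE]
  walk_secs <- vapply(seq_len(nrow(truth)), function(k) {
    lo <- truth$epoch[k] * epoch_s; hi <- lo + epoch_s
    if (!nrow(tr)) return(0)
    sum(pmax(0, pmin(tr$t1, hi) - pmax(tr$t0, lo)))
  }, numeric(1))

  steps <- round(cadence * walk_secs) +
    sample(0:2, nrow(truth), replace = TRUE)
  steps_df <- data.frame(epoch = truth$epoch, receiver_id = receiver_id,
                         steps = as.integer(steps),
                         stringsAsFactors = FALSE)

  accel_df <- NULL
  if (accel) {
    n <- nrow(truth) * epoch_s * rate
    t <- (seq_len(n) - 1) / rate
    amp <- 0.1 + 0.15 * speed
    walking <- vapply(seq_len(nrow(tr)), function(i)
      t >= tr$t0[i] & t < tr$t1[i], logical(n))
    walking <- if (nrow(tr)) rowSums(matrix(walking, nrow = n)) > 0
               else rep(FALSE, n)
    osc <- ifelse(walking, amp * sin(2 * pi * cadence * t), 0)
    accel_df <- data.frame(
      t = t,
      ax = stats::rnorm(n, 0, 0.004),
      ay = stats::rnorm(n, 0, 0.004),
      az = 1 + osc + stats::rnorm(n, 0, 0.004))
  }
  list(steps = steps_df, accel = accel_df)
}

trial_presets <- list(
  `1` = list(speed = 1.4, dwell_s = 180),  # normal pace, >= 3 min per area
  `2` = list(speed = 0.9, dwell_s = 120),  # slow pace, >= 2 min per area
  `3` = list(speed = 2.0, dwell_s = 60)    # fast pace, >= 1 min per area
)

default_route <- function(graph) {
  targets <- graph$areas$area_id[graph$areas$kind %in% c("room", "social")]
  c(targets, targets[1])   # start and finish in the same location
}

#' Generate a complete synthetic walking trial
#'
#' One call produces everything a recorded trial would: the ground-truth
#' area trace, the receiver RSSI stream, the per-epoch step counts and
#' (optionally) raw 100 Hz acceleration, all driven by one seed and
#' bit-identical on regeneration.  Trials 1-3 follow the study protocol
#' presets -- a prescribed route through every room and social area,
#' returning to the start, at normal / slow / fast pace (1.4 / 0.9 /
#' 2.0 m/s) with dwells of at least 180 / 120 / 60 s; trial 4 draws a
#' random route, random dwells (30-200 s) and a random preset speed.
#'
#' @param graph an [area_graph()].
#' @param trial 1, 2, 3 or 4 (4 = `"random"`).
#' @param plan optional explicit plan (`area_id`, `dwell_s`) overriding
#'   the preset route.
#' @param speed optional speed override, m/s.
#' @param seed RNG seed; every stochastic element derives from it.
#' @param noise_sd,glitch_prob,glitch_db,dropout_prob RSSI imperfection
#'   parameters, see [synthesize_rssi()]; set all to zero for the clean
#'   limit.
#' @param epoch_s epoch interval, seconds.
#' @param accel generate raw acceleration (sizeable; skip for speed).
#' @param receiver_id receiver label.
#' @return Object of class `synthetic_trial`: list with `truth`,
#'   `rssi`, `steps`, `accel` and `config`.
#' @examples
#' g <- read_beacon_map(example_map())
#' trial <- simulate_trial(g, trial = 1, seed = 42, accel = FALSE)
#' head(trial$truth)
#' @export
simulate_trial <- function(graph, trial = 1, plan = NULL, speed = NULL,
                           seed = 1L, noise_sd = 4, glitch_prob = 0.02,
                           glitch_db = 15, dropout_prob = 0.05,
                           wall_db = 14, epoch_s = 10, accel = TRUE,
                           receiver_id = "r1") {
  stopifnot(inherits(graph, "area_graph"))
  trial <- as.character(trial)
  if (trial == "random") trial <- "4"
  stopifnot(trial %in% c("1", "2", "3", "4"))
  set.seed(seed)

  if (is.null(plan)) {
    if (trial %in% names(trial_presets)) {
      p <- trial_presets[[trial]]
      if (is.null(speed)) speed <- p$speed
      route <- default_route(graph)
      plan <- data.frame(area_id = route, dwell_s = p$dwell_s,
                         stringsAsFactors = FALSE)
    } else {
      targets <- graph$areas$area_id[graph$areas$kind %in%
                                       c("room", "social")]
      route <- sample(targets, max(3L, length(targets)), replace = FALSE)
      route <- c(route, route[1])
      plan <- data.frame(area_id = route,
                         dwell_s = stats::runif(length(route), 30, 200),
                         stringsAsFactors = FALSE)
      if (is.null(speed))
        speed <- sample(c(0.9, 1.4, 2.0), 1L)
    }
  } else if (is.null(speed)) {
    speed <- 1.4
  }

  truth <- plan_walk(graph, plan, speed, epoch_s)
  rssi <- synthesize_rssi(truth, graph, wall_db = wall_db,
                          noise_sd = noise_sd,
                          glitch_prob = glitch_prob,
                          glitch_db = glitch_db,
                          dropout_prob = dropout_prob,
                          receiver_id = receiver_id)
  motion <- synthesize_motion(truth, accel = accel,
                              receiver_id = receiver_id)
  structure(list(truth = truth, rssi = rssi, steps = motion$steps,
                 accel = motion$accel,
                 config = list(trial = trial, speed = speed, seed = seed,
                               noise_sd = noise_sd,
                               glitch_prob = glitch_prob,
                               glitch_db = glitch_db,
                               dropout_prob = dropout_prob,
                               wall_db = wall_db,
                               epoch_s = epoch_s)),
            class = "synthetic_trial")
}

#' @export
print.synthetic_trial <- function(x, ...) {
  cat(sprintf("Synthetic trial %s: %d epochs (%.0f s) at %.1f m/s, seed %d\n",
              x$config$trial, nrow(x$truth),
              nrow(x$truth) * x$config$epoch_s, x$config$speed,
              x$config$seed))
  cat(sprintf("  RSSI rows: %d; noise %.1f dB, glitch %.0f%%, dropout %.0f%%\n",
              nrow(x$rssi), x$config$noise_sd, 100 * x$config$glitch_prob,
              100 * x$config$dropout_prob))
  invisible(x)
}
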