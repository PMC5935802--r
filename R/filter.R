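#' Localization run configuration
#'
#' Defaults mirror the wrist-worn receiver setup the algorithm was
#' designed for: 10-s proximity epochs (0.1 Hz, the device maximum),
#' RSSI anchors at -45 / -90 dBm, and an anti-hopping stability
#' requirement of 2 consecutive samples (20 s).
#'
#' @param epoch_s epoch interval in seconds.
#' @param stable_len samples a new area must persist before the reported
#'   position switches (anti-hopping rule).
#' @param rssi_hi,rssi_lo RSSI anchors in dBm for the proximity map.
#' @param rssi_map optional replacement mapping function (dBm ->
#'   probability); default is the clipped linear [rssi_to_prob()] between
#'   the anchors.
#' @param transition_window epochs on either side of a ground-truth area
#'   change counted as transition period by the evaluation module.
#' @return An object of class `loc_config`.
#' @export
loc_config <- function(epoch_s = 10, stable_len = 2L,
                       rssi_hi = -45, rssi_lo = -90,
                       rssi_map = NULL, transition_window = 1L) {
  stopifnot(epoch_s > 0, stable_len >= 1, rssi_hi > rssi_lo,
            transition_window >= 0)
  if (is.null(rssi_map))
    rssi_map <- function(rssi) rssi_to_prob(rssi, hi = rssi_hi, lo = rssi_lo)
  structure(list(epoch_s = epoch_s, stable_len = as.integer(stable_len),
                 rssi_hi = rssi_hi, rssi_lo = rssi_lo, rssi_map = rssi_map,
                 transition_window = as.integer(transition_window)),
            class = "loc_config")
}

norm_vec <- function(v) {
  s <- sum(v)
  if (s <= 0)
    stop(structure(class = c("roomtrack_degenerate", "error", "condition"),
                   list(message = "all-zero vector in norm()", call = NULL)))
  v / s
}

#' One prediction step
#'
#' Propagates the state through the motion model:
#' `X~[k+1] = norm(X[k] %*% M)`.
#'
#' @param x state vector (normalized, length N).
#' @param M transition-weight matrix from [transition_matrix()].
#' @return Normalized predicted state.  An all-zero product raises a
#'   condition of class `roomtrack_degenerate`, which [localize()] routes
#'   through exception management.
#' @export
bayes_predict <- function(x, M) {
  stopifnot(length(x) == nrow(M), nrow(M) == ncol(M))
  norm_vec(as.numeric(x %*% M))
}

#' One measurement-update step
#'
#' `X[k+1] = norm(X~[k+1] (*) Y[k+1])`, a point-wise product of the
#' predicted state with the normalized measurement vector.
#'
#' @param x predicted state vector.
#' @param y normalized measurement vector (`Y` from
#'   [build_measurement()]).
#' @return Normalized posterior.  Disjoint supports (all-zero product)
#'   raise a `roomtrack_degenerate` condition (exception 1 path).
#' @export
bayes_update <- function(x, y) {
  stopifnot(length(x) == length(y))
  norm_vec(x * y)
}

#' Anti-hopping smoothing of a MAP area sequence
#'
#' Reflection and scattering can make the raw most-probable area hop
#' between adjacent rooms.  The reported area therefore only switches to
#' a new area once it has persisted for at least `min_run` consecutive
#' samples (20 s at the default), and then retroactively from the first
#' sample of the stable run; shorter excursions are suppressed, holding
#' the pre-hop area.  With `min_run = 2` this is a 1-sample-lookahead
#' rule, harmless in offline batch processing.
#'
#' @param map_idx integer vector of raw MAP area indices.
#' @param min_run required run length (default 2 samples).
#' @return Integer vector of the same length: the smoothed sequence.
#' @examples
#' smooth_hops(c(1, 2, 1))        # 1 1 1 (single-sample excursion)
#' smooth_hops(c(1, 2, 2, 2))     # 1 2 2 2 (stable from its first sample)
#' @export
smooth_hops <- function(map_idx, min_run = 2L) {
  n <- length(map_idx)
  if (n == 0L) return(integer(0))
  min_run <- as.integer(min_run)
  out <- integer(n)
  cur <- map_idx[1L]
  out[1L] <- cur
  if (n == 1L) return(out)
  for (k in 2:n) {
    v <- map_idx[k]
    if (v != cur) {
      run_end <- k + min_run - 1L
      if (run_end <= n && all(map_idx[k:run_end] == v)) cur <- v
    }
    out[k] <- cur
  }
  out
}

#' Run the graph-constrained Bayesian localization filter
#'
#' The full recursion over an epoch-aligned RSSI stream: build the
#' per-epoch measurement vector, predict through the step-count-modulated
#' motion model, update, and apply exception management:
#'
#' 1. *Degenerate posterior* (`c != 0` but predicted and measured support
#'    disjoint, so the product is zero everywhere): the state is resampled
#'    to uniform and the reported area held at the previous epoch's --
#'    the reading was likely a reflection glitch.
#' 2. *No measurement* (`c == 0`): no update is performed; state and
#'    reported area carry forward unchanged.
#' 3. *Anti-hopping*: the reported area switches only after the new area
#'    is stable for `stable_len` samples (see [smooth_hops()]).
#'
#' The state is initialized uniform over all areas; ties in the argmax
#' are broken towards the lowest area index.  The run is deterministic.
#'
#' @param graph an [area_graph()].
#' @param rssi data frame with columns `epoch` (integer, consecutive
#'   epochs may be absent -- absence means no detection), `beacon_id`,
#'   `rssi` (dBm).  A `receiver_id` column, if present, must hold a
#'   single receiver; filter each receiver's stream separately (see
#'   [majority_vote()]).
#' @param steps data frame with columns `epoch` and `steps`, or `NULL`
#'   (required by models 2 and 3); epochs missing from it are treated as
#'   0 steps with a warning (a stationary prior is the conservative
#'   reading of a silent pedometer).
#' @param model a [motion_model()].
#' @param config a [loc_config()].
#' @return An object of class `localization`: list with `trace` (data
#'   frame: `epoch`, `map_raw`, `map_smooth` as area ids, `exception`
#'   flag), `posterior` (epochs x N matrix), plus the graph, model and
#'   config used.
#' @examples
#' g <- read_beacon_map(example_map())
#' trial <- simulate_trial(g, trial = 1, seed = 1)
#' fit <- localize(g, trial$rssi, trial$steps)
#' summary(fit)
#' @export
localize <- function(graph, rssi, steps = NULL,
                     model = motion_model("model3"),
                     config = loc_config()) {
  stopifnot(inherits(graph, "area_graph"), inherits(model, "motion_model"),
            inherits(config, "loc_config"))
  rssi <- as.data.frame(rssi)
  if (!all(c("epoch", "beacon_id", "rssi") %in% names(rssi)))
    stop("`rssi` needs columns epoch, beacon_id, rssi", call. = FALSE)
  if (!is.null(rssi$receiver_id) &&
      length(unique(rssi$receiver_id)) > 1L)
    stop("multiple receiver_ids in one stream; filter each receiver ",
         "separately and combine with majority_vote()", call. = FALSE)

  N <- graph$N
  ids <- graph$areas$area_id
  A <- adjacency(graph)

  if (nrow(rssi) == 0L) {
    trace <- data.frame(epoch = integer(), map_raw = character(),
                        map_smooth = character(), exception = character(),
                        stringsAsFactors = FALSE)
    return(structure(list(trace = trace,
                          posterior = matrix(numeric(), 0, N,
                                             dimnames = list(NULL, ids)),
                          graph = graph, model = model, config = config),
                     class = "localization"))
  }

  epochs <- seq(min(rssi$epoch), max(rssi$epoch))
  K <- length(epochs)

  step_vec <- rep(NA_real_, K)
  if (!is.null(steps)) {
    steps <- as.data.frame(steps)
    stopifnot(all(c("epoch", "steps") %in% names(steps)))
    m <- match(epochs, steps$epoch)
    step_vec <- as.numeric(steps$steps[m])
  }
  if (model$model != "model1") {
    if (is.null(steps))
      stop(model$model, " requires a step-count stream", call. = FALSE)
    if (anyNA(step_vec)) {
      warning(sum(is.na(step_vec)),
              " epoch(s) missing a step count; treated as 0 steps")
      step_vec[is.na(step_vec)] <- 0
    }
  }

  by_epoch <- split(rssi[c("beacon_id", "rssi")], factor(rssi$epoch, epochs))

  post <- matrix(0, K, N, dimnames = list(NULL, ids))
  map_raw <- integer(K)
  exception <- character(K)

  X <- rep(1 / N, N)             # X_0: equal probability everywhere
  prev_map <- 1L                 # lowest index by convention before evidence
  for (k in seq_len(K)) {
    M <- transition_matrix(model, A, graph$areas, step_vec[k])
    meas <- build_measurement(by_epoch[[k]], graph,
                              rssi_map = config$rssi_map)
    flag <- ""
    if (meas$c == 0) {
      # exception 2: no RSSI at all; no update is performed this step
      flag <- "no_measurement"
      map_k <- prev_map
    } else {
      Xp <- tryCatch(bayes_predict(X, M), roomtrack_degenerate = function(e) {
        flag <<- "degenerate_prediction"
        rep(1 / N, N)
      })
      X_new <- tryCatch(bayes_update(Xp, meas$Y),
                        roomtrack_degenerate = function(e) NULL)
      if (is.null(X_new)) {
        # exception 1: measurement inconsistent with the motion model;
        # resample uniform, hold the previous reported area
        flag <- "degenerate_posterior"
        X <- rep(1 / N, N)
        map_k <- prev_map
      } else {
        X <- X_new
        map_k <- which.max(X)    # ties -> lowest index
      }
    }
    post[k, ] <- X
    map_raw[k] <- map_k
    exception[k] <- flag
    prev_map <- map_k
  }

  map_smooth <- smooth_hops(map_raw, config$stable_len)
  trace <- data.frame(epoch = epochs,
                      map_raw = ids[map_raw],
                      map_smooth = ids[map_smooth],
                      exception = exception,
                      stringsAsFactors = FALSE)
  structure(list(trace = trace, posterior = post, graph = graph,
                 model = model, config = config),
            class = "localization")
}

#' @export
print.localization <- function(x, ...) {
  cat("Localization trace:", nrow(x$trace), "epochs,",
      x$graph$N, "areas,", x$model$model, "\n")
  ex <- table(x$trace$exception[x$trace$exception != ""])
  if (length(ex))
    cat("  exceptions:",
        paste(names(ex), ex, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.localization <- function(object, ...) {
  tr <- object$trace
  occ <- sort(table(tr$map_smooth), decreasing = TRUE)
  res <- list(n_epochs = nrow(tr), epoch_s = object$config$epoch_s,
              model = object$model$model,
              occupancy_s = occ * object$config$epoch_s,
              n_exceptions = sum(tr$exception != ""),
              n_hops_suppressed = sum(tr$map_raw != tr$map_smooth))
  class(res) <- "summary.localization"
  res
}

#' @export
print.summary.localization <- function(x, ...) {
  cat("Localization of", x$n_epochs, "epochs (", x$n_epochs * x$epoch_s,
      "s ) under", x$model, "\n")
  cat("Exceptions fired:", x$n_exceptions,
      "; epochs corrected by anti-hopping:", x$n_hops_suppressed, "\n")
  cat("Dwelling time by area (s):\n")
  print(x$occupancy_s)
  invisible(x)
}

#' Combine several receivers' traces by per-epoch majority vote
#'
#' The study protocol wears several receivers at once; each stream is
#' filtered independently and this optional post-hoc vote fuses the
#' smoothed area sequences.  Ties go to the area reported by the earliest
#' listed trace.
#'
#' @param fits list of `localization` objects over the same graph and
#'   epoch range.
#' @return Data frame with `epoch` and the voted `map_smooth`.
#' @export
majority_vote <- function(fits) {
  stopifnot(length(fits) >= 1,
            all(vapply(fits, inherits, TRUE, "localization")))
  epochs <- fits[[1]]$trace$epoch
  for (f in fits[-1])
    if (!identical(f$trace$epoch, epochs))
      stop("traces are not epoch-aligned", call. = FALSE)
  votes <- vapply(fits, function(f) f$trace$map_smooth,
                  character(length(epochs)))
  votes <- matrix(votes, nrow = length(epochs))
  map <- apply(votes, 1L, function(v) names(which.max(table(factor(v, unique(v))))))
  data.frame(epoch = epochs, map_smooth = map, stringsAsFactors = FALSE)
}
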