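#' Map an RSSI reading to a proximity probability
#'
#' Signal strength is converted to a heuristic proximity probability using
#' two anchors observed for wrist-worn BLE receivers: readings never
#' exceed -45 dBm when the receiver is within 1 m of the beacon, and the
#' link drops entirely below -90 dBm.  Between the anchors the map is
#' linear in dBm, `y = (rssi - lo) / (hi - lo)`, clipped to [0, 1]; it is
#' monotone nondecreasing.  The mapping is pluggable: [localize()] accepts
#' any function of the same signature via its config.
#'
#' @param rssi numeric vector of readings in dBm.
#' @param hi RSSI at/above which proximity probability is 1 (default -45).
#' @param lo RSSI at/below which the link is considered absent (default
#'   -90; readings below it map to 0 rather than erroring).
#' @return Probabilities in [0, 1], vectorised over `rssi`.
#' @examples
#' rssi_to_prob(c(-45, -67.5, -95))   # 1, 0.5, 0
#' @export
rssi_to_prob <- function(rssi, hi = -45, lo = -90) {
  stopifnot(hi > lo)
  pmin(1, pmax(0, (rssi - lo) / (hi - lo)))
}

#' Per-area measurement vector for one epoch
#'
#' Aggregates the epoch's per-beacon readings to grouped-area level: each
#' area's unnormalized entry is the *maximum* mapped probability over its
#' beacons heard this epoch (nearest-beacon logic; summing would
#' double-weight areas that happen to hold several beacons), zero when
#' none was heard.  `c` is the sum of unnormalized entries; `Y = y / c`
#' when `c > 0`, and is flagged absent when `c == 0` (no detection --
#' exception 2 territory for the filter).
#'
#' @param samples data frame with columns `beacon_id` and `rssi` for one
#'   epoch (zero rows allowed).  Repeated readings of one beacon within
#'   the epoch keep the maximum.
#' @param graph an [area_graph()].
#' @param rssi_map function mapping dBm to [0, 1]; default
#'   [rssi_to_prob()].
#' @return List with `y` (unnormalized, named by area), `c` (its sum) and
#'   `Y` (normalized vector, or `NULL` when `c == 0`).
#' @export
build_measurement <- function(samples, graph, rssi_map = rssi_to_prob) {
  stopifnot(inherits(graph, "area_graph"))
  ids <- graph$areas$area_id
  y <- stats::setNames(numeric(graph$N), ids)
  if (NROW(samples)) {
    idx <- match(samples$beacon_id, graph$beacons$beacon_id)
    if (anyNA(idx))
      stop("unknown beacon_id: ",
           paste(unique(samples$beacon_id[is.na(idx)]), collapse = ", "),
           call. = FALSE)
    area <- graph$beacons$area_id[idx]
    p <- rssi_map(samples$rssi)
    agg <- tapply(p, area, max)
    y[names(agg)] <- agg
  }
  cc <- sum(y)
  list(y = y, c = cc, Y = if (cc > 0) y / cc else NULL)
}
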