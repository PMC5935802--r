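#' Build a validated area graph
#'
#' The building is represented as a graph whose nodes are *grouped areas*
#' (rooms, social areas, corridors, stairs) and whose edges are walking
#' pathways.  Beacons are grouped into the area they serve; several beacons
#' may serve one area (large social areas, long corridors).  The filter
#' operates on grouped areas, never on raw beacons, so the graph fixes the
#' state indexing `1..N` used everywhere downstream.
#'
#' @param areas data frame with columns `area_id`, `kind` (one of
#'   `"room"`, `"social"`, `"corridor"`, `"stairs"`) and `floor`
#'   (integer, or `"both"` for stairs).
#' @param beacons data frame with columns `beacon_id` and `area_id`.
#' @param edges data frame with columns `from`, `to` and optionally
#'   `distance` (walking distance in metres; defaults to 8 m, a typical
#'   door-to-door spacing, used only by the simulator).
#' @return An object of class `area_graph`: a list with elements `areas`,
#'   `beacons`, `edges`, `N` and the underlying `igraph` object.
#' @seealso [read_beacon_map()], [adjacency()]
#' @examples
#' g <- area_graph(
#'   areas   = data.frame(area_id = c("R1", "R2"),
#'                        kind = "room", floor = 1L),
#'   beacons = data.frame(beacon_id = c("R1", "R2"),
#'                        area_id = c("R1", "R2")),
#'   edges   = data.frame(from = "R1", to = "R2"))
#' g$N
#' @export
area_graph <- function(areas, beacons, edges) {
  areas <- as.data.frame(areas, stringsAsFactors = FALSE)
  beacons <- as.data.frame(beacons, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)

  req <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop(sprintf("%s is missing column(s): %s", what,
                   paste(miss, collapse = ", ")), call. = FALSE)
  }
  req(areas, c("area_id", "kind", "floor"), "`areas`")
  req(beacons, c("beacon_id", "area_id"), "`beacons`")
  if (nrow(edges)) req(edges, c("from", "to"), "`edges`")

  areas$area_id <- as.character(areas$area_id)
  areas$kind <- as.character(areas$kind)
  beacons$beacon_id <- as.character(beacons$beacon_id)
  beacons$area_id <- as.character(beacons$area_id)

  dup <- unique(areas$area_id[duplicated(areas$area_id)])
  if (length(dup))
    stop("duplicate area_id: ", paste(dup, collapse = ", "), call. = FALSE)
  dup <- unique(beacons$beacon_id[duplicated(beacons$beacon_id)])
  if (length(dup))
    stop("duplicate beacon_id: ", paste(dup, collapse = ", "), call. = FALSE)

  bad <- setdiff(areas$kind, c("room", "social", "corridor", "stairs"))
  if (length(bad))
    stop("unknown area kind: ", paste(bad, collapse = ", "), call. = FALSE)

  unknown <- setdiff(beacons$area_id, areas$area_id)
  if (length(unknown))
    stop("beacon references unknown area_id: ",
         paste(unknown, collapse = ", "), call. = FALSE)

  if (nrow(edges)) {
    edges$from <- as.character(edges$from)
    edges$to <- as.character(edges$to)
    unknown <- setdiff(c(edges$from, edges$to), areas$area_id)
    if (length(unknown))
      stop("edge references unknown area_id: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    if (any(edges$from == edges$to))
      stop("self-loop edges are not allowed (self-transitions are implicit)",
           call. = FALSE)
    if (is.null(edges$distance)) edges$distance <- 8
    edges$distance[is.na(edges$distance)] <- 8
    if (any(edges$distance <= 0))
      stop("edge distances must be positive", call. = FALSE)
    # canonical unordered form, drop duplicates
    key <- ifelse(edges$from < edges$to,
                  paste(edges$from, edges$to, sep = "\r"),
                  paste(edges$to, edges$from, sep = "\r"))
    edges <- edges[!duplicated(key), c("from", "to", "distance")]
  } else {
    edges <- data.frame(from = character(), to = character(),
                        distance = numeric(), stringsAsFactors = FALSE)
  }

  ig <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = areas$area_id))
  if (nrow(areas) > 1L && !igraph::is_connected(ig)) {
    comp <- igraph::components(ig)
    small <- names(comp$membership)[comp$membership != which.max(comp$csize)]
    stop("area graph is not connected; unreachable area(s): ",
         paste(small, collapse = ", "), call. = FALSE)
  }

  structure(
    list(areas = areas, beacons = beacons, edges = edges,
         N = nrow(areas), igraph = ig),
    class = "area_graph")
}

#' Load a beacon-map configuration
#'
#' Reads a YAML (or JSON, a YAML subset) beacon map with top-level keys
#' `areas` (list of `id`, `kind`, `floor`), `beacons` (list of `id`,
#' `area`, optional `placement`) and `edges` (list of `from`, `to`,
#' optional `distance` in metres), validates it and returns the grouped
#' [area_graph()].  A packaged example map of a two-floor office building
#' (17 beacons grouped into 14 areas) ships as
#' `system.file("extdata", "building_map.yaml", package = "roomtrack")`.
#'
#' @param path path to the configuration file.
#' @return An `area_graph`.
#' @examples
#' g <- read_beacon_map(example_map())
#' g
#' @export
read_beacon_map <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  for (key in c("areas", "beacons", "edges"))
    if (is.null(cfg[[key]]))
      stop("beacon map is missing top-level key `", key, "`", call. = FALSE)

  pick <- function(lst, field, default = NA) {
    vapply(lst, function(x) {
      v <- x[[field]]
      if (is.null(v)) default else as.character(v)
    }, character(1))
  }
  areas <- data.frame(
    area_id = pick(cfg$areas, "id"),
    kind = pick(cfg$areas, "kind"),
    floor = pick(cfg$areas, "floor"),
    stringsAsFactors = FALSE)
  beacons <- data.frame(
    beacon_id = pick(cfg$beacons, "id"),
    area_id = pick(cfg$beacons, "area"),
    placement_note = pick(cfg$beacons, "placement", ""),
    stringsAsFactors = FALSE)
  edges <- data.frame(
    from = pick(cfg$edges, "from"),
    to = pick(cfg$edges, "to"),
    distance = suppressWarnings(as.numeric(pick(cfg$edges, "distance"))),
    stringsAsFactors = FALSE)
  area_graph(areas, beacons, edges)
}

#' Path to the packaged example beacon map
#'
#' A two-floor mixed-use office layout: 5 standard rooms, 2 social areas
#' (2 beacons each), 6 corridor areas (one long corridor covered by 2
#' beacons) and a stairway beacon serving both floors -- 17 beacons grouped
#' into 14 areas.
#'
#' @return File path of the YAML map.
#' @export
example_map <- function() {
  system.file("extdata", "building_map.yaml", package = "roomtrack",
              mustWork = TRUE)
}

#' Adjacency matrix of an area graph
#'
#' Returns the sparse-structured transition skeleton `A`: `a[i,j] = 1`
#' when areas `i` and `j` are connected by a walking pathway or `i == j`
#' (staying put is always possible), else 0.  Motion model 1 uses `M = A`
#' directly; models 2 and 3 reweight the diagonal.
#'
#' @param graph an [area_graph()].
#' @return An `N x N` 0/1 matrix with `dimnames` set to area ids.
#' @export
adjacency <- function(graph) {
  stopifnot(inherits(graph, "area_graph"))
  ids <- graph$areas$area_id
  A <- diag(1, graph$N)
  dimnames(A) <- list(ids, ids)
  if (nrow(graph$edges)) {
    i <- match(graph$edges$from, ids)
    j <- match(graph$edges$to, ids)
    A[cbind(i, j)] <- 1
    A[cbind(j, i)] <- 1
  }
  A
}

#' @export
print.area_graph <- function(x, ...) {
  cat("Area graph:", x$N, "areas,", nrow(x$edges), "pathways,",
      nrow(x$beacons), "beacons\n")
  tab <- table(x$areas$kind)
  cat("  kinds:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# walking-distance geodesics between all area pairs (metres); simulator use
area_distances <- function(graph) {
  igraph::distances(graph$igraph,
                    weights = igraph::E(graph$igraph)$distance)
}

# shortest area-to-area path as a vector of area ids
area_path <- function(graph, from, to) {
  p <- igraph::shortest_paths(graph$igraph, from, to,
                              weights = igraph::E(graph$igraph)$distance,
                              output = "vpath")$vpath[[1]]
  as.character(igraph::as_ids(p))
}
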