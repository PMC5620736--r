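#' Home layout: rooms, sensor map and adjacency
#'
#' A home layout lists the rooms of the dwelling (always including exactly one
#' virtual \code{"Outside"} room standing for periods spent away from home),
#' maps every PIR sensor identifier to the room it covers, and records which
#' room pairs are directly connected. Adjacency is descriptive: the learner
#' never forbids a transition, but \code{\link{stays_from_observations}} can
#' optionally warn about observed transitions that violate it.
#'
#' @param rooms Character vector of room names, in a fixed order (used for
#'   deterministic tie-breaking). Must contain \code{"Outside"} exactly once.
#' @param sensor_map Named character vector mapping sensor ids to room names.
#' @param adjacency Two-column character matrix (or data.frame) of unordered
#'   room pairs that are directly connected.
#' @return An object of class \code{bms_layout}.
#' @examples
#' lay <- default_home_layout()
#' lay$rooms
#' @export
bms_layout <- function(rooms, sensor_map, adjacency) {
  rooms <- as.character(rooms)
  if (anyDuplicated(rooms)) stop("duplicate room names")
  if (sum(rooms == "Outside") != 1L)
    stop("layout must contain exactly one virtual 'Outside' room")
  sensor_map <- vapply(sensor_map, as.character, character(1))
  if (!all(sensor_map %in% rooms))
    stop("sensor_map references rooms not in the layout: ",
         paste(setdiff(sensor_map, rooms), collapse = ", "))
  adjacency <- as.matrix(adjacency)
  if (ncol(adjacency) != 2L) stop("adjacency must have two columns")
  if (!all(adjacency %in% rooms)) stop("adjacency references unknown rooms")
  # connectivity check over the undirected graph
  reach <- rooms[1L]
  repeat {
    hit <- adjacency[, 1] %in% reach | adjacency[, 2] %in% reach
    nxt <- union(reach, c(adjacency[hit, 1], adjacency[hit, 2]))
    if (length(nxt) == length(reach)) break
    reach <- nxt
  }
  if (!setequal(reach, rooms))
    stop("adjacency graph is not connected; unreachable: ",
         paste(setdiff(rooms, reach), collapse = ", "))
  structure(list(rooms = rooms, sensor_map = sensor_map,
                 adjacency = adjacency),
            class = "bms_layout")
}

#' @export
print.bms_layout <- function(x, ...) {
  cat("Home layout:", length(x$rooms), "rooms,",
      length(x$sensor_map), "sensors\n")
  cat("  rooms:", paste(x$rooms, collapse = ", "), "\n")
  cat("  adjacency:",
      paste(apply(x$adjacency, 1, paste, collapse = "--"), collapse = ", "),
      "\n")
  invisible(x)
}

#' Six-room single-resident home layout
#'
#' The default layout used by the simulator: Bedroom, Bathroom, Livingroom,
#' Kitchen, Store and the virtual Outside room, one PIR sensor per room.
#' The bathroom and store are dead ends; Outside is reached through the
#' living room, the store through the kitchen.
#'
#' @return A \code{\link{bms_layout}}.
#' @export
default_home_layout <- function() {
  rooms <- c("Bedroom", "Bathroom", "Livingroom", "Kitchen", "Store",
             "Outside")
  sensors <- c(bedroom = "Bedroom", bathroom = "Bathroom",
               livingroom = "Livingroom", kitchen = "Kitchen",
               store = "Store", outside = "Outside")
  adj <- rbind(c("Bedroom", "Bathroom"),
               c("Bedroom", "Livingroom"),
               c("Bedroom", "Kitchen"),
               c("Livingroom", "Kitchen"),
               c("Livingroom", "Outside"),
               c("Kitchen", "Store"))
  bms_layout(rooms, sensors, adj)
}

# shortest path between two rooms over the adjacency graph (BFS);
# returns the room sequence including both endpoints
room_path <- function(layout, from, to) {
  if (from == to) return(from)
  edges <- rbind(layout$adjacency, layout$adjacency[, 2:1])
  prev <- stats::setNames(rep(NA_character_, length(layout$rooms)),
                          layout$rooms)
  frontier <- from
  prev[from] <- from
  while (length(frontier) && is.na(prev[to])) {
    nxt <- character(0)
    for (r in frontier) {
      nb <- edges[edges[, 1] == r, 2]
      nb <- nb[is.na(prev[nb])]
      prev[nb] <- r
      nxt <- c(nxt, nb)
    }
    frontier <- nxt
  }
  if (is.na(prev[to])) stop("no path between ", from, " and ", to)
  path <- to
  while (path[1] != from) path <- c(prev[path[1]], path)
  path
}

is_adjacent <- function(layout, a, b) {
  any((layout$adjacency[, 1] == a & layout$adjacency[, 2] == b) |
      (layout$adjacency[, 1] == b & layout$adjacency[, 2] == a))
}
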