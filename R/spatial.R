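# Road-network accessibility on a flat km plane: per-edge driving minutes
# from length and class speed, lake polygons as restrictive barriers,
# facility snapping with a search tolerance, multi-source shortest travel
# time towards the nearest facility, and six non-overlapping time bands.

#' National speed limits per road class (km/h)
#'
#' Defaults: primary 120, secondary 80, tertiary 60, residential 40,
#' tracks 20.
#'
#' @return named numeric vector.
#' @export
default_speeds <- function() {
  c(primary = 120, secondary = 80, tertiary = 60, residential = 40,
    tracks = 20)
}

#' Driving minutes along a road segment
#'
#' minutes = length / speed(class) * 60.
#'
#' @param length_km segment length in km (> 0).
#' @param road_class road class label present in \code{speeds}.
#' @param speeds named km/h speed table.
#' @return driving time in minutes.
#' @examples
#' edge_travel_minutes(60, "tertiary")  # 60
#' edge_travel_minutes(60, "tracks")    # 180
#' @export
edge_travel_minutes <- function(length_km, road_class,
                                speeds = default_speeds()) {
  if (any(length_km <= 0)) stop("segment length must be positive", call. = FALSE)
  if (any(speeds <= 0)) stop("speeds must be positive", call. = FALSE)
  sp <- speeds[as.character(road_class)]
  if (anyNA(sp)) {
    stop("unknown road class: ",
         paste(unique(road_class[is.na(sp)]), collapse = ", "), call. = FALSE)
  }
  unname(length_km / sp * 60)
}

## ---- planar geometry primitives (km plane) ----

polyline_length <- function(coords) {
  d <- diff(coords)
  sum(sqrt(rowSums(d^2)))
}

# orientation of the triplet (p, q, r): >0 counter-clockwise
orient <- function(px, py, qx, qy, rx, ry) {
  (qx - px) * (ry - py) - (qy - py) * (rx - px)
}

segments_intersect <- function(p1, p2, q1, q2) {
  d1 <- orient(q1[1], q1[2], q2[1], q2[2], p1[1], p1[2])
  d2 <- orient(q1[1], q1[2], q2[1], q2[2], p2[1], p2[2])
  d3 <- orient(p1[1], p1[2], p2[1], p2[2], q1[1], q1[2])
  d4 <- orient(p1[1], p1[2], p2[1], p2[2], q2[1], q2[2])
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  on_seg <- function(a, b, c) {
    min(a[1], b[1]) - 1e-12 <= c[1] && c[1] <= max(a[1], b[1]) + 1e-12 &&
      min(a[2], b[2]) - 1e-12 <= c[2] && c[2] <= max(a[2], b[2]) + 1e-12
  }
  (d1 == 0 && on_seg(q1, q2, p1)) || (d2 == 0 && on_seg(q1, q2, p2)) ||
    (d3 == 0 && on_seg(p1, p2, q1)) || (d4 == 0 && on_seg(p1, p2, q2))
}

#' Point-in-polygon test (even-odd ray casting)
#'
#' @param x,y point coordinates.
#' @param poly 2-column matrix of polygon vertices (closed or open ring).
#' @return logical.
#' @export
point_in_polygon <- function(x, y, poly) {
  px <- poly[, 1]; py <- poly[, 2]
  n <- length(px)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if (((py[i] > y) != (py[j] > y)) &&
        (x < (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i])) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

# does a polyline pass through the interior of a polygon?
polyline_crosses_polygon <- function(coords, poly) {
  n <- nrow(coords)
  ring <- rbind(poly, poly[1, ])
  for (i in seq_len(n - 1)) {
    mid <- (coords[i, ] + coords[i + 1, ]) / 2
    if (point_in_polygon(mid[1], mid[2], poly)) return(TRUE)
    for (j in seq_len(nrow(ring) - 1)) {
      if (segments_intersect(coords[i, ], coords[i + 1, ],
                             ring[j, ], ring[j + 1, ])) return(TRUE)
    }
  }
  any(vapply(seq_len(n), function(i)
    point_in_polygon(coords[i, 1], coords[i, 2], poly), logical(1)))
}

# nearest point on a polyline: returns squared-free distance, arc position
project_on_polyline <- function(pt, coords) {
  best <- list(dist = Inf, arc = 0, point = coords[1, ])
  arc0 <- 0
  for (i in seq_len(nrow(coords) - 1)) {
    a <- coords[i, ]; b <- coords[i + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- if (len2 == 0) 0 else max(0, min(1, sum((pt - a) * ab) / len2))
    proj <- a + t * ab
    d <- sqrt(sum((pt - proj)^2))
    if (d < best$dist) {
      best <- list(dist = d, arc = arc0 + t * sqrt(len2), point = proj)
    }
    arc0 <- arc0 + sqrt(len2)
  }
  best$total <- arc0
  best
}

## ---- road graph ----

node_key <- function(x, y) paste(round(x, 6), round(y, 6))

#' Build a road graph from classed segments
#'
#' Shared segment endpoints (within a coordinate epsilon) become single
#' nodes; each segment becomes one undirected edge weighted by its driving
#' minutes (\code{\link{edge_travel_minutes}} on the polyline length).
#' Parallel edges between the same node pair are collapsed to the cheaper
#' one. Node ids are deterministic.
#'
#' @param roads data.frame with columns \code{segment_id},
#'   \code{road_class} and a list-column \code{geometry} of 2-column
#'   coordinate matrices (km plane).
#' @param speeds named speed table (km/h).
#' @return object of class \code{road_graph}: \code{nodes} (id, x, y),
#'   \code{edges} (from, to, minutes, length_km, road_class, segment_id),
#'   \code{geoms} (per-edge coordinate matrices), empty facility table.
#' @export
build_road_graph <- function(roads, speeds = default_speeds()) {
  stopifnot(is.data.frame(roads), nrow(roads) > 0,
            all(c("segment_id", "road_class", "geometry") %in% names(roads)))
  ends <- do.call(rbind, lapply(roads$geometry, function(g)
    rbind(g[1, ], g[nrow(g), ])))
  keys <- node_key(ends[, 1], ends[, 2])
  ukeys <- unique(keys)
  nodes <- data.frame(
    node_id = sprintf("N%04d", seq_along(ukeys)),
    x = ends[match(ukeys, keys), 1],
    y = ends[match(ukeys, keys), 2],
    stringsAsFactors = FALSE
  )
  from <- nodes$node_id[match(keys[seq(1, length(keys), 2)], ukeys)]
  to <- nodes$node_id[match(keys[seq(2, length(keys), 2)], ukeys)]
  len <- vapply(roads$geometry, polyline_length, numeric(1))
  edges <- data.frame(
    edge_id = sprintf("E%04d", seq_len(nrow(roads))),
    from = from, to = to,
    length_km = len,
    minutes = edge_travel_minutes(len, roads$road_class, speeds),
    road_class = as.character(roads$road_class),
    segment_id = as.character(roads$segment_id),
    stringsAsFactors = FALSE
  )
  geoms <- roads$geometry
  # collapse parallel edges (same unordered node pair) keeping the cheaper
  pair <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
  ord <- order(pair, edges$minutes)
  keepi <- ord[!duplicated(pair[ord])]
  keepi <- sort(keepi)
  structure(list(nodes = nodes, edges = edges[keepi, , drop = FALSE],
                 geoms = geoms[keepi],
                 facilities = data.frame(facility_id = character(),
                                         node_id = character(),
                                         snap_km = numeric(),
                                         stringsAsFactors = FALSE),
                 unlocated = data.frame(facility_id = character(),
                                        dist_km = numeric(),
                                        stringsAsFactors = FALSE),
                 speeds = speeds),
            class = "road_graph")
}

#' @export
print.road_graph <- function(x, ...) {
  cat(sprintf("Road graph: %d nodes, %d edges, %d located facilities",
              nrow(x$nodes), nrow(x$edges), nrow(x$facilities)))
  if (nrow(x$unlocated)) {
    cat(sprintf(" (%d unlocated)", nrow(x$unlocated)))
  }
  cat("\n")
  invisible(x)
}

#' Remove edges crossing lake polygons (restrictive barriers)
#'
#' Every edge whose geometry passes through a lake polygon is removed;
#' nodes are retained, so parts of the network can become unreachable.
#' Removed edge ids are recorded in the \code{removed_edges} attribute.
#'
#' @param graph a \code{road_graph}.
#' @param lakes list of 2-column polygon vertex matrices.
#' @return the pruned \code{road_graph}.
#' @export
apply_barriers <- function(graph, lakes) {
  stopifnot(inherits(graph, "road_graph"))
  if (length(lakes) == 0) return(graph)
  hit <- vapply(seq_along(graph$geoms), function(i) {
    any(vapply(lakes, function(lk)
      polyline_crosses_polygon(graph$geoms[[i]], lk), logical(1)))
  }, logical(1))
  removed <- graph$edges$edge_id[hit]
  graph$edges <- graph$edges[!hit, , drop = FALSE]
  graph$geoms <- graph$geoms[!hit]
  attr(graph, "removed_edges") <- removed
  graph
}

#' Snap facilities onto the road graph within a search tolerance
#'
#' Each facility attaches to the nearest point on the nearest edge; the
#' edge is split at the projection (driving minutes divided in proportion
#' to arc length) and a new node carries the facility. Projections landing
#' on an existing endpoint reuse that node. Facilities farther than
#' \code{tolerance_km} from every edge are listed as unlocated and take no
#' part in routing.
#'
#' @param graph a \code{road_graph}.
#' @param facilities data.frame with \code{facility_id}, \code{x}, \code{y}.
#' @param tolerance_km search tolerance in km (default 15).
#' @return the \code{road_graph} with facility attachments.
#' @export
snap_facilities <- function(graph, facilities, tolerance_km = 15) {
  stopifnot(inherits(graph, "road_graph"))
  for (fi in seq_len(nrow(facilities))) {
    pt <- c(facilities$x[fi], facilities$y[fi])
    best <- list(dist = Inf)
    best_e <- NA_integer_
    for (ei in seq_along(graph$geoms)) {
      pr <- project_on_polyline(pt, graph$geoms[[ei]])
      if (pr$dist < best$dist) { best <- pr; best_e <- ei }
    }
    fid <- as.character(facilities$facility_id[fi])
    if (!is.finite(best$dist) || best$dist > tolerance_km) {
      graph$unlocated <- rbind(graph$unlocated, data.frame(
        facility_id = fid,
        dist_km = if (is.finite(best$dist)) best$dist else NA_real_,
        stringsAsFactors = FALSE))
      next
    }
    e <- graph$edges[best_e, ]
    frac <- best$arc / best$total
    if (frac < 1e-9 || frac > 1 - 1e-9) {
      node <- if (frac < 0.5) e$from else e$to
    } else {
      node <- sprintf("F%03d", fi)
      graph$nodes <- rbind(graph$nodes, data.frame(
        node_id = node, x = best$point[1], y = best$point[2],
        stringsAsFactors = FALSE))
      g <- graph$geoms[[best_e]]
      e1 <- e; e2 <- e
      e1$edge_id <- paste0(e$edge_id, "a"); e2$edge_id <- paste0(e$edge_id, "b")
      e1$to <- node; e2$from <- node
      e1$length_km <- e$length_km * frac
      e2$length_km <- e$length_km * (1 - frac)
      e1$minutes <- e$minutes * frac
      e2$minutes <- e$minutes * (1 - frac)
      graph$edges <- rbind(graph$edges[-best_e, , drop = FALSE], e1, e2)
      # split geometry at the projection
      g1 <- rbind(g[1, , drop = FALSE], matrix(best$point, 1))
      g2 <- rbind(matrix(best$point, 1), g[nrow(g), , drop = FALSE])
      graph$geoms <- c(graph$geoms[-best_e], list(g1), list(g2))
    }
    graph$facilities <- rbind(graph$facilities, data.frame(
      facility_id = fid, node_id = node, snap_km = best$dist,
      stringsAsFactors = FALSE))
  }
  graph
}

as_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    graph$edges[, c("from", "to")], directed = FALSE,
    vertices = graph$nodes$node_id)
}

#' Minimum driving minutes from every node towards the nearest facility
#'
#' Multi-source shortest paths over the undirected weighted graph (driving
#' towards the facility and away are symmetric here). Nodes farther than
#' the last band break (default 240 minutes) or disconnected from every
#' facility are classed unreachable.
#'
#' @param graph a \code{road_graph} with at least one located facility.
#' @param breaks ascending band upper bounds in minutes; the default six
#'   non-overlapping bands are (0,30], (30,45], (45,60], (60,90],
#'   (90,180], (180,240].
#' @return object of class \code{access_surface}: per-node minutes and
#'   band (integer 1..6 or NA for unreachable).
#' @export
travel_time_surface <- function(graph,
                                breaks = c(30, 45, 60, 90, 180, 240)) {
  stopifnot(inherits(graph, "road_graph"))
  if (nrow(graph$facilities) == 0) {
    stop("no located facilities to route towards", call. = FALSE)
  }
  if (is.unsorted(breaks, strictly = TRUE)) {
    stop("band breaks must be strictly ascending", call. = FALSE)
  }
  g <- as_igraph(graph)
  dm <- igraph::distances(g, v = unique(graph$facilities$node_id),
                          weights = graph$edges$minutes)
  minutes <- apply(dm, 2, min)[graph$nodes$node_id]
  band <- assign_band(minutes, breaks)
  structure(list(
    nodes = data.frame(graph$nodes, minutes = unname(minutes),
                       band = band, stringsAsFactors = FALSE),
    breaks = breaks), class = "access_surface")
}

#' Assign travel minutes to service-area bands
#'
#' Band b covers (breaks[b-1], breaks[b]] with the first band including 0;
#' minutes beyond the last break, or infinite, are unreachable (NA).
#'
#' @param minutes numeric vector of travel minutes.
#' @param breaks ascending upper bounds.
#' @return integer band indices with NA for unreachable.
#' @export
assign_band <- function(minutes, breaks = c(30, 45, 60, 90, 180, 240)) {
  b <- findInterval(minutes, breaks, left.open = TRUE) + 1L
  b[minutes < 0] <- NA_integer_
  b[!is.finite(minutes) | minutes > breaks[length(breaks)]] <- NA_integer_
  b
}

#' @export
print.access_surface <- function(x, ...) {
  cat("Travel-time surface:", nrow(x$nodes), "nodes; bands at",
      paste(x$breaks, collapse = "/"), "minutes\n")
  reach <- x$nodes$minutes[!is.na(x$nodes$band)]
  if (length(reach)) {
    cat(sprintf("  reachable: %d nodes, median %.1f min, max %.1f min\n",
                length(reach), median(reach), max(reach)))
  }
  if (anyNA(x$nodes$band)) {
    cat(sprintf("  unreachable (> %g min or disconnected): %d nodes\n",
                max(x$breaks), sum(is.na(x$nodes$band))))
  }
  invisible(x)
}

#' Per-district access summary from the travel-time surface
#'
#' Demand points (women, or district centroids) are mapped to the nearest
#' graph node; per district the report gives the share of women in each
#' band (unreachable included), the median minutes, and a flag for
#' districts whose median exceeds the last band break.
#'
#' @param surface an \code{access_surface}.
#' @param women_points data.frame with \code{district_id}, \code{x},
#'   \code{y} (one row per woman or per district centroid).
#' @return data.frame, one row per district: band shares
#'   (\code{band_1}..\code{band_K}, \code{unreachable}), median minutes,
#'   \code{flag_over_max}.
#' @export
district_access_report <- function(surface, women_points) {
  stopifnot(inherits(surface, "access_surface"))
  nd <- surface$nodes
  ni <- vapply(seq_len(nrow(women_points)), function(i) {
    which.min((nd$x - women_points$x[i])^2 + (nd$y - women_points$y[i])^2)
  }, integer(1))
  minutes <- nd$minutes[ni]
  band <- nd$band[ni]
  K <- length(surface$breaks)
  d <- split(seq_along(minutes), as.character(women_points$district_id))
  out <- do.call(rbind, lapply(names(d), function(dd) {
    i <- d[[dd]]
    shares <- vapply(seq_len(K), function(b) mean(band[i] %in% b), numeric(1))
    data.frame(district_id = dd, n = length(i),
               t(setNames(shares, paste0("band_", seq_len(K)))),
               unreachable = mean(is.na(band[i])),
               median_minutes = median(minutes[i]),
               stringsAsFactors = FALSE)
  }))
  out$flag_over_max <- !is.finite(out$median_minutes) |
    out$median_minutes > surface$breaks[K]
  rownames(out) <- NULL
  out
}
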