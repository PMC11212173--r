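# Planar toy geography (km coordinates): a connected road grid with five
# road classes, health-facility points, lake polygons and a rectangular
# district partition. Exported and re-imported as GeoJSON.

#' Simulate the toy geography
#'
#' Builds an nx-by-ny road grid (each grid edge one segment, class drawn
#' from the five-class vocabulary), places facilities on the network at
#' random positions along random segments (a configurable fraction is
#' deliberately placed beyond the snapping tolerance to exercise
#' unlocated-facility handling), adds rectangular lake polygons overlapping
#' interior grid edges, and partitions the bounding box into
#' \code{n_districts} rectangular districts.
#'
#' @param config an \code{\link{sim_config}}; uses its \code{geography}
#'   block, \code{n_districts} and \code{seed}.
#' @param tolerance_km snapping tolerance used to place off-network
#'   facilities safely beyond it.
#' @return object of class \code{toy_geography}: \code{roads} (data.frame
#'   with geometry list-column), \code{facilities}, \code{lakes} (list of
#'   polygon matrices), \code{districts} (list with ids and polygon
#'   matrices).
#' @export
simulate_geography <- function(config, tolerance_km = 15) {
  stopifnot(inherits(config, "mcp_sim_config"))
  g <- config$geography
  set.seed(derive_seed(config$seed, "geography"))
  nx <- g$nx; ny <- g$ny; s <- g$spacing_km
  classes <- names(g$speeds %||% default_speeds())

  # grid segments: horizontal then vertical, deterministic order
  segs <- list(); cls <- character(0)
  for (j in seq_len(ny)) for (i in seq_len(nx - 1)) {
    segs[[length(segs) + 1L]] <- rbind(c((i - 1) * s, (j - 1) * s),
                                       c(i * s, (j - 1) * s))
  }
  for (j in seq_len(ny - 1)) for (i in seq_len(nx)) {
    segs[[length(segs) + 1L]] <- rbind(c((i - 1) * s, (j - 1) * s),
                                       c((i - 1) * s, j * s))
  }
  cls <- sample(classes, length(segs), replace = TRUE,
                prob = c(0.08, 0.15, 0.22, 0.30, 0.25))
  roads <- data.frame(segment_id = sprintf("R%04d", seq_along(segs)),
                      road_class = cls, stringsAsFactors = FALSE)
  roads$geometry <- segs

  # facilities: on-network ones at a random point of a random segment
  nf <- g$n_facilities
  n_off <- round((g$unlocated_fraction %||% 0) * nf)
  fac <- data.frame(facility_id = sprintf("HF%03d", seq_len(nf)),
                    x = numeric(nf), y = numeric(nf),
                    stringsAsFactors = FALSE)
  for (fi in seq_len(nf)) {
    if (fi <= nf - n_off) {
      sg <- segs[[sample.int(length(segs), 1)]]
      t <- runif(1)
      fac$x[fi] <- sg[1, 1] + t * (sg[2, 1] - sg[1, 1])
      fac$y[fi] <- sg[1, 2] + t * (sg[2, 2] - sg[1, 2])
    } else {
      # beyond the tolerance from every road
      fac$x[fi] <- (nx - 1) * s + tolerance_km + 5 + runif(1, 0, 5)
      fac$y[fi] <- runif(1, 0, (ny - 1) * s)
    }
  }

  # lakes: rectangles covering one interior grid cell plus a margin, so
  # the edges crossing the cell are barred but the grid stays connected
  lakes <- list()
  for (li in seq_len(g$n_lakes %||% 0)) {
    ci <- sample(seq_len(nx - 2), 1)
    cj <- sample(seq_len(ny - 2), 1)
    x0 <- (ci - 0.3) * s; x1 <- (ci + 1.3) * s
    y0 <- (cj - 0.3) * s; y1 <- (cj + 1.3) * s
    lakes[[li]] <- rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1))
  }

  districts <- make_district_grid(config$n_districts,
                                  xmax = (nx - 1) * s, ymax = (ny - 1) * s)
  structure(list(roads = roads, facilities = fac, lakes = lakes,
                 districts = districts),
            class = "toy_geography")
}

# partition [0,xmax] x [0,ymax] into n simple rectangles (r rows, the
# remainder spread over the first rows)
make_district_grid <- function(n, xmax, ymax) {
  r <- max(1L, floor(sqrt(n)))
  base <- n %/% r
  extra <- n %% r
  ids <- character(0); polys <- list(); centroids <- NULL
  k <- 0L
  for (row in seq_len(r)) {
    ncol_r <- base + (row <= extra)
    y0 <- (row - 1) * ymax / r; y1 <- row * ymax / r
    for (col in seq_len(ncol_r)) {
      k <- k + 1L
      x0 <- (col - 1) * xmax / ncol_r; x1 <- col * xmax / ncol_r
      ids <- c(ids, sprintf("D%03d", k))
      polys[[k]] <- rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1))
      centroids <- rbind(centroids, c((x0 + x1) / 2, (y0 + y1) / 2))
    }
  }
  list(district_id = ids, polygons = polys,
       centroids = data.frame(district_id = ids, x = centroids[, 1],
                              y = centroids[, 2], stringsAsFactors = FALSE))
}

#' @export
print.toy_geography <- function(x, ...) {
  cat(sprintf("Toy geography: %d road segments, %d facilities, %d lakes, %d districts\n",
              nrow(x$roads), nrow(x$facilities), length(x$lakes),
              length(x$districts$district_id)))
  invisible(x)
}

## ---- GeoJSON I/O (planar coordinates carried through verbatim) ----

geojson_feature <- function(geom_type, coords, props) {
  list(type = "Feature", properties = props,
       geometry = list(type = geom_type, coordinates = coords))
}

coords_list <- function(m) lapply(seq_len(nrow(m)), function(i)
  c(round(m[i, 1], 6), round(m[i, 2], 6)))

#' Write the toy geography to GeoJSON files
#'
#' Writes \code{roads.geojson} (LineString with a \code{class} property),
#' \code{facilities.geojson} (Point), \code{lakes.geojson} and
#' \code{districts.geojson} (Polygon). Output is deterministic (fixed
#' coordinate rounding), so a fixed-seed geography exports byte-identically.
#'
#' @param geo a \code{toy_geography}.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_geography_geojson <- function(geo, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fc <- function(features) list(type = "FeatureCollection", features = features)
  wj <- function(obj, file) {
    jsonlite::write_json(obj, file.path(dir, file), auto_unbox = TRUE,
                         digits = NA, pretty = FALSE)
  }
  wj(fc(lapply(seq_len(nrow(geo$roads)), function(i) geojson_feature(
    "LineString", coords_list(geo$roads$geometry[[i]]),
    list(segment_id = geo$roads$segment_id[i],
         class = geo$roads$road_class[i])))), "roads.geojson")
  wj(fc(lapply(seq_len(nrow(geo$facilities)), function(i) geojson_feature(
    "Point", c(round(geo$facilities$x[i], 6), round(geo$facilities$y[i], 6)),
    list(facility_id = geo$facilities$facility_id[i])))),
    "facilities.geojson")
  wj(fc(lapply(seq_along(geo$lakes), function(i) {
    ring <- rbind(geo$lakes[[i]], geo$lakes[[i]][1, ])
    geojson_feature("Polygon", list(coords_list(ring)),
                    list(lake_id = sprintf("L%03d", i)))
  })), "lakes.geojson")
  wj(fc(lapply(seq_along(geo$districts$polygons), function(i) {
    ring <- rbind(geo$districts$polygons[[i]], geo$districts$polygons[[i]][1, ])
    geojson_feature("Polygon", list(coords_list(ring)),
                    list(district_id = geo$districts$district_id[i]))
  })), "districts.geojson")
  invisible(file.path(dir, c("roads.geojson", "facilities.geojson",
                             "lakes.geojson", "districts.geojson")))
}

#' Read a toy geography back from GeoJSON files
#'
#' @param dir directory holding the four files written by
#'   \code{\link{write_geography_geojson}}.
#' @return a \code{toy_geography}.
#' @export
read_geography_geojson <- function(dir) {
  rd <- function(file) jsonlite::read_json(file.path(dir, file))
  mat <- function(cc) do.call(rbind, lapply(cc, function(p)
    c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
  rj <- rd("roads.geojson")
  roads <- data.frame(
    segment_id = vapply(rj$features, function(f) f$properties$segment_id,
                        character(1)),
    road_class = vapply(rj$features, function(f) f$properties$class,
                        character(1)),
    stringsAsFactors = FALSE)
  roads$geometry <- lapply(rj$features, function(f) mat(f$geometry$coordinates))
  fj <- rd("facilities.geojson")
  fac <- data.frame(
    facility_id = vapply(fj$features, function(f) f$properties$facility_id,
                         character(1)),
    x = vapply(fj$features, function(f) as.numeric(f$geometry$coordinates[[1]]),
               numeric(1)),
    y = vapply(fj$features, function(f) as.numeric(f$geometry$coordinates[[2]]),
               numeric(1)),
    stringsAsFactors = FALSE)
  lj <- rd("lakes.geojson")
  lakes <- lapply(lj$features, function(f) {
    m <- mat(f$geometry$coordinates[[1]])
    m[-nrow(m), , drop = FALSE]
  })
  dj <- rd("districts.geojson")
  ids <- vapply(dj$features, function(f) f$properties$district_id, character(1))
  polys <- lapply(dj$features, function(f) {
    m <- mat(f$geometry$coordinates[[1]])
    m[-nrow(m), , drop = FALSE]
  })
  cen <- t(vapply(polys, colMeans, numeric(2)))
  structure(list(roads = roads, facilities = fac, lakes = lakes,
                 districts = list(district_id = ids, polygons = polys,
                                  centroids = data.frame(
                                    district_id = ids, x = cen[, 1],
                                    y = cen[, 2], stringsAsFactors = FALSE))),
            class = "toy_geography")
}
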