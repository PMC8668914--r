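#' Raster grid container
#'
#' Lightweight in-memory single-band raster on a regular grid in a planar,
#' kilometre-unit coordinate system. Values are stored as a matrix whose
#' first row is the TOP (northernmost) row, i.e. row-major from top-left as
#' rasters are displayed.
#'
#' Cell convention: cells are half-open; the centre of column j is
#' \code{xll + (j - 0.5) * cellsize} and a point lying exactly on a vertical
#' cell edge belongs to the cell on its right, on a horizontal edge to the
#' cell below (the lower-y cell).
#'
#' @param values numeric matrix (row 1 = top row).
#' @param xll,yll coordinates of the lower-left corner of the grid (km).
#' @param cellsize cell edge length (km), \code{> 0}.
#' @param nodata sentinel written to files for missing cells (kept as
#'   \code{NA} in memory).
#' @param crs free-text CRS description; must be planar (not degrees).
#' @return an object of class \code{raster_grid}.
#' @export
raster_grid <- function(values, xll, yll, cellsize, nodata = -9999,
                        crs = "local planar (km)") {
  values <- as.matrix(values)
  stopifnot(is.numeric(cellsize), cellsize > 0, is.finite(xll), is.finite(yll))
  structure(list(values = values, xll = xll, yll = yll,
                 cellsize = cellsize, nrow = nrow(values),
                 ncol = ncol(values), nodata = nodata, crs = crs),
            class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  cat("raster_grid:", x$nrow, "x", x$ncol, "cells of", x$cellsize, "km\n")
  cat("  origin (lower-left):", x$xll, ",", x$yll, "km; crs:", x$crs, "\n")
  v <- x$values[is.finite(x$values)]
  if (length(v)) cat("  values:", signif(min(v), 4), "..", signif(max(v), 4),
                     " (", sum(is.na(x$values)), "NA )\n")
  invisible(x)
}

#' Cell-centre coordinates of a raster grid
#' @param grid a \code{raster_grid}.
#' @return data.frame with x, y (km) of every cell centre in storage order
#'   (row-major from top-left).
#' @export
cell_centers <- function(grid) {
  stopifnot(inherits(grid, "raster_grid"))
  xs <- grid$xll + (seq_len(grid$ncol) - 0.5) * grid$cellsize
  ys <- grid$yll + (grid$nrow - seq_len(grid$nrow) + 0.5) * grid$cellsize
  data.frame(x = rep(xs, times = grid$nrow),
             y = rep(ys, each = grid$ncol))
}

crs_is_geographic <- function(crs) {
  grepl("GEOGCS|longlat|degree|EPSG:4326|WGS ?84$", crs, ignore.case = TRUE)
}

#' Read / write rasters as ESRI ASCII grids
#'
#' Plain-text single-band raster interchange. The writer emits the standard
#' six-line header (\code{ncols}, \code{nrows}, \code{xllcorner},
#' \code{yllcorner}, \code{cellsize}, \code{NODATA_value}) followed by rows
#' top-to-bottom, and a sidecar \code{<path>.prj} text file carrying the CRS
#' description. The reader rejects geographic (degree) coordinate systems:
#' project to a planar CRS (e.g. a UTM zone) first. Units are km in memory;
#' files written by this package are also in km.
#'
#' @param path file path (.asc).
#' @param grid a \code{raster_grid}.
#' @return \code{read_raster_asc} returns a \code{raster_grid};
#'   \code{write_raster_asc} returns \code{path} invisibly.
#' @export
read_raster_asc <- function(path) {
  if (!file.exists(path)) stop("no such raster file: ", path)
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  for (k in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize"))
    if (is.null(hdr[[k]])) stop("ASCII grid header missing ", k)
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  body <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(body) != hdr$ncols * hdr$nrows)
    stop("ASCII grid body has ", length(body), " values, expected ",
         hdr$ncols * hdr$nrows)
  vals <- matrix(body, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  vals[vals == nodata] <- NA
  crs <- "local planar (km)"
  prj <- paste0(path, ".prj")
  if (file.exists(prj)) crs <- paste(readLines(prj), collapse = " ")
  if (crs_is_geographic(crs))
    stop("raster CRS appears geographic (degrees): ", crs,
         "; project to a planar CRS (the study used WGS 84/UTM zone 45N)")
  raster_grid(vals, hdr$xllcorner, hdr$yllcorner, hdr$cellsize,
              nodata = nodata, crs = crs)
}

#' @rdname read_raster_asc
#' @export
write_raster_asc <- function(grid, path) {
  stopifnot(inherits(grid, "raster_grid"))
  vals <- grid$values
  vals[is.na(vals)] <- grid$nodata
  hdr <- c(paste("ncols", grid$ncol), paste("nrows", grid$nrow),
           paste("xllcorner", sprintf("%.17g", grid$xll)),
           paste("yllcorner", sprintf("%.17g", grid$yll)),
           paste("cellsize", sprintf("%.17g", grid$cellsize)),
           paste("NODATA_value", grid$nodata))
  rows <- apply(vals, 1, function(r) paste(sprintf("%.17g", r),
                                           collapse = " "))
  writeLines(c(hdr, rows), path)
  writeLines(grid$crs, paste0(path, ".prj"))
  invisible(path)
}

#' Read a household point table from CSV
#'
#' Coordinates are expected in metres in a projected planar CRS and are
#' converted once to the package-internal kilometre unit (x 0.001). Rows
#' whose coordinates cannot be parsed are dropped and counted, mirroring
#' field surveys where some clusters carry unmatched geographic
#' coordinates; the count is available as \code{attr(x, "n_dropped")}.
#'
#' @param path CSV path.
#' @param columns named character vector mapping internal names to file
#'   column names; must provide \code{hh_id}, \code{cluster_id}, \code{x_m},
#'   \code{y_m} and at least one \code{outcome*} entry. Any additional
#'   mapped columns are carried through unchanged.
#' @return data.frame of class \code{point_table} with columns
#'   \code{hh_id}, \code{cluster_id}, \code{x}, \code{y} (km) plus mapped
#'   extras; attribute \code{units = "km"}.
#' @export
read_point_csv <- function(path,
                           columns = c(hh_id = "hh_id", cluster_id = "cluster_id",
                                       x_m = "x_m", y_m = "y_m",
                                       outcome = "outcome")) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0) stop("empty point table: ", path)
  if (!any(grepl("^outcome", names(columns))))
    stop("column map must name at least one outcome column")
  missing_cols <- setdiff(unname(columns), names(raw))
  if (length(missing_cols))
    stop("mapped columns absent from file: ", paste(missing_cols, collapse = ", "))
  x <- suppressWarnings(as.numeric(raw[[columns[["x_m"]]]]))
  y <- suppressWarnings(as.numeric(raw[[columns[["y_m"]]]]))
  keep <- is.finite(x) & is.finite(y)
  n_dropped <- sum(!keep)
  out <- data.frame(hh_id = raw[[columns[["hh_id"]]]][keep],
                    cluster_id = raw[[columns[["cluster_id"]]]][keep],
                    x = x[keep] * 0.001, y = y[keep] * 0.001,
                    stringsAsFactors = FALSE)
  extra <- setdiff(names(columns), c("hh_id", "cluster_id", "x_m", "y_m"))
  for (nm in extra) out[[nm]] <- raw[[columns[[nm]]]][keep]
  if (anyDuplicated(out$hh_id)) stop("hh_id values are not unique")
  attr(out, "n_dropped") <- n_dropped
  attr(out, "units") <- "km"
  class(out) <- c("point_table", "data.frame")
  out
}

#' Write a household point table to CSV (coordinates back in metres)
#' @param points a \code{point_table} (km units).
#' @param path output CSV path.
#' @export
write_point_csv <- function(points, path) {
  out <- as.data.frame(points)
  out$x_m <- out$x * 1000
  out$y_m <- out$y * 1000
  out$x <- NULL
  out$y <- NULL
  # full-precision doubles so the write -> read round trip is lossless
  for (nm in names(out))
    if (is.double(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- GeoJSON vector layers ------------------------------------------------

close_ring <- function(m) {
  if (!isTRUE(all.equal(m[1, ], m[nrow(m), ]))) m <- rbind(m, m[1, ])
  m
}

#' Read polygons from GeoJSON
#'
#' Accepts a FeatureCollection of Polygon (outer ring only) features. Each
#' feature must carry a unit-id property; duplicate ids are rejected. Rings
#' are closed if needed; degenerate (zero-area) rings are rejected.
#'
#' @param path GeoJSON file.
#' @param id_property property name holding the administrative unit id.
#' @return list of class \code{polygon_set}: each element has \code{id} and
#'   \code{ring} (closed 2-column matrix, km).
#' @export
read_polygons <- function(path, id_property = "id") {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path)
  polys <- lapply(gj$features, function(f) {
    if (!identical(f$geometry$type, "Polygon"))
      stop("expected Polygon geometry, got ", f$geometry$type)
    id <- f$properties[[id_property]]
    if (is.null(id)) stop("feature missing unit-id property '", id_property, "'")
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(p) c(p[[1]], p[[2]])))
    ring <- close_ring(ring)
    if (abs(ring_area(ring)) < 1e-12) stop("degenerate polygon ring (id ", id, ")")
    list(id = as.character(id), ring = ring)
  })
  ids <- vapply(polys, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate unit ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  structure(polys, class = "polygon_set")
}

#' Read polylines from GeoJSON
#'
#' Accepts LineString and Polygon features (polygon boundaries are treated
#' as closed polylines, e.g. lake shores among river lines).
#'
#' @param path GeoJSON file.
#' @return list of class \code{polyline_set}; each element is a 2-column
#'   coordinate matrix (km).
#' @export
read_polylines <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path)
  lines <- lapply(gj$features, function(f) {
    ty <- f$geometry$type
    coords <- if (identical(ty, "LineString")) f$geometry$coordinates
      else if (identical(ty, "Polygon")) f$geometry$coordinates[[1]]
      else stop("expected LineString or Polygon geometry, got ", ty)
    m <- do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
    if (identical(ty, "Polygon")) m <- close_ring(m)
    if (nrow(m) < 2) stop("polyline needs at least two vertices")
    m
  })
  structure(lines, class = "polyline_set")
}

#' Write polygons or polylines to GeoJSON
#' @param features a \code{polygon_set} or \code{polyline_set}; polygons may
#'   carry extra per-feature properties via \code{properties} (data.frame,
#'   one row per feature).
#' @param path output path.
#' @param properties optional data.frame of feature properties.
#' @export
write_geojson <- function(features, path, properties = NULL) {
  is_poly <- inherits(features, "polygon_set")
  feats <- lapply(seq_along(features), function(i) {
    f <- features[[i]]
    coords <- if (is_poly) f$ring else f
    props <- if (is_poly) list(id = f$id) else list()
    if (!is.null(properties))
      props <- c(props, as.list(properties[i, , drop = FALSE]))
    list(type = "Feature",
         properties = props,
         geometry = list(
           type = if (is_poly) "Polygon" else "LineString",
           coordinates = if (is_poly)
             list(lapply(seq_len(nrow(coords)), function(r) coords[r, ]))
           else lapply(seq_len(nrow(coords)), function(r) coords[r, ])))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

## ---- planar geometry primitives ------------------------------------------

#' Signed area of a closed ring (shoelace), km^2
#' @param ring closed 2-column coordinate matrix.
#' @export
ring_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  0.5 * sum(x[-n] * y[-1] - x[-1] * y[-n])
}

#' Length of a polyline, km
#' @param line 2-column coordinate matrix.
#' @export
polyline_length <- function(line) {
  d <- diff(line)
  sum(sqrt(rowSums(d^2)))
}

#' Point-in-polygon test (even-odd rule)
#'
#' @param x,y point coordinates (vectors, km).
#' @param ring closed outer-ring matrix.
#' @return logical vector; boundary points count as inside.
#' @export
point_in_polygon <- function(x, y, ring) {
  rx <- ring[, 1]; ry <- ring[, 2]
  n <- length(rx)
  inside <- logical(length(x))
  for (k in seq_along(x)) {
    px <- x[k]; py <- y[k]
    ins <- FALSE
    on_edge <- FALSE
    # ring closed: vertex n == vertex 1; iterate edges 1..n-1
    for (i in seq_len(n - 1L)) {
      xi <- rx[i]; yi <- ry[i]; xj <- rx[i + 1L]; yj <- ry[i + 1L]
      # boundary check
      if (point_segment_distance(px, py, xi, yi, xj, yj) < 1e-12) {
        on_edge <- TRUE
        break
      }
      if ((yi > py) != (yj > py)) {
        xcross <- xi + (py - yi) / (yj - yi) * (xj - xi)
        if (px < xcross) ins <- !ins
      }
    }
    inside[k] <- on_edge || ins
  }
  inside
}

#' Distance from a point to a segment, km
#' @param px,py point; @param ax,ay,bx,by segment endpoints.
#' @keywords internal
point_segment_distance <- function(px, py, ax, ay, bx, by) {
  vx <- bx - ax; vy <- by - ay
  wx <- px - ax; wy <- py - ay
  L2 <- vx * vx + vy * vy
  t <- if (L2 == 0) 0 else max(0, min(1, (wx * vx + wy * vy) / L2))
  dx <- px - (ax + t * vx); dy <- py - (ay + t * vy)
  sqrt(dx * dx + dy * dy)
}
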