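#' Poverty Probability Index lookup table
#'
#' The PPI maps the summed points of ten survey items through a national
#' lookup table to the likelihood that the household falls below a poverty
#' line. The national table itself is licensed survey material and must be
#' supplied by the user as a CSV with columns \code{score} (integer, unique,
#' contiguous) and \code{likelihood} (fraction in [0, 1]).
#'
#' @param path CSV path.
#' @return data.frame of class \code{ppi_lookup}.
#' @export
read_ppi_lookup <- function(path) {
  tab <- utils::read.csv(path)
  ppi_lookup(tab$score, tab$likelihood)
}

#' @rdname read_ppi_lookup
#' @param score integer scores; @param likelihood poverty likelihoods.
#' @export
ppi_lookup <- function(score, likelihood) {
  stopifnot(length(score) == length(likelihood))
  o <- order(score)
  score <- as.integer(score[o]); likelihood <- likelihood[o]
  if (anyDuplicated(score)) stop("PPI lookup scores must be unique")
  if (!all(diff(score) == 1L)) stop("PPI lookup scores must be contiguous")
  if (any(likelihood < 0 | likelihood > 1))
    stop("PPI likelihoods must lie in [0, 1]")
  structure(data.frame(score = score, likelihood = likelihood),
            class = c("ppi_lookup", "data.frame"))
}

#' A synthetic PPI lookup table (score s -> s/100)
#'
#' Stand-in for the national table, used by the synthetic-survey generator
#' and the test-suite; clearly synthetic, not the Nepal table.
#' @param max_score top of the score domain.
#' @export
synthetic_ppi_lookup <- function(max_score = 100) {
  s <- 0:max_score
  ppi_lookup(s, pmin(1, s / 100))
}

#' Score households on the Poverty Probability Index
#'
#' Sums the configured item points and reads the poverty likelihood off the
#' lookup table. The returned covariate is the likelihood itself, a fraction
#' in [0, 1], so that a unit change spans the index's whole range — this is
#' the scale on which the model coefficient is interpreted.
#'
#' @param answers data.frame or matrix of per-item integer points, one row
#'   per household; all configured items must be present.
#' @param lookup a \code{ppi_lookup}.
#' @param items character vector of required item columns (defaults to all
#'   columns of \code{answers}).
#' @return numeric vector of poverty likelihoods in [0, 1].
#' @export
ppi_score <- function(answers, lookup, items = colnames(answers)) {
  stopifnot(inherits(lookup, "ppi_lookup"))
  answers <- as.data.frame(answers)
  miss <- setdiff(items, colnames(answers))
  if (length(miss)) stop("missing PPI items: ", paste(miss, collapse = ", "))
  total <- rowSums(answers[, items, drop = FALSE])
  if (any(total != round(total))) stop("PPI item points must be integers")
  out_of_domain <- total < min(lookup$score) | total > max(lookup$score)
  if (any(out_of_domain))
    stop(sum(out_of_domain), " household score(s) outside the lookup domain [",
         min(lookup$score), ", ", max(lookup$score), "]")
  lookup$likelihood[match(total, lookup$score)]
}

#' Euclidean distance to the nearest waterbody
#'
#' Exact point-to-segment minimum distance over every segment of every
#' water feature (polylines; polygons contribute their boundary, and points
#' inside a water polygon get distance 0). Units km.
#'
#' @param points data.frame with \code{x}, \code{y} (km) or 2-column matrix.
#' @param water a \code{polyline_set}, \code{polygon_set}, or plain list of
#'   2-column coordinate matrices.
#' @return numeric vector of distances (km).
#' @export
distance_to_water <- function(points, water) {
  if (length(water) == 0) stop("empty water feature set")
  pts <- if (is.data.frame(points)) cbind(points$x, points$y) else as.matrix(points)
  is_poly <- inherits(water, "polygon_set")
  segs <- list()
  rings <- list()
  for (f in water) {
    m <- if (is_poly) f$ring else f
    if (is_poly) rings[[length(rings) + 1L]] <- m
    for (i in seq_len(nrow(m) - 1L))
      segs[[length(segs) + 1L]] <- c(m[i, ], m[i + 1L, ])
  }
  A <- do.call(rbind, segs)   # ax ay bx by
  d <- vapply(seq_len(nrow(pts)), function(k) {
    px <- pts[k, 1]; py <- pts[k, 2]
    vx <- A[, 3] - A[, 1]; vy <- A[, 4] - A[, 2]
    wx <- px - A[, 1]; wy <- py - A[, 2]
    L2 <- vx * vx + vy * vy
    t <- ifelse(L2 == 0, 0, pmax(0, pmin(1, (wx * vx + wy * vy) / L2)))
    dx <- px - (A[, 1] + t * vx); dy <- py - (A[, 2] + t * vy)
    min(sqrt(dx * dx + dy * dy))
  }, numeric(1))
  if (length(rings)) {
    for (r in rings) {
      inside <- point_in_polygon(pts[, 1], pts[, 2], r)
      d[inside] <- 0
    }
  }
  d
}

#' Extract raster values at point locations
#'
#' Value of the containing cell under the package's half-open cell
#' convention (see \code{\link{raster_grid}}). Points outside the raster
#' footprint yield \code{NA} and are counted in \code{attr(, "n_outside")};
#' nodata cells yield \code{NA} counted in \code{attr(, "n_nodata")}.
#'
#' @param raster a \code{raster_grid}.
#' @param points data.frame with \code{x}, \code{y} (km) or 2-column matrix.
#' @return numeric vector of cell values (NA where missing).
#' @export
extract_at_points <- function(raster, points) {
  stopifnot(inherits(raster, "raster_grid"))
  pts <- if (is.data.frame(points)) cbind(points$x, points$y) else as.matrix(points)
  relx <- (pts[, 1] - raster$xll) / raster$cellsize
  rely <- (pts[, 2] - raster$yll) / raster$cellsize
  col <- floor(relx) + 1L                 # vertical edge -> cell to the right
  row_bottom <- ceiling(rely)             # horizontal edge -> cell below
  inside <- col >= 1L & col <= raster$ncol &
    row_bottom >= 1L & row_bottom <= raster$nrow
  row_top <- raster$nrow - row_bottom + 1L
  out <- rep(NA_real_, nrow(pts))
  idx <- which(inside)
  out[idx] <- raster$values[cbind(row_top[idx], col[idx])]
  attr(out, "n_outside") <- sum(!inside)
  attr(out, "n_nodata") <- sum(inside & is.na(out))
  out
}

#' Default covariate scaling map
#'
#' Multiplicative factors that bring the raw covariates onto comparable
#' scales before model fitting: distances m to km, temperatures to tens of
#' degrees C, precipitation to hundreds of mm, PPI percent to fraction,
#' livestock head counts to thousands. Indices already in [0, 1] (NDVI,
#' human-modification) are left alone. Quantities the package already
#' carries in km (e.g. \code{dist_water} from
#' \code{\link{distance_to_water}}) use factor 1.
#'
#' @return named numeric vector of factors.
#' @export
default_scaling <- function() {
  c(ndvi = 1, dist_water = 1, dist_water_m = 0.001, hmts = 1,
    bio1 = 0.1, bio6 = 0.1, bio17 = 0.01, ppi = 1, ppi_percent = 0.01,
    pig_density = 0.001, sheep_density = 0.001,
    food_storage = 1, straw_storage = 1, sleep_floor = 1, animal_shed = 1)
}

#' Apply the covariate scaling map exactly once
#'
#' Multiplies each named column by its factor and tags the table so a
#' second application raises instead of silently rescaling.
#'
#' @param design data.frame of raw covariate columns.
#' @param scaling named numeric vector of positive factors. An explicitly
#'   supplied map must name only design columns; the default map is
#'   filtered to the columns present. Columns not named are left unscaled.
#' @return the scaled design with \code{attr(, "scaled") = TRUE}.
#' @export
scale_covariates <- function(design, scaling = default_scaling()) {
  if (isTRUE(attr(design, "scaled")))
    stop("design is already scaled; refusing to scale twice")
  if (!missing(scaling)) {     # an explicit map must match the design
    unknown <- setdiff(names(scaling), names(design))
    if (length(unknown))
      stop("scaling names not in design: ", paste(unknown, collapse = ", "))
  }
  scaling <- scaling[names(scaling) %in% names(design)]
  if (any(scaling <= 0)) stop("scaling factors must be > 0")
  for (nm in names(scaling)) design[[nm]] <- design[[nm]] * scaling[[nm]]
  attr(design, "scaled") <- TRUE
  design
}

#' Assemble the scaled per-household design table
#'
#' Convenience wrapper around the preparation steps: extracts every raster
#' surface at the household locations, computes distance to water, scores
#' the PPI, merges the binary survey answers, and applies the scaling map.
#'
#' @param households \code{point_table} (or data.frame with x, y in km)
#'   carrying binary survey-answer columns.
#' @param rasters named list of \code{raster_grid} surfaces.
#' @param water polyline/polygon water set (optional; adds
#'   \code{dist_water}).
#' @param ppi_answers per-item PPI points (optional; adds \code{ppi}).
#' @param ppi_table a \code{ppi_lookup} (required with \code{ppi_answers}).
#' @param answers character vector of answer columns to carry over.
#' @param scaling scaling map applied once at the end.
#' @return scaled design data.frame (one row per household).
#' @export
build_design <- function(households, rasters = list(), water = NULL,
                         ppi_answers = NULL, ppi_table = NULL,
                         answers = intersect(c("food_storage", "straw_storage",
                                               "sleep_floor", "animal_shed"),
                                             names(households)),
                         scaling = default_scaling()) {
  design <- data.frame(row.names = seq_len(nrow(households)))
  for (nm in names(rasters))
    design[[nm]] <- as.numeric(extract_at_points(rasters[[nm]], households))
  if (!is.null(water)) design$dist_water <- distance_to_water(households, water)
  if (!is.null(ppi_answers)) {
    if (is.null(ppi_table)) stop("ppi_table required to score PPI answers")
    design$ppi <- ppi_score(ppi_answers, ppi_table)
  }
  for (nm in answers) design[[nm]] <- households[[nm]]
  scale_covariates(design, scaling[names(scaling) %in% names(design)])
}
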