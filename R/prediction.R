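#' Build a regular prediction grid over a region
#'
#' Candidate cell centres tile the region polygon's bounding box at the
#' given spacing — a w x h box yields floor(w/s) x floor(h/s) candidates —
#' then centres outside the region polygon are dropped and centres inside
#' any exclusion polygon (e.g. highly populated urban units, removed by
#' design) are masked.
#'
#' @param region a polygon (list with \code{ring}, or a closed 2-column
#'   matrix) in km.
#' @param spacing cell size in km (default 1).
#' @param exclusions optional \code{polygon_set} of masked areas.
#' @return list of class \code{prediction_grid}: \code{grid} (a
#'   \code{raster_grid} template of the bounding box), \code{points}
#'   (data.frame x, y of retained centres), \code{cell} (their cell index
#'   in storage order), \code{masked} (logical per retained centre).
#' @export
build_grid <- function(region, spacing = 1, exclusions = NULL) {
  ring <- if (is.list(region) && !is.null(region$ring)) region$ring
          else close_ring(as.matrix(region))
  stopifnot(spacing > 0)
  xr <- range(ring[, 1]); yr <- range(ring[, 2])
  nc <- floor(diff(xr) / spacing); nr <- floor(diff(yr) / spacing)
  if (nc < 1 || nr < 1) stop("spacing larger than the region extent")
  template <- raster_grid(matrix(NA_real_, nr, nc), xr[1], yr[1], spacing)
  ctr <- cell_centers(template)
  inside <- point_in_polygon(ctr$x, ctr$y, ring)
  masked <- rep(FALSE, nrow(ctr))
  if (!is.null(exclusions))
    for (ex in exclusions)
      masked <- masked | point_in_polygon(ctr$x, ctr$y, ex$ring)
  keep <- inside
  structure(list(grid = template,
                 points = ctr[keep, , drop = FALSE],
                 cell = which(keep),
                 masked = masked[keep]),
            class = "prediction_grid")
}

#' @export
print.prediction_grid <- function(x, ...) {
  cat("prediction_grid:", nrow(x$points), "cell centres at",
      x$grid$cellsize, "km (", sum(x$masked), "masked )\n")
  invisible(x)
}

#' Map posterior risk over a prediction grid
#'
#' Runs \code{\link{predict.glgm}} at every unmasked cell centre and writes
#' the posterior mean and SD of the risk into rasters; masked cells carry
#' nodata.
#'
#' @param fitted a \code{glgm} fit.
#' @param grid a \code{prediction_grid}.
#' @param design data.frame of scaled covariate values, one row per
#'   retained grid centre (same order as \code{grid$points}); every model
#'   covariate must be present.
#' @param nsim,seed Monte-Carlo controls passed to the predictor.
#' @return list of class \code{risk_surface}: \code{mean} and \code{sd}
#'   rasters.
#' @export
map_risk <- function(fitted, grid, design, nsim = 2000, seed = 1) {
  stopifnot(inherits(grid, "prediction_grid"))
  need <- setdiff(all.vars(stats::delete.response(fitted$terms)),
                  names(design))
  if (length(need))
    stop("covariate(s) missing on the prediction grid: ",
         paste(need, collapse = ", "))
  if (nrow(design) != nrow(grid$points))
    stop("design must have one row per grid centre")
  newdata <- cbind(design, grid$points)
  attr(newdata, "scaled") <- attr(design, "scaled")
  active <- !grid$masked
  mean_r <- grid$grid; sd_r <- grid$grid
  if (any(active)) {
    pr <- predict(fitted, newdata[active, , drop = FALSE],
                  type = "response", nsim = nsim, seed = seed)
    mean_r$values[grid$cell[active]] <- pr$mean
    sd_r$values[grid$cell[active]] <- pr$sd
  }
  structure(list(mean = mean_r, sd = sd_r), class = "risk_surface")
}

#' Expected households at risk per cell-year
#'
#' Cellwise product of the posterior mean risk and the household density
#' (households per cell): the expected number of bitten households per
#' km^2 in one year. Nodata propagates.
#'
#' @param risk mean-risk \code{raster_grid}.
#' @param hh_density household-count \code{raster_grid} on the identical
#'   geometry.
#' @return \code{raster_grid} of expected affected households.
#' @export
households_at_risk <- function(risk, hh_density) {
  stopifnot(inherits(risk, "raster_grid"), inherits(hh_density, "raster_grid"))
  if (risk$nrow != hh_density$nrow || risk$ncol != hh_density$ncol ||
      abs(risk$cellsize - hh_density$cellsize) > 1e-9 ||
      abs(risk$xll - hh_density$xll) > 1e-9 ||
      abs(risk$yll - hh_density$yll) > 1e-9)
    stop("risk and household-density rasters are not aligned")
  out <- risk
  out$values <- risk$values * hh_density$values
  out
}

#' Convert households to people
#'
#' Multiplies by the average household size (5.27 people per household in
#' the study region).
#'
#' @param households non-negative scalar, vector or \code{raster_grid}.
#' @param persons_per_household conversion factor.
#' @return same shape as the input, in people.
#' @export
people_from_households <- function(households, persons_per_household = 5.27) {
  if (inherits(households, "raster_grid")) {
    if (any(households$values < 0, na.rm = TRUE))
      stop("household counts must be non-negative")
    households$values <- households$values * persons_per_household
    return(households)
  }
  if (any(households < 0, na.rm = TRUE))
    stop("household counts must be non-negative")
  households * persons_per_household
}

#' Write a risk surface's rasters to ESRI ASCII grids
#' @param surface a \code{risk_surface}; @param dir output directory;
#' @param hh_at_risk optional households-at-risk raster to include.
#' @export
write_risk_surface <- function(surface, dir, hh_at_risk = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_raster_asc(surface$mean, file.path(dir, "risk_mean.asc"))
  write_raster_asc(surface$sd, file.path(dir, "risk_sd.asc"))
  if (!is.null(hh_at_risk))
    write_raster_asc(hh_at_risk, file.path(dir, "households_at_risk.asc"))
  invisible(dir)
}
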