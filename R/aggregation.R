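#' Threshold masks of a mean-risk raster
#'
#' One logical mask per threshold, selecting the cells with risk greater
#' than or equal to the threshold (closed comparison, per "larger or equal
#' to"). Masks are nested by construction because the thresholds are
#' required to be strictly increasing.
#'
#' @param risk mean-risk \code{raster_grid}.
#' @param thresholds strictly increasing values in (0, 1); default
#'   \code{c(0.01, 0.05, 0.1)}.
#' @return named list of logical matrices (NA risk gives FALSE).
#' @export
classify_risk <- function(risk, thresholds = c(0.01, 0.05, 0.1)) {
  stopifnot(inherits(risk, "raster_grid"))
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly increasing")
  if (any(thresholds <= 0 | thresholds >= 1))
    stop("thresholds must lie in (0, 1)")
  out <- lapply(thresholds, function(t) {
    m <- !is.na(risk$values) & risk$values >= t
    m
  })
  names(out) <- paste0("ge_", thresholds)
  out
}

#' Population at risk by administrative unit
#'
#' For every admin polygon and threshold, sums the population of the cells
#' whose centres fall inside the polygon and the threshold mask. Cells
#' with nodata population (e.g. the urban areas excluded by design) count
#' in neither the numerator nor the adjusted denominator. Percentages are
#' exact here; round at the report layer.
#'
#' @param population population \code{raster_grid} (people per cell).
#' @param masks named list of logical matrices from
#'   \code{\link{classify_risk}} (aligned with \code{population}).
#' @param admin a \code{polygon_set} with unique unit ids.
#' @return data.frame of class \code{risk_class_table}: one row per unit
#'   with \code{adjusted_pop}, and \code{pop_<mask>} / \code{pct_<mask>}
#'   per threshold; units whose polygons contain no unmasked cell are
#'   flagged in \code{empty}.
#' @export
zonal_population <- function(population, masks, admin) {
  stopifnot(inherits(population, "raster_grid"))
  for (m in masks)
    if (!all(dim(m) == dim(population$values)))
      stop("mask geometry does not match the population raster")
  ctr <- cell_centers(population)
  pop <- as.vector(t(population$values))   # storage order of cell_centers
  rows <- lapply(admin, function(poly) {
    inside <- point_in_polygon(ctr$x, ctr$y, poly$ring)
    valid <- inside & !is.na(pop)
    adj <- sum(pop[valid])
    row <- data.frame(unit = poly$id, adjusted_pop = adj,
                      empty = !any(valid))
    for (nm in names(masks)) {
      mv <- as.vector(t(masks[[nm]]))
      at_risk <- sum(pop[valid & mv])
      row[[paste0("pop_", nm)]] <- at_risk
      row[[paste0("pct_", nm)]] <- if (adj > 0) 100 * at_risk / adj else 0
    }
    row
  })
  structure(do.call(rbind, rows), class = c("risk_class_table", "data.frame"))
}

#' Expected annual snakebite cases
#'
#' Product of the population at risk and the risk level; the published
#' figures round to the nearest ten at the report layer
#' (613,043 people at risk >= 0.01 is "around 6,130 victims in 1 year").
#'
#' @param population_at_risk people count(s), non-negative.
#' @param risk_level risk in [0, 1].
#' @param report round to the nearest ten (report layer)?
#' @return expected cases.
#' @export
expected_cases <- function(population_at_risk, risk_level, report = FALSE) {
  if (any(population_at_risk < 0)) stop("population must be non-negative")
  if (any(risk_level < 0 | risk_level > 1)) stop("risk must lie in [0, 1]")
  out <- population_at_risk * risk_level
  if (report) out <- round(out / 10) * 10
  out
}

#' Write a risk-class table as CSV (2-decimal percentages)
#' @param table a \code{risk_class_table}; @param path output CSV.
#' @export
write_risk_class_table <- function(table, path) {
  out <- as.data.frame(table)
  for (nm in grep("^pct_", names(out), value = TRUE))
    out[[nm]] <- round(out[[nm]], 2)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
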