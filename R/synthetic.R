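#' Reference logit-scale effect sizes
#'
#' Posterior-mean coefficients of the published household snakebite models
#' (human and domestic-animal outcomes), on the scaled-covariate logit
#' scale. Used as the default "true" effects of the synthetic-survey
#' generator so that simulated data carry realistic signal strength.
#' @format named numeric vectors.
#' @export
human_model_betas <- c(food_storage = 1.02, straw_storage = 0.58,
                       sleep_floor = -0.77, ppi = 4.16, ndvi = -1.43,
                       dist_water = 0.32)

#' @rdname human_model_betas
#' @export
animal_model_betas <- c(animal_shed = 1.84, straw_storage = 0.50,
                        hmts = -2.01, bio6 = 3.15, pig_density = 0.82,
                        sheep_density = 2.09)

#' Configuration of a synthetic household survey
#'
#' Defines the statistical conditions a simulated survey emulates: a
#' multi-cluster design over a flat Terai-like strip, smooth environmental
#' surfaces in realistic ranges, a Matern latent field, and a rare binary
#' outcome. Defaults reproduce the published study conditions: 249 clusters
#' of 53 households (13,197 total, near the surveyed 13k), human outcome
#' prevalence 1.18\%, field SD 1 and range 30 km, minimum winter temperature
#' (BIO6) in 1.8-10.9 degC and dry-quarter precipitation (BIO17) in
#' 18-71 mm.
#'
#' @param region_extent c(width, height) of the region in km.
#' @param n_clusters number of survey clusters (>= 1).
#' @param households_per_cluster households per cluster (>= 1).
#' @param cluster_radius household scatter radius around each cluster
#'   centre (km); must fit inside the region.
#' @param true_beta named logit-scale coefficients applied to the scaled
#'   design columns of the same names.
#' @param intercept logit-scale intercept (overridden when
#'   \code{outcome_prevalence_target} is set).
#' @param spatial_sd,spatial_range Matern field SD and practical range (km).
#' @param outcome_prevalence_target realized-prevalence target used to
#'   calibrate the intercept by bisection, or \code{NULL} to use
#'   \code{intercept} as given.
#' @param surface_cell_km raster cell size of the generated surfaces (km).
#' @param surface_smoothness_km correlation length of the low-pass filter
#'   applied to the white-noise surfaces; 0 leaves white noise.
#' @param covariate_ranges named list of c(min, max) raw value ranges.
#' @param answer_prevalence named prevalences of the binary survey answers.
#' @param ppi_items per-item maximum points of the poverty-index items
#'   (answers are drawn uniformly over 0..max so scores span the table).
#' @param n_water number of random river polylines; the default keeps
#'   household distances to water in the low-kilometre range typical of a
#'   river-dense floodplain, the scale on which the per-km odds effect is
#'   interpreted.
#' @param n_admin c(nx, ny) rectangular administrative units partitioning
#'   the region.
#' @param seed integer RNG seed: identical config + seed gives a
#'   bit-identical survey.
#' @return validated list of class \code{synth_config}.
#' @export
synth_config <- function(region_extent = c(600, 150), n_clusters = 249,
                         households_per_cluster = 53, cluster_radius = 1.5,
                         true_beta = human_model_betas, intercept = -2.21,
                         spatial_sd = 1, spatial_range = 30,
                         outcome_prevalence_target = 0.0118,
                         surface_cell_km = 2, surface_smoothness_km = 20,
                         covariate_ranges = list(
                           ndvi = c(0, 1), bio1 = c(18, 26),
                           bio6 = c(1.8, 10.9), bio17 = c(18, 71),
                           hmts = c(0, 1), pig_density = c(0, 1000),
                           sheep_density = c(0, 1500), hh_density = c(5, 200)),
                         answer_prevalence = c(food_storage = 0.5,
                                               straw_storage = 0.5,
                                               sleep_floor = 0.3,
                                               animal_shed = 0.6),
                         ppi_items = rep(10L, 10), n_water = 12,
                         n_admin = c(6, 2), seed = 1) {
  cfg <- list(region_extent = region_extent, n_clusters = n_clusters,
              households_per_cluster = households_per_cluster,
              cluster_radius = cluster_radius, true_beta = true_beta,
              intercept = intercept, spatial_sd = spatial_sd,
              spatial_range = spatial_range,
              outcome_prevalence_target = outcome_prevalence_target,
              surface_cell_km = surface_cell_km,
              surface_smoothness_km = surface_smoothness_km,
              covariate_ranges = covariate_ranges,
              answer_prevalence = answer_prevalence,
              ppi_items = as.integer(ppi_items), n_water = n_water,
              n_admin = n_admin, seed = as.integer(seed))
  with(cfg, {
    stopifnot(length(region_extent) == 2, all(region_extent > 0),
              n_clusters >= 1, households_per_cluster >= 1,
              cluster_radius > 0, spatial_sd >= 0, spatial_range > 0,
              surface_cell_km > 0, surface_smoothness_km >= 0)
    if (2 * cluster_radius >= min(region_extent))
      stop("cluster_radius too large for the region extent")
    if (!is.null(outcome_prevalence_target))
      stopifnot(outcome_prevalence_target > 0, outcome_prevalence_target < 1)
  })
  structure(cfg, class = "synth_config")
}

#' Animal-outcome preset
#'
#' Same survey design, with the published animal-model effects, weaker and
#' much longer-ranged latent field (SD 0.77, range 430 km) and prevalence
#' 0.7\%.
#' @param ... overrides passed to \code{\link{synth_config}}.
#' @export
animal_synth_config <- function(...) {
  synth_config(true_beta = animal_model_betas, intercept = -5.38,
               spatial_sd = 0.77, spatial_range = 430,
               outcome_prevalence_target = 0.007, ...)
}

## low-pass-filtered uniform noise rescaled into [lo, hi]
smooth_noise_matrix <- function(nr, nc, smooth_cells, vrange) {
  z <- matrix(stats::runif(nr * nc), nr, nc)
  if (smooth_cells > 0) {
    half <- min(max(1L, ceiling(3 * smooth_cells)),
                floor((min(nr, nc) - 1) / 2))
    k <- stats::dnorm(seq(-half, half) / smooth_cells)
    k <- k / sum(k)
    if (length(k) > 1) {
      z <- apply(z, 2, function(col) stats::filter(col, k, circular = TRUE))
      z <- t(apply(z, 1, function(row) stats::filter(row, k, circular = TRUE)))
    }
    rng <- range(z)
    z <- if (diff(rng) > 0) (z - rng[1]) / diff(rng) else z * 0 + 0.5
    z <- vrange[1] + z * (vrange[2] - vrange[1])
  } else {
    z <- vrange[1] + z * (vrange[2] - vrange[1])
  }
  z
}

#' Generate the synthetic covariate surfaces and vector layers
#'
#' Smooth (low-pass-filtered uniform noise) surfaces within the configured
#' value ranges, random river polylines, and a rectangular partition of the
#' region into administrative units.
#'
#' @param config a \code{synth_config}.
#' @param seed optional seed; \code{NULL} continues the current RNG stream.
#' @return list with \code{rasters} (named \code{raster_grid} list),
#'   \code{water} (\code{polyline_set}), \code{admin}
#'   (\code{polygon_set}).
#' @export
generate_covariate_surfaces <- function(config, seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (!is.null(seed)) set.seed(seed)
  w <- config$region_extent[1]; h <- config$region_extent[2]
  cs <- config$surface_cell_km
  nc <- max(2L, ceiling(w / cs)); nr <- max(2L, ceiling(h / cs))
  sm <- config$surface_smoothness_km / cs
  rasters <- lapply(config$covariate_ranges, function(vrange)
    raster_grid(smooth_noise_matrix(nr, nc, sm, vrange), 0, 0, cs))
  water <- lapply(seq_len(config$n_water), function(i) {
    y <- stats::runif(1, 0.1 * h, 0.9 * h)
    xs <- seq(0, w, by = max(5, w / 40))
    ys <- y + cumsum(stats::rnorm(length(xs), 0, h / 30))
    cbind(xs, pmin(pmax(ys, 0), h))
  })
  nxa <- config$n_admin[1]; nya <- config$n_admin[2]
  admin <- list()
  for (iy in seq_len(nya)) for (ix in seq_len(nxa)) {
    x0 <- (ix - 1) * w / nxa; x1 <- ix * w / nxa
    y0 <- (iy - 1) * h / nya; y1 <- iy * h / nya
    admin[[length(admin) + 1L]] <- list(
      id = sprintf("unit_%02d", length(admin) + 1L),
      ring = rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1), c(x0, y0)))
  }
  list(rasters = rasters,
       water = structure(water, class = "polyline_set"),
       admin = structure(admin, class = "polygon_set"))
}

#' Sample clustered household locations and survey answers
#'
#' Cluster centres uniform in the region (inset by the cluster radius so
#' every disc fits); households uniform in the disc around their centre.
#' Binary answers are Bernoulli draws at the configured prevalences, and
#' poverty-index item points are uniform over each item's 0..max range.
#'
#' @inheritParams generate_covariate_surfaces
#' @return list with \code{households} (data.frame: hh_id, cluster_id, x, y
#'   in km, binary answers, ppi_item_* columns) and \code{centers}
#'   (n_clusters x 2 matrix).
#' @export
sample_households <- function(config, seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (!is.null(seed)) set.seed(seed)
  w <- config$region_extent[1]; h <- config$region_extent[2]
  r <- config$cluster_radius
  k <- config$n_clusters; m <- config$households_per_cluster
  centers <- cbind(stats::runif(k, r, w - r), stats::runif(k, r, h - r))
  n <- k * m
  cl <- rep(seq_len(k), each = m)
  rad <- r * sqrt(stats::runif(n))
  ang <- stats::runif(n, 0, 2 * pi)
  hh <- data.frame(hh_id = seq_len(n), cluster_id = cl,
                   x = centers[cl, 1] + rad * cos(ang),
                   y = centers[cl, 2] + rad * sin(ang))
  for (nm in names(config$answer_prevalence))
    hh[[nm]] <- stats::rbinom(n, 1, config$answer_prevalence[[nm]])
  for (i in seq_along(config$ppi_items))
    hh[[sprintf("ppi_item_%02d", i)]] <-
      sample.int(config$ppi_items[i] + 1L, n, replace = TRUE) - 1L
  attr(hh, "units") <- "km"
  class(hh) <- c("point_table", "data.frame")
  list(households = hh, centers = centers)
}

#' Draw binary outcomes from the hierarchical spatial logistic model
#'
#' Evaluates the linear predictor \eqn{\eta_i = \beta_0 + X_i \beta + u(s_i)}
#' on the scaled design, with \eqn{u} one Matern field realization, and
#' draws \eqn{y_i \sim Bernoulli(logit^{-1}(\eta_i))}. When the config sets
#' a prevalence target, the intercept is calibrated by bisection so the
#' realized mean of \eqn{logit^{-1}(\eta)} hits the target. The field is
#' simulated at household locations when their number is within the dense
#' factorization limit, otherwise at the cluster centres (households within
#' a cluster then share the field value, accurate when the range is much
#' larger than the cluster radius).
#'
#' @param households household table from \code{\link{sample_households}}.
#' @param design scaled design table (see \code{\link{build_design}}).
#' @param config a \code{synth_config}.
#' @param seed optional seed.
#' @param centers cluster-centre matrix (needed for the cluster-level field
#'   path).
#' @return list with \code{outcome} (0/1 vector), \code{u} (realized field
#'   per household), \code{intercept} (value actually used), \code{eta}.
#' @export
generate_outcomes <- function(households, design, config, seed = NULL,
                              centers = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (!is.null(seed)) set.seed(seed)
  beta <- config$true_beta
  miss <- setdiff(names(beta), names(design))
  if (length(miss))
    stop("true_beta names missing from design: ", paste(miss, collapse = ", "))
  X <- as.matrix(design[, names(beta), drop = FALSE])
  xb <- drop(X %*% beta)
  n <- nrow(households)
  if (config$spatial_sd == 0) {
    u <- numeric(n)
  } else if (n <= 5000) {
    u <- simulate_matern_grf(cbind(households$x, households$y),
                             config$spatial_sd, config$spatial_range)
  } else {
    if (is.null(centers)) stop("centers required for the cluster-level field ",
                               "path (> 5000 households)")
    u_cl <- simulate_matern_grf(centers, config$spatial_sd,
                                config$spatial_range)
    u <- u_cl[households$cluster_id]
  }
  eta_fixed <- xb + u
  b0 <- config$intercept
  if (!is.null(config$outcome_prevalence_target)) {
    target <- config$outcome_prevalence_target
    f <- function(b) mean(stats::plogis(b + eta_fixed)) - target
    b0 <- stats::uniroot(f, c(-50, 50), tol = 1e-10)$root
  }
  eta <- b0 + eta_fixed
  list(outcome = stats::rbinom(n, 1, stats::plogis(eta)), u = u,
       intercept = b0, eta = eta)
}

#' Simulate a complete synthetic survey
#'
#' Runs the whole generator: surfaces and vector layers, clustered
#' households with answers, scaled design, latent field and outcomes. All
#' randomness flows from \code{config$seed}, so identical configs give
#' bit-identical surveys.
#'
#' @param config a \code{synth_config}.
#' @param outcome_name name of the outcome column (default
#'   \code{"outcome"}).
#' @return list of class \code{synthetic_survey}: \code{households} (with
#'   the outcome column), \code{design} (scaled), \code{rasters},
#'   \code{water}, \code{admin}, \code{centers}, and \code{truth} (config,
#'   realized field \code{u}, calibrated intercept, linear predictor).
#' @export
simulate_survey <- function(config = synth_config(), outcome_name = "outcome") {
  set.seed(config$seed)
  hh <- sample_households(config)
  surf <- generate_covariate_surfaces(config)
  design_rasters <- surf$rasters[setdiff(names(surf$rasters), "hh_density")]
  lookup <- synthetic_ppi_lookup(sum(config$ppi_items))
  item_cols <- grep("^ppi_item_", names(hh$households), value = TRUE)
  design <- build_design(hh$households, rasters = design_rasters,
                         water = surf$water,
                         ppi_answers = hh$households[, item_cols, drop = FALSE],
                         ppi_table = lookup)
  out <- generate_outcomes(hh$households, design, config,
                           centers = hh$centers)
  households <- hh$households
  households[[outcome_name]] <- out$outcome
  structure(list(households = households, design = design,
                 rasters = surf$rasters, water = surf$water,
                 admin = surf$admin, centers = hh$centers,
                 truth = list(config = config, u = out$u,
                              intercept = out$intercept, eta = out$eta)),
            class = "synthetic_survey")
}

#' @export
print.synthetic_survey <- function(x, ...) {
  cfg <- x$truth$config
  oc <- setdiff(names(x$households),
                c("hh_id", "cluster_id", "x", "y",
                  names(cfg$answer_prevalence),
                  grep("^ppi_item_", names(x$households), value = TRUE)))
  cat("synthetic_survey:", nrow(x$households), "households in",
      cfg$n_clusters, "clusters over", cfg$region_extent[1], "x",
      cfg$region_extent[2], "km\n")
  for (nm in oc)
    cat("  ", nm, "prevalence:",
        format(mean(x$households[[nm]]), digits = 3), "\n")
  cat("  field: sd", cfg$spatial_sd, ", range", cfg$spatial_range, "km;",
      "intercept used:", format(x$truth$intercept, digits = 4), "\n")
  invisible(x)
}

#' Empirical semivariogram
#'
#' Binned moment estimator \eqn{\gamma(h) = mean((z_i - z_j)^2)/2} over
#' point pairs, for checking that simulated fields flatten at the field
#' variance beyond the range.
#'
#' @param xy n x 2 coordinates (km); @param z field values;
#' @param breaks distance bin edges (km).
#' @return data.frame with bin midpoint, semivariance, pair count.
#' @export
empirical_semivariogram <- function(xy, z, breaks) {
  D <- pairwise_dist(xy)
  iu <- which(upper.tri(D))
  d <- D[iu]
  g <- 0.5 * (outer(z, z, "-")[iu])^2
  bin <- cut(d, breaks, include.lowest = TRUE)
  data.frame(dist = tapply(d, bin, mean),
             gamma = tapply(g, bin, mean),
             n = as.integer(table(bin)))
}

#' Write a synthetic survey to disk in the standard exchange formats
#'
#' Household table as CSV (metre coordinates), surfaces as ESRI ASCII
#' grids, water and admin layers as GeoJSON, and the generating truth as a
#' YAML sidecar.
#'
#' @param survey a \code{synthetic_survey}; @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
write_survey <- function(survey, dir) {
  stopifnot(inherits(survey, "synthetic_survey"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_point_csv(survey$households, file.path(dir, "households.csv"))
  for (nm in names(survey$rasters))
    write_raster_asc(survey$rasters[[nm]], file.path(dir, paste0(nm, ".asc")))
  write_geojson(survey$water, file.path(dir, "water.geojson"))
  write_geojson(survey$admin, file.path(dir, "admin.geojson"))
  cfg <- survey$truth$config
  cfg$true_beta <- as.list(cfg$true_beta)
  cfg$answer_prevalence <- as.list(cfg$answer_prevalence)
  yaml::write_yaml(list(config = unclass(cfg),
                        intercept = survey$truth$intercept),
                   file.path(dir, "truth.yaml"))
  invisible(dir)
}
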