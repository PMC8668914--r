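#' Default run configuration
#'
#' One structured list driving the whole pipeline: paths, seeds, the model
#' spec, the three selection thresholds (0.6 correlation, VIF 5, 0.1
#' log-odds band), grid spacing (1 km), risk thresholds (0.01/0.05/0.1)
#' and persons per household (5.27). Write it to YAML with
#' \code{yaml::write_yaml} and load with \code{\link{read_run_config}}.
#'
#' @param workdir directory for all stage artifacts.
#' @param seed master seed; every stochastic stage derives from it.
#' @param ... overrides of any top-level field.
#' @export
default_run_config <- function(workdir = "snakerisk_run", seed = 1, ...) {
  cfg <- list(
    workdir = workdir, seed = seed,
    synth = list(n_clusters = 60, households_per_cluster = 25,
                 region_extent = c(240, 100)),
    model = list(outcome = "outcome",
                 covariates = c("food_storage", "straw_storage",
                                "sleep_floor", "ppi", "ndvi", "dist_water",
                                "bio1", "bio6", "bio17", "hmts",
                                "pig_density", "sheep_density"),
                 sigma_bounds = c(0.1, 1.5), grid_res = c(5, 5)),
    selection = list(cor_threshold = 0.6, max_vif = 5, band = 0.1),
    grid_spacing = 4, risk_thresholds = c(0.01, 0.05, 0.1),
    persons_per_household = 5.27)
  utils::modifyList(cfg, list(...))
}

#' @rdname default_run_config
#' @param path YAML config file.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  utils::modifyList(default_run_config(), cfg)
}

log_line <- function(cfg, ...) {
  line <- paste(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), ...)
  cat(line, "\n", file = file.path(cfg$workdir, "run.log"), append = TRUE)
  invisible(line)
}

validate_run_config <- function(cfg) {
  sel <- cfg$selection
  if (sel$cor_threshold <= 0 || sel$cor_threshold >= 1)
    stop("config selection$cor_threshold must lie in (0, 1)")
  if (sel$max_vif <= 1) stop("config selection$max_vif must exceed 1")
  if (sel$band < 0) stop("config selection$band must be >= 0")
  if (cfg$grid_spacing <= 0) stop("config grid_spacing must be > 0")
  if (any(diff(cfg$risk_thresholds) <= 0))
    stop("config risk_thresholds must be strictly increasing")
  if (cfg$persons_per_household <= 0)
    stop("config persons_per_household must be > 0")
  invisible(cfg)
}

stage_file <- function(cfg, ...) file.path(cfg$workdir, ...)

require_artifact <- function(cfg, path, produced_by) {
  f <- stage_file(cfg, path)
  if (!file.exists(f))
    stop("missing upstream artifact '", path, "'; run stage '",
         produced_by, "' first")
  f
}

#' Run one pipeline stage
#'
#' Stages: \code{simulate} (synthetic survey to disk), \code{prepare}
#' (design matrix from the raw layers), \code{select} (covariate
#' selection), \code{fit} (final model), \code{predict} (risk rasters),
#' \code{aggregate} (population-at-risk table), \code{report} (rendered
#' coefficient and risk tables). Each stage reads its upstream artifacts
#' from \code{config$workdir}, writes its own, and appends to the run log;
#' reruns with the same config and seed reproduce identical outputs.
#'
#' @param stage stage name.
#' @param config a run config list (see \code{\link{default_run_config}}).
#' @return stage-specific result, invisibly.
#' @export
run_stage <- function(stage = c("simulate", "prepare", "select", "fit",
                                "predict", "aggregate", "report"),
                      config = default_run_config()) {
  stage <- match.arg(stage)
  cfg <- validate_run_config(config)
  dir.create(cfg$workdir, recursive = TRUE, showWarnings = FALSE)
  res <- switch(stage,
    simulate = {
      sc <- do.call(synth_config, c(cfg$synth, list(seed = cfg$seed)))
      survey <- simulate_survey(sc)
      write_survey(survey, stage_file(cfg, "data"))
      log_line(cfg, "simulate: seed", cfg$seed, ",",
               nrow(survey$households), "households")
      survey
    },
    prepare = {
      hh_path <- require_artifact(cfg, "data/households.csv", "simulate")
      raw <- utils::read.csv(hh_path)
      cmap <- stats::setNames(names(raw), names(raw))
      names(cmap)[names(cmap) == "x_m"] <- "x_m"
      hh <- read_point_csv(hh_path, columns = cmap)
      rfiles <- list.files(stage_file(cfg, "data"), pattern = "\\.asc$",
                           full.names = TRUE)
      rasters <- lapply(rfiles, read_raster_asc)
      names(rasters) <- sub("\\.asc$", "", basename(rfiles))
      water <- read_polylines(require_artifact(cfg, "data/water.geojson",
                                               "simulate"))
      item_cols <- grep("^ppi_item_", names(hh), value = TRUE)
      design <- build_design(
        hh, rasters = rasters[setdiff(names(rasters), "hh_density")],
        water = water,
        ppi_answers = if (length(item_cols)) hh[item_cols] else NULL,
        ppi_table = if (length(item_cols))
          synthetic_ppi_lookup(10 * length(item_cols)) else NULL)
      prepared <- cbind(hh[c("hh_id", "cluster_id", "x", "y",
                             grep("^outcome", names(hh), value = TRUE))],
                        design)
      attr(prepared, "scaled") <- TRUE
      utils::write.csv(prepared, stage_file(cfg, "design.csv"),
                       row.names = FALSE)
      log_line(cfg, "prepare:", nrow(prepared), "rows,",
               ncol(design), "covariates,", attr(hh, "n_dropped"),
               "dropped coordinate rows")
      prepared
    },
    select = {
      prepared <- read_prepared(cfg)
      covs <- intersect(cfg$model$covariates, names(prepared))
      sel <- select_covariates(cfg$model$outcome, covs, prepared,
                               cor_threshold = cfg$selection$cor_threshold,
                               max_vif = cfg$selection$max_vif,
                               band = cfg$selection$band,
                               sigma_bounds = cfg$model$sigma_bounds,
                               grid_res = cfg$model$grid_res,
                               seed = cfg$seed)
      write_selection_trace(sel, stage_file(cfg, "selection"))
      writeLines(sel$covariates, stage_file(cfg, "final_covariates.txt"))
      log_line(cfg, "select:", length(covs), "->",
               length(sel$covariates), "covariates, final WAIC",
               format(sel$final_fit$waic$waic, digits = 8))
      sel
    },
    fit = {
      prepared <- read_prepared(cfg)
      covs <- readLines(require_artifact(cfg, "final_covariates.txt",
                                         "select"))
      fit <- glgm(stats::reformulate(covs, response = cfg$model$outcome),
                  prepared, sigma_bounds = cfg$model$sigma_bounds,
                  grid_res = cfg$model$grid_res, seed = cfg$seed)
      saveRDS(fit, stage_file(cfg, "fit.rds"))
      write_coefficient_table(fit, stage_file(cfg, "coefficients.csv"))
      log_line(cfg, "fit: WAIC", format(fit$waic$waic, digits = 8))
      fit
    },
    predict = {
      fit <- readRDS(require_artifact(cfg, "fit.rds", "fit"))
      rfiles <- list.files(stage_file(cfg, "data"), pattern = "\\.asc$",
                           full.names = TRUE)
      rasters <- lapply(rfiles, read_raster_asc)
      names(rasters) <- sub("\\.asc$", "", basename(rfiles))
      admin <- read_polygons(require_artifact(cfg, "data/admin.geojson",
                                              "simulate"))
      water <- read_polylines(stage_file(cfg, "data/water.geojson"))
      bbox <- do.call(rbind, lapply(admin, `[[`, "ring"))
      region <- rbind(c(min(bbox[, 1]), min(bbox[, 2])),
                      c(max(bbox[, 1]), min(bbox[, 2])),
                      c(max(bbox[, 1]), max(bbox[, 2])),
                      c(min(bbox[, 1]), max(bbox[, 2])),
                      c(min(bbox[, 1]), min(bbox[, 2])))
      grid <- build_grid(region, spacing = cfg$grid_spacing)
      covs <- all.vars(stats::delete.response(fit$terms))
      gdesign <- data.frame(row.names = seq_len(nrow(grid$points)))
      for (nm in intersect(covs, names(rasters)))
        gdesign[[nm]] <- as.numeric(extract_at_points(rasters[[nm]],
                                                      grid$points))
      if ("dist_water" %in% covs)
        gdesign$dist_water <- distance_to_water(grid$points, water)
      survey_covs <- setdiff(covs, names(gdesign))
      prepared <- read_prepared(cfg)
      for (nm in survey_covs)            # survey-only covariates cannot be
        gdesign[[nm]] <- mean(prepared[[nm]])   # imputed: hold at the mean
      gdesign <- scale_covariates(gdesign)
      surface <- map_risk(fit, grid, gdesign, seed = cfg$seed)
      hh_dens <- raster_grid(
        matrix(as.numeric(extract_at_points(rasters$hh_density,
                                            grid$points)) *
                 cfg$grid_spacing^2,
               grid$grid$nrow, grid$grid$ncol, byrow = TRUE),
        grid$grid$xll, grid$grid$yll, grid$grid$cellsize)
      har <- households_at_risk(surface$mean, hh_dens)
      write_risk_surface(surface, stage_file(cfg, "prediction"), har)
      write_raster_asc(hh_dens, stage_file(cfg, "prediction",
                                           "hh_density_grid.asc"))
      log_line(cfg, "predict:", nrow(grid$points), "grid cells")
      surface
    },
    aggregate = {
      mean_r <- read_raster_asc(require_artifact(
        cfg, "prediction/risk_mean.asc", "predict"))
      hh_dens <- read_raster_asc(require_artifact(
        cfg, "prediction/hh_density_grid.asc", "predict"))
      admin <- read_polygons(stage_file(cfg, "data/admin.geojson"))
      pop <- people_from_households(hh_dens, cfg$persons_per_household)
      masks <- classify_risk(mean_r, cfg$risk_thresholds)
      tab <- zonal_population(pop, masks, admin)
      write_risk_class_table(tab, stage_file(cfg, "risk_classes.csv"))
      log_line(cfg, "aggregate:", nrow(tab), "admin units")
      tab
    },
    report = {
      fit <- readRDS(require_artifact(cfg, "fit.rds", "fit"))
      cat("== Coefficients (posterior marginals) ==\n")
      print(summary(fit))
      tab_path <- stage_file(cfg, "risk_classes.csv")
      tab <- NULL
      if (file.exists(tab_path)) {
        tab <- utils::read.csv(tab_path)
        cat("\n== Population at risk by admin unit ==\n")
        print(tab)
      }
      log_line(cfg, "report rendered")
      invisible(list(fit = fit, risk_classes = tab))
    })
  invisible(res)
}

read_prepared <- function(cfg) {
  prepared <- utils::read.csv(require_artifact(cfg, "design.csv", "prepare"))
  attr(prepared, "scaled") <- TRUE
  prepared
}

#' Run the whole pipeline in order
#' @param config run config; @param stages stages to run.
#' @export
run_pipeline <- function(config = default_run_config(),
                         stages = c("simulate", "prepare", "select", "fit",
                                    "predict", "aggregate", "report")) {
  for (s in stages) run_stage(s, config)
  invisible(config$workdir)
}
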