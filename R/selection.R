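## Iterative covariate selection: correlation filter, sequential VIF,
## negligible-effect pruning against the fitted model, WAIC comparison,
## interaction checks and spatial ablation. Every removal is logged with
## the statistic that justified it, so a selection run replays exactly.

new_trace <- function() {
  data.frame(step = character(), covariate = character(),
             statistic = character(), value = numeric(),
             waic_before = numeric(), waic_after = numeric(),
             stringsAsFactors = FALSE)
}

add_trace <- function(trace, step, covariate, statistic, value,
                      waic_before = NA, waic_after = NA) {
  rbind(trace, data.frame(step = step, covariate = covariate,
                          statistic = statistic, value = value,
                          waic_before = waic_before, waic_after = waic_after,
                          stringsAsFactors = FALSE))
}

#' Pairwise Pearson correlation filter
#'
#' While any covariate pair has \eqn{|r|} above the threshold (the
#' published band kept pairs within -0.6..0.6), one member is removed: the
#' one with the larger mean absolute correlation to all other covariates;
#' ties fall to the later column in \code{priority} (the configured
#' priority order, default the column order). Binary covariates enter as
#' 0/1. Constant columns, whose correlation is undefined, are removed
#' first and logged.
#'
#' @param design data.frame of numeric covariate columns.
#' @param threshold absolute-correlation threshold (default 0.6; the pair
#'   is removed only when \eqn{|r|} exceeds it, so r = 0.6 exactly is
#'   kept).
#' @param priority character vector; later entries lose ties.
#' @return list: \code{design} (reduced), \code{trace}.
#' @export
pearson_filter <- function(design, threshold = 0.6,
                           priority = names(design)) {
  stopifnot(ncol(design) >= 2)
  trace <- new_trace()
  keep <- names(design)
  const <- keep[vapply(design[keep], function(v) stats::var(v) == 0, TRUE)]
  for (nm in const) {
    trace <- add_trace(trace, "pearson_constant", nm, "variance", 0)
    keep <- setdiff(keep, nm)
  }
  repeat {
    if (length(keep) < 2) break
    R <- stats::cor(design[keep])
    diag(R) <- 0
    mx <- max(abs(R))
    if (mx <= threshold) break
    worst <- which(abs(R) == mx, arr.ind = TRUE)[1, ]
    pair <- keep[worst]
    score <- rowMeans(abs(R))[pair]
    drop_nm <- pair[which.max(score)]
    if (abs(diff(score)) < 1e-12)
      drop_nm <- pair[which.max(match(pair, priority))]
    trace <- add_trace(trace, "pearson", drop_nm, "abs_correlation", mx)
    keep <- setdiff(keep, drop_nm)
  }
  list(design = design[keep], trace = trace)
}

#' Variance inflation factors
#'
#' \eqn{VIF_j = 1 / (1 - R^2_j)} from the ordinary least squares
#' regression of covariate j on all the others (with intercept). A
#' perfectly collinear covariate reports \code{Inf}.
#'
#' @param design data.frame of numeric covariates (>= 2 columns).
#' @return named numeric vector of VIFs.
#' @export
vif <- function(design) {
  stopifnot(ncol(design) >= 2)
  vapply(names(design), function(j) {
    fit <- stats::lm(stats::reformulate(setdiff(names(design), j),
                                        response = j), data = design)
    # perfect fits are legitimate here (duplicated columns -> VIF = Inf)
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Sequential VIF reduction
#'
#' Iteratively drops the highest-VIF covariate while the maximum VIF
#' exceeds the threshold (published threshold 5), recomputing each round.
#' Infinite VIFs (perfect collinearity) drop first.
#'
#' @inheritParams pearson_filter
#' @param max_vif threshold (strictly-greater comparison).
#' @return list: \code{design}, \code{trace}.
#' @export
sequential_vif <- function(design, max_vif = 5) {
  stopifnot(ncol(design) >= 2)
  trace <- new_trace()
  repeat {
    if (ncol(design) < 2) break
    v <- vif(design)
    if (max(v) <= max_vif) break
    drop_nm <- names(v)[which.max(v)]
    trace <- add_trace(trace, "vif", drop_nm, "vif", unname(max(v)))
    design <- design[setdiff(names(design), drop_nm)]
  }
  list(design = design, trace = trace)
}

#' Flag covariates with negligible posterior effects
#'
#' Covariates whose marginal posterior mean lies strictly inside the open
#' band (-band, band) on the log-odds scale (published band 0.1, "an
#' effect change of just above 10\%") are negligible candidates; a mean of
#' exactly +/- band is kept. The intercept is never flagged.
#'
#' @param fitted a \code{glgm} fit.
#' @param band half-width of the open negligible band.
#' @return character vector of flagged covariate names (possibly empty).
#' @export
prune_negligible <- function(fitted, band = 0.1) {
  tab <- fitted$marginals
  cand <- tab$name[abs(tab$mean) < band & tab$name != "(Intercept)"]
  as.character(cand)
}

#' Compare two fitted models by WAIC
#'
#' Lower WAIC preferred. Both models must be fitted on identical
#' observations.
#'
#' @param a,b \code{glgm} fits (or lists with \code{waic$waic} and
#'   \code{y}).
#' @return list: \code{preferred} (\code{"A"}, \code{"B"} or
#'   \code{"tie"}), \code{delta} (\code{|WAIC_A - WAIC_B|}),
#'   \code{waic_a}, \code{waic_b}.
#' @export
compare_waic <- function(a, b) {
  wa <- if (is.numeric(a)) a else a$waic$waic
  wb <- if (is.numeric(b)) b else b$waic$waic
  if (!is.numeric(a) && !is.numeric(b) &&
      !isTRUE(all.equal(a$y, b$y)))
    stop("models were fitted on different observation sets")
  list(preferred = if (wa < wb) "A" else if (wb < wa) "B" else "tie",
       delta = abs(wa - wb), waic_a = wa, waic_b = wb)
}

#' Test pairwise covariate interactions
#'
#' Refits the model with one product term per requested pair; the
#' interaction is "significant" when the 90\% credible interval of its
#' coefficient excludes 0 on the logit scale (equivalently, the odds-scale
#' interval excludes 1). Product columns collinear with the main effects
#' are reported and skipped.
#'
#' @param fitted a \code{glgm} fit.
#' @param data the data the model was fitted on.
#' @param pairs list of length-2 character vectors drawn from the current
#'   covariate set.
#' @param ... passed to \code{\link{glgm}} refits.
#' @return data.frame: pair, coefficient mean, 90\% CI, significance flag,
#'   delta WAIC versus the base model, skipped flag.
#' @export
test_interactions <- function(fitted, data, pairs, ...) {
  stopifnot(inherits(fitted, "glgm"))
  base_terms <- attr(stats::terms(fitted$formula), "term.labels")
  out <- lapply(pairs, function(pr) {
    if (length(pr) != 2 || pr[1] == pr[2])
      stop("interaction pairs must be two distinct covariates")
    if (!all(pr %in% base_terms))
      stop("pair not in the model's covariate set: ", paste(pr, collapse = ":"))
    prod_col <- data[[pr[1]]] * data[[pr[2]]]
    Xm <- cbind(1, as.matrix(data[base_terms]), prod_col)
    if (qr(Xm)$rank < ncol(Xm))
      return(data.frame(pair = paste(pr, collapse = ":"), mean = NA,
                        lo90 = NA, hi90 = NA, significant = NA,
                        delta_waic = NA, skipped = TRUE))
    f2 <- stats::update.formula(fitted$formula,
                                paste(". ~ . +", pr[1], ":", pr[2]))
    refit <- glgm(f2, data,
                  spatial = fitted$spatial,
                  field_at = if (fitted$spatial) fitted$field_at else "cluster",
                  beta_prec = fitted$beta_prec, seed = fitted$seed, ...)
    iname <- grep(":", refit$marginals$name, value = TRUE)[1]
    row <- refit$marginals[refit$marginals$name == iname, ]
    data.frame(pair = paste(pr, collapse = ":"), mean = row$mean,
               lo90 = row$lo90, hi90 = row$hi90,
               significant = row$lo90 > 0 | row$hi90 < 0,
               delta_waic = refit$waic$waic - fitted$waic$waic,
               skipped = FALSE)
  })
  do.call(rbind, out)
}

#' Spatial-ablation comparison
#'
#' Fits the identical covariate set with and without the spatial random
#' effect and reports both WAICs; the published models showed a clear
#' worsening without the spatial component.
#'
#' @param formula,data model as for \code{\link{glgm}}.
#' @param ... passed to both fits.
#' @return list: \code{spatial_fit}, \code{nonspatial_fit},
#'   \code{waic_spatial}, \code{waic_nonspatial}, \code{delta}
#'   (nonspatial - spatial; positive favours the spatial model),
#'   \code{delta_se} (standard error of the difference from the pointwise
#'   WAIC contributions), \code{comparison}.
#' @export
ablate_spatial <- function(formula, data, ...) {
  fs <- glgm(formula, data, spatial = TRUE, ...)
  fn <- glgm(formula, data, spatial = FALSE, ...)
  dpw <- fn$waic$pointwise - fs$waic$pointwise
  list(spatial_fit = fs, nonspatial_fit = fn,
       waic_spatial = fs$waic$waic, waic_nonspatial = fn$waic$waic,
       delta = fn$waic$waic - fs$waic$waic,
       delta_se = sqrt(length(dpw) * stats::var(dpw)),
       comparison = compare_waic(fs, fn))
}

#' Run the full iterative covariate-selection procedure
#'
#' The published pipeline: (1) remove one member of every covariate pair
#' correlated beyond the threshold; (2) sequential VIF reduction; (3) fit,
#' then iteratively remove negligible-effect covariates (open band on the
#' log-odds scale), refitting after each single removal and keeping a
#' covariate whenever its removal worsens the WAIC; stop at a fixed point.
#' Every step is logged in a replayable trace.
#'
#' @param outcome name of the outcome column in \code{data}.
#' @param covariates starting covariate set (column names).
#' @param data data.frame with outcome, covariates, coordinates, cluster
#'   id.
#' @param cor_threshold,max_vif,band the three selection thresholds
#'   (published values 0.6, 5, 0.1).
#' @param ... passed to the \code{\link{glgm}} fits.
#' @return list of class \code{selection_result}: \code{final_fit},
#'   \code{covariates}, \code{trace}.
#' @export
select_covariates <- function(outcome, covariates, data,
                              cor_threshold = 0.6, max_vif = 5, band = 0.1,
                              ...) {
  pf <- pearson_filter(data[covariates], threshold = cor_threshold)
  trace <- pf$trace
  sv <- sequential_vif(pf$design, max_vif = max_vif)
  trace <- rbind(trace, sv$trace)
  current <- names(sv$design)

  fit_with <- function(covs) {
    glgm(stats::reformulate(covs, response = outcome), data, ...)
  }
  fit <- fit_with(current)
  repeat {
    cand <- prune_negligible(fit, band = band)
    cand <- intersect(cand, current)
    if (!length(cand)) break
    # one removal per iteration: try each candidate, take the removal that
    # improves (lowers) the WAIC the most; if none improves, keep them all
    trials <- lapply(cand, function(nm) fit_with(setdiff(current, nm)))
    deltas <- vapply(trials, function(f) f$waic$waic, 0) - fit$waic$waic
    best <- which.min(deltas)
    if (deltas[best] >= 0) {
      for (nm in cand)
        trace <- add_trace(trace, "prune_kept", nm, "posterior_mean",
                           fit$marginals$mean[fit$marginals$name == nm],
                           fit$waic$waic, fit$waic$waic + min(deltas))
      break
    }
    nm <- cand[best]
    trace <- add_trace(trace, "prune", nm, "posterior_mean",
                       fit$marginals$mean[fit$marginals$name == nm],
                       fit$waic$waic, trials[[best]]$waic$waic)
    current <- setdiff(current, nm)
    fit <- trials[[best]]
    if (length(current) < 1) break
  }
  structure(list(final_fit = fit, covariates = current, trace = trace),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("covariate selection:", nrow(x$trace), "logged steps; final set:\n  ",
      paste(x$covariates, collapse = ", "), "\n")
  cat("final WAIC:", format(x$final_fit$waic$waic, digits = 6), "\n")
  invisible(x)
}

#' Write a selection trace to a log file and CSV
#' @param result a \code{selection_result}; @param path base path (writes
#'   \code{<path>.log} and \code{<path>.csv}).
#' @export
write_selection_trace <- function(result, path) {
  tr <- result$trace
  lines <- sprintf("%s\t%s\t%s=%.6g\twaic %.4f -> %.4f",
                   tr$step, tr$covariate, tr$statistic, tr$value,
                   tr$waic_before, tr$waic_after)
  writeLines(c(lines, paste("final:", paste(result$covariates,
                                            collapse = ", "))),
             paste0(path, ".log"))
  utils::write.csv(tr, paste0(path, ".csv"), row.names = FALSE)
  invisible(path)
}
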