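# Independent oracles and fixture builders shared across the suite.

# Matern nu=1 correlation at one practical range, sqrt(8)*K1(sqrt(8)),
# frozen from an independent evaluation of the Bessel function
# (scipy.special.k1).
MATERN_CORR_AT_RANGE <- 0.1396674740152931

# Independent ridge-penalized IRLS logistic regression (the textbook
# weighted-least-squares loop), used as the oracle for the non-spatial
# limit of the Laplace engine.
ridge_irls <- function(y, X, prec = 1e-3, tol = 1e-12, maxit = 200) {
  X <- as.matrix(X)
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-12)
    z <- eta + (y - p) / w
    bnew <- drop(solve(crossprod(X, X * w) + diag(prec, ncol(X)),
                       crossprod(X, w * z)))
    if (max(abs(bnew - beta)) < tol) return(bnew)
    beta <- bnew
  }
  beta
}

# The human-outcome model formula used throughout the recovery suites.
human_formula <- outcome ~ food_storage + straw_storage + sleep_floor +
  ppi + ndvi + dist_water

# One synthetic survey in model-ready form. Defaults are the recovery-suite
# conditions: 2,000 households in 80 clusters, field SD 1, range 30 km,
# published human effect sizes, prevalence calibrated to 0.25 so the
# outcome carries information about the field hyperparameters.
survey_data <- function(seed, n_clusters = 80, households_per_cluster = 25,
                        prevalence = 0.25, sd_field = 1, range_km = 30,
                        extent = c(300, 120), ...) {
  cfg <- synth_config(n_clusters = n_clusters,
                      households_per_cluster = households_per_cluster,
                      region_extent = extent, spatial_sd = sd_field,
                      spatial_range = range_km,
                      outcome_prevalence_target = prevalence,
                      seed = seed, ...)
  sv <- simulate_survey(cfg)
  d <- cbind(sv$households[c("outcome", "cluster_id", "x", "y")], sv$design)
  attr(d, "scaled") <- TRUE
  list(data = d, survey = sv)
}

# Tiny fabricated posterior for marginal-mixture tests.
fake_mixture_fit <- function(modes, vars, weights, name = "x") {
  list(fits = lapply(seq_along(modes),
                     function(i) list(mode = modes[i], diag_cov = vars[i],
                                      p = 1L)),
       hyper = data.frame(weight = weights),
       coef_names = name)
}
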