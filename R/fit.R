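## Bernoulli-logit latent Gaussian model, Laplace-approximation engine.
##
## Model: y_i ~ Bernoulli(pi_i), logit(pi_i) = eta_i = x_i' beta + u(s_i)
##        beta ~ N(0, beta_prec^-1 I),  u ~ N(0, Sigma(sigma, rho))  (Matern nu=1)
## For fixed hyperparameters the joint posterior of theta = (beta, u) is
## maximized by Newton-Raphson; the Gaussian at the mode gives conditional
## marginals and a Laplace estimate of log p(y | sigma, rho), which is then
## integrated over a grid of hyperparameter values.

log1pexp <- function(x) ifelse(x > 33, x, log1p(exp(x)))

bernoulli_loglik <- function(y, eta) {
  # log p(y | eta), numerically stable in both tails
  ifelse(y == 1, stats::plogis(eta, log.p = TRUE),
         stats::plogis(-eta, log.p = TRUE))
}

#' Laplace approximation of the conditional posterior at fixed hyperparameters
#'
#' Newton-Raphson maximization of the joint log-posterior of
#' \eqn{\theta = (\beta, u)} under a Bernoulli-logit likelihood, a vague
#' Gaussian prior on \eqn{\beta} and a Matern Gaussian-field prior on
#' \eqn{u} evaluated at the knot locations. Convergence when the maximum
#' absolute score drops below \code{tol}; steps are halved whenever the log
#' posterior would decrease.
#'
#' @param y 0/1 outcome vector.
#' @param X fixed-effects design matrix (including the intercept column).
#' @param knots m x 2 knot locations of the latent field (km), or
#'   \code{NULL} for a purely fixed-effects (non-spatial) fit.
#' @param knot_index length-n map from observation to knot row.
#' @param sigma,rho Matern hyperparameters (ignored when \code{knots} is
#'   \code{NULL}).
#' @param beta_prec prior precision of every fixed effect (intercept
#'   included); default \code{1e-3}, effectively vague.
#' @param jitter relative covariance jitter (see
#'   \code{\link{build_covariance}}).
#' @param start optional starting value for \eqn{\theta}.
#' @param tol score tolerance; @param max_iter iteration cap.
#' @return list: \code{mode}, \code{chol_prec} (upper Cholesky of the
#'   negative Hessian), \code{diag_cov} (marginal variances),
#'   \code{log_ml} (Laplace log marginal likelihood), \code{converged},
#'   \code{iterations}, \code{separation} flag, \code{p} (number of fixed
#'   effects).
#' @export
laplace_fit <- function(y, X, knots = NULL, knot_index = NULL,
                        sigma = 1, rho = 30, beta_prec = 1e-3,
                        jitter = 1e-8, start = NULL,
                        tol = 1e-6, max_iter = 100) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("outcomes must be binary 0/1")
  X <- as.matrix(X)
  n <- length(y); p <- ncol(X)
  spatial <- !is.null(knots)
  m <- if (spatial) nrow(knots) else 0L
  d <- p + m
  if (qr(X)$rank < p) stop("fixed-effects design is rank deficient")

  if (spatial) {
    S <- build_covariance(knots, sigma, rho, jitter = jitter)
    cholS <- chol(S)
    Qu <- chol2inv(cholS)
    logdet_Qu <- -2 * sum(log(diag(cholS)))
  } else {
    Qu <- NULL; logdet_Qu <- 0
  }
  logdet_Q0 <- p * log(beta_prec) + logdet_Qu

  theta <- if (is.null(start)) numeric(d) else start
  eta_of <- function(th) {
    e <- drop(X %*% th[seq_len(p)])
    if (spatial) e <- e + th[p + knot_index]
    e
  }
  logpost <- function(th, eta) {
    lp <- sum(bernoulli_loglik(y, eta)) -
      0.5 * beta_prec * sum(th[seq_len(p)]^2)
    if (spatial) {
      u <- th[p + seq_len(m)]
      lp <- lp - 0.5 * drop(crossprod(u, Qu %*% u))
    }
    lp
  }

  eta <- eta_of(theta)
  lp <- logpost(theta, eta)
  converged <- FALSE
  iter <- 0L
  H <- NULL
  repeat {
    iter <- iter + 1L
    pi_ <- stats::plogis(eta)
    w <- pmax(pi_ * (1 - pi_), 1e-12)
    resid <- y - pi_
    # score = A'(y - pi) - Q0 theta
    score <- numeric(d)
    score[seq_len(p)] <- drop(crossprod(X, resid)) -
      beta_prec * theta[seq_len(p)]
    if (spatial) {
      ru <- rowsum(resid, knot_index, reorder = TRUE)
      su <- numeric(m); su[as.integer(rownames(ru))] <- ru
      score[p + seq_len(m)] <- su - drop(Qu %*% theta[p + seq_len(m)])
    }
    # Hessian = Q0 + A' W A
    H <- matrix(0, d, d)
    H[seq_len(p), seq_len(p)] <- crossprod(X, X * w) +
      diag(beta_prec, p)
    if (spatial) {
      XWZ <- rowsum(X * w, knot_index, reorder = TRUE)
      XWZfull <- matrix(0, m, p)
      XWZfull[as.integer(rownames(XWZ)), ] <- XWZ
      H[seq_len(p), p + seq_len(m)] <- t(XWZfull)
      H[p + seq_len(m), seq_len(p)] <- XWZfull
      wz <- rowsum(w, knot_index, reorder = TRUE)
      wzfull <- numeric(m); wzfull[as.integer(rownames(wz))] <- wz
      H[p + seq_len(m), p + seq_len(m)] <- Qu + diag(wzfull, m)
    }
    if (max(abs(score)) < tol) { converged <- TRUE; break }
    if (iter > max_iter) break
    step <- drop(solve(H, score))
    # halve the step until the log posterior improves
    sf <- 1
    repeat {
      cand <- theta + sf * step
      eta_c <- eta_of(cand)
      lp_c <- logpost(cand, eta_c)
      if (lp_c >= lp - 1e-12 || sf < 1e-4) break
      sf <- sf / 2
    }
    theta <- cand; eta <- eta_c; lp <- lp_c
  }
  if (!converged && iter > max_iter)
    warning("Newton-Raphson did not converge in ", max_iter,
            " iterations (max score ", signif(max(abs(score)), 3), ")")
  cholH <- chol(H)
  Hinv <- chol2inv(cholH)
  # Laplace log marginal likelihood:
  #   l(mode) + log prior(mode) + 0.5 logdet Q0 - 0.5 logdet H
  log_ml <- lp + 0.5 * logdet_Q0 - 0.5 * 2 * sum(log(diag(cholH)))
  separation <- any(abs(theta[seq_len(p)]) > 8)
  list(mode = theta, chol_prec = cholH, diag_cov = diag(Hinv),
       cov = Hinv, log_ml = log_ml, converged = converged,
       iterations = iter, separation = separation, p = p, m = m)
}

#' Hyperparameter grid with normalized posterior weights
#'
#' Lays out a log-spaced grid over (sigma, rho), runs
#' \code{\link{laplace_fit}} at every node (warm-started from the previous
#' node) and converts the Laplace log marginal likelihoods plus independent
#' log-uniform hyperpriors into normalized weights (rescaled by the maximum
#' before exponentiating, so underflow cannot zero the grid).
#'
#' @inheritParams laplace_fit
#' @param sigma_bounds log-uniform prior bounds for the field SD (default
#'   0.1 to 1.5, a sensible range for logistic regression).
#' @param rho_bounds log-uniform prior bounds for the range (km); default
#'   0.1x to 10x the median inter-knot distance.
#' @param grid_res c(n_sigma, n_rho) nodes per axis (>= 1; >= 3 for a
#'   proper grid).
#' @return list: \code{hyper} data.frame (sigma, rho, log_ml, weight) and
#'   \code{fits} (per-node \code{laplace_fit} results).
#' @export
hyperparameter_grid <- function(y, X, knots, knot_index,
                                sigma_bounds = c(0.1, 1.5),
                                rho_bounds = NULL, grid_res = c(7, 7),
                                beta_prec = 1e-3, jitter = 1e-8,
                                tol = 1e-6, max_iter = 100) {
  if (is.null(rho_bounds)) {
    med <- stats::median(pairwise_dist(knots)[upper.tri(diag(nrow(knots)))])
    rho_bounds <- c(0.1, 10) * med
  }
  grid_res <- rep(grid_res, length.out = 2)
  sig <- exp(seq(log(sigma_bounds[1]), log(sigma_bounds[2]),
                 length.out = grid_res[1]))
  rho <- exp(seq(log(rho_bounds[1]), log(rho_bounds[2]),
                 length.out = grid_res[2]))
  nodes <- expand.grid(sigma = sig, rho = rho)
  fits <- vector("list", nrow(nodes))
  start <- NULL
  for (i in seq_len(nrow(nodes))) {
    fits[[i]] <- laplace_fit(y, X, knots, knot_index,
                             sigma = nodes$sigma[i], rho = nodes$rho[i],
                             beta_prec = beta_prec, jitter = jitter,
                             start = start, tol = tol, max_iter = max_iter)
    start <- fits[[i]]$mode
  }
  log_ml <- vapply(fits, `[[`, 0, "log_ml")
  # log-uniform prior is flat on the log-spaced grid: weights from log_ml
  lw <- log_ml - max(log_ml)
  w <- exp(lw); w <- w / sum(w)
  list(hyper = data.frame(sigma = nodes$sigma, rho = nodes$rho,
                          log_ml = log_ml, weight = w),
       fits = fits)
}

## ---- Gaussian-mixture marginals -------------------------------------------

mixture_quantile <- function(p, w, mu, sd) {
  lo <- min(mu - 6 * sd); hi <- max(mu + 6 * sd)
  f <- function(q) sum(w * stats::pnorm(q, mu, sd)) - p
  stats::uniroot(f, c(lo, hi), tol = 1e-9)$root
}

mixture_mode <- function(w, mu, sd, npoints = 512) {
  g <- seq(min(mu - 4 * sd), max(mu + 4 * sd), length.out = npoints)
  dens <- vapply(g, function(q) sum(w * stats::dnorm(q, mu, sd)), 0)
  g[which.max(dens)]
}

#' Posterior marginals of the fixed-effect coefficients
#'
#' Gaussian-mixture marginals over the hyperparameter grid: each node
#' contributes its conditional Gaussian (mode, marginal SD from the inverse
#' negative Hessian) with the node's weight. Reports the posterior mean,
#' SD, mode (highest-density point of the mixture on a 512-point grid) and
#' equal-tailed 90\% credible interval, both on the logit and odds scales.
#'
#' @param fitted a \code{glgm} fit (or the list from
#'   \code{\link{hyperparameter_grid}} plus \code{weights}).
#' @return data.frame, one row per coefficient.
#' @export
coefficient_marginals <- function(fitted) {
  fits <- fitted$fits
  w <- fitted$hyper$weight
  p <- fits[[1]]$p
  cn <- fitted$coef_names
  if (is.null(cn)) cn <- paste0("beta", seq_len(p) - 1L)
  out <- lapply(seq_len(p), function(j) {
    mu <- vapply(fits, function(f) f$mode[j], 0)
    sd <- sqrt(vapply(fits, function(f) f$diag_cov[j], 0))
    mean_j <- sum(w * mu)
    var_j <- sum(w * (sd^2 + mu^2)) - mean_j^2
    data.frame(name = cn[j], mean = mean_j, sd = sqrt(var_j),
               mode = mixture_mode(w, mu, sd),
               lo90 = mixture_quantile(0.05, w, mu, sd),
               hi90 = mixture_quantile(0.95, w, mu, sd))
  })
  out <- do.call(rbind, out)
  out$odds <- odds_from_logit(out$mean)
  out$odds_lo90 <- odds_from_logit(out$lo90)
  out$odds_hi90 <- odds_from_logit(out$hi90)
  out
}

#' Logit-scale to odds-scale conversion
#'
#' Exponentiates a posterior mean or credible-interval endpoint. Rounding
#' (2 decimals in the published tables) belongs to the report layer, not
#' here.
#' @param x logit-scale value(s).
#' @return \code{exp(x)}.
#' @examples odds_from_logit(0.32)   # 1.38 at 2 dp
#' @export
odds_from_logit <- function(x) {
  stopifnot(all(is.finite(x)))
  exp(x)
}

## ---- WAIC ------------------------------------------------------------------

#' WAIC from a matrix of pointwise log-likelihood draws
#'
#' \eqn{WAIC = -2 (lppd - p_{waic})} with
#' \eqn{lppd = \sum_i \log mean_s p(y_i | \theta_s)} and
#' \eqn{p_{waic} = \sum_i var_s \log p(y_i | \theta_s)}.
#'
#' @param loglik n_obs x n_samples matrix of \eqn{\log p(y_i|\theta_s)}.
#' @return list with \code{waic}, \code{lppd}, \code{p_waic} and the
#'   per-observation \code{pointwise} WAIC contributions.
#' @export
waic_from_loglik <- function(loglik) {
  loglik <- as.matrix(loglik)
  S <- ncol(loglik)
  if (S < 2) stop("WAIC needs at least 2 posterior samples")
  mx <- apply(loglik, 1, max)
  lppd_i <- mx + log(rowMeans(exp(loglik - mx)))
  p_i <- apply(loglik, 1, stats::var)
  pointwise <- -2 * (lppd_i - p_i)
  list(waic = sum(pointwise), lppd = sum(lppd_i), p_waic = sum(p_i),
       pointwise = pointwise)
}

draw_posterior <- function(fitted, nsim, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- fitted$hyper$weight
  counts <- drop(stats::rmultinom(1, nsim, w))
  d <- length(fitted$fits[[1]]$mode)
  draws <- matrix(0, d, nsim)
  node <- integer(nsim)
  pos <- 0L
  for (h in which(counts > 0)) {
    f <- fitted$fits[[h]]
    z <- matrix(stats::rnorm(d * counts[h]), d, counts[h])
    draws[, pos + seq_len(counts[h])] <- f$mode +
      backsolve(f$chol_prec, z)
    node[pos + seq_len(counts[h])] <- h
    pos <- pos + counts[h]
  }
  list(draws = draws, node = node)
}

#' Watanabe-Akaike information criterion of a fitted model
#'
#' Draws from the Gaussian-mixture posterior over the hyperparameter grid
#' and applies \code{\link{waic_from_loglik}} to the pointwise Bernoulli
#' log-likelihoods.
#'
#' @param fitted a \code{glgm} fit.
#' @param nsim number of posterior draws (default 1000, must be >= 2).
#' @param seed RNG seed for the draws.
#' @return list with \code{waic}, \code{lppd}, \code{p_waic}, \code{nsim}.
#' @export
waic <- function(fitted, nsim = 1000, seed = 1) {
  stopifnot(inherits(fitted, "glgm"))
  if (nsim < 2) stop("WAIC needs at least 2 posterior samples")
  dr <- draw_posterior(fitted, nsim, seed)
  p <- fitted$fits[[1]]$p
  eta <- fitted$X %*% dr$draws[seq_len(p), , drop = FALSE]
  if (fitted$spatial)
    eta <- eta + dr$draws[p + fitted$knot_index, , drop = FALSE]
  ll <- matrix(bernoulli_loglik(rep(fitted$y, ncol(eta)), eta),
               nrow = length(fitted$y))
  out <- waic_from_loglik(ll)
  out$nsim <- nsim
  out
}

## ---- main fitting function -------------------------------------------------

#' Fit a hierarchical Bayesian spatial logistic model
#'
#' The package's central model: a Bernoulli-logit regression for a rare
#' binary household outcome with a Matern (nu = 1) spatially correlated
#' random effect,
#' \deqn{y_i \sim Bernoulli(\pi_i), \quad logit(\pi_i) = x_i'\beta + u(s_i),
#'       \quad u \sim GMRF(0, \Sigma_{Matern}(\sigma, \rho)),}
#' fitted by Laplace approximation at each node of a log-spaced
#' \eqn{(\sigma, \rho)} grid and integrated over the grid (INLA-style
#' empirical-Bayes grid integration, with an independent dense Matern
#' engine rather than an SPDE mesh).
#'
#' @param formula model formula, e.g. \code{outcome ~ ppi + ndvi +
#'   dist_water}; an intercept is included unless removed explicitly.
#' @param data data.frame holding the outcome, the (scaled) covariates, the
#'   coordinates and, for the clustered field representation, a cluster id.
#' @param coords formula naming the coordinate columns (km), default
#'   \code{~ x + y}.
#' @param spatial include the spatial random effect? \code{FALSE} gives
#'   penalized (vague-ridge) logistic regression under the same engine.
#' @param field_at \code{"cluster"} ties the latent field to cluster
#'   centroids (one knot per cluster; accurate when the range is much
#'   larger than the cluster radius and far faster), \code{"location"} puts
#'   a knot at every observation location (dense, capped at
#'   \code{dense_limit}).
#' @param cluster name of the cluster-id column (for
#'   \code{field_at = "cluster"}).
#' @param sigma_bounds,rho_bounds,grid_res hyperparameter grid controls,
#'   see \code{\link{hyperparameter_grid}}.
#' @param beta_prec Gaussian prior precision of the fixed effects.
#' @param jitter covariance jitter policy, see
#'   \code{\link{build_covariance}}.
#' @param waic_nsim posterior draws for the WAIC (default 1000).
#' @param dense_limit refusal threshold for \code{field_at = "location"}.
#' @param seed seed for the WAIC draws.
#' @param tol,max_iter Newton-Raphson controls.
#' @return object of class \code{glgm}; see
#'   \code{\link{coefficient_marginals}}, \code{\link{waic}},
#'   \code{\link{predict.glgm}}.
#' @export
glgm <- function(formula, data, coords = ~ x + y, spatial = TRUE,
                 field_at = c("cluster", "location"), cluster = "cluster_id",
                 sigma_bounds = c(0.1, 1.5), rho_bounds = NULL,
                 grid_res = c(7, 7), beta_prec = 1e-3, jitter = 1e-8,
                 waic_nsim = 1000, dense_limit = 5000, seed = 1,
                 tol = 1e-6, max_iter = 100) {
  cl <- match.call()
  field_at <- match.arg(field_at)
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  cn <- colnames(X)
  coord_names <- all.vars(coords)

  knots <- NULL; knot_index <- NULL
  if (spatial) {
    if (!all(coord_names %in% names(data)))
      stop("coordinate columns not found: ", paste(coord_names, collapse = ", "))
    xy <- cbind(data[[coord_names[1]]], data[[coord_names[2]]])
    if (field_at == "cluster") {
      if (!cluster %in% names(data))
        stop("cluster column '", cluster, "' not found")
      cid <- factor(data[[cluster]])
      knots <- cbind(tapply(xy[, 1], cid, mean), tapply(xy[, 2], cid, mean))
      knot_index <- as.integer(cid)
    } else {
      if (nrow(xy) > dense_limit)
        stop("location-level field with ", nrow(xy), " points exceeds the ",
             "dense limit (", dense_limit, "); use field_at = 'cluster' ",
             "or thin the data")
      knots <- xy
      knot_index <- seq_len(nrow(xy))
    }
  }

  if (spatial) {
    hg <- hyperparameter_grid(y, X, knots, knot_index,
                              sigma_bounds = sigma_bounds,
                              rho_bounds = rho_bounds, grid_res = grid_res,
                              beta_prec = beta_prec, jitter = jitter,
                              tol = tol, max_iter = max_iter)
  } else {
    f <- laplace_fit(y, X, beta_prec = beta_prec, tol = tol,
                     max_iter = max_iter)
    hg <- list(hyper = data.frame(sigma = NA_real_, rho = NA_real_,
                                  log_ml = f$log_ml, weight = 1),
               fits = list(f))
  }

  fit <- structure(
    list(call = cl, formula = formula, terms = attr(mf, "terms"),
         y = as.numeric(y), X = X, coef_names = cn, n_obs = length(y),
         spatial = spatial, field_at = if (spatial) field_at else "none",
         knots = knots, knot_index = knot_index,
         coord_names = coord_names,
         hyper = hg$hyper, fits = hg$fits,
         beta_prec = beta_prec, jitter = jitter, seed = seed,
         scaled_design = isTRUE(attr(data, "scaled")),
         converged = all(vapply(hg$fits, `[[`, TRUE, "converged")),
         separation = any(vapply(hg$fits, `[[`, TRUE, "separation"))),
    class = "glgm")
  fit$marginals <- coefficient_marginals(fit)
  if (spatial) {
    w <- fit$hyper$weight
    hs <- lapply(c("sigma", "rho"), function(nm) {
      v <- fit$hyper[[nm]]
      mn <- sum(w * v)
      data.frame(name = nm, mean = mn, sd = sqrt(sum(w * v^2) - mn^2),
                 mode = v[which.max(w)])
    })
    fit$hyper_summary <- do.call(rbind, hs)
  }
  fit$waic <- waic(fit, nsim = waic_nsim, seed = seed)
  fit
}

#' @export
print.glgm <- function(x, ...) {
  cat("Hierarchical Bayesian", if (x$spatial) "spatial" else "(non-spatial)",
      "logistic model\n")
  cat("  ", x$n_obs, "observations,", sum(x$y), "positive;",
      length(x$coef_names), "fixed effects\n")
  if (x$spatial)
    cat("  field:", x$field_at, "knots (", nrow(x$knots), "),",
        nrow(x$hyper), "hyperparameter grid nodes\n")
  cat("  WAIC:", format(x$waic$waic, digits = 6), "\n")
  cat("\nPosterior means (logit scale):\n")
  print(round(stats::setNames(x$marginals$mean, x$marginals$name), 4))
  invisible(x)
}

#' @export
coef.glgm <- function(object, ...) {
  stats::setNames(object$marginals$mean, object$marginals$name)
}

#' @export
fitted.glgm <- function(object, ...) {
  # posterior-mode plug-in risk at the observation points
  best <- which.max(object$hyper$weight)
  f <- object$fits[[best]]
  eta <- drop(object$X %*% f$mode[seq_len(f$p)])
  if (object$spatial) eta <- eta + f$mode[f$p + object$knot_index]
  stats::plogis(eta)
}

#' Summarize a fitted spatial logistic model
#'
#' Coefficient table in the published layout: posterior marginal mean, SD
#' and mode on the logit scale, plus the odds-scale mean and 90\% credible
#' interval; field hyperparameters and WAIC underneath.
#' @param object a \code{glgm} fit; @param ... unused.
#' @export
summary.glgm <- function(object, ...) {
  structure(list(marginals = object$marginals,
                 hyper_summary = object$hyper_summary,
                 waic = object$waic, n_obs = object$n_obs,
                 n_pos = sum(object$y), spatial = object$spatial,
                 converged = object$converged,
                 separation = object$separation),
            class = "summary.glgm")
}

#' @export
print.summary.glgm <- function(x, ...) {
  tab <- x$marginals
  out <- data.frame(Mean = round(tab$mean, 2), SD = round(tab$sd, 2),
                    Mode = round(tab$mode, 2), Odds = round(tab$odds, 2),
                    `Odds 90% LL` = round(tab$odds_lo90, 2),
                    `Odds 90% UL` = round(tab$odds_hi90, 2),
                    check.names = FALSE, row.names = tab$name)
  print(out)
  if (!is.null(x$hyper_summary)) {
    hs <- x$hyper_summary
    cat(sprintf("Range (rho):  mean %.2f  sd %.2f  mode %.2f km\n",
                hs$mean[hs$name == "rho"], hs$sd[hs$name == "rho"],
                hs$mode[hs$name == "rho"]))
    cat(sprintf("Field SD (sigma):  mean %.2f  sd %.2f  mode %.2f\n",
                hs$mean[hs$name == "sigma"], hs$sd[hs$name == "sigma"],
                hs$mode[hs$name == "sigma"]))
  }
  cat(sprintf("WAIC: %.2f  (p_waic %.2f)  on %d observations (%d positive)\n",
              x$waic$waic, x$waic$p_waic, x$n_obs, x$n_pos))
  if (x$separation) cat("note: separation regularized by the prior\n")
  invisible(x)
}

#' Predict posterior risk at new locations
#'
#' Standard Gaussian-process conditioning of the latent field at the new
#' points given its posterior at the knots (per hyperparameter node),
#' combined with the fixed-effect posterior, then integrated over the grid
#' by seeded Monte Carlo on the mixture (default 2000 draws of the linear
#' predictor per point).
#'
#' @param object a \code{glgm} fit.
#' @param newdata data.frame with the model covariates (scaled with the
#'   same scaling map as the training design; a missing scale tag on a
#'   tagged model is rejected) and coordinate columns.
#' @param type \code{"response"} for posterior mean and SD of the risk
#'   \eqn{\pi}, \code{"link"} for the linear predictor's mixture mean/SD,
#'   \code{"field"} for the latent field u alone.
#' @param nsim Monte-Carlo draws for \code{type = "response"}.
#' @param seed RNG seed.
#' @param ... unused.
#' @return data.frame with \code{mean} and \code{sd}, one row per row of
#'   \code{newdata}.
#' @export
predict.glgm <- function(object, newdata, type = c("response", "link", "field"),
                         nsim = 2000, seed = 1, ...) {
  type <- match.arg(type)
  if (object$scaled_design && !isTRUE(attr(newdata, "scaled")))
    stop("model was fitted on a scaled design but newdata carries no ",
         "'scaled' unit tag; apply scale_covariates() with the same map")
  tt <- stats::delete.response(object$terms)
  Xs <- if (type == "field") NULL else
    stats::model.matrix(tt, stats::model.frame(tt, newdata))
  nstar <- nrow(newdata)
  w <- object$hyper$weight
  H <- length(object$fits)
  p <- object$fits[[1]]$p

  node_mean <- matrix(0, nstar, H)
  node_var <- matrix(0, nstar, H)
  for (h in seq_len(H)) {
    f <- object$fits[[h]]
    if (object$spatial) {
      xy_new <- cbind(newdata[[object$coord_names[1]]],
                      newdata[[object$coord_names[2]]])
      sigma <- object$hyper$sigma[h]; rho <- object$hyper$rho[h]
      S <- build_covariance(object$knots, sigma, rho, jitter = object$jitter)
      Sstar <- matern_cov(pairwise_dist(xy_new, object$knots), sigma, rho)
      dim(Sstar) <- c(nstar, nrow(object$knots))
      A <- Sstar %*% chol2inv(chol(S))          # n* x m conditioning weights
      v_cond <- pmax(sigma^2 - rowSums(A * Sstar), 0)
      Cmat <- if (type == "field")
        cbind(matrix(0, nstar, p), A) else cbind(Xs, A)
    } else {
      if (type == "field") stop("no latent field in a non-spatial model")
      Cmat <- Xs
      v_cond <- 0
    }
    node_mean[, h] <- drop(Cmat %*% f$mode)
    node_var[, h] <- rowSums((Cmat %*% f$cov) * Cmat) + v_cond
  }
  mix_mean <- drop(node_mean %*% w)
  mix_var <- drop((node_var + node_mean^2) %*% w) - mix_mean^2
  if (type %in% c("link", "field"))
    return(data.frame(mean = mix_mean, sd = sqrt(pmax(mix_var, 0))))
  # Monte-Carlo on the risk scale
  set.seed(seed)
  counts <- drop(stats::rmultinom(1, nsim, w))
  psum <- numeric(nstar); psum2 <- numeric(nstar)
  for (h in which(counts > 0)) {
    z <- matrix(stats::rnorm(nstar * counts[h]), nstar, counts[h])
    eta <- node_mean[, h] + sqrt(pmax(node_var[, h], 0)) * z
    pi_ <- stats::plogis(eta)
    psum <- psum + rowSums(pi_)
    psum2 <- psum2 + rowSums(pi_^2)
  }
  mean_pi <- psum / nsim
  var_pi <- pmax(psum2 / nsim - mean_pi^2, 0)
  data.frame(mean = mean_pi, sd = sqrt(var_pi))
}

#' Simulate outcomes from the posterior predictive distribution
#'
#' @param object a \code{glgm} fit; @param nsim number of replicate outcome
#'   vectors; @param seed RNG seed; @param ... unused.
#' @return n_obs x nsim matrix of 0/1 draws.
#' @export
simulate.glgm <- function(object, nsim = 1, seed = 1, ...) {
  dr <- draw_posterior(object, nsim, seed)
  p <- object$fits[[1]]$p
  eta <- object$X %*% dr$draws[seq_len(p), , drop = FALSE]
  if (object$spatial)
    eta <- eta + dr$draws[p + object$knot_index, , drop = FALSE]
  matrix(stats::rbinom(length(eta), 1, stats::plogis(eta)),
         nrow = object$n_obs)
}

#' Export the coefficient table as CSV (report layer, 2-decimal odds)
#' @param fitted a \code{glgm} fit; @param path output CSV.
#' @export
write_coefficient_table <- function(fitted, path) {
  tab <- fitted$marginals
  out <- data.frame(covariate = tab$name,
                    mean = round(tab$mean, 2), sd = round(tab$sd, 2),
                    mode = round(tab$mode, 2), odds = round(tab$odds, 2),
                    odds_lo90 = round(tab$odds_lo90, 2),
                    odds_hi90 = round(tab$odds_hi90, 2))
  if (!is.null(fitted$hyper_summary)) {
    hs <- fitted$hyper_summary
    out <- rbind(out, data.frame(covariate = c("range_rho", "sd_sigma"),
                                 mean = round(hs$mean, 2), sd = round(hs$sd, 2),
                                 mode = round(hs$mode, 2), odds = NA,
                                 odds_lo90 = NA, odds_hi90 = NA))
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
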