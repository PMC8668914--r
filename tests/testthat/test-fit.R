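test_that("the non-spatial limit reproduces penalized logistic regression", {
  # intercept-only, 12 successes in 100 trials: mode ~ log(12/88)
  y <- rep(c(1, 0), c(12, 88))
  f <- laplace_fit(y, matrix(1, 100, 1))
  expect_equal(f$mode, log(12 / 88), tolerance = 1e-2)
  expect_true(f$converged)
  # against the independent ridge-IRLS oracle on random small datasets
  set.seed(31)
  for (i in 1:5) {
    n <- 150
    X <- cbind(1, rnorm(n), rbinom(n, 1, 0.4))
    b <- c(-1, 0.8, -0.6)
    y <- rbinom(n, 1, plogis(drop(X %*% b)))
    expect_equal(laplace_fit(y, X)$mode, ridge_irls(y, X),
                 tolerance = 1e-4)
  }
  # rank-deficient design rejected
  expect_error(laplace_fit(y, cbind(1, X[, 2], X[, 2])), "rank")
})

test_that("a vanishing field SD collapses the spatial model to the non-spatial one", {
  dat <- survey_data(32, n_clusters = 30, households_per_cluster = 20,
                     extent = c(150, 80))$data
  fs <- glgm(outcome ~ ppi + ndvi + dist_water, dat,
             sigma_bounds = c(1e-6, 1e-6), rho_bounds = c(30, 30),
             grid_res = c(1, 1), waic_nsim = 10)
  fn <- glgm(outcome ~ ppi + ndvi + dist_water, dat, spatial = FALSE,
             waic_nsim = 10)
  expect_equal(coef(fs), coef(fn), tolerance = 1e-4)
})

test_that("complete separation is regularized by the prior and flagged", {
  y <- rep(0, 120)
  f <- laplace_fit(y, matrix(1, 120, 1))
  expect_true(is.finite(f$mode))
  expect_lt(f$mode, -4)
  expect_true(f$separation)
})

test_that("hyperparameter grid weights normalize and degenerate correctly", {
  dat <- survey_data(33, n_clusters = 25, households_per_cluster = 15,
                     extent = c(120, 60))$data
  fit <- glgm(outcome ~ ppi + dist_water, dat, grid_res = c(3, 3),
              waic_nsim = 10)
  expect_equal(sum(fit$hyper$weight), 1, tolerance = 1e-12)
  single <- glgm(outcome ~ ppi + dist_water, dat, grid_res = c(1, 1),
                 sigma_bounds = c(1, 1), rho_bounds = c(30, 30),
                 waic_nsim = 10)
  expect_identical(single$hyper$weight, 1)
})

test_that("coefficient marginals are exact Gaussian mixtures", {
  # single node: CI is mean +/- z_0.95 * SD
  one <- fake_mixture_fit(0.7, 0.09, 1)
  m <- coefficient_marginals(one)
  expect_equal(m$lo90, 0.7 - qnorm(0.95) * 0.3, tolerance = 1e-6)
  expect_equal(m$hi90, 0.7 + qnorm(0.95) * 0.3, tolerance = 1e-6)
  expect_equal(m$sd, 0.3, tolerance = 1e-6)
  # equal mixture of N(0,1) and N(2,1): mean exactly 1
  two <- fake_mixture_fit(c(0, 2), c(1, 1), c(0.5, 0.5))
  expect_equal(coefficient_marginals(two)$mean, 1.0)
  # random mixtures: quantiles match brute-force sampling
  set.seed(34)
  for (i in 1:3) {
    k <- 3
    mu <- rnorm(k); sd <- runif(k, 0.5, 2)
    w <- runif(k); w <- w / sum(w)
    mix <- fake_mixture_fit(mu, sd^2, w)
    m <- coefficient_marginals(mix)
    comp <- sample.int(k, 1e6, replace = TRUE, prob = w)
    draws <- rnorm(1e6, mu[comp], sd[comp])
    for (q in c(0.05, 0.95)) {
      qs <- quantile(draws, q, names = FALSE)
      dens <- sum(w * dnorm(qs, mu, sd))
      se <- sqrt(q * (1 - q) / 1e6) / dens
      got <- if (q == 0.05) m$lo90 else m$hi90
      expect_lt(abs(got - qs), 3 * se)
    }
  }
})

test_that("logit-to-odds conversion reproduces the published 2-dp odds", {
  expect_identical(odds_from_logit(0), 1)
  expect_equal(round(odds_from_logit(0.32), 2), 1.38)
  expect_equal(round(odds_from_logit(-1.43), 2), 0.24)
  expect_equal(round(odds_from_logit(0.82), 2), 2.27)
  expect_equal(round(odds_from_logit(-0.77), 2), 0.46)
  expect_equal(round(odds_from_logit(-2.12), 2), 0.12)
  expect_error(odds_from_logit(Inf), "finite")
})

test_that("WAIC follows the direct formula", {
  # explicit 3-sample toy posterior on 2 observations, hand arithmetic
  ll <- rbind(log(c(0.2, 0.3, 0.25)), log(c(0.9, 0.8, 0.85)))
  lppd <- log(mean(c(0.2, 0.3, 0.25))) + log(mean(c(0.9, 0.8, 0.85)))
  p_waic <- var(log(c(0.2, 0.3, 0.25))) + var(log(c(0.9, 0.8, 0.85)))
  got <- waic_from_loglik(ll)
  expect_equal(got$waic, -2 * (lppd - p_waic), tolerance = 1e-12)
  expect_equal(got$lppd, lppd, tolerance = 1e-12)
  expect_equal(got$p_waic, p_waic, tolerance = 1e-12)
  # degenerate posterior (identical samples): p_waic = 0, plug-in deviance
  ll0 <- cbind(log(c(0.2, 0.9)), log(c(0.2, 0.9)))
  got0 <- waic_from_loglik(ll0)
  expect_equal(got0$p_waic, 0)
  expect_equal(got0$waic, -2 * sum(log(c(0.2, 0.9))))
  # fewer than 2 samples rejected
  expect_error(waic_from_loglik(matrix(ll[, 1])), "at least 2")
  # invariant to observation order
  set.seed(35)
  llr <- matrix(log(runif(300, 0.01, 1)), 30)
  perm <- sample(30)
  expect_equal(waic_from_loglik(llr)$waic, waic_from_loglik(llr[perm, ])$waic)
})

test_that("posterior prediction follows Gaussian-process conditioning", {
  # balanced intercept-only data, vanishing field: risk 0.5 everywhere
  n <- 400
  d0 <- data.frame(outcome = rep(c(0, 1), n / 2), cluster_id = rep(1:20, 20),
                   x = runif(n, 0, 100), y = runif(n, 0, 50))
  f0 <- glgm(outcome ~ 1, d0, sigma_bounds = c(1e-6, 1e-6),
             rho_bounds = c(30, 30), grid_res = c(1, 1), waic_nsim = 10)
  pr <- predict(f0, data.frame(x = c(10, 90), y = c(25, 40)),
                nsim = 20000, seed = 2)
  expect_equal(pr$mean, c(0.5, 0.5), tolerance = 1e-3)

  # single-node location-level fit for exact conditioning identities
  dat <- survey_data(36, n_clusters = 20, households_per_cluster = 10,
                     extent = c(100, 60))$data
  fit <- glgm(outcome ~ ppi + dist_water, dat, field_at = "location",
              sigma_bounds = c(1, 1), rho_bounds = c(10, 10),
              grid_res = c(1, 1), waic_nsim = 10)
  # far from all data the field marginal reverts to N(0, sigma^2)
  far <- data.frame(ppi = 0.5, dist_water = 1, x = 1e4, y = 1e4)
  attr(far, "scaled") <- TRUE
  uf <- predict(fit, far, type = "field")
  expect_equal(uf$mean, 0, tolerance = 1e-3)
  expect_equal(uf$sd, 1, tolerance = 1e-3)
  # at an observed location the field mean equals that point's mode
  i <- 7
  at <- dat[i, c("ppi", "dist_water", "x", "y")]
  attr(at, "scaled") <- TRUE
  ui <- predict(fit, at, type = "field")
  mode_u <- fit$fits[[1]]$mode[fit$fits[[1]]$p + i]
  expect_equal(ui$mean, mode_u, tolerance = 1e-6)
  # unscaled newdata rejected via the unit tag
  bad <- dat[1:2, c("ppi", "dist_water", "x", "y")]
  attr(bad, "scaled") <- NULL
  expect_error(predict(fit, bad), "unit tag")
})

test_that("the Laplace chain is continuous in the hyperparameters", {
  dat <- survey_data(37, n_clusters = 30, households_per_cluster = 20,
                     extent = c(150, 80))$data
  mf <- model.frame(outcome ~ ppi + ndvi + dist_water, dat)
  y <- model.response(mf)
  X <- model.matrix(attr(mf, "terms"), mf)
  cid <- factor(dat$cluster_id)
  knots <- cbind(tapply(dat$x, cid, mean), tapply(dat$y, cid, mean))
  idx <- as.integer(cid)
  base <- laplace_fit(y, X, knots, idx, sigma = 1, rho = 30)
  pert <- laplace_fit(y, X, knots, idx, sigma = 1.01, rho = 30.3)
  rel <- abs(pert$mode[1:4] - base$mode[1:4]) /
    pmax(abs(base$mode[1:4]), 0.1)
  expect_lt(max(rel), 0.05)
})

test_that("posterior predictive simulation matches the fitted prevalence", {
  dat <- survey_data(38, n_clusters = 25, households_per_cluster = 20,
                     extent = c(120, 60))$data
  fit <- glgm(outcome ~ ppi + dist_water, dat, grid_res = c(3, 3),
              waic_nsim = 10)
  sim <- simulate(fit, nsim = 200, seed = 3)
  expect_equal(dim(sim), c(nrow(dat), 200))
  expect_true(all(sim %in% 0:1))
  obs <- mean(dat$outcome)
  expect_lt(abs(mean(sim) - obs), 0.05)
})
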