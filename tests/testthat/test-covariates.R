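test_that("PPI scoring is sum-then-lookup on the score table", {
  lk <- synthetic_ppi_lookup(100)
  ans <- data.frame(a = 15, b = 10, c = 15)    # total 40
  expect_equal(ppi_score(ans, lk), 0.40)
  expect_equal(ppi_score(data.frame(a = 0, b = 0), lk), 0)
  # random item vectors against the brute-force oracle
  set.seed(14)
  for (i in 1:25) {
    items <- matrix(sample(0:10, 50, replace = TRUE), 5, 10)
    colnames(items) <- paste0("q", 1:10)
    expected <- vapply(seq_len(5), function(r) {
      s <- sum(items[r, ])                      # brute force: sum then look up
      lk$likelihood[lk$score == s]
    }, numeric(1))
    expect_equal(ppi_score(items, lk), expected)
  }
  # contract: out-of-domain score, missing item, malformed table
  small <- ppi_lookup(0:10, seq(0, 1, length.out = 11))
  expect_error(ppi_score(data.frame(a = 5, b = 9), small), "outside")
  expect_error(ppi_score(data.frame(a = 1), lk, items = c("a", "b")),
               "missing")
  expect_error(ppi_lookup(c(0, 2), c(0, 1)), "contiguous")
  expect_error(ppi_lookup(0:1, c(0, 2)), "0, 1")
})

test_that("distance to water is the exact segment minimum", {
  seg <- list(rbind(c(3, -5), c(3, 5)))
  expect_equal(distance_to_water(cbind(0, 0), seg), 3)
  expect_equal(distance_to_water(cbind(3, -5), seg), 0)  # on a vertex
  expect_error(distance_to_water(cbind(0, 0), list()), "empty")
  # densification oracle: minimum over features sampled every metre
  set.seed(15)
  for (i in 1:100) {
    nseg <- sample(1:3, 1)
    feats <- lapply(seq_len(nseg), function(j)
      matrix(runif(4, 0, 8), 2, 2))
    p <- runif(2, 0, 8)
    dense <- do.call(rbind, lapply(feats, function(m) {
      k <- max(2, ceiling(polyline_length(m) / 0.001))
      t <- seq(0, 1, length.out = k)
      cbind(m[1, 1] + t * (m[2, 1] - m[1, 1]),
            m[1, 2] + t * (m[2, 2] - m[1, 2]))
    }))
    brute <- min(sqrt((dense[, 1] - p[1])^2 + (dense[, 2] - p[2])^2))
    expect_equal(distance_to_water(rbind(p), feats), brute,
                 tolerance = 1e-3)
  }
})

test_that("distance to water is rigid-motion invariant", {
  set.seed(16)
  pts <- cbind(runif(20, 0, 50), runif(20, 0, 50))
  feats <- list(cbind(runif(5, 0, 50), runif(5, 0, 50)),
                cbind(runif(3, 0, 50), runif(3, 0, 50)))
  d0 <- distance_to_water(pts, feats)
  for (i in 1:10) {
    th <- runif(1, 0, 2 * pi); tr <- runif(2, -100, 100)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    move <- function(m) sweep(m %*% t(R), 2, -tr)
    expect_equal(distance_to_water(move(pts), lapply(feats, move)), d0,
                 tolerance = 1e-9)
  }
})

test_that("points inside water polygons get distance zero", {
  lake <- structure(list(list(id = "lake",
    ring = rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10), c(0, 0)))),
    class = "polygon_set")
  d <- distance_to_water(rbind(c(5, 5), c(12, 5)), lake)
  expect_equal(d, c(0, 2))
})

test_that("raster extraction matches brute-force nearest-centre search", {
  set.seed(17)
  g <- raster_grid(matrix(rnorm(30), 5, 6), xll = 2, yll = 1, cellsize = 0.7)
  ctr <- cell_centers(g)
  vals <- as.vector(t(g$values))
  pts <- cbind(runif(200, 2, 2 + 6 * 0.7), runif(200, 1, 1 + 5 * 0.7))
  got <- extract_at_points(g, pts)
  brute <- vapply(seq_len(nrow(pts)), function(i) {
    vals[which.min((ctr$x - pts[i, 1])^2 + (ctr$y - pts[i, 2])^2)]
  }, numeric(1))
  expect_equal(as.numeric(got), brute)
  # constant raster extracts the constant
  gc <- raster_grid(matrix(7, 3, 3), 0, 0, 1)
  expect_equal(as.numeric(extract_at_points(gc, cbind(runif(10, 0, 3),
                                                      runif(10, 0, 3)))),
               rep(7, 10))
  # outside points: NA plus an error count, run continues
  out <- extract_at_points(g, rbind(c(-5, -5), c(2.1, 1.1)))
  expect_true(is.na(out[1]) && !is.na(out[2]))
  expect_equal(attr(out, "n_outside"), 1)
})

test_that("covariate scaling applies each factor exactly once", {
  raw <- data.frame(ppi_percent = 63, bio6 = 10, ndvi = 0.8,
                    dist_water_m = 2500)
  sc <- scale_covariates(raw)
  expect_equal(sc$ppi_percent, 0.63)   # percent -> fraction
  expect_equal(sc$bio6, 1.0)           # degC -> tens of degC
  expect_equal(sc$ndvi, 0.8)           # factor 1: unchanged
  expect_equal(sc$dist_water_m, 2.5)   # m -> km
  # idempotence guard: a second application raises
  expect_error(scale_covariates(sc), "already scaled")
  # explicit map naming an absent covariate is rejected
  expect_error(scale_covariates(raw, scaling = c(nope = 2)), "not in design")
  expect_error(scale_covariates(raw, scaling = c(bio6 = -1)), "> 0")
})
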