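test_that("haversine distances match closed forms", {
  expect_equal(haversine_km(10, 20, 10, 20), 0)
  expect_equal(haversine_km(0, 0, 0, 180), pi * 6371, tolerance = 1e-9)
  set.seed(5)
  a <- data.frame(lat = runif(10, -80, 80), lon = runif(10, -180, 180))
  b <- data.frame(lat = runif(10, -80, 80), lon = runif(10, -180, 180))
  expect_equal(haversine_km(a$lat, a$lon, b$lat, b$lon),
               haversine_km(b$lat, b$lon, a$lat, a$lon))
})

test_that("empirical variogram handles degenerate pairs", {
  two_same <- data.frame(lat = c(0, 0.5), lon = c(0, 0), indicator = c(1, 1))
  e <- empirical_variogram(two_same, max_lag = 100, n_bins = 2)
  expect_equal(e$gamma[e$n_pairs > 0], 0)
  two_diff <- data.frame(lat = c(0, 0.5), lon = c(0, 0), indicator = c(0, 1))
  e2 <- empirical_variogram(two_diff, max_lag = 100, n_bins = 2)
  expect_equal(e2$gamma[e2$n_pairs > 0], 0.5)  # (1/2)(1)^2
  expect_error(empirical_variogram(two_same[1, , drop = FALSE]),
               "insufficient")
})

test_that("empirical variogram equals a brute-force double loop", {
  set.seed(42)
  n <- 20
  pts <- data.frame(lat = runif(n, -5, 5), lon = runif(n, 100, 110),
                    indicator = rbinom(n, 1, 0.4))
  n_bins <- 8; max_lag <- 700
  e <- empirical_variogram(pts, max_lag = max_lag, n_bins = n_bins)
  ssq <- rep(0, n_bins); np <- integer(n_bins)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    h <- haversine_km(pts$lat[i], pts$lon[i], pts$lat[j], pts$lon[j])
    if (h > 0 && h <= max_lag) {
      b <- min(n_bins, floor(h / (max_lag / n_bins)) + 1L)
      np[b] <- np[b] + 1L
      ssq[b] <- ssq[b] + (pts$indicator[i] - pts$indicator[j])^2
    }
  }
  expect_equal(e$n_pairs, np)
  expect_equal(e$gamma[np > 0], (ssq / (2 * np))[np > 0])
  expect_true(all(is.na(e$gamma[np == 0])))
})

test_that("pair counts partition n(n-1)/2 and indicator gamma is bounded by 0.5", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 30
    pts <- data.frame(lat = runif(n, -10, 10), lon = runif(n, 50, 70),
                      indicator = rbinom(n, 1, 0.5))
    dmax <- max(haversine_matrix(pts$lat, pts$lon))
    e <- empirical_variogram(pts, max_lag = dmax * 1.001, n_bins = 10)
    expect_equal(sum(e$n_pairs), n * (n - 1) / 2)
    expect_true(all(e$gamma[!is.na(e$gamma)] <= 0.5 + 1e-12))
  }
})

test_that("model semi-variograms evaluate their closed forms", {
  sph <- variogram_model("spherical", 0, 1, 300)
  expect_equal(model_gamma(sph, 300), 1)
  expect_equal(model_gamma(sph, 600), 1)
  expect_equal(model_gamma(sph, 150), 1.5 * 0.5 - 0.5 * 0.5^3)
  ex <- variogram_model("exponential", 0, 1, 300)
  expect_equal(model_gamma(ex, 300), 1 - exp(-1))
  # gamma(0) = nugget; partial sill 0 gives a constant nugget for h > 0
  for (fam in variogram_families()) {
    m0 <- variogram_model(fam, 0.3, 0, 100)
    expect_equal(model_gamma(m0, 0), 0.3, info = fam)
    expect_equal(model_gamma(m0, c(50, 500)), c(0.3, 0.3), info = fam)
  }
  # bounded families reach nugget + partial sill beyond the range
  for (fam in c("spherical", "circular", "pentaspherical")) {
    m <- variogram_model(fam, 0.1, 0.4, 200)
    expect_equal(model_gamma(m, c(200, 1000)), c(0.5, 0.5), info = fam)
  }
  # matern with kappa 0.5 equals the exponential
  mt <- variogram_model("matern", 0, 1, 300, kappa = 0.5)
  expect_equal(model_gamma(mt, c(100, 300, 900)),
               model_gamma(ex, c(100, 300, 900)), tolerance = 1e-9)
})

make_emp <- function(model, lags = seq(20, 600, length.out = 15),
                     n_pairs = 100L) {
  emp <- data.frame(lag = lags, gamma = model_gamma(model, lags),
                    n_pairs = n_pairs)
  attr(emp, "max_lag") <- max(lags)
  class(emp) <- c("empirical_variogram", "data.frame")
  emp
}

test_that("fitting recovers parameters within 1% on noiseless model bins", {
  for (fam in c("spherical", "exponential", "gaussian")) {
    truth <- variogram_model(fam, 0.1, 0.4, 300)
    fit <- fit_variogram(make_emp(truth), fam)
    expect_true(fit$converged, info = fam)
    expect_equal(fit$nugget, 0.1, tolerance = 0.01, info = fam)
    expect_equal(fit$psill, 0.4, tolerance = 0.01, info = fam)
    expect_equal(fit$range_km, 300, tolerance = 0.01, info = fam)
    expect_lt(fit$rmse, 1e-6)
  }
})

test_that("a flat empirical variogram fits as pure nugget", {
  emp <- make_emp(variogram_model("spherical", 0.25, 0, 100))
  fit <- fit_variogram(emp, "spherical")
  expect_true(fit$converged)
  expect_equal(fit$nugget + fit$psill * 1e-6, 0.25, tolerance = 0.02)
  expect_lt(fit$psill, 0.01)
})

test_that("insufficient bins give a typed failure, never an exception", {
  emp <- make_emp(variogram_model("spherical", 0.1, 0.4, 300))
  emp$gamma <- NA_real_
  fit <- fit_variogram(emp, "spherical")
  expect_false(fit$converged)
  expect_match(attr(fit, "reason"), "insufficient-data")
  expect_equal(fit$rmse, Inf)
})

test_that("selection returns the generating family or an equal-RMSE fit", {
  truth <- variogram_model("spherical", 0.1, 0.4, 300)
  sel <- select_variogram(make_emp(truth))
  expect_false(sel$all_failed)
  best <- sel$model
  conv <- Filter(function(m) m$converged, sel$fits)
  expect_true(all(best$rmse <= vapply(conv, function(m) m$rmse, 0) + 1e-12))
  if (best$family != "spherical") {
    expect_equal(best$rmse, sel$fits$spherical$rmse, tolerance = 1e-6)
  }
  # single-family selection is that family
  one <- select_variogram(make_emp(truth), families = "exponential")
  expect_equal(one$model$family, "exponential")
})

test_that("selection over unusable input returns the all-failed flag", {
  emp <- data.frame(lag = c(10, 20), gamma = c(0.1, NA), n_pairs = c(5L, 0L))
  attr(emp, "max_lag") <- 20
  class(emp) <- c("empirical_variogram", "data.frame")
  sel <- select_variogram(emp)
  expect_true(sel$all_failed)
  expect_null(sel$model)
})

test_that("variogram dumps write a model card plus the binned table", {
  emp <- make_emp(variogram_model("spherical", 0.1, 0.4, 300))
  sel <- select_variogram(emp, families = c("spherical", "exponential"))
  f <- tempfile(fileext = ".tsv")
  write_variogram(emp, sel, f)
  lines <- readLines(f)
  expect_match(lines[1], "# model:")
  expect_equal(length(lines), nrow(emp) + 2)
})
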