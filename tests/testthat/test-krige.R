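sph01 <- function(nugget = 0) variogram_model("spherical", nugget, 1, 200)

test_that("kriging honours the unbiasedness constraint", {
  one <- data.frame(lat = 0, lon = 0, indicator = 1)
  expect_equal(as.numeric(krige_cell(5, 5, one, sph01())), 1)
  same <- data.frame(lat = c(0, 1, 2), lon = c(0, 1, 0),
                     indicator = c(0.4, 0.4, 0.4))
  expect_equal(as.numeric(krige_cell(0.5, 0.5, same, sph01())), 0.4)
})

test_that("weights sum to one and predictions stay within [0, 1]", {
  set.seed(8)
  pts <- data.frame(lat = runif(30, -1, 1), lon = runif(30, 100, 102),
                    indicator = rbinom(30, 1, 0.5))
  for (tl in list(c(0, 101), c(0.5, 100.5), c(-0.9, 101.9))) {
    p <- krige_cell(tl[1], tl[2], pts, sph01(0.05), neighborhood = 16)
    expect_equal(attr(p, "weights_sum"), 1, tolerance = 1e-8)
    expect_gte(as.numeric(p), 0)
    expect_lte(as.numeric(p), 1)
  }
})

test_that("kriging is exact at data points when the nugget is zero", {
  pts <- data.frame(lat = c(0, 0.5, 1.2), lon = c(0, 0.8, 0.3),
                    indicator = c(1, 0, 1))
  for (i in 1:3) {
    expect_equal(as.numeric(krige_cell(pts$lat[i], pts$lon[i], pts, sph01())),
                 pts$indicator[i], tolerance = 1e-10)
  }
})

test_that("coincident presence and pseudo-absence points are handled", {
  both <- data.frame(lat = c(0, 0, 1), lon = c(0, 0, 1),
                     indicator = c(1, 0, 0))
  # zero nugget: coincident points collapse to their mean indicator
  p <- krige_cell(0, 0, both, sph01())
  expect_equal(as.numeric(p), 0.5, tolerance = 1e-10)
  # positive nugget: solvable directly, probability strictly below 1
  p2 <- krige_cell(0, 0, both, sph01(0.2))
  expect_lt(as.numeric(p2), 1)
  expect_gt(as.numeric(p2), 0)
})

test_that("local kriging matches an independent dense solve of the system", {
  set.seed(12)
  pts <- data.frame(lat = c(0, 0.5, 1.2, -0.4, 0.9, 0.1),
                    lon = c(0, 0.8, 0.3, 0.5, -0.6, 1.4),
                    indicator = c(1, 0, 1, 0, 0, 1))
  targets <- list(c(0.4, 0.4), c(-0.2, 0.9), c(1.0, 0.0))
  models <- list(sph01(0), sph01(0.1),
                 variogram_model("exponential", 0.05, 0.6, 150),
                 variogram_model("matern", 0.02, 0.8, 120, kappa = 1.5))
  for (m in models) for (tl in targets) {
    mine <- as.numeric(krige_cell(tl[1], tl[2], pts, m))
    D <- haversine_matrix(pts$lat, pts$lon)
    G <- model_gamma(m, D); diag(G) <- 0
    g0 <- model_gamma(m, haversine_km(tl[1], tl[2], pts$lat, pts$lon))
    A <- rbind(cbind(G, 1), c(rep(1, 6), 0))
    sol <- solve(A, c(g0, 1))
    dense <- min(max(sum(sol[1:6] * pts$indicator), 0), 1)
    expect_equal(mine, dense, tolerance = 1e-10,
                 info = paste(m$family, paste(tl, collapse = ",")))
  }
})

test_that("probabilities decay with distance from a dense presence cluster", {
  set.seed(31)
  pts <- rbind(
    data.frame(lat = runif(15, -0.2, 0.2), lon = runif(15, 99.8, 100.2),
               indicator = 1),
    data.frame(lat = runif(15, 4.8, 5.2), lon = runif(15, 104.8, 105.2),
               indicator = 0)
  )
  m <- sph01(0.02)
  along <- seq(0, 5, by = 1)
  probs <- vapply(along, function(s) {
    as.numeric(krige_cell(s, 100 + s, pts, m))
  }, numeric(1))
  expect_true(all(diff(probs) <= 1e-9))
  expect_gt(probs[1], 0.9)
  expect_lt(probs[length(probs)], 0.1)
})

test_that("a region-year without presences falls back to zero everywhere", {
  g <- tiny_grid()
  region <- region_specs()[region_specs()$name == "indian", ]
  pts <- data.frame(cell_id = g$cells$cell_id, lat = g$cells$lat,
                    lon = g$cells$lon, year = 1998L, indicator = 0L)
  frag <- krige_region(region, 1998, pts, g)
  expect_true(all(frag$prob == 0))
  expect_true(all(frag$provenance == "zero-fallback"))
})

test_that("merging averages overlapping fragments and keeps singletons", {
  f1 <- data.frame(cell_id = c(1L, 2L), lat = 0, lon = 0, year = 1998L,
                   prob = c(0.4, 0.8), provenance = "kriged")
  f2 <- data.frame(cell_id = 1L, lat = 0, lon = 0, year = 1998L,
                   prob = 0.6, provenance = "kriged")
  f3 <- data.frame(cell_id = 3L, lat = 0, lon = 0, year = 1998L,
                   prob = 0.9, provenance = "kriged")
  out <- merge_overlaps(list(f1, f2, f3))
  expect_equal(out$prob[out$cell_id == 1], 0.5)
  expect_equal(out$provenance[out$cell_id == 1], "averaged-overlap")
  expect_equal(out$prob[out$cell_id == 2], 0.8)
  expect_equal(out$provenance[out$cell_id == 2], "kriged")
  # three-fragment overlap takes the arithmetic mean
  f4 <- data.frame(cell_id = 9L, lat = 0, lon = 0, year = 1998L,
                   prob = c(0.3), provenance = "kriged")
  f5 <- f4; f5$prob <- 0.6
  f6 <- f4; f6$prob <- 0.9
  out2 <- merge_overlaps(list(f4, f5, f6))
  expect_equal(out2$prob, 0.6)
})

test_that("recovery error shrinks as sampling density increases", {
  maes <- vapply(c(0.06, 0.25, 0.9), function(p) {
    w <- dense_world(p_survey = p)
    krige_recovery_error(w, 1998, "indian")$mae_kriged
  }, numeric(1))
  expect_true(all(diff(maes) < 0))
})
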