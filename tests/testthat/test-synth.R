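# Small single-region configuration used across generator tests.
small_cfg <- function(seed = 3, ...) {
  synth_config(seed = seed, years = 1997:1999,
               regions = region_specs()[2, , drop = FALSE],
               cells_per_region = 24, clusters_per_region = 2,
               events = data.frame(year = 1998, region = "indian",
                                   cluster = 1, radius_km = 400,
                                   amplitude = 2, prob = 0.9),
               ...)
}

test_that("the generator is deterministic under a fixed seed", {
  w1 <- simulate_bleaching_study(small_cfg())
  w2 <- simulate_bleaching_study(small_cfg())
  expect_identical(w1$grid$cells, w2$grid$cells)
  expect_identical(w1$sst, w2$sst)
  expect_identical(w1$latent, w2$latent)
  expect_identical(w1$reports, w2$reports)
  w3 <- simulate_bleaching_study(small_cfg(seed = 4))
  expect_false(identical(w1$grid$cells, w3$grid$cells))
})

test_that("a single-cell grid has positive area and total area is additive", {
  cfg <- synth_config(seed = 1, regions = region_specs()[1, , drop = FALSE],
                      cells_per_region = 1, clusters_per_region = 1,
                      events = NULL)
  g <- make_reef_grid(cfg)
  expect_equal(nrow(g$cells), 1)
  expect_gt(g$cells$reef_area, 0)
  g2 <- make_reef_grid(small_cfg())
  expect_equal(reef_area_of(g2$cells$cell_id, g2), sum(g2$cells$reef_area))
})

test_that("without events every reef cell is a pseudo-absence every year", {
  cfg <- small_cfg(); cfg$events <- NULL
  g <- make_reef_grid(cfg)
  th <- simulate_sst(g, cfg)
  ann <- annual_max_dhw(dhw_matrix(th$times, th$sst, th$mmm), th$times)
  expect_true(all(ann$max_dhw == 0))
  for (y in cfg$years) {
    expect_equal(nrow(pseudo_absence_cells(ann, g, y)), nrow(g$cells))
  }
})

test_that("a +2 C, 84-day anomaly yields exactly 24 C-weeks with noise disabled", {
  cfg <- small_cfg(sst = list(mmm_base = 29, mmm_lat_coef = 0,
                              seasonal_amp = 0, noise_sd = 0, noise_cap = 0,
                              step_days = 3.5, event_duration_days = 84))
  g <- make_reef_grid(cfg)
  th <- simulate_sst(g, cfg)
  ann <- annual_max_dhw(dhw_matrix(th$times, th$sst, th$mmm), th$times)
  ev <- th$events[[1]]
  hit <- ann$year == 1998 & ann$cell_id %in% ev$cell_ids
  expect_equal(unique(ann$max_dhw[hit]), 24)
  expect_true(all(ann$max_dhw[!hit] == 0))
})

test_that("planted stress never leaks into the next calendar year", {
  w <- simulate_bleaching_study(small_cfg())
  ann <- annual_max_dhw(dhw_matrix(w$times, w$sst, w$mmm), w$times)
  expect_true(all(ann$max_dhw[ann$year != 1998] == 0))
  ev <- w$events[[1]]
  expect_true(all(ann$max_dhw[ann$year == 1998 &
                              ann$cell_id %in% ev$cell_ids] > 0))
})

test_that("zero partial sill gives a spatially constant latent field", {
  cfg <- small_cfg(latent = list(family = "exponential", nugget = 0,
                                 psill = 0, range_km = 250))
  g <- make_reef_grid(cfg)
  p <- simulate_latent_field(g, cfg, 1997, events = list())
  expect_lt(diff(range(p)), 1e-3)
})

test_that("the latent Gaussian field reproduces the configured variogram", {
  cfg <- synth_config(seed = 4, regions = region_specs()[2, , drop = FALSE])
  g <- make_reef_grid(cfg)
  L <- latent_chol(g, cfg)
  gam <- vapply(cfg$years, function(y) {
    z <- attr(simulate_latent_field(g, cfg, y, events = list(),
                                    chol_cov = L), "gaussian")
    empirical_variogram(data.frame(lat = g$cells$lat, lon = g$cells$lon,
                                   indicator = z),
                        max_lag = 1200, n_bins = 12)$gamma
  }, numeric(12))
  m <- do.call(variogram_model, c(cfg$latent, list()))
  lag <- (1:12 - 0.5) * 100
  diff_ <- abs(rowMeans(gam) - model_gamma(m, lag))
  expect_lt(max(diff_), 0.15)
  expect_lt(mean(diff_), 0.07)
})

test_that("reports saturate and vanish at the latent extremes", {
  sat <- small_cfg(base_rate = 1 - 1e-12, severity_noise = 0,
                   effort = list(centers_per_region = 1, decay_km = 1e9,
                                 p_near = 1, event_survey = 1))
  sat$events <- NULL
  w <- simulate_bleaching_study(sat)
  per_year <- table(w$reports$year)
  expect_true(all(per_year == nrow(w$grid$cells)))
  expect_true(all(w$reports$severity_code >= 2))
  none <- small_cfg(base_rate = 1e-12,
                    effort = list(centers_per_region = 1, decay_km = 1e9,
                                  p_near = 1, event_survey = 1))
  none$events <- NULL
  w0 <- simulate_bleaching_study(none)
  expect_true(all(w0$reports$severity_code == 0))
})

test_that("observed bleaching fraction matches the mean latent probability", {
  cfg <- synth_config(seed = 3, years = 1997:1999,
                      regions = region_specs()[2, , drop = FALSE],
                      cells_per_region = 150, clusters_per_region = 6,
                      base_rate = 0.3, events = NULL,
                      effort = list(centers_per_region = 1, decay_km = 1e9,
                                    p_near = 1, event_survey = 1))
  g <- make_reef_grid(cfg)
  p <- simulate_latent_field(g, cfg, 1998, events = list())
  rep98 <- sample_reports(p, g, cfg, 1998, events = list())
  frac <- mean(rep98$severity_code >= 1)
  mu <- mean(p)
  se <- sqrt(mu * (1 - mu) / nrow(rep98))
  expect_lt(abs(frac - mu), 3 * se)
})

test_that("reports carry a valid schema and fall inside their cells", {
  w <- simulate_bleaching_study(small_cfg())
  r <- w$reports
  expect_true(all(r$severity_code %in% c(0L, 1L, 2L, 3L)))
  expect_true(all(r$percent_bleached >= 0 & r$percent_bleached <= 100))
  expect_true(all(r$database_code == 2L))
  ids <- cell_index(r$latitude, r$longitude, w$grid)
  expect_true(all(ids %in% w$grid$cells$cell_id))
})
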